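#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` is the package's central container: a compartmentalized
#' reaction network with flux bounds (mmol/gDW/h), optional gene-protein-reaction
#' (GPR) rules, subsystem labels and a biomass objective. Joint multi-member
#' models additionally carry a `member_tag` per reaction/metabolite.
#'
#' @param id model identifier.
#' @param compartments data frame with columns `id`, `name`.
#' @param metabolites data frame with columns `id`, `name`, `compartment` and
#'   optionally `formula`, `charge`, `member_tag`.
#' @param reactions data frame with columns `id`, `lower_bound`, `upper_bound`
#'   and optionally `name`, `gpr` (boolean rule string over gene ids, e.g.
#'   `"g1 and (g2 or g3)"`), `subsystem`, `member_tag`.
#' @param stoich data frame with columns `reaction`, `metabolite`,
#'   `coefficient` (signed; negative = consumed).
#' @param genes data frame with column `id` and optionally `name`.
#' @param objective reaction id of the (biomass) objective.
#' @param validate run [validate_model()] on the result.
#'
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions, stoich,
                            genes = NULL, objective = NULL, validate = TRUE) {
  compartments <- .complete_df(compartments, list(id = NA_character_, name = ""))
  metabolites <- .complete_df(metabolites, list(
    id = NA_character_, name = "", compartment = NA_character_,
    formula = NA_character_, charge = NA_integer_, member_tag = NA_character_))
  reactions <- .complete_df(reactions, list(
    id = NA_character_, name = "", lower_bound = NA_real_, upper_bound = NA_real_,
    gpr = NA_character_, subsystem = NA_character_, member_tag = NA_character_))
  stoich <- .complete_df(stoich, list(
    reaction = NA_character_, metabolite = NA_character_, coefficient = NA_real_))
  if (is.null(genes)) genes <- data.frame(id = character(), name = character())
  genes <- .complete_df(genes, list(id = NA_character_, name = ""))
  m <- structure(list(
    id = id, compartments = compartments, metabolites = metabolites,
    reactions = reactions, stoich = stoich, genes = genes,
    objective = objective), class = "metabolic_model")
  if (validate) validate_model(m)
  m
}

.complete_df <- function(df, defaults) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- rep(defaults[[nm]], nrow(df))
    df[[nm]] <- switch(class(defaults[[nm]])[1],
                       character = as.character(df[[nm]]),
                       integer = as.integer(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       df[[nm]])
  }
  rownames(df) <- NULL
  df[names(defaults)]
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, compartment references, bound sanity
#' (`lower_bound <= upper_bound`, no NA/NaN), stoichiometry references,
#' resolvable objective, and that every GPR leaf is a declared gene.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with an informative error otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions; mets <- model$metabolites
  if (anyDuplicated(model$compartments$id))
    stop("duplicate compartment ids in model '", model$id, "'")
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rx$id))
    stop("duplicate reaction ids: ",
         paste(unique(rx$id[duplicated(rx$id)]), collapse = ", "))
  bad <- !mets$compartment %in% model$compartments$id
  if (any(bad))
    stop("metabolites reference undeclared compartments: ",
         paste(utils::head(mets$id[bad], 5), collapse = ", "))
  if (any(!is.finite(rx$lower_bound)) || any(!is.finite(rx$upper_bound)))
    stop("non-finite reaction bounds in: ",
         paste(utils::head(rx$id[!is.finite(rx$lower_bound) |
                                 !is.finite(rx$upper_bound)], 5), collapse = ", "))
  if (any(rx$lower_bound > rx$upper_bound))
    stop("lower_bound > upper_bound for: ",
         paste(utils::head(rx$id[rx$lower_bound > rx$upper_bound], 5),
               collapse = ", "))
  bad <- !model$stoich$metabolite %in% mets$id
  if (any(bad))
    stop("stoichiometry references undeclared metabolites: ",
         paste(utils::head(unique(model$stoich$metabolite[bad]), 5), collapse = ", "))
  bad <- !model$stoich$reaction %in% rx$id
  if (any(bad))
    stop("stoichiometry references undeclared reactions: ",
         paste(utils::head(unique(model$stoich$reaction[bad]), 5), collapse = ", "))
  empty <- setdiff(rx$id, unique(model$stoich$reaction))
  if (length(empty))
    stop("reactions with empty stoichiometry: ", paste(utils::head(empty, 5), collapse = ", "))
  if (!is.null(model$objective) && !model$objective %in% rx$id)
    stop("objective reaction '", model$objective, "' not found")
  # every GPR leaf must be a declared gene
  rules <- rx$gpr[!is.na(rx$gpr) & nzchar(rx$gpr)]
  if (length(rules)) {
    leaves <- unique(unlist(lapply(unique(rules), function(r) gpr_genes(parse_gpr(r)))))
    missing <- setdiff(leaves, model$genes$id)
    if (length(missing))
      stop("GPR rules reference undeclared genes: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  compartments: ", nrow(x$compartments),
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  genes: ", nrow(x$genes), "\n",
      "  objective: ", if (is.null(x$objective)) "<none>" else x$objective, "\n",
      sep = "")
  tags <- unique(stats::na.omit(x$reactions$member_tag))
  if (length(tags)) cat("  member tags: ", paste(tags, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build the sparse stoichiometric matrix S
#'
#' Rows are metabolites, columns reactions; entry (i, j) is the signed
#' coefficient of metabolite i in reaction j.
#'
#' @param model a validated `metabolic_model`.
#' @return a `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
build_stoichiometric_matrix <- function(model) {
  i <- match(model$stoich$metabolite, model$metabolites$id)
  j <- match(model$stoich$reaction, model$reactions$id)
  Matrix::sparseMatrix(
    i = i, j = j, x = model$stoich$coefficient,
    dims = c(nrow(model$metabolites), nrow(model$reactions)),
    dimnames = list(model$metabolites$id, model$reactions$id))
}

# ---- small accessors used across modules ----

#' Look up a reaction's stoichiometry as a named vector
#' @param model a `metabolic_model`.
#' @param rid reaction id.
#' @return named numeric vector (metabolite id -> coefficient).
#' @export
reaction_stoich <- function(model, rid) {
  s <- model$stoich[model$stoich$reaction == rid, , drop = FALSE]
  stats::setNames(s$coefficient, s$metabolite)
}

#' Set flux bounds on one or more reactions
#' @param model a `metabolic_model`.
#' @param rids reaction ids.
#' @param lb,ub new bounds, recycled along `rids`; `NA` leaves a bound as is.
#' @return the modified model.
#' @export
set_bounds <- function(model, rids, lb = NA, ub = NA) {
  ix <- match(rids, model$reactions$id)
  if (anyNA(ix)) stop("unknown reaction id(s): ",
                      paste(rids[is.na(ix)], collapse = ", "))
  lb <- rep_len(lb, length(ix)); ub <- rep_len(ub, length(ix))
  keep <- !is.na(lb); model$reactions$lower_bound[ix[keep]] <- lb[keep]
  keep <- !is.na(ub); model$reactions$upper_bound[ix[keep]] <- ub[keep]
  model
}

#' Identify boundary exchange reactions
#'
#' An exchange (boundary) reaction touches exactly one metabolite.
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  tab <- table(model$stoich$reaction)
  names(tab)[tab == 1]
}
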