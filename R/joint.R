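# Host + multi-microbe joint-model assembly: member tagging, interspace
# transport creation (met[e] <-> met[u] with the [-I; I] block), shared lumen
# unification, the host body-fluid layer [b], futile-cycle pruning, and
# co-metabolite identification.

.HOST_TAG <- "Host"

#' Prefix all identifiers of a model with a member tag
#'
#' Reactions, metabolites, compartments (and genes, unless `prefix_genes` is
#' `FALSE`) are renamed `tag_id`; internal references stay consistent and the
#' `member_tag` columns are set. Tagging an already-tagged model with the same
#' tag is an error unless `idempotent` is `TRUE` (then it is a no-op).
#'
#' @param model a `metabolic_model`.
#' @param tag identifier (letters, digits, underscore; must not start with a
#'   digit).
#' @param prefix_genes prefix gene ids too (default `TRUE`; `FALSE`
#'   corresponds to merging gene namespaces across members).
#' @param idempotent if `TRUE`, re-tagging with the same tag returns the model
#'   unchanged instead of erroring.
#' @return the tagged `metabolic_model`.
#' @export
tag_model <- function(model, tag, prefix_genes = TRUE, idempotent = FALSE) {
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", tag)) stop("invalid member tag: ", tag)
  already <- !anyNA(model$reactions$member_tag) &&
    nrow(model$reactions) > 0 && all(model$reactions$member_tag == tag)
  if (already) {
    if (idempotent) return(model)
    stop("model is already tagged '", tag, "'")
  }
  p <- function(x) paste0(tag, "_", x)
  model$compartments$id <- p(model$compartments$id)
  model$metabolites$id <- p(model$metabolites$id)
  model$metabolites$compartment <- p(model$metabolites$compartment)
  model$metabolites$member_tag <- tag
  old_rxn <- model$reactions$id
  model$reactions$id <- p(old_rxn)
  model$reactions$member_tag <- tag
  model$stoich$reaction <- p(model$stoich$reaction)
  model$stoich$metabolite <- p(model$stoich$metabolite)
  if (!is.null(model$objective)) model$objective <- p(model$objective)
  if (prefix_genes && nrow(model$genes)) {
    gmap <- stats::setNames(p(model$genes$id), model$genes$id)
    model$genes$id <- unname(gmap)
    model$reactions$gpr <- vapply(model$reactions$gpr, function(r) {
      if (is.na(r)) return(NA_character_)
      .gpr_deparse(.gpr_rename(parse_gpr(r), gmap))
    }, character(1))
  }
  if (anyDuplicated(model$reactions$id) || anyDuplicated(model$metabolites$id))
    stop("id collision after tagging with '", tag, "'")
  model$id <- p(model$id)
  model
}

.gpr_rename <- function(tree, map) {
  if (tree$op == "gene") {
    if (!is.na(map[tree$gene])) tree$gene <- unname(map[tree$gene])
    return(tree)
  }
  tree$args <- lapply(tree$args, .gpr_rename, map = map)
  tree
}

.gpr_deparse <- function(tree) {
  if (tree$op == "gene") return(tree$gene)
  parts <- vapply(tree$args, function(a) {
    s <- .gpr_deparse(a)
    if (a$op != "gene" && a$op != tree$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = if (tree$op == "and") " and " else " or ")
}

.base_met_id <- function(met_ids, tag, comp_suffix) {
  out <- sub(paste0("^", tag, "_"), "", met_ids)
  sub(paste0("_", comp_suffix, "$"), "", out)
}

#' Create interspace transport reactions toward the shared lumen
#'
#' For each of the n metabolites in the member's extracellular compartment, a
#' lumen twin `base_u` (shared, untagged namespace) and one reversible
#' transport reaction `met[e] <-> met[u]` with coefficients -1/+1 are added,
#' so the new stoichiometric columns restricted to the ([e]; [u]) rows form
#' the block `[-I; I]`.
#'
#' @param model a (typically tagged) `metabolic_model` with an extracellular
#'   compartment whose id is `"e"` or `"<tag>_e"`.
#' @param tag member tag used to name the reactions
#'   (`<tag>_IEX_<base>_u_tr`).
#' @param bound transport bound magnitude (default 1000).
#' @return list with `model` (extended) and `registry` (data frame: reaction,
#'   member, base, extracellular met, lumen met).
#' @export
create_interspace <- function(model, tag, bound = 1000) {
  ecomp <- intersect(c(paste0(tag, "_e"), "e"), model$compartments$id)
  if (!length(ecomp))
    stop("model has no extracellular compartment ('e' or '", tag, "_e')")
  ecomp <- ecomp[1]
  emets <- model$metabolites$id[model$metabolites$compartment == ecomp]
  if (!length(emets))
    return(list(model = model,
                registry = data.frame(reaction = character(), member = character(),
                                      base = character(), met_e = character(),
                                      met_u = character(), stringsAsFactors = FALSE)))
  base <- .base_met_id(emets, tag, "e")
  met_u <- paste0(base, "_u")
  rxn_id <- paste0(tag, "_IEX_", base, "_u_tr")
  if (!"u" %in% model$compartments$id)
    model$compartments <- rbind(model$compartments,
                                data.frame(id = "u", name = "shared lumen"))
  new_u <- !met_u %in% model$metabolites$id
  if (any(new_u))
    model$metabolites <- rbind(model$metabolites, data.frame(
      id = met_u[new_u], name = paste0(base[new_u], " (lumen)"), compartment = "u",
      formula = NA, charge = NA, member_tag = NA, stringsAsFactors = FALSE))
  model$reactions <- rbind(model$reactions, data.frame(
    id = rxn_id, name = paste0(base, " interspace transport (", tag, ")"),
    lower_bound = -bound, upper_bound = bound, gpr = NA,
    subsystem = "Interspace exchange", member_tag = tag, stringsAsFactors = FALSE))
  model$stoich <- rbind(model$stoich,
                        data.frame(reaction = rxn_id, metabolite = emets,
                                   coefficient = -1, stringsAsFactors = FALSE),
                        data.frame(reaction = rxn_id, metabolite = met_u,
                                   coefficient = 1, stringsAsFactors = FALSE))
  list(model = model,
       registry = data.frame(reaction = rxn_id, member = tag, base = base,
                             met_e = emets, met_u = met_u, stringsAsFactors = FALSE))
}

#' Assemble a host + multi-microbe joint co-metabolic model
#'
#' Each member model is tagged, its boundary exchanges on the extracellular
#' compartment are removed (the shared lumen becomes the only outside), and
#' interspace transports to the lumen are created; lumen metabolites with the
#' same base id are unified across members. The host (optional) additionally
#' receives a body-fluid compartment `b`: its original boundary exchanges are
#' relocated there behind reversible `[e] <-> [b]` transports, so host
#' nutrition flows through `b` while secretion to the microbiota flows through
#' the lumen. The lumen itself gets one boundary exchange per metabolite
#' (efflux open, influx closed unless listed in `diet`).
#'
#' @param members list of microbe `metabolic_model`s (untagged).
#' @param biomass_ids character vector, one biomass reaction id per member.
#' @param tags unique member tags, same length as `members`.
#' @param host optional host `metabolic_model` (untagged); tagged `"Host"`.
#' @param host_biomass host biomass reaction id (defaults to `host$objective`).
#' @param merge_genes if `TRUE`, gene namespaces are merged (ids not
#'   prefixed); default `FALSE`.
#' @param remove_futile if `TRUE`, run [remove_futile_cycles()] on the result.
#' @param diet named numeric vector: lumen influx capacity per base metabolite
#'   id (e.g. `c(glc = 10)`); everything else has influx 0.
#' @param bound default bound magnitude for created reactions (default 1000).
#' @return a `joint_model` (also a `metabolic_model`) with extra fields:
#'   `members` (data frame tag/biomass/is_host), `interspace` (registry),
#'   `lumen_exchanges` (reaction ids).
#' @export
merge_models <- function(members, biomass_ids, tags, host = NULL,
                         host_biomass = NULL, merge_genes = FALSE,
                         remove_futile = FALSE, diet = NULL, bound = 1000) {
  stopifnot(length(members) == length(biomass_ids),
            length(members) == length(tags))
  if (anyDuplicated(tags)) stop("duplicate member tags")
  if (.HOST_TAG %in% tags) stop("tag '", .HOST_TAG, "' is reserved for the host")
  for (i in seq_along(members))
    if (!biomass_ids[i] %in% members[[i]]$reactions$id)
      stop("biomass reaction '", biomass_ids[i], "' not found in member '", tags[i], "'")

  pieces <- list(); registry <- list(); memtab <- list()
  prep_member <- function(m, tag, biomass) {
    tm <- tag_model(m, tag, prefix_genes = !merge_genes)
    # boundary exchanges on [e] are removed: the lumen is the only outside
    ex <- exchange_reactions(tm)
    emets <- tm$metabolites$id[tm$metabolites$compartment == paste0(tag, "_e")]
    ex_e <- ex[vapply(ex, function(r)
      all(tm$stoich$metabolite[tm$stoich$reaction == r] %in% emets), logical(1))]
    if (length(ex_e)) tm <- subset_reactions(tm, setdiff(tm$reactions$id, ex_e))
    ci <- create_interspace(tm, tag, bound = bound)
    registry[[tag]] <<- ci$registry
    memtab[[tag]] <<- data.frame(tag = tag, biomass = paste0(tag, "_", biomass),
                                 is_host = identical(tag, .HOST_TAG),
                                 stringsAsFactors = FALSE)
    ci$model
  }
  if (!is.null(host)) {
    if (is.null(host_biomass)) host_biomass <- host$objective
    if (is.null(host_biomass)) stop("host model needs a biomass/objective reaction")
    th <- tag_model(host, .HOST_TAG, prefix_genes = !merge_genes)
    th <- .add_body_fluid(th, bound = bound)
    ci <- create_interspace(th, .HOST_TAG, bound = bound)
    registry[[.HOST_TAG]] <- ci$registry
    memtab[[.HOST_TAG]] <- data.frame(tag = .HOST_TAG,
                                      biomass = paste0(.HOST_TAG, "_", host_biomass),
                                      is_host = TRUE, stringsAsFactors = FALSE)
    pieces[[.HOST_TAG]] <- ci$model
  }
  for (i in seq_along(members))
    pieces[[tags[i]]] <- prep_member(members[[i]], tags[i], biomass_ids[i])

  # concatenate; lumen metabolites/compartment are shared and deduplicated
  cmb <- function(f) do.call(rbind, lapply(pieces, `[[`, f))
  comp <- unique(cmb("compartments"))
  mets <- cmb("metabolites"); mets <- mets[!duplicated(mets$id), , drop = FALSE]
  rxns <- cmb("reactions"); stoich <- cmb("stoich"); genes <- unique(cmb("genes"))
  rownames(comp) <- rownames(mets) <- rownames(rxns) <- rownames(stoich) <- NULL
  if (anyDuplicated(rxns$id))
    stop("reaction id collision across members: ",
         paste(utils::head(rxns$id[duplicated(rxns$id)], 5), collapse = ", "))

  # lumen boundary: efflux open, influx closed unless in `diet`
  lumen <- mets$id[mets$compartment == "u"]
  lumen_base <- sub("_u$", "", lumen)
  influx <- rep(0, length(lumen))
  if (!is.null(diet)) {
    hit <- match(lumen_base, names(diet))
    influx[!is.na(hit)] <- diet[hit[!is.na(hit)]]
  }
  lex <- paste0("EX_", lumen)
  rxns <- rbind(rxns, data.frame(
    id = lex, name = paste0(lumen_base, " lumen exchange"),
    lower_bound = -influx, upper_bound = bound, gpr = NA,
    subsystem = "Lumen exchange", member_tag = NA, stringsAsFactors = FALSE))
  stoich <- rbind(stoich, data.frame(reaction = lex, metabolite = lumen,
                                     coefficient = -1, stringsAsFactors = FALSE))

  memtab <- do.call(rbind, memtab); rownames(memtab) <- NULL
  objective <- if (!is.null(host)) memtab$biomass[memtab$is_host][1] else memtab$biomass[1]
  joint <- metabolic_model(
    id = paste0("joint_", paste(tags, collapse = "_"),
                if (!is.null(host)) "_host" else ""),
    compartments = comp, metabolites = mets, reactions = rxns, stoich = stoich,
    genes = genes, objective = objective)
  joint$members <- memtab
  joint$interspace <- do.call(rbind, registry); rownames(joint$interspace) <- NULL
  joint$lumen_exchanges <- lex
  class(joint) <- c("joint_model", class(joint))
  if (remove_futile) joint <- remove_futile_cycles(joint)
  joint
}

# relocate host boundary exchanges behind a body-fluid layer [b]:
# met[e] -EX-> outside   becomes   met[e] <-> met[b] -EX-> outside
.add_body_fluid <- function(th, bound = 1000) {
  tag <- .HOST_TAG
  ecomp <- paste0(tag, "_e")
  emets <- th$metabolites$id[th$metabolites$compartment == ecomp]
  ex <- exchange_reactions(th)
  ex_e <- ex[vapply(ex, function(r)
    all(th$stoich$metabolite[th$stoich$reaction == r] %in% emets), logical(1))]
  if (!length(ex_e)) return(th)
  th$compartments <- rbind(th$compartments,
                           data.frame(id = paste0(tag, "_b"), name = "host body fluid"))
  for (r in ex_e) {
    met_e <- th$stoich$metabolite[th$stoich$reaction == r]
    base <- .base_met_id(met_e, tag, "e")
    met_b <- paste0(tag, "_", base, "_b")
    th$metabolites <- rbind(th$metabolites, data.frame(
      id = met_b, name = paste0(base, " (body fluid)"), compartment = paste0(tag, "_b"),
      formula = NA, charge = NA, member_tag = tag, stringsAsFactors = FALSE))
    tr <- paste0(tag, "_BFT_", base, "_b_tr")
    th$reactions <- rbind(th$reactions, data.frame(
      id = tr, name = paste0(base, " body-fluid transport"),
      lower_bound = -bound, upper_bound = bound, gpr = NA,
      subsystem = "Body-fluid transport", member_tag = tag, stringsAsFactors = FALSE))
    th$stoich <- rbind(th$stoich,
                       data.frame(reaction = tr, metabolite = c(met_e, met_b),
                                  coefficient = c(-1, 1), stringsAsFactors = FALSE))
    # re-point the boundary exchange at the body-fluid twin
    th$stoich$metabolite[th$stoich$reaction == r] <- met_b
  }
  th
}

#' Prune futile secretion/re-uptake cycles across the lumen
#'
#' With every boundary exchange closed, any interspace reaction still able to
#' carry flux (by FVA) marks its lumen metabolite as loop-prone. For each
#' flagged metabolite the host transport is restricted to secretion-only and
#' microbial transports to uptake-only; a restriction is reverted if it shifts
#' any member's biomass optimum by more than `tol` (minimal restriction
#' preserving optima).
#'
#' @param joint a `joint_model`.
#' @param tol biomass-preservation tolerance (default 1e-6).
#' @return the pruned `joint_model`; attribute `futile_restricted` lists the
#'   restricted lumen metabolites.
#' @export
remove_futile_cycles <- function(joint, tol = 1e-6) {
  closed <- joint
  ex <- exchange_reactions(closed)
  closed <- set_bounds(closed, ex, lb = 0, ub = 0)
  f <- fva(closed, 0, reactions = joint$interspace$reaction)
  loopy <- abs(f$min) > tol | abs(f$max) > tol
  flagged <- unique(joint$interspace$met_u[loopy])
  if (!length(flagged)) {
    attr(joint, "futile_restricted") <- character()
    return(joint)
  }
  opt_of <- function(m) vapply(m$members$biomass, function(b)
    fba(m, objective = b)$objective, numeric(1))
  before <- opt_of(joint)
  kept <- character()
  for (mu in flagged) {
    reg <- joint$interspace[joint$interspace$met_u == mu, , drop = FALSE]
    host_rx <- reg$reaction[reg$member == .HOST_TAG]
    mic_rx <- reg$reaction[reg$member != .HOST_TAG]
    trial <- joint
    # positive interspace flux is [e] -> [u]; host keeps secretion (lb = 0),
    # microbes keep uptake (ub = 0)
    if (length(host_rx)) trial <- set_bounds(trial, host_rx, lb = 0)
    if (length(mic_rx)) trial <- set_bounds(trial, mic_rx, ub = 0)
    if (all(abs(opt_of(trial) - before) <= tol)) {
      joint <- trial
      kept <- c(kept, mu)
    }
  }
  attr(joint, "futile_restricted") <- kept
  joint
}

#' Identify co-metabolites and classify the lumen
#'
#' A lumen metabolite is a co-metabolite when the host interspace transport
#' can carry secretion flux (host [e] to lumen) and at least one microbial
#' interspace transport can carry uptake flux (lumen to microbe [e]),
#' certified by FVA on the joint model. Every lumen metabolite is classified
#' as `"co_metabolite"`, `"host_derived"` (host-secretable, no microbial
#' uptake) or `"microbe_derived"` (everything else, i.e. lumen content fed by
#' the microbiota).
#'
#' @param joint a `joint_model` containing a host member.
#' @param tol flux-capability tolerance (default 1e-6).
#' @return a list of class `co_metabolite_table`: `co_metabolites` (data
#'   frame: base, met_u, host_reaction, members, uptake_reactions —
#'   comma-collapsed), `classification` (data frame: met_u, base, class).
#' @export
identify_co_metabolites <- function(joint, tol = 1e-6) {
  if (!any(joint$members$is_host)) stop("joint model has no host member")
  reg <- joint$interspace
  f <- fva(joint, 0, reactions = reg$reaction)
  reg$can_secrete <- f$max > tol      # [e] -> [u]
  reg$can_uptake <- f$min < -tol      # [u] -> [e]
  mets <- unique(reg$met_u)
  rows <- lapply(mets, function(mu) {
    r <- reg[reg$met_u == mu, , drop = FALSE]
    h <- r[r$member == .HOST_TAG, , drop = FALSE]
    m <- r[r$member != .HOST_TAG, , drop = FALSE]
    host_secretes <- nrow(h) > 0 && any(h$can_secrete)
    up <- m[m$can_uptake, , drop = FALSE]
    cls <- if (host_secretes && nrow(up)) "co_metabolite"
           else if (host_secretes) "host_derived"
           else "microbe_derived"
    list(base = sub("_u$", "", mu), met_u = mu, class = cls,
         host_reaction = if (nrow(h)) h$reaction[1] else NA_character_,
         members = paste(sort(unique(up$member)), collapse = ","),
         uptake_reactions = paste(up$reaction[order(up$member)], collapse = ","))
  })
  cls_df <- data.frame(met_u = vapply(rows, `[[`, "", "met_u"),
                       base = vapply(rows, `[[`, "", "base"),
                       class = vapply(rows, `[[`, "", "class"),
                       stringsAsFactors = FALSE)
  co <- rows[cls_df$class == "co_metabolite"]
  co_df <- data.frame(base = vapply(co, `[[`, "", "base"),
                      met_u = vapply(co, `[[`, "", "met_u"),
                      host_reaction = vapply(co, `[[`, "", "host_reaction"),
                      members = vapply(co, `[[`, "", "members"),
                      uptake_reactions = vapply(co, `[[`, "", "uptake_reactions"),
                      stringsAsFactors = FALSE)
  structure(list(co_metabolites = co_df, classification = cls_df),
            class = "co_metabolite_table")
}

#' @export
print.co_metabolite_table <- function(x, ...) {
  tab <- table(x$classification$class)
  cat("<co_metabolite_table> lumen metabolites:", nrow(x$classification), "\n")
  for (cl in names(tab)) cat("  ", cl, ": ", tab[[cl]], "\n", sep = "")
  invisible(x)
}
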