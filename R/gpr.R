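#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean rule string such as `"g1 and (g2 or g3)"` into an AND/OR
#' tree. Operators are case-insensitive (`and`/`AND`/`&`, `or`/`OR`/`|`);
#' `and` binds tighter than `or`. Leaves are gene identifiers.
#'
#' @param rule a rule string; `NA` or `""` give `NULL` (no GPR).
#' @return a nested list with elements `op` (`"and"`, `"or"`, `"gene"`) and
#'   either `args` (subtrees) or `gene` (leaf id), or `NULL`.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule) || !nzchar(trimws(rule)))
    return(NULL)
  toks <- .gpr_tokens(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  tree <- .gpr_or(st)
  if (st$pos <= length(st$toks))
    stop("malformed GPR rule near '", st$toks[st$pos], "' in: ", rule)
  tree
}

.gpr_tokens <- function(rule) {
  rule <- gsub("&&?", " and ", rule)
  rule <- gsub("\\|\\|?", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "[[:space:]]+")[[1]]
  if (!length(toks)) stop("empty GPR rule")
  toks
}

.gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
.gpr_take <- function(st) { t <- .gpr_peek(st); st$pos <- st$pos + 1L; t }

.gpr_or <- function(st) {
  args <- list(.gpr_and(st))
  while (!is.na(t <- .gpr_peek(st)) && tolower(t) == "or") {
    .gpr_take(st)
    args[[length(args) + 1L]] <- .gpr_and(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

.gpr_and <- function(st) {
  args <- list(.gpr_atom(st))
  while (!is.na(t <- .gpr_peek(st)) && tolower(t) == "and") {
    .gpr_take(st)
    args[[length(args) + 1L]] <- .gpr_atom(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

.gpr_atom <- function(st) {
  t <- .gpr_take(st)
  if (is.na(t)) stop("unexpected end of GPR rule")
  if (t == "(") {
    inner <- .gpr_or(st)
    cl <- .gpr_take(st)
    if (is.na(cl) || cl != ")") stop("unbalanced parentheses in GPR rule")
    return(inner)
  }
  if (t == ")" || tolower(t) %in% c("and", "or"))
    stop("malformed GPR rule: unexpected '", t, "'")
  list(op = "gene", gene = t)
}

#' List the gene leaves of a parsed GPR tree
#' @param tree result of [parse_gpr()].
#' @return character vector of gene ids (possibly empty).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$op == "gene") return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Score a reaction from gene-level values through its GPR
#'
#' The E-flux convention: AND combines by `min` (enzyme complex limited by its
#' scarcest subunit), OR by `max` (isozymes add capacity, bounded by the best).
#' Genes absent from `gene_values` are treated as unmeasured: they are dropped
#' from OR alternatives, and any AND touching one becomes unmeasured. A fully
#' unmeasured rule (or no rule at all) returns `NA`, meaning "leave the
#' reaction unconstrained".
#'
#' @param gpr a rule string or a tree from [parse_gpr()]; `NULL`/`NA` allowed.
#' @param gene_values named non-negative numeric vector (gene id -> score).
#' @return a single non-negative score, or `NA_real_` if unmeasured.
#' @export
evaluate_gpr <- function(gpr, gene_values) {
  tree <- if (is.list(gpr)) gpr else parse_gpr(gpr)
  if (is.null(tree)) return(NA_real_)
  stopifnot(is.numeric(gene_values))
  if (any(gene_values < 0, na.rm = TRUE)) stop("gene scores must be non-negative")
  .gpr_eval(tree, gene_values)
}

.gpr_eval <- function(tree, vals) {
  if (tree$op == "gene") {
    v <- vals[tree$gene]
    return(if (length(v) == 0 || is.na(v)) NA_real_ else unname(v))
  }
  parts <- vapply(tree$args, .gpr_eval, numeric(1), vals = vals)
  if (tree$op == "and") {
    if (anyNA(parts)) return(NA_real_)   # complex with an unmeasured subunit
    return(min(parts))
  }
  parts <- parts[!is.na(parts)]          # unmeasured isozymes drop out
  if (!length(parts)) return(NA_real_)
  max(parts)
}

#' Evaluate a GPR rule as a boolean under an active-gene set
#'
#' Leaves are `TRUE` iff the gene is in `active_genes`.
#' @param gpr rule string or parsed tree; `NULL`/`NA` return `NA` (no rule).
#' @param active_genes character vector of active gene ids.
#' @return logical; `NA` when there is no rule.
#' @export
gpr_active <- function(gpr, active_genes) {
  tree <- if (is.list(gpr)) gpr else parse_gpr(gpr)
  if (is.null(tree)) return(NA)
  .gpr_bool(tree, active_genes)
}

.gpr_bool <- function(tree, act) {
  if (tree$op == "gene") return(tree$gene %in% act)
  parts <- vapply(tree$args, .gpr_bool, logical(1), act = act)
  if (tree$op == "and") all(parts) else any(parts)
}

#' Score all reactions of a model from an expression profile
#' @param model a `metabolic_model`.
#' @param gene_values named numeric vector of gene scores (e.g. mean TPM).
#' @return named numeric vector, one score per reaction (`NA` = unmeasured
#'   or no GPR).
#' @export
reaction_scores <- function(model, gene_values) {
  vapply(seq_len(nrow(model$reactions)), function(i) {
    evaluate_gpr(model$reactions$gpr[i], gene_values)
  }, numeric(1)) |> stats::setNames(model$reactions$id)
}
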