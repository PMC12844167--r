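# Tissue-contextualization of a generic model from bulk expression:
# TPM aggregation, active-gene filtering, greedy expression-based reaction
# extraction, E-flux bound tightening, and generic-vs-specific comparison.

#' Aggregate a TPM table into a per-gene expression profile
#'
#' Computes the arithmetic mean TPM per gene across samples, the summary the
#' contextualization steps consume (one stable expression value per gene).
#'
#' @param tpm_table a data frame whose first column is the gene id (or a
#'   numeric matrix with gene rownames); remaining columns are per-sample TPM.
#' @return an `expression_profile`: data frame with columns `gene`,
#'   `mean_tpm`, plus attribute `n_samples`.
#' @export
aggregate_expression <- function(tpm_table) {
  if (is.matrix(tpm_table)) {
    genes <- rownames(tpm_table)
    vals <- tpm_table
  } else {
    genes <- as.character(tpm_table[[1]])
    vals <- as.matrix(tpm_table[, -1, drop = FALSE])
  }
  if (is.null(genes)) stop("TPM table must name its genes")
  if (anyDuplicated(genes))
    stop("duplicate gene rows: ", paste(unique(genes[duplicated(genes)]), collapse = ", "),
         " (isoform aggregation must happen upstream)")
  if (ncol(vals) < 1) stop("TPM table needs at least one sample column")
  storage.mode(vals) <- "double"
  if (anyNA(vals) || any(vals < 0)) stop("TPM values must be non-negative and NA-free")
  out <- data.frame(gene = genes, mean_tpm = rowMeans(vals), stringsAsFactors = FALSE)
  attr(out, "n_samples") <- ncol(vals)
  class(out) <- c("expression_profile", class(out))
  out
}

#' Read a gene x sample TPM table from TSV
#' @param path TSV with a `gene` id column followed by sample columns.
#' @return data frame suitable for [aggregate_expression()].
#' @export
read_expression <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Filter active genes from an expression profile
#'
#' A gene is active when its mean TPM is strictly greater than the threshold
#' (default 1).
#'
#' @param profile from [aggregate_expression()].
#' @param threshold strict TPM cutoff (default 1).
#' @return character vector of active gene ids.
#' @export
filter_active_genes <- function(profile, threshold = 1) {
  stopifnot(is.data.frame(profile), all(c("gene", "mean_tpm") %in% names(profile)))
  profile$gene[profile$mean_tpm > threshold]
}

.profile_values <- function(profile) {
  if (is.data.frame(profile)) stats::setNames(profile$mean_tpm, profile$gene)
  else profile
}

#' Subset a model to a set of reactions
#'
#' Drops all other reactions, then prunes metabolites and genes no longer
#' referenced.
#' @param model a `metabolic_model`.
#' @param keep reaction ids to retain.
#' @return a `metabolic_model`.
#' @export
subset_reactions <- function(model, keep) {
  keep <- unique(keep)
  miss <- setdiff(keep, model$reactions$id)
  if (length(miss)) stop("unknown reaction id(s): ", paste(miss, collapse = ", "))
  model$reactions <- model$reactions[model$reactions$id %in% keep, , drop = FALSE]
  model$stoich <- model$stoich[model$stoich$reaction %in% keep, , drop = FALSE]
  used_m <- unique(model$stoich$metabolite)
  model$metabolites <- model$metabolites[model$metabolites$id %in% used_m, , drop = FALSE]
  rules <- model$reactions$gpr[!is.na(model$reactions$gpr)]
  used_g <- if (length(rules))
    unique(unlist(lapply(unique(rules), function(r) gpr_genes(parse_gpr(r))))) else character()
  model$genes <- model$genes[model$genes$id %in% used_g, , drop = FALSE]
  rownames(model$reactions) <- rownames(model$metabolites) <- rownames(model$genes) <- NULL
  if (!is.null(model$objective) && !model$objective %in% keep) model$objective <- NULL
  model
}

#' Extract an expression-contextualized core model
#'
#' Greedy expression-based extraction: reactions whose GPR evaluates inactive
#' under the active-gene set are removed (reactions without GPR and protected
#' reactions are always kept); if the objective then fails to carry flux, the
#' removed reactions are restored one at a time in decreasing expression-score
#' order until it does.
#'
#' @param model validated `metabolic_model`.
#' @param active_genes character vector (see [filter_active_genes()]).
#' @param protected_reactions reaction ids never removed; the objective is
#'   protected by default.
#' @param profile optional `expression_profile` (or named score vector) used
#'   to order feasibility restoration; without it, original model order is used.
#' @param feasibility_tol minimal objective flux considered "feasible"
#'   (default 1e-6).
#' @return a feasible `metabolic_model`; attribute `restored_reactions` lists
#'   reactions brought back by the feasibility repair.
#' @export
extract_context_model <- function(model, active_genes,
                                  protected_reactions = model$objective,
                                  profile = NULL, feasibility_tol = 1e-6) {
  act <- vapply(model$reactions$gpr, function(r) gpr_active(r, active_genes), logical(1))
  removable <- !is.na(act) & !act & !model$reactions$id %in% protected_reactions
  keep <- model$reactions$id[!removable]
  removed <- model$reactions$id[removable]
  out <- subset_reactions(model, keep)
  out$id <- paste0(model$id, "_context")

  score_of <- if (!is.null(profile)) {
    sc <- reaction_scores(model, .profile_values(profile))
    function(ids) ifelse(is.na(sc[ids]), -Inf, sc[ids])
  } else {
    function(ids) -match(ids, model$reactions$id)  # later reactions restored last
  }

  restored <- character()
  feasible <- function(m) {
    z <- fba(m)
    z$status == "optimal" && z$objective > feasibility_tol
  }
  if (!is.null(out$objective) && !feasible(out)) {
    order_restore <- removed[order(score_of(removed), decreasing = TRUE)]
    for (rid in order_restore) {
      restored <- c(restored, rid)
      out <- subset_reactions(model, c(keep, restored))
      out$id <- paste0(model$id, "_context")
      if (feasible(out)) break
    }
    if (!feasible(out))
      stop("objective cannot carry flux even with all removed reactions restored")
  }
  attr(out, "restored_reactions") <- restored
  out
}

#' Constrain flux bounds by expression (E-flux)
#'
#' Each reaction with a measured GPR score s gets bounds
#' `lb' = max(lb, -B * s_hat)`, `ub' = min(ub, B * s_hat)`, where `s_hat` is
#' the score normalized to `[0, 1]` and `B` is the model's default bound
#' magnitude. Unmeasured reactions (no GPR, or all genes unmeasured) keep
#' their original bounds. Bounds are never widened.
#'
#' @param model a contextualized `metabolic_model`.
#' @param profile `expression_profile` or named gene score vector.
#' @param scaling `"quantile"` (score divided by the `quantile_probs` quantile
#'   of measured scores, clipped to 1; default) or `"absolute"` (divided by
#'   the maximum score).
#' @param quantile_probs quantile used by `"quantile"` scaling (default 0.95).
#' @return the model with tightened bounds; attribute `eflux_scores` carries
#'   the normalized scores.
#' @export
apply_eflux <- function(model, profile, scaling = c("quantile", "absolute"),
                        quantile_probs = 0.95) {
  scaling <- match.arg(scaling)
  sc <- reaction_scores(model, .profile_values(profile))
  meas <- sc[!is.na(sc)]
  if (!length(meas)) return(model)
  ref <- switch(scaling,
                quantile = stats::quantile(meas, quantile_probs, names = FALSE),
                absolute = max(meas))
  if (ref <= 0) ref <- 1
  shat <- pmin(1, sc / ref)
  B <- max(abs(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  ok <- !is.na(shat)
  model$reactions$lower_bound[ok] <-
    pmax(model$reactions$lower_bound[ok], -B * shat[ok])
  model$reactions$upper_bound[ok] <-
    pmin(model$reactions$upper_bound[ok], B * shat[ok])
  attr(model, "eflux_scores") <- shat
  model
}

#' Compare a generic and a contextualized model
#'
#' Reports structural reductions, GPR coverage, a paired test on FVA spans of
#' shared reactions (the direction of solution-space contraction), and the
#' essential-reaction difference sets.
#'
#' @param generic,specific two feasible `metabolic_model`s.
#' @param paired_test `"signed-rank"` (paired Wilcoxon, default) or
#'   `"rank-sum"` (unpaired).
#' @param fraction_of_optimum passed to [fva()] for both models (default 0).
#' @param essentiality_tolerance passed to [single_reaction_deletion()].
#' @return a `model_comparison` list: `gene_reduction`, `reaction_reduction`,
#'   `gpr_coverage` (named pair), `fva_spans` (shared-reaction data frame),
#'   `test` (statistic, p.value, method), `essential` (sets and differences).
#' @export
compare_models <- function(generic, specific,
                           paired_test = c("signed-rank", "rank-sum"),
                           fraction_of_optimum = 0,
                           essentiality_tolerance = 0.01) {
  paired_test <- match.arg(paired_test)
  shared <- intersect(generic$reactions$id, specific$reactions$id)
  if (!length(shared)) stop("models share no reactions")
  fg <- fva(generic, fraction_of_optimum, reactions = shared)
  fs <- fva(specific, fraction_of_optimum, reactions = shared)
  spans <- data.frame(reaction = shared, span_generic = fg$span,
                      span_specific = fs$span,
                      delta = fs$span - fg$span, stringsAsFactors = FALSE)
  tst <- if (all(spans$delta == 0)) {
    list(statistic = 0, p.value = 1, method = paste(paired_test, "(all ties)"))
  } else if (paired_test == "signed-rank") {
    w <- suppressWarnings(stats::wilcox.test(spans$span_specific, spans$span_generic,
                                             paired = TRUE))
    list(statistic = unname(w$statistic), p.value = w$p.value, method = w$method)
  } else {
    w <- suppressWarnings(stats::wilcox.test(spans$span_specific, spans$span_generic))
    list(statistic = unname(w$statistic), p.value = w$p.value, method = w$method)
  }
  cov <- function(m) mean(!is.na(m$reactions$gpr) & nzchar(m$reactions$gpr))
  eg <- single_reaction_deletion(generic, essentiality_tolerance)
  es <- single_reaction_deletion(specific, essentiality_tolerance)
  eset_g <- eg$reaction[eg$essential]; eset_s <- es$reaction[es$essential]
  out <- list(
    gene_reduction = if (nrow(generic$genes))
      1 - nrow(specific$genes) / nrow(generic$genes) else 0,
    reaction_reduction = 1 - nrow(specific$reactions) / nrow(generic$reactions),
    gpr_coverage = c(generic = cov(generic), specific = cov(specific)),
    fva_spans = spans,
    test = tst,
    essential = list(generic = eset_g, specific = eset_s,
                     gained = setdiff(eset_s, eset_g),
                     lost = setdiff(eset_g, eset_s)))
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n",
      sprintf("  gene reduction: %.1f%%   reaction reduction: %.1f%%\n",
              100 * x$gene_reduction, 100 * x$reaction_reduction),
      sprintf("  GPR coverage: generic %.1f%%, specific %.1f%%\n",
              100 * x$gpr_coverage["generic"], 100 * x$gpr_coverage["specific"]),
      sprintf("  FVA span test (%s): stat %.3g, p = %.3g\n",
              x$test$method, x$test$statistic, x$test$p.value),
      sprintf("  essential reactions: generic %d, specific %d (+%d / -%d)\n",
              length(x$essential$generic), length(x$essential$specific),
              length(x$essential$gained), length(x$essential$lost)),
      sep = "")
  invisible(x)
}
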