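# Differential metabolic analysis under restricted co-metabolite supply:
# zero-flux restriction scenarios, per-reaction Kolmogorov-Smirnov tests with
# Benjamini-Hochberg correction, the normalized flux-change statistic FC with
# its 0.82 screening threshold (~10-fold flux ratio), bootstrap confidence
# intervals, biomass-effect classification and key co-metabolite screening.

#' Restrict a member's uptake of a co-metabolite to zero flux
#'
#' Sets `lb = ub = 0` on the member's interspace transport(s) for the
#' metabolite, mimicking a host that has lost the capacity to supply it.
#' All other bounds are untouched.
#'
#' @param joint a `joint_model`.
#' @param co_metabolite base metabolite id (without compartment suffix).
#' @param member member tag whose uptake routes are closed.
#' @return a scenario-stamped copy of the joint model (attribute `scenario`).
#' @export
apply_restriction <- function(joint, co_metabolite, member) {
  reg <- joint$interspace
  hit <- reg$base == co_metabolite & reg$member == member
  if (!any(hit))
    stop("member '", member, "' has no registered uptake route for '",
         co_metabolite, "'")
  out <- set_bounds(joint, reg$reaction[hit], lb = 0, ub = 0)
  attr(out, "scenario") <- list(co_metabolite = co_metabolite, member = member,
                                reactions = reg$reaction[hit])
  out
}

.sample_matrix <- function(x) {
  if (inherits(x, "flux_sample")) x$samples else as.matrix(x)
}

#' Per-reaction two-sample Kolmogorov-Smirnov comparison
#'
#' Compares the flux distribution of every reaction between two samples
#' (D = sup |ECDF_a - ECDF_b|, asymptotic two-sided p). A reaction present in
#' only one sample is compared against a constant-zero distribution.
#'
#' @param sample_a,sample_b `flux_sample`s or matrices with reaction colnames.
#' @param reactions optional subset (default: union of both).
#' @return data frame: `reaction`, `statistic`, `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b, reactions = NULL) {
  a <- .sample_matrix(sample_a); b <- .sample_matrix(sample_b)
  if (!nrow(a) || !nrow(b)) stop("empty flux sample")
  rxns <- if (is.null(reactions)) union(colnames(a), colnames(b)) else reactions
  get <- function(m, r, n) if (r %in% colnames(m)) m[, r] else rep(0, n)
  res <- t(vapply(rxns, function(r) {
    x <- get(a, r, nrow(a)); y <- get(b, r, nrow(b))
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && x[1] == y[1])
      return(c(0, 1))  # both degenerate at the same constant
    k <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    c(unname(k$statistic), k$p.value)
  }, numeric(2)))
  data.frame(reaction = rxns, statistic = res[, 1], p_value = res[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#' @param p_values numeric vector in `[0, 1]`.
#' @return step-up adjusted q-values (capped at 1).
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Normalized flux change
#'
#' `FC = (S_Restricted - S_Unrestricted) / |S_Restricted + S_Unrestricted|`.
#' A 10:1 same-sign ratio gives 9/11 ~ 0.818, i.e. the screening threshold
#' 0.82 corresponds to about a 10-fold flux difference. When both means are
#' zero, FC = 0; when the denominator underflows (|sum| < `eps`) with unequal
#' means, the result is the sentinel `+/-1e12` and is flagged via the
#' `"clipped"` attribute.
#'
#' @param s_restricted,s_unrestricted mean fluxes (vectorized).
#' @param eps denominator underflow guard (default 1e-12).
#' @return numeric FC values, attribute `clipped` (logical).
#' @export
flux_change <- function(s_restricted, s_unrestricted, eps = 1e-12) {
  num <- s_restricted - s_unrestricted
  den <- abs(s_restricted + s_unrestricted)
  fc <- ifelse(num == 0, 0, num / den)
  clipped <- den < eps & num != 0
  fc[clipped] <- sign(num[clipped]) * 1e12
  attr(fc, "clipped") <- clipped
  fc
}

#' Percentile bootstrap confidence interval of a mean
#'
#' @param diff_samples numeric observations (e.g. per-point flux differences).
#' @param n_boot bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed optional RNG seed for reproducibility.
#' @return numeric `c(lower, upper)`; zero-width at the constant for
#'   degenerate input.
#' @export
bootstrap_ci <- function(diff_samples, n_boot = 1000, level = 0.95, seed = NULL) {
  n <- length(diff_samples)
  if (n < 2) stop("need at least 2 observations")
  if (stats::sd(diff_samples) == 0)
    return(c(lower = diff_samples[1], upper = diff_samples[1]))
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  means <- colMeans(matrix(diff_samples[idx], n, n_boot))
  a <- (1 - level) / 2
  q <- stats::quantile(means, c(a, 1 - a), names = FALSE)
  c(lower = q[1], upper = q[2])
}

# joint percentile bootstrap of column means: one resampling-weight matrix
# shared by all columns, evaluated as a single matrix product
.bootstrap_mean_ci_matrix <- function(D, n_boot, level) {
  n <- nrow(D)
  W <- vapply(seq_len(n_boot), function(b)
    tabulate(sample.int(n, n, replace = TRUE), n), numeric(n))
  means <- crossprod(W, D) / n           # n_boot x n_cols
  a <- (1 - level) / 2
  t(apply(means, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
}

#' Full per-reaction differential analysis between two flux samples
#'
#' Combines the KS test (BH-corrected across reactions), the normalized flux
#' change, and a bootstrap CI of the mean per-point flux difference (paired
#' by sample index). A reaction is significant when `q < alpha` AND
#' `|FC| >= fc_threshold` AND 0 lies outside the CI.
#'
#' @param sample_restricted,sample_unrestricted `flux_sample`s or matrices.
#' @param alpha significance level (default 0.05).
#' @param fc_threshold normalized flux-change cutoff (default 0.82).
#' @param n_boot bootstrap replicates (default 1000).
#' @param level CI level (default 0.95).
#' @param seed optional seed for the bootstrap.
#' @return data frame (one row per reaction): means, KS statistic, `p_value`,
#'   `q_value`, `fc`, `ci_lower`, `ci_upper`, `significant`.
#' @export
differential_analysis <- function(sample_restricted, sample_unrestricted,
                                  alpha = 0.05, fc_threshold = 0.82,
                                  n_boot = 1000, level = 0.95, seed = NULL) {
  r <- .sample_matrix(sample_restricted); u <- .sample_matrix(sample_unrestricted)
  ks <- ks_compare(r, u)
  ks$q_value <- bh_fdr(ks$p_value)
  n <- min(nrow(r), nrow(u))
  get <- function(m, rid) if (rid %in% colnames(m)) m[seq_len(n), rid] else rep(0, n)
  D <- vapply(ks$reaction, function(rid) get(r, rid) - get(u, rid), numeric(n))
  mr <- vapply(ks$reaction, function(rid) mean(get(r, rid)), numeric(1))
  mu <- vapply(ks$reaction, function(rid) mean(get(u, rid)), numeric(1))
  if (!is.null(seed)) set.seed(seed)
  ci <- .bootstrap_mean_ci_matrix(D, n_boot = n_boot, level = level)
  lo <- ci[, 1]; hi <- ci[, 2]
  fc <- flux_change(mr, mu)
  out <- data.frame(reaction = ks$reaction, mean_restricted = mr,
                    mean_unrestricted = mu, statistic = ks$statistic,
                    p_value = ks$p_value, q_value = ks$q_value,
                    fc = as.numeric(fc), fc_clipped = attr(fc, "clipped"),
                    ci_lower = lo, ci_upper = hi, stringsAsFactors = FALSE)
  out$significant <- out$q_value < alpha & abs(out$fc) >= fc_threshold &
    (out$ci_lower > 0 | out$ci_upper < 0)
  out
}

#' Screen significant reactions from a differential result
#'
#' Conjunction of the three filters: `q < alpha`, `|FC| >= fc_threshold`,
#' and 0 outside the bootstrap CI.
#'
#' @param results data frame from [differential_analysis()].
#' @param alpha significance level (default 0.05).
#' @param fc_threshold FC cutoff (default 0.82).
#' @return character vector of significant reaction ids.
#' @export
screen_reactions <- function(results, alpha = 0.05, fc_threshold = 0.82) {
  keep <- results$q_value < alpha & abs(results$fc) >= fc_threshold &
    (results$ci_lower > 0 | results$ci_upper < 0)
  results$reaction[keep]
}

#' Classify the biomass response to a restriction
#'
#' `"blocked"` when the restricted biomass mean falls below `zero_tol`;
#' `"reduced"` when the decrease passes the screening filters (KS
#' significance, `|FC| >= fc_threshold`, 0 outside the bootstrap CI of the
#' paired difference); `"unchanged"` otherwise.
#'
#' @param sample_before,sample_after `flux_sample`s or matrices covering the
#'   biomass reaction (before = unrestricted).
#' @param biomass_id biomass reaction id.
#' @param zero_tol blocked-growth tolerance in flux units (default 1e-9).
#' @param alpha,fc_threshold,n_boot,level,seed screening parameters as in
#'   [differential_analysis()].
#' @return a one-row data frame: `biomass_before`, `biomass_after`, `class`,
#'   `p_value`, `fc`, `ci_lower`, `ci_upper`.
#' @export
classify_biomass_effect <- function(sample_before, sample_after, biomass_id,
                                    zero_tol = 1e-9, alpha = 0.05,
                                    fc_threshold = 0.82, n_boot = 1000,
                                    level = 0.95, seed = NULL) {
  b <- .sample_matrix(sample_before); a <- .sample_matrix(sample_after)
  if (!biomass_id %in% colnames(b) || !biomass_id %in% colnames(a))
    stop("biomass reaction '", biomass_id, "' missing from a sample")
  x <- b[, biomass_id]; y <- a[, biomass_id]
  before <- mean(x); after <- mean(y)
  ks <- ks_compare(matrix(y, dimnames = list(NULL, biomass_id)),
                   matrix(x, dimnames = list(NULL, biomass_id)))
  fc <- as.numeric(flux_change(after, before))
  n <- min(length(x), length(y))
  if (!is.null(seed)) set.seed(seed)
  ci <- bootstrap_ci(y[seq_len(n)] - x[seq_len(n)], n_boot = n_boot, level = level)
  cls <- if (after < zero_tol && before >= zero_tol) "blocked"
  else if (ks$p_value < alpha && after < before && abs(fc) >= fc_threshold &&
           (ci[1] > 0 || ci[2] < 0)) "reduced"
  else "unchanged"
  data.frame(biomass_before = before, biomass_after = after, class = cls,
             p_value = ks$p_value, fc = fc, ci_lower = ci[1], ci_upper = ci[2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Screen key co-metabolites from a biomass-effect grid
#'
#' A co-metabolite is "key" when restricting its uptake produces a
#' non-"unchanged" biomass effect in at least one member. Output is shaped
#' like a key-metabolite table: metabolite, affected members (sorted,
#' deduplicated), effect classes.
#'
#' @param effects data frame with columns `co_metabolite`, `member`, `class`
#'   (one row per restriction scenario, classes from
#'   [classify_biomass_effect()]).
#' @return data frame: `co_metabolite`, `members`, `effects`, `n_affected`.
#' @export
screen_key_co_metabolites <- function(effects) {
  stopifnot(all(c("co_metabolite", "member", "class") %in% names(effects)))
  hit <- effects[effects$class != "unchanged", , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(co_metabolite = character(), members = character(),
                      effects = character(), n_affected = integer(),
                      stringsAsFactors = FALSE))
  sp <- split(hit, hit$co_metabolite)
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[!duplicated(d$member), , drop = FALSE]
    d <- d[order(d$member), , drop = FALSE]
    data.frame(co_metabolite = d$co_metabolite[1],
               members = paste(d$member, collapse = ","),
               effects = paste(d$class, collapse = ","),
               n_affected = nrow(d), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$co_metabolite), , drop = FALSE]
  rownames(out) <- NULL
  out
}
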