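# Hypergeometric over-representation of significantly changed reactions in
# metabolic subsystems, with BH correction across subsystems, and the
# subsystem x co-metabolite x member grid export.

.hyper_support_ok <- function(N, K, n, k) {
  all(c(N, K, n, k) >= 0) && K <= N && n <= N && k <= min(K, n) && k >= max(0, n - (N - K))
}

#' Hypergeometric point probability P(X = k)
#'
#' Probability that a subsystem holding K of the model's N reactions contains
#' exactly k of the n significantly changed ones:
#' `C(K,k) C(N-K, n-k) / C(N,n)` (evaluated in log space). Out-of-support
#' arguments return 0 with attribute `out_of_support = TRUE`.
#'
#' @param N total reactions in the model.
#' @param K reactions in the subsystem.
#' @param n significantly changed reactions.
#' @param k significantly changed reactions inside the subsystem.
#' @return probability in `[0, 1]`.
#' @export
hypergeom_point <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (any(c(N, K, n, k) != floor(c(N, K, n, k)))) stop("arguments must be integers")
  if (!.hyper_support_ok(N, K, n, k))
    return(structure(0, out_of_support = TRUE))
  stats::dhyper(k, K, N - K, n)
}

#' Hypergeometric upper-tail probability P(X >= k)
#'
#' @inheritParams hypergeom_point
#' @return probability in `[0, 1]`; out-of-support k above the support gives
#'   0 (flagged), k at or below the minimum gives 1.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (any(c(N, K, n, k) != floor(c(N, K, n, k)))) stop("arguments must be integers")
  if (k <= max(0, n - (N - K))) return(1)
  if (!.hyper_support_ok(N, K, n, k))
    return(structure(0, out_of_support = TRUE))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Subsystem enrichment of significant reactions
#'
#' One hypergeometric test per subsystem (reactions without a label are
#' pooled into `"unassigned"`). Both the point mass P(X = k) and the
#' upper-tail P(X >= k) are always reported, each with BH-adjusted q-values
#' across subsystems; the `enriched` flag uses the chosen `mode` and `alpha`.
#'
#' @param model the background `metabolic_model` (N = all its reactions, or
#'   the subset in `background`).
#' @param significant_reactions character vector of significant reaction ids.
#' @param mode `"tail"` (default; standard over-representation) or `"point"`.
#' @param alpha flag threshold on the adjusted q (default 0.05).
#' @param background optional reaction-id subset to use as the universe
#'   (e.g. to exclude transport/exchange classes).
#' @return data frame per subsystem: `subsystem`, `N`, `K`, `n`, `k`,
#'   `p_point`, `p_tail`, `q_point`, `q_tail`, `enriched`.
#' @export
enrich_subsystems <- function(model, significant_reactions,
                              mode = c("tail", "point"), alpha = 0.05,
                              background = NULL) {
  mode <- match.arg(mode)
  rx <- model$reactions
  if (!is.null(background)) {
    miss <- setdiff(background, rx$id)
    if (length(miss)) stop("background reactions not in model: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    rx <- rx[rx$id %in% background, , drop = FALSE]
  }
  miss <- setdiff(significant_reactions, rx$id)
  if (length(miss))
    stop("significant reactions not in the background: ",
         paste(utils::head(miss, 5), collapse = ", "))
  subs <- ifelse(is.na(rx$subsystem), "unassigned", rx$subsystem)
  N <- nrow(rx)
  n <- length(unique(significant_reactions))
  labs <- sort(unique(subs))
  K <- vapply(labs, function(s) sum(subs == s), integer(1))
  k <- vapply(labs, function(s)
    sum(rx$id[subs == s] %in% significant_reactions), integer(1))
  if (n == 0) {
    out <- data.frame(subsystem = labs, N = N, K = K, n = 0L, k = 0L,
                      p_point = NA_real_, p_tail = NA_real_,
                      q_point = NA_real_, q_tail = NA_real_, enriched = FALSE,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  p_point <- mapply(function(K, k) as.numeric(hypergeom_point(N, K, n, k)), K, k)
  p_tail <- mapply(function(K, k) as.numeric(hypergeom_tail(N, K, n, k)), K, k)
  out <- data.frame(subsystem = labs, N = N, K = K, n = n, k = k,
                    p_point = p_point, p_tail = p_tail,
                    q_point = bh_fdr(p_point), q_tail = bh_fdr(p_tail),
                    stringsAsFactors = FALSE)
  out$enriched <- if (mode == "tail") out$q_tail < alpha else out$q_point < alpha
  rownames(out) <- NULL
  out
}

#' Assemble the subsystem x co-metabolite x member enrichment grid
#'
#' @param per_scenario data frame binding [enrich_subsystems()] outputs with
#'   added columns `member` and `co_metabolite`, or a list of such data
#'   frames.
#' @return list with `long` (the row-bound long table) and `matrix`
#'   (subsystems x member:co_metabolite matrix of tail q-values, `NA` where a
#'   subsystem was absent from a scenario).
#' @export
build_enrichment_grid <- function(per_scenario) {
  if (is.data.frame(per_scenario)) long <- per_scenario
  else long <- do.call(rbind, per_scenario)
  if (is.null(long) || !nrow(long))
    return(list(long = data.frame(), matrix = matrix(numeric(), 0, 0)))
  stopifnot(all(c("subsystem", "member", "co_metabolite", "q_tail") %in% names(long)))
  rownames(long) <- NULL
  scen <- paste(long$member, long$co_metabolite, sep = ":")
  subsystems <- sort(unique(long$subsystem))
  cols <- sort(unique(scen))
  m <- matrix(NA_real_, length(subsystems), length(cols),
              dimnames = list(subsystems, cols))
  m[cbind(match(long$subsystem, subsystems), match(scen, cols))] <- long$q_tail
  list(long = long, matrix = m)
}
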