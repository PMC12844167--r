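# Uniform flux sampling of the steady-state polytope by artificial-centering
# hit-and-run (warm-up from FVA-style vertex optimization, thinning,
# validity diagnostics).

# bounds at or beyond this magnitude are treated as unbounded rays, for which
# uniform sampling is undefined
.SAMPLING_BOUND_LIMIT <- 1e5

#' Sampler configuration
#'
#' @param n_samples number of retained points (default 10000).
#' @param thinning keep every `thinning`-th chain state (default 100).
#' @param n_warmup number of warm-up points; default `min(2 * n_reactions,
#'   2000)` resolved at run time (`NULL`).
#' @param seed RNG seed recorded in the sample's provenance (`NULL` = do not
#'   touch the RNG state).
#' @param tol_feas steady-state residual tolerance for validity checks.
#' @param max_failures chain restarts allowed on degenerate directions.
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(n_samples = 10000, thinning = 100, n_warmup = NULL,
                           seed = NULL, tol_feas = 1e-6, max_failures = 10000) {
  stopifnot(n_samples >= 1, thinning >= 1)
  structure(list(n_samples = as.integer(n_samples), thinning = as.integer(thinning),
                 n_warmup = n_warmup, seed = seed, tol_feas = tol_feas,
                 max_failures = as.integer(max_failures)),
            class = "sampler_config")
}

.check_bounded <- function(model) {
  r <- model$reactions
  bad <- abs(r$lower_bound) >= .SAMPLING_BOUND_LIMIT |
    abs(r$upper_bound) >= .SAMPLING_BOUND_LIMIT
  if (any(bad))
    stop("flux polytope has effectively unbounded reactions (|bound| >= ",
         .SAMPLING_BOUND_LIMIT, "): ",
         paste(utils::head(r$id[bad], 10), collapse = ", "),
         "; uniform sampling is undefined on unbounded rays")
}

#' Generate warm-up points for hit-and-run sampling
#'
#' Optimizes each reaction flux in both directions (FVA-style vertex
#' enumeration); if more points are requested than `2 * n_reactions`, the
#' remainder come from random dense objectives.
#'
#' @param model a feasible, bounded `metabolic_model`.
#' @param n_warmup number of points (default `min(2 * n_reactions, 2000)`).
#' @return matrix `n_reactions x n_warmup` of feasible flux vectors
#'   (rownames = reaction ids).
#' @export
generate_warmup <- function(model, n_warmup = NULL) {
  .check_bounded(model)
  lp <- .lp_matrices(model)
  n <- length(lp$rxn)
  if (is.null(n_warmup)) n_warmup <- min(2L * n, 2000L)
  n_warmup <- max(2L, as.integer(n_warmup))
  # +/- each reaction, interleaved, truncated or extended as needed
  ord <- rep(seq_len(n), each = 2)
  sgn <- rep(c(1, -1), n)
  k0 <- min(2L * n, n_warmup)
  objs <- matrix(0, n, n_warmup)
  senses <- numeric(n_warmup)
  pick <- if (k0 < 2L * n) round(seq(1, 2L * n, length.out = k0)) else seq_len(2L * n)
  for (q in seq_len(k0)) {
    objs[ord[pick[q]], q] <- 1
    senses[q] <- sgn[pick[q]]
  }
  if (n_warmup > 2L * n) {
    extra <- n_warmup - 2L * n
    objs[, (2L * n + 1L):n_warmup] <- matrix(stats::rnorm(n * extra), n, extra)
    senses[(2L * n + 1L):n_warmup] <- 1
  }
  r <- .lp_solve_many_cpp(lp$S, objs, senses, lp$lb, lp$ub, TRUE)
  if (any(r$status == 1L)) stop("model is infeasible; cannot generate warmup")
  if (any(r$status != 0L)) stop("warmup LP failed (solver status ",
                                paste(unique(r$status), collapse = ","), ")")
  w <- r$solutions
  rownames(w) <- lp$rxn
  w
}

#' Sample the flux polytope by artificial-centering hit-and-run
#'
#' Iterates the ACHR chain: a direction through the running center and a
#' random warm-up point, a chord delimited by the flux bounds, a uniform step
#' on the chord; every `thinning`-th state is retained. Deterministic for a
#' fixed seed.
#'
#' @param model a feasible, bounded `metabolic_model`.
#' @param config a [sampler_config()].
#' @return a `flux_sample`: list with `samples`
#'   (`n_samples x n_reactions`, colnames = reaction ids), `model_id`,
#'   `config`, `n_warmup`, `failures`.
#' @export
achr_sample <- function(model, config = sampler_config()) {
  stopifnot(inherits(config, "sampler_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  w <- generate_warmup(model, config$n_warmup)
  lp <- .lp_matrices(model)
  rng <- apply(w, 1, function(x) diff(range(x)))
  if (all(rng < 1e-10)) {
    # fully determined polytope: the unique point, replicated
    s <- matrix(rep(w[, 1], each = config$n_samples), config$n_samples,
                nrow(w), dimnames = list(NULL, lp$rxn))
    out <- list(samples = s, failures = 0L, steps = 0)
  } else {
    ch <- .achr_chain_cpp(w, lp$lb, lp$ub, config$n_samples, config$thinning,
                          config$max_failures)
    colnames(ch$samples) <- lp$rxn
    out <- ch
  }
  structure(list(samples = out$samples, model_id = model$id, config = config,
                 n_warmup = ncol(w), failures = out$failures),
            class = "flux_sample")
}

#' @export
print.flux_sample <- function(x, ...) {
  cat("<flux_sample> model:", x$model_id, "\n  points:", nrow(x$samples),
      " reactions:", ncol(x$samples),
      " thinning:", x$config$thinning,
      " seed:", if (is.null(x$config$seed)) "<unset>" else x$config$seed, "\n")
  invisible(x)
}

#' Validate a flux sample against its model
#'
#' Reports the maximal steady-state residual and bound violation, flags
#' offending rows, per-reaction means/SDs, and a split-half convergence
#' diagnostic (first- vs second-half mean shift in pooled-SE units).
#'
#' @param sample a `flux_sample` (or plain matrix with reaction colnames).
#' @param model the `metabolic_model` it was drawn from.
#' @param tol residual/bound tolerance (default 1e-6).
#' @return a `sample_validation` list: `pass`, `max_residual`,
#'   `max_bound_violation`, `bad_rows`, `stats` (data frame), `split_half`
#'   (max |shift| in SE units).
#' @export
validate_sample <- function(sample, model, tol = 1e-6) {
  s <- if (inherits(sample, "flux_sample")) sample$samples else sample
  ix <- match(model$reactions$id, colnames(s))
  if (anyNA(ix)) stop("sample does not cover all model reactions")
  s <- s[, ix, drop = FALSE]
  S <- build_stoichiometric_matrix(model)
  res <- abs(S %*% t(s))
  row_res <- apply(res, 2, max)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  viol <- pmax(sweep(s, 2, ub, "-"), sweep(-s, 2, -lb, "-"), 0)  # s-ub, lb-s
  row_viol <- apply(viol, 1, max)
  h <- nrow(s) %/% 2
  m1 <- colMeans(s[seq_len(h), , drop = FALSE])
  m2 <- colMeans(s[(h + 1):nrow(s), , drop = FALSE])
  sd_all <- apply(s, 2, stats::sd)
  se <- sd_all / sqrt(h)
  shift <- ifelse(se > 0, abs(m1 - m2) / se, 0)
  bad <- which(row_res > tol | row_viol > tol)
  structure(list(
    pass = length(bad) == 0,
    max_residual = max(row_res),
    max_bound_violation = max(0, max(row_viol)),
    bad_rows = bad,
    stats = data.frame(reaction = colnames(s), mean = colMeans(s), sd = sd_all,
                       stringsAsFactors = FALSE),
    split_half = max(shift)), class = "sample_validation")
}

#' Lag-1 autocorrelation per reaction of a flux sample
#' @param sample a `flux_sample` or matrix.
#' @return named numeric vector (NA for constant reactions).
#' @export
sample_autocorrelation <- function(sample) {
  s <- if (inherits(sample, "flux_sample")) sample$samples else sample
  apply(s, 2, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x[-length(x)], x[-1])
  })
}

#' Write a flux sample as TSV with a JSON metadata sidecar
#' @param sample a `flux_sample`.
#' @param path TSV destination; the sidecar is written at `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_sample <- function(sample, path) {
  utils::write.table(sample$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(model_id = sample$model_id,
               config = unclass(sample$config),
               n_warmup = sample$n_warmup, failures = sample$failures)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
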