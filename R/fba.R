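# Linear-programming analyses: FBA, FVA, single-reaction deletion.
# LPs are solved by the package's bounded-variable simplex (src/lp.cpp).

# bounds wider than this are treated as "effectively unbounded" and clamped
# so the simplex works on a finite box; fba() reports when the optimum rides
# the clamp, which signals a genuinely unbounded problem.
.LP_INF <- 1e6

.lp_matrices <- function(model) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  lb <- pmax(model$reactions$lower_bound, -.LP_INF)
  ub <- pmin(model$reactions$upper_bound, .LP_INF)
  list(S = S, lb = lb, ub = ub, rxn = model$reactions$id)
}

#' Flux balance analysis
#'
#' Optimizes the objective flux subject to steady state (`S v = 0`) and the
#' flux bounds.
#'
#' @param model a feasible `metabolic_model` with an objective reaction.
#' @param direction `"max"` (default) or `"min"`.
#' @param objective optional reaction id overriding `model$objective`.
#' @return a list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"failed"`), `objective` (optimal value or `NA`) and
#'   `flux` (named flux vector satisfying the constraints within tolerance).
#' @export
fba <- function(model, direction = c("max", "min"), objective = NULL) {
  direction <- match.arg(direction)
  obj_id <- if (is.null(objective)) model$objective else objective
  if (is.null(obj_id)) stop("model has no objective reaction")
  lp <- .lp_matrices(model)
  cvec <- as.numeric(lp$rxn == obj_id)
  if (!any(cvec > 0)) stop("objective reaction '", obj_id, "' not in model")
  .fba_raw(lp, cvec, direction)
}

.fba_raw <- function(lp, cvec, direction) {
  sense <- if (direction == "max") 1L else -1L
  r <- .lp_solve_cpp(lp$S, cvec, lp$lb, lp$ub, sense)
  status <- switch(as.character(r$status),
                   "0" = "optimal", "1" = "infeasible", "failed")
  flux <- stats::setNames(as.numeric(r$flux), lp$rxn)
  obj <- if (status == "optimal") r$objective else NA_real_
  if (status == "optimal" && is.finite(obj) && abs(obj) >= .LP_INF * 0.999)
    status <- "unbounded"
  list(status = status, objective = obj, flux = flux)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum feasible flux while the objective is held
#' at at least `fraction_of_optimum` of its optimal value.
#'
#' @param model a feasible `metabolic_model`.
#' @param fraction_of_optimum number in `[0, 1]`; 0 drops the objective
#'   constraint entirely.
#' @param reactions optional subset of reaction ids (default: all).
#' @return data frame with columns `reaction`, `min`, `max`, `span`.
#' @export
fva <- function(model, fraction_of_optimum = 0, reactions = NULL) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  lp <- .lp_matrices(model)
  if (fraction_of_optimum > 0) {
    if (is.null(model$objective)) stop("fraction_of_optimum > 0 needs an objective")
    z <- fba(model)
    if (z$status != "optimal")
      stop("model is ", z$status, "; cannot anchor the objective for FVA")
    # impose c.v >= f z* by turning the objective flux's lower bound up;
    # works because the objective is a single reaction flux here
    oi <- match(model$objective, lp$rxn)
    lp$lb[oi] <- max(lp$lb[oi], fraction_of_optimum * z$objective)
  }
  rids <- if (is.null(reactions)) lp$rxn else reactions
  ix <- match(rids, lp$rxn)
  if (anyNA(ix)) stop("unknown reaction id(s): ", paste(rids[is.na(ix)], collapse = ", "))
  n <- length(lp$rxn)
  objs <- matrix(0, n, 2L * length(ix))
  senses <- numeric(2L * length(ix))
  for (q in seq_along(ix)) {
    objs[ix[q], 2L * q - 1L] <- 1; senses[2L * q - 1L] <- -1  # min
    objs[ix[q], 2L * q]      <- 1; senses[2L * q]      <- 1   # max
  }
  r <- .lp_solve_many_cpp(lp$S, objs, senses, lp$lb, lp$ub, FALSE)
  if (any(r$status != 0L))
    stop("FVA subproblem not optimal for: ",
         paste(rids[unique((which(r$status != 0L) + 1L) %/% 2L)], collapse = ", "))
  mn <- r$objective[seq(1L, length(senses), by = 2L)]
  mx <- r$objective[seq(2L, length(senses), by = 2L)]
  # guard fp dust so min <= max always holds
  flip <- mn > mx
  if (any(flip)) { tmp <- mn[flip]; mn[flip] <- mx[flip]; mx[flip] <- tmp }
  data.frame(reaction = rids, min = mn, max = mx, span = mx - mn,
             stringsAsFactors = FALSE)
}

#' Single-reaction deletion analysis
#'
#' Re-optimizes the objective after forcing each reaction's flux to zero.
#' A reaction is essential iff the post-deletion optimum falls below
#' `essentiality_tolerance` times the wild-type optimum.
#'
#' @param model a feasible `metabolic_model` with objective.
#' @param essentiality_tolerance fraction of the wild-type optimum below which
#'   a deletion counts as lethal (default 0.01).
#' @param reactions optional subset of reaction ids.
#' @return data frame with columns `reaction`, `objective`, `essential`.
#' @export
single_reaction_deletion <- function(model, essentiality_tolerance = 0.01,
                                     reactions = NULL) {
  wt <- fba(model)
  if (wt$status != "optimal") stop("wild-type model is ", wt$status)
  lp <- .lp_matrices(model)
  cvec <- as.numeric(lp$rxn == model$objective)
  rids <- if (is.null(reactions)) lp$rxn else reactions
  ix <- match(rids, lp$rxn)
  if (anyNA(ix)) stop("unknown reaction id(s)")
  res <- vapply(ix, function(i) {
    lpi <- lp
    lpi$lb[i] <- 0; lpi$ub[i] <- 0
    s <- .fba_raw(lpi, cvec, "max")
    if (s$status == "optimal") s$objective else 0
  }, numeric(1))
  data.frame(reaction = rids, objective = res,
             essential = res < essentiality_tolerance * wt$objective,
             stringsAsFactors = FALSE)
}
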