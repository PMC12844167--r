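# Independent brute-force oracles kept deliberately naive.

# dense stoichiometric matrix by a double loop
dense_stoich_oracle <- function(model) {
  M <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (i in seq_len(nrow(model$stoich))) {
    row <- model$stoich[i, ]
    M[row$metabolite, row$reaction] <- M[row$metabolite, row$reaction] + row$coefficient
  }
  M
}

# LP oracle through boot::simplex on the shifted nonnegative formulation
simplex_oracle <- function(model, objective, direction = "max") {
  S <- as.matrix(build_stoichiometric_matrix(model))
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  cvec <- as.numeric(model$reactions$id == objective)
  n <- length(cvec)
  rhs <- as.numeric(-S %*% lb)
  A3 <- S; b3 <- rhs
  neg <- b3 < 0; A3[neg, ] <- -A3[neg, ]; b3[neg] <- -b3[neg]
  o <- boot::simplex(a = cvec, A1 = diag(n), b1 = ub - lb, A3 = A3, b3 = b3,
                     maxi = (direction == "max"))
  if (o$solved != 1) return(NA_real_)
  unname(o$value + sum(cvec * lb))
}

# two-sample KS statistic by an explicit ECDF sweep over all pooled points
ks_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n); out[o] <- pmin(q, 1)
  out
}

# hypergeometric point/tail by exhaustive enumeration of all n-subsets
hyper_enum_oracle <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  inK <- colSums(subsets <= K)   # items 1..K are "in the subsystem"
  c(point = mean(inK == k), tail = mean(inK >= k))
}

# exact paired signed-rank p-value by enumerating all sign assignments
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.numeric(signs %*% r)
  p <- 2 * min(mean(Vs <= V), mean(Vs >= V))   # doubled smaller tail
  list(statistic = V, p.value = min(1, p))
}
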