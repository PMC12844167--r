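test_that("zero-flux restriction closes exactly the member's uptake routes", {
  h <- generate_host_model(seed = 3)
  m <- test_microbe("m1", seed = 5, hard_auxotrophies = "cm01")
  j <- merge_models(list(m), "BIOMASS_m1", "m1", host = h, diet = c(glc = 10))
  r <- apply_restriction(j, "cm01", "m1")
  ix <- r$reactions$id == "m1_IEX_cm01_u_tr"
  expect_equal(r$reactions$lower_bound[ix], 0)
  expect_equal(r$reactions$upper_bound[ix], 0)
  expect_equal(r$reactions[!ix, c("lower_bound", "upper_bound")],
               j$reactions[!ix, c("lower_bound", "upper_bound")])
  # planted auxotrophy: the member's biomass collapses to zero
  expect_equal(fba(r, objective = "m1_BIOMASS_m1")$objective, 0)
  expect_error(apply_restriction(j, "cm05", "m1"), "no registered uptake route")
  # restriction only ever shrinks the flux space
  f0 <- fva(j, 0); f1 <- fva(r, 0)
  expect_true(all(f1$min >= f0$min - 1e-7 & f1$max <= f0$max + 1e-7))
})

test_that("KS statistics match a brute-force ECDF sweep", {
  mk <- function(x) matrix(x, ncol = 1, dimnames = list(NULL, "r1"))
  same <- ks_compare(mk(c(1, 2, 3, 3)), mk(c(1, 2, 3, 3)))
  expect_equal(same$statistic, 0)
  disjoint <- ks_compare(mk(1:50), mk(101:150))
  expect_equal(disjoint$statistic, 1)
  expect_lt(disjoint$p_value, 1e-10)
  set.seed(10)
  for (rep in 1:5) {
    x <- stats::rnorm(50); y <- stats::rnorm(50, mean = 0.3)
    got <- ks_compare(mk(x), mk(y))
    expect_equal(got$statistic, ks_oracle(x, y), tolerance = 1e-12)
  }
  # a reaction missing from one sample is treated as constant zero flux
  a <- matrix(stats::rnorm(40, 5), ncol = 1, dimnames = list(NULL, "only_a"))
  b <- matrix(stats::rnorm(40), ncol = 1, dimnames = list(NULL, "only_b"))
  d <- ks_compare(a, b)
  expect_setequal(d$reaction, c("only_a", "only_b"))
  expect_equal(d$statistic[d$reaction == "only_a"],
               ks_oracle(a[, 1], rep(0, 40)))
  expect_error(ks_compare(a[0, , drop = FALSE], b), "empty")
})

test_that("BH adjustment equals the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(3)
  for (rep in 1:10) {
    p <- stats::runif(sample(2:10, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
    expect_true(all(bh_fdr(p) >= p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)))
})

test_that("normalized flux change has the 10-fold threshold geometry", {
  expect_equal(as.numeric(flux_change(10, 1)), 9 / 11)
  expect_equal(as.numeric(flux_change(3, 3)), 0)
  expect_equal(as.numeric(flux_change(0, 5)), -1)
  expect_equal(as.numeric(flux_change(0, 0)), 0)
  # antisymmetry and boundedness for same-sign means
  set.seed(5)
  a <- stats::runif(50, 0, 10); b <- stats::runif(50, 0, 10)
  expect_equal(as.numeric(flux_change(a, b)), -as.numeric(flux_change(b, a)))
  expect_true(all(abs(flux_change(a, b)) <= 1 + 1e-12))
  # cancelling means hit the flagged sentinel
  fc <- flux_change(1e-13, -1e-13)
  expect_equal(as.numeric(fc), 1e12)
  expect_true(attr(fc, "clipped"))
})

test_that("bootstrap CIs are deterministic, degenerate-safe and calibrated", {
  expect_equal(unname(bootstrap_ci(rep(2.5, 10))), c(2.5, 2.5))
  x <- stats::rnorm(30)
  expect_identical(bootstrap_ci(x, 2000, seed = 11), bootstrap_ci(x, 2000, seed = 11))
  expect_error(bootstrap_ci(1), "at least 2")
  # coverage of zero for centred samples roughly at the nominal level
  set.seed(20)
  cover <- mean(vapply(1:300, function(i) {
    ci <- bootstrap_ci(stats::rnorm(30), n_boot = 300)
    ci[1] <= 0 && ci[2] >= 0
  }, logical(1)))
  expect_gt(cover, 0.89)
  expect_lte(cover, 1)
})

test_that("reaction screening is a conjunction and monotone in its thresholds", {
  res <- data.frame(
    reaction = c("a", "b", "c", "d"),
    q_value = c(0.04, 0.04, 0.2, 0.01),
    fc = c(0.9, 0.5, 0.95, -0.85),
    ci_lower = c(0.1, 0.1, 0.1, -0.5), ci_upper = c(0.5, 0.5, 0.5, -0.1))
  expect_setequal(screen_reactions(res), c("a", "d"))
  expect_setequal(screen_reactions(res, alpha = 0.5), c("a", "c", "d"))
  # lowering alpha or raising the FC threshold never adds reactions
  for (al in c(0.2, 0.05, 0.01))
    for (fcth in c(0.5, 0.82, 0.95)) {
      kept <- screen_reactions(res, al, fcth)
      expect_true(all(kept %in% screen_reactions(res, 0.2, 0.5)))
    }
  # CI containing zero excludes a reaction regardless of q and FC
  res2 <- data.frame(reaction = "x", q_value = 1e-5, fc = 1,
                     ci_lower = -0.1, ci_upper = 0.1)
  expect_length(screen_reactions(res2), 0)
})

test_that("differential analysis flags a planted shift and spares the rest", {
  set.seed(30)
  n <- 800
  before <- cbind(hit = stats::runif(n, 8, 12), null = stats::rnorm(n, 5),
                  still = rep(1, n))
  after <- cbind(hit = stats::runif(n, 0, 0.4), null = stats::rnorm(n, 5),
                 still = rep(1, n))
  d <- differential_analysis(after, before, seed = 1)
  expect_setequal(screen_reactions(d), "hit")
  expect_true(d$q_value[d$reaction == "hit"] < 1e-6)
  expect_lt(d$fc[d$reaction == "hit"], -0.9)
  # identical columns give p = 1, FC = 0
  expect_equal(d$p_value[d$reaction == "still"], 1)
  expect_equal(d$fc[d$reaction == "still"], 0)
  # deterministic given the seed
  d2 <- differential_analysis(after, before, seed = 1)
  expect_identical(d, d2)
})

test_that("biomass classification separates blocked, reduced and unchanged", {
  set.seed(31)
  n <- 600
  bm <- function(x) matrix(x, ncol = 1, dimnames = list(NULL, "BM"))
  before <- bm(stats::runif(n, 2, 6))
  expect_equal(classify_biomass_effect(before, bm(rep(0, n)), "BM")$class, "blocked")
  expect_equal(classify_biomass_effect(before, bm(stats::runif(n, 0, 0.2)), "BM")$class,
               "reduced")
  expect_equal(classify_biomass_effect(before, bm(stats::runif(n, 2, 6)), "BM")$class,
               "unchanged")
  # a mild shift is NOT "reduced": the 10-fold FC gate keeps it unchanged
  expect_equal(classify_biomass_effect(before, bm(stats::runif(n, 1.5, 5)), "BM")$class,
               "unchanged")
  expect_error(classify_biomass_effect(before, bm(rep(0, n)), "nope"), "missing")
})

test_that("key co-metabolite screening reports exactly the affected ones", {
  eff <- data.frame(
    co_metabolite = c("k1", "k1", "k2", "k3", "d1", "d2", "d2"),
    member = c("m2", "m1", "m1", "m3", "m1", "m2", "m1"),
    class = c("blocked", "reduced", "blocked", "reduced",
              "unchanged", "unchanged", "unchanged"))
  key <- screen_key_co_metabolites(eff)
  expect_equal(key$co_metabolite, c("k1", "k2", "k3"))
  expect_equal(key$members[key$co_metabolite == "k1"], "m1,m2")  # sorted
  expect_equal(key$n_affected, c(2L, 1L, 1L))
  none <- screen_key_co_metabolites(
    data.frame(co_metabolite = "d", member = "m1", class = "unchanged"))
  expect_equal(nrow(none), 0)
  # duplicated member rows are deduplicated
  dup <- rbind(eff, eff[1, ])
  expect_equal(screen_key_co_metabolites(dup)$members[1], "m1,m2")
})
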