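test_that("model validation catches structural defects", {
  m <- chain_model()
  expect_silent(validate_model(m))
  bad <- m; bad$reactions$lower_bound[2] <- NaN
  expect_error(validate_model(bad), "non-finite")
  bad <- m; bad$reactions$lower_bound[1] <- 5
  expect_error(validate_model(bad), "lower_bound > upper_bound")
  bad <- m; bad$stoich$metabolite[1] <- "nope"
  expect_error(validate_model(bad), "undeclared metabolites")
  bad <- m; bad$reactions$gpr[2] <- "ghost_gene"
  expect_error(validate_model(bad), "undeclared genes")
  expect_error(metabolic_model(
    id = "dup", compartments = df(id = "c", name = ""),
    metabolites = df(id = c("A_c", "A_c"), compartment = "c"),
    reactions = df(id = "r", lower_bound = 0, upper_bound = 1),
    stoich = df(reaction = "r", metabolite = "A_c", coefficient = -1)),
    "duplicate metabolite")
})

test_that("stoichiometric matrix matches a dense double-loop assembly", {
  m <- chain_model()
  S <- build_stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(S["A_e", "AB"], -1)
  expect_equal(S["B_c", "AB"], 1)
  h <- generate_host_model(seed = 7)
  expect_equal(as.matrix(build_stoichiometric_matrix(h)), dense_stoich_oracle(h))
  mic <- test_microbe(hard_auxotrophies = "cm01", decoys = "cm12")
  expect_equal(as.matrix(build_stoichiometric_matrix(mic)), dense_stoich_oracle(mic))
})

test_that("FBA solves the chain model and reports infeasibility", {
  m <- chain_model()
  z <- fba(m)
  expect_equal(z$status, "optimal")
  expect_equal(z$objective, 10)
  expect_lt(max(abs(build_stoichiometric_matrix(m) %*% z$flux)), 1e-6)
  # deleting the only route drops the optimum to zero
  z0 <- fba(set_bounds(m, "AB", lb = 0, ub = 0))
  expect_equal(z0$objective, 0)
  # forcing incompatible flux makes the LP infeasible
  bad <- set_bounds(m, "AB", lb = 50, ub = 60)
  expect_equal(fba(bad)$status, "infeasible")
  expect_true(is.na(fba(bad)$objective))
})

test_that("FBA optimum matches an independent simplex formulation", {
  skip_if_not_installed("boot")
  for (s in 1:12) {
    m <- random_net_model(s)
    mine <- fba(m)
    oracle <- simplex_oracle(m, m$objective)
    expect_equal(mine$status, "optimal")
    expect_equal(mine$objective, oracle, tolerance = 1e-6)
  }
})

test_that("FBA optimum is invariant under reaction column permutation", {
  m <- random_net_model(3)
  set.seed(1)
  perm <- sample(nrow(m$reactions))
  mp <- m
  mp$reactions <- mp$reactions[perm, , drop = FALSE]
  rownames(mp$reactions) <- NULL
  expect_equal(fba(mp)$objective, fba(m)$objective, tolerance = 1e-8)
})

test_that("FVA brackets fluxes and matches per-reaction LP calls", {
  m <- chain_model()
  f <- fva(m, 0)
  expect_equal(f$min[f$reaction == "AB"], 0)
  expect_equal(f$max[f$reaction == "AB"], 10)
  # a pinned reaction has a zero-width range
  pinned <- set_bounds(m, "AB", lb = 0, ub = 0)
  fp <- fva(pinned, 0)
  expect_equal(fp[fp$reaction == "AB", c("min", "max")],
               data.frame(min = 0, max = 0), ignore_attr = TRUE)
  # oracle: direct FBA with each reaction as the objective
  mic <- test_microbe(hard_auxotrophies = "cm01", partial_dependencies = "cm02")
  f <- fva(mic, 0)
  for (i in seq_len(nrow(f))) {
    expect_equal(f$min[i], fba(mic, "min", objective = f$reaction[i])$objective,
                 tolerance = 1e-6)
    expect_equal(f$max[i], fba(mic, "max", objective = f$reaction[i])$objective,
                 tolerance = 1e-6)
  }
})

test_that("FVA at a fraction of optimum keeps the objective constraint active", {
  m <- chain_model()
  f <- fva(m, fraction_of_optimum = 0.8)
  expect_gte(f$min[f$reaction == "EX_B"], 8 - 1e-8)
  expect_gte(f$min[f$reaction == "AB"], 8 - 1e-8)
})

test_that("tightening bounds never widens FVA ranges", {
  m <- random_net_model(9)
  f0 <- fva(m, 0)
  set.seed(42)
  m2 <- m
  shrink <- stats::runif(nrow(m2$reactions), 0.3, 1)
  mid <- (m2$reactions$lower_bound + m2$reactions$upper_bound) / 2
  m2$reactions$lower_bound <- mid + (m2$reactions$lower_bound - mid) * shrink
  m2$reactions$upper_bound <- mid + (m2$reactions$upper_bound - mid) * shrink
  f2 <- fva(m2, 0)
  expect_true(all(f2$span <= f0$span + 1e-8))
})

test_that("single-reaction deletion finds essential reactions (brute force)", {
  m <- chain_model()
  d <- single_reaction_deletion(m)
  expect_setequal(d$reaction[d$essential], c("EX_A", "AB", "EX_B"))
  # parallel routes: neither route is essential alone
  p <- parallel_model()
  dp <- single_reaction_deletion(p)
  expect_false(any(dp$essential[dp$reaction %in% c("AB1", "AB2")]))
  expect_true(all(dp$essential[dp$reaction %in% c("EX_A", "EX_B")]))
  # brute-force oracle on a synthetic host
  h <- generate_host_model(seed = 2)
  mine <- single_reaction_deletion(h)
  wt <- fba(h)$objective
  brute <- vapply(h$reactions$id, function(r)
    fba(set_bounds(h, r, lb = 0, ub = 0))$objective < 0.01 * wt, logical(1))
  expect_equal(mine$essential, unname(brute))
})

test_that("GPR evaluation follows the min/max convention with unmeasured genes", {
  expect_equal(evaluate_gpr("g1 and g2", c(g1 = 5, g2 = 2)), 2)
  expect_equal(evaluate_gpr("g1 or g2", c(g1 = 5, g2 = 2)), 5)
  expect_equal(evaluate_gpr("(g1 and g2) or g3", c(g1 = 1, g2 = 0, g3 = 4)), 4)
  # unmeasured genes drop out of OR, poison AND
  expect_equal(evaluate_gpr("g1 or g2", c(g1 = 3)), 3)
  expect_true(is.na(evaluate_gpr("g1 and g2", c(g1 = 3))))
  expect_true(is.na(evaluate_gpr(NA, c(g1 = 3))))
  expect_error(evaluate_gpr("g1 and", c(g1 = 1)), "GPR")
  expect_error(parse_gpr("(g1 or g2"), "parentheses")
  expect_error(evaluate_gpr("g1", c(g1 = -2)), "non-negative")
})
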