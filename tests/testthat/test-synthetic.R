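test_that("generators are deterministic functions of their seed", {
  expect_identical(generate_host_model(seed = 9), generate_host_model(seed = 9))
  expect_false(identical(generate_host_model(seed = 9),
                         generate_host_model(seed = 10)))
  a <- test_microbe("mX", seed = 2, hard_auxotrophies = "cm01")
  b <- test_microbe("mX", seed = 2, hard_auxotrophies = "cm01")
  expect_identical(a, b)
  fa <- generate_community_fixture(seed = 5, n_microbes = 2)
  fb <- generate_community_fixture(seed = 5, n_microbes = 2)
  expect_identical(fa, fb)
  # written fixtures are byte-identical across regenerations
  d1 <- file.path(tempfile(), "f1"); d2 <- file.path(tempfile(), "f2")
  write_fixture(fa, d1); write_fixture(fb, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("generated models validate, are feasible, and carry enough GPRs", {
  h <- generate_host_model(seed = 13, n_exchange = 12)
  expect_silent(validate_model(h))
  expect_gt(fba(h)$objective, 0)
  expect_equal(sum(h$metabolites$compartment == "e"), 13)  # panel + nutrient
  expect_gte(mean(!is.na(h$reactions$gpr)), 0.6)
  m <- test_microbe("m9", seed = 13, hard_auxotrophies = "cm03",
                    partial_dependencies = "cm05", decoys = "cm07")
  expect_silent(validate_model(m))
  expect_gt(fba(m)$objective, 0)
})

test_that("planted dependency classes behave as planted under restriction", {
  m <- test_microbe("m1", seed = 21, hard_auxotrophies = "cm01",
                    partial_dependencies = "cm02", decoys = "cm11")
  wt <- fba(m)$objective
  cut <- function(p) fba(set_bounds(m, paste0("EX_", p, "_e"), lb = 0, ub = 0))$objective
  expect_lt(cut("cm01"), 1e-9)                       # hard: no growth
  expect_gt(cut("cm02"), 1e-9)                       # partial: between
  expect_lt(cut("cm02"), wt - 1e-6)
  expect_equal(cut("cm11"), wt, tolerance = 1e-8)    # decoy: unchanged
  # impossible layouts are rejected with a diagnosis
  expect_error(test_microbe("mz", hard_auxotrophies = "nope"), "outside the panel")
  expect_error(test_microbe("mz", hard_auxotrophies = "cm01",
                            decoys = "cm01"), "disjoint")
})

test_that("the planted enriched subsystem sits downstream of a dependency", {
  m <- test_microbe("m1", seed = 3, hard_auxotrophies = "cm01")
  ple <- m$reactions$id[m$reactions$subsystem == "Glycerophospholipid metabolism"]
  expect_gte(length(ple), 3)
  # cutting the dependency collapses the whole labelled chain
  cutm <- set_bounds(m, "EX_cm01_e", lb = 0, ub = 0)
  f <- fva(cutm, 0, reactions = ple)
  expect_true(all(abs(f$min) < 1e-9 & abs(f$max) < 1e-9))
})

test_that("expression tables separate active and inactive genes", {
  h <- generate_host_model(seed = 2)
  tab <- generate_expression_table(h, active_fraction = 0.5, seed = 4)
  prof <- aggregate_expression(tab)
  planted <- attr(tab, "active_genes")
  got <- filter_active_genes(prof)
  expect_setequal(got, planted)
  expect_equal(ncol(tab), 21)
})

test_that("the standard community fixture is coherent and joint-feasible", {
  fx <- generate_community_fixture(seed = 17)
  expect_length(fx$microbes, 5)
  expect_length(fx$ground_truth$key_co_metabolites, 3)
  expect_length(fx$ground_truth$decoys, 2)
  tr <- fx$ground_truth$expected
  expect_true(all(tr$co_metabolite %in% std_panel))
  # every member grows in its pairwise joint model with the host
  for (tag in fx$tags) {
    j <- merge_models(fx$microbes[tag], unname(fx$biomass_ids[tag]), tag,
                      host = fx$host, diet = fx$diet)
    expect_gt(fba(j, objective = paste0(tag, "_", fx$biomass_ids[tag]))$objective, 0)
  }
  # fixtures round-trip through disk loading
  d <- tempfile()
  write_fixture(fx, d)
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  gt <- jsonlite::fromJSON(file.path(d, "ground_truth.json"))
  expect_equal(sort(gt$key_co_metabolites), fx$ground_truth$key_co_metabolites)
})
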