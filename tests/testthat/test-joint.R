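test_that("tagging prefixes all ids consistently and preserves the optimum", {
  m <- chain_model()
  t <- tag_model(m, "FN")
  expect_true("FN_AB" %in% t$reactions$id)
  expect_true(all(t$stoich$metabolite %in% t$metabolites$id))
  expect_equal(t$objective, "FN_EX_B")
  expect_equal(fba(t)$objective, fba(m)$objective)
  expect_error(tag_model(t, "FN"), "already tagged")
  expect_identical(tag_model(t, "FN", idempotent = TRUE), t)
  expect_error(tag_model(m, "1bad"), "invalid member tag")
  # GPR gene leaves are renamed with the genes
  p <- tag_model(parallel_model(), "BF")
  expect_equal(p$reactions$gpr[p$reactions$id == "BF_AB1"], "BF_g1")
  expect_silent(validate_model(p))
})

test_that("create_interspace builds one reversible [-1/+1] transport per [e] metabolite", {
  h <- generate_host_model(n_exchange = 3, seed = 1)
  th <- tag_model(h, "Host")
  ci <- create_interspace(th, "Host")
  expect_equal(nrow(ci$registry), 4)  # 3 panel + 1 nutrient
  expect_true(all(ci$registry$met_u %in% ci$model$metabolites$id))
  S <- build_stoichiometric_matrix(ci$model)
  for (i in seq_len(nrow(ci$registry))) {
    col <- S[, ci$registry$reaction[i]]
    expect_equal(unname(col[ci$registry$met_e[i]]), -1)
    expect_equal(unname(col[ci$registry$met_u[i]]), 1)
    expect_equal(sum(col != 0), 2)
  }
  # reversibility
  ix <- match(ci$registry$reaction, ci$model$reactions$id)
  expect_true(all(ci$model$reactions$lower_bound[ix] < 0))
  # declared but empty [e]: no-op with empty registry
  cyt <- box_model(c(2, 3))
  cyt$compartments <- rbind(cyt$compartments,
                            df(id = "e", name = "extracellular"))
  ci0 <- create_interspace(cyt, "m1")
  expect_equal(nrow(ci0$registry), 0)
  expect_equal(nrow(ci0$model$reactions), nrow(cyt$reactions))
  # no [e] compartment at all: explicit error
  expect_error(create_interspace(box_model(2), "m1"),
               "no extracellular compartment")
})

test_that("two microbes sharing glucose unify a single lumen metabolite", {
  m1 <- test_microbe("m1", seed = 1)
  m2 <- test_microbe("m2", seed = 2)
  j <- merge_models(list(m1, m2), c("BIOMASS_m1", "BIOMASS_m2"), c("m1", "m2"),
                    diet = c(glc = 10))
  expect_equal(sum(j$metabolites$id == "glc_u"), 1)
  glc_iex <- j$interspace[j$interspace$base == "glc", ]
  expect_setequal(glc_iex$member, c("m1", "m2"))
  expect_error(merge_models(list(m1, m2), c("BIOMASS_m1", "BIOMASS_m2"),
                            c("m1", "m1")), "duplicate member tags")
  expect_error(merge_models(list(m1), "BIOMASS_nope", "m1"), "not found")
})

test_that("a single member's joint optimum equals its standalone optimum", {
  m <- test_microbe("m1", seed = 4)     # no dependencies: glucose-limited
  alone <- fba(m)$objective
  j <- merge_models(list(m), "BIOMASS_m1", "m1", diet = c(glc = 10))
  expect_equal(fba(j, objective = "m1_BIOMASS_m1")$objective, alone,
               tolerance = 1e-8)
})

test_that("joint metabolite counts decompose into members plus lumen and body fluid", {
  h <- generate_host_model(seed = 3)
  m <- test_microbe("m1", seed = 5, hard_auxotrophies = "cm01")
  j <- merge_models(list(m), "BIOMASS_m1", "m1", host = h, diet = c(glc = 10))
  n_host_e <- sum(h$metabolites$compartment == "e")
  lumen <- unique(c(h$metabolites$id[h$metabolites$compartment == "e"],
                    m$metabolites$id[m$metabolites$compartment == "e"]))
  expect_equal(nrow(j$metabolites),
               nrow(h$metabolites) + n_host_e +   # host + its [b] twins
                 nrow(m$metabolites) + length(lumen))
  # no microbe reaction touches the host body-fluid compartment
  bmets <- j$metabolites$id[j$metabolites$compartment == "Host_b"]
  touching <- unique(j$stoich$reaction[j$stoich$metabolite %in% bmets])
  expect_true(all(j$reactions$member_tag[match(touching, j$reactions$id)] == "Host"))
})

test_that("merge order only relabels: biomass optima are invariant", {
  m1 <- test_microbe("m1", seed = 1, hard_auxotrophies = "cm01")
  m2 <- test_microbe("m2", seed = 2)
  h <- generate_host_model(seed = 3)
  j12 <- merge_models(list(m1, m2), c("BIOMASS_m1", "BIOMASS_m2"),
                      c("m1", "m2"), host = h, diet = c(glc = 10))
  j21 <- merge_models(list(m2, m1), c("BIOMASS_m2", "BIOMASS_m1"),
                      c("m2", "m1"), host = h, diet = c(glc = 10))
  for (b in c("m1_BIOMASS_m1", "m2_BIOMASS_m2", "Host_BIOMASS_host"))
    expect_equal(fba(j12, objective = b)$objective,
                 fba(j21, objective = b)$objective, tolerance = 1e-7)
})

test_that("no member grows faster jointly than standalone with open supply", {
  fx <- generate_community_fixture(seed = 9, n_microbes = 3)
  for (tag in fx$tags) {
    alone <- fba(fx$microbes[[tag]])$objective
    j <- merge_models(fx$microbes[tag], unname(fx$biomass_ids[tag]), tag,
                      host = fx$host, diet = fx$diet)
    expect_lte(fba(j, objective = paste0(tag, "_", fx$biomass_ids[tag]))$objective,
               alone + 1e-7)
  }
})

test_that("futile secretion/re-uptake loops are pruned without hurting biomass", {
  mk_looper <- function(id, from, to) {
    metabolic_model(
      id = id,
      compartments = df(id = c("e", "c"), name = c("extracellular", "cytosol")),
      metabolites = df(id = c("A_e", "B_e", "X_c"), compartment = c("e", "e", "c")),
      reactions = df(id = c("CONV", "GROW"),
                     lower_bound = c(-50, 0), upper_bound = c(50, 10)),
      stoich = df(reaction = c("CONV", "CONV", "GROW"),
                  metabolite = c(from, to, "X_c"),
                  coefficient = c(-1, 1, -1)),
      objective = "GROW")
  }
  l1 <- mk_looper("l1", "A_e", "B_e")
  l2 <- mk_looper("l2", "B_e", "A_e")
  j <- merge_models(list(l1, l2), c("GROW", "GROW"), c("l1", "l2"))
  closed <- set_bounds(j, exchange_reactions(j), lb = 0, ub = 0)
  f_loop <- fva(closed, 0, reactions = j$interspace$reaction)
  expect_true(any(abs(f_loop$min) > 1e-6 | abs(f_loop$max) > 1e-6))
  pruned <- remove_futile_cycles(j)
  expect_setequal(attr(pruned, "futile_restricted"), c("A_u", "B_u"))
  closed_p <- set_bounds(pruned, exchange_reactions(pruned), lb = 0, ub = 0)
  f_p <- fva(closed_p, 0, reactions = pruned$interspace$reaction)
  expect_true(all(abs(f_p$min) < 1e-6 & abs(f_p$max) < 1e-6))
  # loop-free community: no restriction, biomass optima preserved
  fx <- generate_community_fixture(seed = 4, n_microbes = 2)
  j2 <- merge_models(fx$microbes, unname(fx$biomass_ids), fx$tags,
                     host = fx$host, diet = fx$diet)
  before <- vapply(j2$members$biomass, function(b)
    fba(j2, objective = b)$objective, numeric(1))
  j2p <- remove_futile_cycles(j2)
  expect_length(attr(j2p, "futile_restricted"), 0)
  after <- vapply(j2p$members$biomass, function(b)
    fba(j2p, objective = b)$objective, numeric(1))
  expect_equal(after, before, tolerance = 1e-6)
})

test_that("co-metabolite identification matches per-reaction FVA sign analysis", {
  h <- generate_host_model(seed = 3)
  m <- test_microbe("m1", seed = 5, hard_auxotrophies = "cm01",
                    partial_dependencies = "cm02", decoys = c("cm11", "cm12"))
  j <- merge_models(list(m), "BIOMASS_m1", "m1", host = h, diet = c(glc = 10))
  cm <- identify_co_metabolites(j)
  expect_setequal(cm$co_metabolites$base, c("cm01", "cm02", "cm11", "cm12"))
  x <- cm$co_metabolites[cm$co_metabolites$base == "cm01", ]
  expect_equal(x$host_reaction, "Host_IEX_cm01_u_tr")
  expect_equal(x$uptake_reactions, "m1_IEX_cm01_u_tr")
  # host-secreted but not taken up -> host_derived, not co-metabolite
  cls <- cm$classification
  expect_true(all(cls$class[cls$base %in% sprintf("cm%02d", 3:10)] == "host_derived"))
  expect_equal(cls$class[cls$base == "waste"], "microbe_derived")
  # partition property: every lumen metabolite in exactly one class
  expect_setequal(cls$met_u, j$metabolites$id[j$metabolites$compartment == "u"])
  expect_true(all(cls$class %in% c("co_metabolite", "host_derived", "microbe_derived")))
  # brute-force oracle: per-reaction min/max sign analysis
  reg <- j$interspace
  sec <- up <- logical(nrow(reg))
  for (i in seq_len(nrow(reg))) {
    sec[i] <- fba(j, "max", objective = reg$reaction[i])$objective > 1e-6
    up[i] <- fba(j, "min", objective = reg$reaction[i])$objective < -1e-6
  }
  brute <- unique(reg$base[reg$member == "Host" & sec])
  brute <- intersect(brute, unique(reg$base[reg$member != "Host" & up]))
  expect_setequal(cm$co_metabolites$base, brute)
  expect_error(identify_co_metabolites(
    merge_models(list(m), "BIOMASS_m1", "m1", diet = c(glc = 10))), "no host")
})
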