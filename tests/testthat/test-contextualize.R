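test_that("expression aggregation means match a streaming-sum oracle", {
  tab <- data.frame(gene = "g", s1 = 0, s2 = 2, s3 = 4)
  expect_equal(aggregate_expression(tab)$mean_tpm, 2)
  one <- data.frame(gene = c("a", "b"), s1 = c(1.5, 0.2))
  expect_equal(aggregate_expression(one)$mean_tpm, c(1.5, 0.2))
  set.seed(8)
  big <- cbind(data.frame(gene = sprintf("g%03d", 1:100)),
               matrix(stats::rexp(2000), 100, 20))
  prof <- aggregate_expression(big)
  stream <- apply(as.matrix(big[, -1]), 1, function(x) {
    s <- 0; for (v in x) s <- s + v; s / length(x)
  })
  expect_equal(prof$mean_tpm, unname(stream))
  expect_equal(attr(prof, "n_samples"), 20)
  expect_error(aggregate_expression(rbind(tab, tab)), "duplicate gene")
  expect_error(aggregate_expression(data.frame(gene = "g", s1 = -1)),
               "non-negative")
})

test_that("active-gene filtering is strictly greater-than the threshold", {
  prof <- data.frame(gene = c("g1", "g2"), mean_tpm = c(1.0, 1.01))
  class(prof) <- c("expression_profile", class(prof))
  expect_equal(filter_active_genes(prof), "g2")
  prof$mean_tpm <- c(0, 0)
  expect_length(filter_active_genes(prof), 0)
})

test_that("planted active fractions are recovered within the binomial interval", {
  h <- generate_host_model(seed = 1)
  n_genes <- nrow(h$genes)
  for (s in 1:5) {
    tab <- generate_expression_table(h, active_fraction = 0.4, n_samples = 20,
                                     seed = s)
    frac <- length(filter_active_genes(aggregate_expression(tab))) / n_genes
    expect_gte(frac, 0.4 - 3 * sqrt(0.4 * 0.6 / n_genes))
    expect_lte(frac, 0.4 + 3 * sqrt(0.4 * 0.6 / n_genes))
  }
  all_on <- generate_expression_table(h, active_fraction = 1, seed = 1)
  expect_setequal(filter_active_genes(aggregate_expression(all_on)), h$genes$id)
  all_off <- generate_expression_table(h, active_fraction = 0, seed = 1)
  expect_length(filter_active_genes(aggregate_expression(all_off)), 0)
})

test_that("context extraction prunes inactive reactions but keeps feasibility", {
  p <- parallel_model()
  # all genes active: nothing is removed
  full <- extract_context_model(p, c("g1", "g2"))
  expect_setequal(full$reactions$id, p$reactions$id)
  # the g2 route is inactive; the g1 route still carries the optimum
  ctx <- extract_context_model(p, "g1")
  expect_false("AB2" %in% ctx$reactions$id)
  expect_equal(fba(ctx)$objective, 10)
  expect_length(attr(ctx, "restored_reactions"), 0)
  # sole-route model with an inactive gene: the reaction is restored, flagged
  m <- chain_model()
  m$reactions$gpr[m$reactions$id == "AB"] <- "g1"
  m$genes <- df(id = "g1", name = "")
  ctx2 <- extract_context_model(m, character())
  expect_true("AB" %in% ctx2$reactions$id)
  expect_equal(attr(ctx2, "restored_reactions"), "AB")
  expect_equal(fba(ctx2)$objective, 10)
})

test_that("protected reactions survive extraction", {
  p <- parallel_model()
  ctx <- extract_context_model(p, "g1", protected_reactions = c("EX_B", "AB2"))
  expect_true("AB2" %in% ctx$reactions$id)
})

test_that("E-flux tightens bounds proportionally and never widens them", {
  p <- parallel_model()
  prof <- c(g1 = 100, g2 = 0)
  ef <- apply_eflux(p, prof, scaling = "absolute")
  rx <- function(m, id, f) m$reactions[[f]][m$reactions$id == id]
  # top-scoring reaction keeps its bounds
  expect_equal(rx(ef, "AB1", "upper_bound"), rx(p, "AB1", "upper_bound"))
  # zero-scoring reaction is pinned to zero
  expect_equal(rx(ef, "AB2", "lower_bound"), 0)
  expect_equal(rx(ef, "AB2", "upper_bound"), 0)
  # unmeasured reactions keep their bounds
  expect_equal(rx(ef, "EX_A", "lower_bound"), -10)
  # FVA ranges only contract (host fixture, quantile scaling)
  h <- generate_host_model(seed = 6)
  prof <- aggregate_expression(generate_expression_table(h, 0.7, seed = 2))
  ef <- apply_eflux(h, prof)
  f0 <- fva(h, 0); f1 <- fva(ef, 0)
  expect_true(all(f1$min >= f0$min - 1e-9))
  expect_true(all(f1$max <= f0$max + 1e-9))
})

test_that("model self-comparison is null", {
  m <- chain_model()
  cmp <- compare_models(m, m)
  expect_equal(cmp$gene_reduction, 0)
  expect_equal(cmp$reaction_reduction, 0)
  expect_equal(cmp$test$p.value, 1)
  expect_length(cmp$essential$gained, 0)
  expect_length(cmp$essential$lost, 0)
})

test_that("comparison against an e-fluxed model contracts every shared span", {
  h <- generate_host_model(seed = 6)
  prof <- aggregate_expression(generate_expression_table(h, 0.6, seed = 3))
  ef <- apply_eflux(h, prof)
  cmp <- compare_models(h, ef)
  expect_true(all(cmp$fva_spans$delta <= 1e-8))
})

test_that("the paired signed-rank test matches exact sign-flip enumeration", {
  g <- random_net_model(21, m = 3, n = 10)
  set.seed(77)
  sp <- g
  shrink <- stats::runif(nrow(sp$reactions), 0.2, 0.95)
  mid <- (sp$reactions$lower_bound + sp$reactions$upper_bound) / 2
  sp$reactions$lower_bound <- mid + (sp$reactions$lower_bound - mid) * shrink
  sp$reactions$upper_bound <- mid + (sp$reactions$upper_bound - mid) * shrink
  cmp <- compare_models(g, sp)
  d <- cmp$fva_spans$delta
  skip_if(any(d == 0) || anyDuplicated(abs(d)), "tied spans; exact test undefined")
  oracle <- signed_rank_oracle(d)
  expect_equal(unname(cmp$test$statistic), oracle$statistic)
  expect_equal(cmp$test$p.value, oracle$p.value, tolerance = 1e-12)
})

test_that("rank-sum variant is available", {
  g <- random_net_model(22, m = 3, n = 8)
  sp <- g
  sp$reactions$upper_bound <- sp$reactions$upper_bound * 0.7 +
    sp$reactions$lower_bound * 0.3
  cmp <- compare_models(g, sp, paired_test = "rank-sum")
  expect_match(cmp$test$method, "rank sum")
})
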