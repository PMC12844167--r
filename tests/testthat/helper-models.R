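# Tiny fixture models built in code.

df <- function(...) data.frame(..., stringsAsFactors = FALSE)

# EX_A (uptake, lb -10) -> AB -> EX_B; FBA max EX_B = 10
chain_model <- function(ub = 100) {
  metabolic_model(
    id = "chain",
    compartments = df(id = c("e", "c"), name = c("extracellular", "cytosol")),
    metabolites = df(id = c("A_e", "B_c"), compartment = c("e", "c")),
    reactions = df(id = c("EX_A", "AB", "EX_B"),
                   lower_bound = c(-10, 0, 0), upper_bound = c(0, ub, ub)),
    stoich = df(reaction = c("EX_A", "AB", "AB", "EX_B"),
                metabolite = c("A_e", "A_e", "B_c", "B_c"),
                coefficient = c(-1, -1, 1, -1)),
    objective = "EX_B")
}

# chain with two parallel A->B routes carrying GPRs g1 / g2
parallel_model <- function() {
  metabolic_model(
    id = "parallel",
    compartments = df(id = c("e", "c"), name = c("extracellular", "cytosol")),
    metabolites = df(id = c("A_e", "B_c"), compartment = c("e", "c")),
    reactions = df(id = c("EX_A", "AB1", "AB2", "EX_B"),
                   lower_bound = c(-10, 0, 0, 0),
                   upper_bound = c(0, 100, 100, 100),
                   gpr = c(NA, "g1", "g2", NA)),
    stoich = df(reaction = c("EX_A", "AB1", "AB1", "AB2", "AB2", "EX_B"),
                metabolite = c("A_e", "A_e", "B_c", "A_e", "B_c", "B_c"),
                coefficient = c(-1, -1, 1, -1, 1, -1)),
    genes = df(id = c("g1", "g2"), name = ""),
    objective = "EX_B")
}

# k independent in/out pairs: S v = 0 forces IN_i = OUT_i in [0, w_i];
# the free coordinates are uniform on an axis-aligned box
box_model <- function(widths) {
  k <- length(widths)
  mets <- sprintf("X%d_c", seq_len(k))
  rid <- c(rbind(sprintf("IN_%d", seq_len(k)), sprintf("OUT_%d", seq_len(k))))
  metabolic_model(
    id = "box",
    compartments = df(id = "c", name = "cytosol"),
    metabolites = df(id = mets, compartment = "c"),
    reactions = df(id = rid, lower_bound = 0,
                   upper_bound = rep(widths, each = 2)),
    stoich = df(reaction = rid, metabolite = rep(mets, each = 2),
                coefficient = rep(c(1, -1), k)),
    objective = NULL, validate = TRUE)
}

# random sparse network with a guaranteed interior feasible point (nullspace
# sample); continuous bounds so FVA spans are almost surely tie-free
random_net_model <- function(seed, m = 4, n = 8, slack = 2) {
  set.seed(seed)
  repeat {
    S <- matrix(stats::rnorm(m * n), m, n)
    S[abs(S) < 0.3] <- 0
    if (all(colSums(S != 0) > 0) && all(rowSums(S != 0) > 0)) break
  }
  NS <- svd(S, nu = 0, nv = n)$v[, -(seq_len(qr(S)$rank)), drop = FALSE]
  if (!ncol(NS)) return(random_net_model(seed + 1000, m, n, slack))
  v0 <- as.numeric(NS %*% stats::rnorm(ncol(NS)))
  lb <- v0 - stats::runif(n, 0.2, slack)
  ub <- v0 + stats::runif(n, 0.2, slack)
  mets <- sprintf("M%d_c", seq_len(m)); rid <- sprintf("r%d", seq_len(n))
  idx <- which(S != 0, arr.ind = TRUE)
  metabolic_model(
    id = paste0("rand", seed),
    compartments = df(id = "c", name = "cytosol"),
    metabolites = df(id = mets, compartment = "c"),
    reactions = df(id = rid, lower_bound = lb, upper_bound = ub),
    stoich = df(reaction = rid[idx[, 2]], metabolite = mets[idx[, 1]],
                coefficient = S[idx]),
    objective = rid[1])
}

# label-only model for enrichment tests: one sink reaction per metabolite,
# subsystems assigned in blocks
subsystem_model <- function(n_per_subsystem, labels) {
  k <- length(labels)
  n <- n_per_subsystem * k
  rid <- sprintf("r%03d", seq_len(n)); mets <- sprintf("M%03d_c", seq_len(n))
  metabolic_model(
    id = "subsys",
    compartments = df(id = "c", name = "cytosol"),
    metabolites = df(id = mets, compartment = "c"),
    reactions = df(id = rid, lower_bound = 0, upper_bound = 1,
                   subsystem = rep(labels, each = n_per_subsystem)),
    stoich = df(reaction = rid, metabolite = mets, coefficient = -1),
    objective = NULL)
}

std_panel <- sprintf("cm%02d", 1:12)

# small microbe used across joint/differential tests
test_microbe <- function(id = "m1", seed = 5, ...) {
  generate_microbe_model(id, panel = std_panel, seed = seed, ...)
}
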