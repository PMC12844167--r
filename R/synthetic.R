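# Synthetic toy fixtures with planted ground truth: a secreting host model, a
# panel of auxotrophic/partially dependent microbe models, log-normal TPM
# tables, and the assembled community fixture. Every generator is a
# deterministic function of (seed, parameters) and verifies its own planted
# dependency classes by direct FBA at generation time.

.derive_seed <- function(seed, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647 + 1)
}

.df <- function(...) data.frame(..., stringsAsFactors = FALSE)

.rxn_row <- function(id, name, lb, ub, gpr = NA, subsystem = NA, member = NA) {
  .df(id = id, name = name, lower_bound = lb, upper_bound = ub, gpr = gpr,
      subsystem = subsystem, member_tag = member)
}

.stoich_rows <- function(id, coefs) {
  .df(reaction = id, metabolite = names(coefs), coefficient = unname(coefs))
}

# random 1- or 2-gene rule drawn from a gene pool
.random_gpr <- function(pool) {
  k <- sample(3L, 1)
  g <- sample(pool, min(2, k))
  switch(k, g[1], paste(g[1], "and", g[2]), paste(g[1], "or", g[2]))
}

#' Generate a synthetic secreting host model
#'
#' A two-compartment (cytosol/extracellular) toy host: nutrient uptake, a
#' short GPR-covered central chain to a precursor, a biomass sink, and one
#' biosynthesis + secretion + exchange route per panel metabolite, so the
#' host can supply a defined metabolite panel to a shared lumen. At least
#' 60% of reactions carry GPR rules.
#'
#' @param n_core_metabolites length of the central chain (>= 1, default 3).
#' @param n_exchange panel size = number of secreted extracellular
#'   metabolites (default 12).
#' @param seed RNG seed (gene wiring).
#' @param panel optional explicit panel ids (default `cm01`, `cm02`, ...).
#' @param default_bound bound magnitude B (default 1000).
#' @param nutrient_uptake host nutrient uptake capacity (default 20).
#' @return a feasible `metabolic_model` with objective `BIOMASS_host`.
#' @export
generate_host_model <- function(n_core_metabolites = 3, n_exchange = 12,
                                seed = 1, panel = NULL, default_bound = 1000,
                                nutrient_uptake = 20) {
  stopifnot(n_core_metabolites >= 1, n_exchange >= 1)
  set.seed(seed)
  B <- default_bound
  if (is.null(panel)) panel <- sprintf("cm%02d", seq_len(n_exchange))
  stopifnot(length(panel) == n_exchange)
  pool <- sprintf("hg%03d", seq_len(max(6, round(1.5 * (n_core_metabolites + 2 * n_exchange)))))

  chain <- c("nut_c", if (n_core_metabolites > 1)
    sprintf("ic%02d_c", seq_len(n_core_metabolites - 1)), "pre_c")
  mets <- .df(id = c("nut_e", chain, paste0(panel, "_c"), paste0(panel, "_e")),
              compartment = c("e", rep("c", length(chain)),
                              rep("c", n_exchange), rep("e", n_exchange)))
  mets$name <- mets$id

  rx <- list(); st <- list()
  rx$exn <- .rxn_row("EX_nut_e", "nutrient exchange", -nutrient_uptake, 0,
                     subsystem = "Exchange")
  st$exn <- .stoich_rows("EX_nut_e", c(nut_e = -1))
  rx$trn <- .rxn_row("TR_nut", "nutrient transport", 0, B, .random_gpr(pool), "Transport")
  st$trn <- .stoich_rows("TR_nut", c(nut_e = -1, nut_c = 1))
  for (i in seq_len(n_core_metabolites)) {
    id <- sprintf("CORE%02d", i)
    rx[[id]] <- .rxn_row(id, paste("central step", i), 0, B, .random_gpr(pool),
                         "Central metabolism")
    st[[id]] <- .stoich_rows(id, stats::setNames(c(-1, 1), c(chain[i], chain[i + 1])))
  }
  rx$bm <- .rxn_row("BIOMASS_host", "host biomass", 0, B, subsystem = "Biomass")
  st$bm <- .stoich_rows("BIOMASS_host", c(pre_c = -1))
  for (p in panel) {
    syn <- paste0("SYN_", p); tr <- paste0("TRS_", p); ex <- paste0("EX_", p, "_e")
    rx[[syn]] <- .rxn_row(syn, paste(p, "biosynthesis"), 0, B, .random_gpr(pool),
                          "Secretion biosynthesis")
    st[[syn]] <- .stoich_rows(syn, stats::setNames(c(-1, 1), c("pre_c", paste0(p, "_c"))))
    rx[[tr]] <- .rxn_row(tr, paste(p, "secretion"), 0, B, .random_gpr(pool), "Transport")
    st[[tr]] <- .stoich_rows(tr, stats::setNames(c(-1, 1), paste0(p, c("_c", "_e"))))
    rx[[ex]] <- .rxn_row(ex, paste(p, "exchange"), 0, B, subsystem = "Exchange")
    st[[ex]] <- .stoich_rows(ex, stats::setNames(-1, paste0(p, "_e")))
  }
  rxns <- do.call(rbind, rx); stoich <- do.call(rbind, st)
  used_genes <- sort(unique(unlist(lapply(
    rxns$gpr[!is.na(rxns$gpr)], function(r) gpr_genes(parse_gpr(r))))))
  m <- metabolic_model(
    id = "synthetic_host",
    compartments = .df(id = c("c", "e"), name = c("cytosol", "extracellular")),
    metabolites = mets, reactions = rxns, stoich = stoich,
    genes = .df(id = used_genes, name = used_genes), objective = "BIOMASS_host")
  z <- fba(m)
  if (z$status != "optimal" || z$objective <= 0)
    stop("generated host model is not viable (status ", z$status, ")")
  m
}

#' Generate a synthetic microbe model with planted dependencies
#'
#' A toy gut microbe: glucose uptake and glycolysis to an energy currency,
#' a biomass reaction, and per planted metabolite an uptake transport.
#' Hard auxotrophies enter biomass with no internal synthesis route; partial
#' dependencies additionally get a low-capacity internal bypass (so
#' restriction reduces but does not abolish growth); decoys are taken up and
#' degraded to a secreted waste product without touching biomass. The first
#' hard auxotrophy is wired through a short activation chain labelled with a
#' designated subsystem, planting a downstream enrichment signal. Planted
#' classes are verified by FBA at generation time.
#'
#' @param id member identifier (also names the biomass reaction
#'   `BIOMASS_<id>`).
#' @param panel allowed metabolite panel (superset of all planted ids).
#' @param hard_auxotrophies,partial_dependencies,decoys disjoint subsets of
#'   `panel`.
#' @param subsystem_layout optional named list overriding subsystem labels;
#'   entry `enriched` names the planted-enriched subsystem (default
#'   `"Glycerophospholipid metabolism"`).
#' @param seed RNG seed (gene wiring).
#' @param default_bound bound magnitude (default 1000).
#' @param glc_uptake carbon uptake capacity (default 10).
#' @param partial_capacity bypass capacity of partial dependencies
#'   (default 0.05).
#' @param biomass_coef stoichiometric demand of each dependency per unit
#'   biomass (default 0.5).
#' @return a feasible `metabolic_model` with objective `BIOMASS_<id>`.
#' @export
generate_microbe_model <- function(id = "m1", panel,
                                   hard_auxotrophies = character(),
                                   partial_dependencies = character(),
                                   decoys = character(),
                                   subsystem_layout = NULL, seed = 1,
                                   default_bound = 1000, glc_uptake = 10,
                                   partial_capacity = 0.05, biomass_coef = 0.5) {
  set.seed(seed)
  B <- default_bound
  planted <- c(hard_auxotrophies, partial_dependencies, decoys)
  if (anyDuplicated(planted))
    stop("hard/partial/decoy sets must be disjoint")
  if (!all(planted %in% panel))
    stop("planted metabolites outside the panel: ",
         paste(setdiff(planted, panel), collapse = ", "))
  lay <- list(enriched = "Glycerophospholipid metabolism", transport = "Transport",
              exchange = "Exchange", glycolysis = "Glycolysis",
              salvage = "Salvage biosynthesis", degradation = "Degradation",
              biomass = "Biomass")
  lay[names(subsystem_layout)] <- subsystem_layout
  pool <- sprintf("%s_g%03d", id, seq_len(max(4, 2 * (length(planted) + 2))))

  deps <- c(hard_auxotrophies, partial_dependencies)
  mets <- .df(id = c("glc_e", "glc_c", "atp_c", "waste_c", "waste_e",
                     paste0(planted, "_e", recycle0 = TRUE),
                     paste0(planted, "_c", recycle0 = TRUE)),
              compartment = c("e", "c", "c", "c", "e",
                              rep("e", length(planted)), rep("c", length(planted))))
  rx <- list(); st <- list()
  rx$exg <- .rxn_row("EX_glc_e", "glucose exchange", -glc_uptake, 0,
                     subsystem = lay$exchange)
  st$exg <- .stoich_rows("EX_glc_e", c(glc_e = -1))
  rx$trg <- .rxn_row("TR_glc", "glucose transport", 0, B, .random_gpr(pool),
                     lay$transport)
  st$trg <- .stoich_rows("TR_glc", c(glc_e = -1, glc_c = 1))
  rx$gly <- .rxn_row("GLYC", "glycolysis (lumped)", 0, B, .random_gpr(pool),
                     lay$glycolysis)
  st$gly <- .stoich_rows("GLYC", c(glc_c = -1, atp_c = 2))

  biomass_in <- c(atp_c = -1)
  chain_target <- if (length(hard_auxotrophies)) hard_auxotrophies[1] else NA
  for (p in planted) {
    tr <- paste0("TR_", p); ex <- paste0("EX_", p, "_e")
    rx[[tr]] <- .rxn_row(tr, paste(p, "uptake transport"), 0, B,
                         if (stats::runif(1) < 0.7) .random_gpr(pool) else NA,
                         lay$transport)
    st[[tr]] <- .stoich_rows(tr, stats::setNames(c(-1, 1), paste0(p, c("_e", "_c"))))
    rx[[ex]] <- .rxn_row(ex, paste(p, "exchange"), -glc_uptake, 0,
                         subsystem = lay$exchange)
    st[[ex]] <- .stoich_rows(ex, stats::setNames(-1, paste0(p, "_e")))
  }
  for (p in partial_dependencies) {
    syn <- paste0("SYN_", p)
    rx[[syn]] <- .rxn_row(syn, paste(p, "internal bypass"), 0, partial_capacity,
                          .random_gpr(pool), lay$salvage)
    st[[syn]] <- .stoich_rows(syn, stats::setNames(c(-1, 1), c("atp_c", paste0(p, "_c"))))
  }
  for (p in deps) {
    if (!is.na(chain_target) && p == chain_target) {
      # activation chain planting a downstream enriched subsystem
      ch <- paste0(p, c("_act1_c", "_act2_c", "_act3_c"))
      mets <- rbind(mets, .df(id = ch, compartment = "c"))
      prev <- paste0(p, "_c")
      for (q in seq_along(ch)) {
        rid <- sprintf("PLE_%s_%d", p, q)
        rx[[rid]] <- .rxn_row(rid, paste(p, "activation step", q), 0, B,
                              .random_gpr(pool), lay$enriched)
        st[[rid]] <- .stoich_rows(rid, stats::setNames(c(-1, 1), c(prev, ch[q])))
        prev <- ch[q]
      }
      biomass_in[prev] <- -biomass_coef
    } else {
      biomass_in[paste0(p, "_c")] <- -biomass_coef
    }
  }
  for (p in decoys) {
    dg <- paste0("DEG_", p)
    rx[[dg]] <- .rxn_row(dg, paste(p, "degradation"), 0, B, .random_gpr(pool),
                         lay$degradation)
    st[[dg]] <- .stoich_rows(dg, stats::setNames(c(-1, 1), c(paste0(p, "_c"), "waste_c")))
  }
  rx$sw <- .rxn_row("SEC_waste", "waste secretion", 0, B, NA, lay$transport)
  st$sw <- .stoich_rows("SEC_waste", c(waste_c = -1, waste_e = 1))
  rx$exw <- .rxn_row("EX_waste_e", "waste exchange", 0, B, subsystem = lay$exchange)
  st$exw <- .stoich_rows("EX_waste_e", c(waste_e = -1))
  bm <- paste0("BIOMASS_", id)
  rx$bm <- .rxn_row(bm, paste(id, "biomass"), 0, B, subsystem = lay$biomass)
  st$bm <- .stoich_rows(bm, biomass_in)

  mets$name <- mets$id
  rxns <- do.call(rbind, rx); stoich <- do.call(rbind, st)
  used_genes <- sort(unique(unlist(lapply(
    rxns$gpr[!is.na(rxns$gpr)], function(r) gpr_genes(parse_gpr(r))))))
  m <- metabolic_model(
    id = paste0("synthetic_", id),
    compartments = .df(id = c("c", "e"), name = c("cytosol", "extracellular")),
    metabolites = mets, reactions = rxns, stoich = stoich,
    genes = .df(id = used_genes, name = used_genes), objective = bm)

  # verify the planted dependency classes by direct FBA under restriction
  wt <- fba(m)
  if (wt$status != "optimal" || wt$objective <= 1e-6)
    stop("generated microbe '", id, "' is not viable")
  for (p in planted) {
    r <- fba(set_bounds(m, paste0("EX_", p, "_e"), lb = 0, ub = 0))
    cls <- if (p %in% hard_auxotrophies) "hard"
           else if (p %in% partial_dependencies) "partial" else "decoy"
    ok <- switch(cls,
                 hard = r$objective < 1e-9,
                 partial = r$objective > 1e-9 && r$objective < wt$objective - 1e-6,
                 decoy = abs(r$objective - wt$objective) < 1e-6)
    if (!ok)
      stop("planted ", cls, " dependency '", p, "' of microbe '", id,
           "' failed verification (wild-type ", signif(wt$objective, 4),
           ", restricted ", signif(r$objective, 4), ")")
  }
  m
}

#' Generate a synthetic TPM expression table
#'
#' Gene activity is Bernoulli(`active_fraction`); active genes draw their
#' mean TPM log-normally above 1, inactive genes below 1, with multiplicative
#' per-sample log-normal noise.
#'
#' @param model the model whose genes are profiled.
#' @param active_fraction target fraction of active genes (default 0.4).
#' @param n_samples number of samples (default 20).
#' @param seed RNG seed.
#' @param noise_sd sd of the per-sample log-noise (default 0.3).
#' @return data frame: `gene` column plus `n_samples` TPM columns.
#' @export
generate_expression_table <- function(model, active_fraction = 0.4,
                                      n_samples = 20, seed = 1, noise_sd = 0.3) {
  stopifnot(active_fraction >= 0, active_fraction <= 1, n_samples >= 1)
  genes <- model$genes$id
  if (!length(genes)) stop("model has no genes")
  set.seed(seed)
  active <- stats::runif(length(genes)) < active_fraction
  mu <- ifelse(active,
               pmax(1.5, exp(stats::rnorm(length(genes), log(30), 0.8))),
               pmin(0.5, exp(stats::rnorm(length(genes), log(0.05), 0.8))))
  vals <- mu * exp(matrix(stats::rnorm(length(genes) * n_samples, 0, noise_sd),
                          length(genes)) - noise_sd^2 / 2)
  out <- data.frame(gene = genes, vals, stringsAsFactors = FALSE)
  names(out) <- c("gene", sprintf("s%02d", seq_len(n_samples)))
  attr(out, "active_genes") <- genes[active]
  out
}

.default_assignment <- function(tags, key, decoys) {
  # rotates hard/partial roles over the key metabolites so each key
  # metabolite hits at least one member
  patterns <- list(list(hard = key[1]),
                   list(hard = key[2], partial = key[3]),
                   list(partial = key[3]),
                   list(hard = key[1], partial = key[2]),
                   list(partial = key[3]))
  out <- lapply(seq_along(tags), function(i) {
    a <- patterns[[(i - 1) %% length(patterns) + 1]]
    a$decoys <- decoys
    a
  })
  names(out) <- tags
  out
}

#' Generate the standard synthetic community fixture
#'
#' A secreting host, `n_microbes` microbe models with planted hard/partial
#' dependencies on the key co-metabolites and shared decoys, and a host
#' expression table. The planted ground truth (key co-metabolites, decoys,
#' expected per-member biomass classes) ships with the fixture. The default
#' layout is 5 microbes on a 12-metabolite panel with 3 planted key
#' co-metabolites and 2 decoys.
#'
#' @param n_microbes number of microbe members (default 5).
#' @param panel_size host secretion panel size (default 12).
#' @param planted_spec list with `key` (3 panel ids), `decoys` (2 panel ids)
#'   and optionally `assignments` (per-member list of `hard`/`partial`/
#'   `decoys`); `NULL` = default layout.
#' @param seed global fixture seed; member seeds are derived from it.
#' @param active_fraction host expression active fraction (default 0.85, so
#'   contextualization keeps the secretion machinery largely intact).
#' @param ... forwarded to [generate_microbe_model()] (e.g.
#'   `partial_capacity`).
#' @return a `community_fixture`: `host`, `microbes` (named list), `tags`,
#'   `biomass_ids` (named), `expression`, `diet`, `ground_truth`, `seed`,
#'   `params`.
#' @export
generate_community_fixture <- function(n_microbes = 5, panel_size = 12,
                                       planted_spec = NULL, seed = 1,
                                       active_fraction = 0.85, ...) {
  panel <- sprintf("cm%02d", seq_len(panel_size))
  if (is.null(planted_spec))
    planted_spec <- list(key = panel[1:3], decoys = panel[(panel_size - 1):panel_size])
  key <- planted_spec$key; decoys <- planted_spec$decoys
  stopifnot(all(c(key, decoys) %in% panel), !anyDuplicated(c(key, decoys)))
  tags <- sprintf("m%d", seq_len(n_microbes))
  assign <- planted_spec$assignments
  if (is.null(assign)) assign <- .default_assignment(tags, key, decoys)

  host <- generate_host_model(n_exchange = panel_size, panel = panel,
                              seed = .derive_seed(seed, "host"))
  expression <- generate_expression_table(host, active_fraction = active_fraction,
                                          seed = .derive_seed(seed, "expression"))
  microbes <- list(); truth_rows <- list()
  for (tag in tags) {
    a <- assign[[tag]]
    microbes[[tag]] <- generate_microbe_model(
      id = tag, panel = panel,
      hard_auxotrophies = a$hard %||% character(),
      partial_dependencies = a$partial %||% character(),
      decoys = a$decoys %||% character(),
      seed = .derive_seed(seed, tag), ...)
    cls <- c(stats::setNames(rep("blocked", length(a$hard)), a$hard),
             stats::setNames(rep("reduced", length(a$partial)), a$partial),
             stats::setNames(rep("unchanged", length(a$decoys)), a$decoys))
    if (length(cls))
      truth_rows[[tag]] <- .df(member = tag, co_metabolite = names(cls),
                               expected_class = unname(cls))
  }
  truth <- do.call(rbind, truth_rows); rownames(truth) <- NULL
  structure(list(
    host = host, microbes = microbes, tags = tags,
    biomass_ids = stats::setNames(paste0("BIOMASS_", tags), tags),
    expression = expression,
    diet = c(glc = 10),
    ground_truth = list(key_co_metabolites = sort(key), decoys = sort(decoys),
                        expected = truth),
    seed = seed,
    params = list(n_microbes = n_microbes, panel_size = panel_size,
                  active_fraction = active_fraction)),
    class = "community_fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.community_fixture <- function(x, ...) {
  cat("<community_fixture> seed:", x$seed, "\n  host:", x$host$id,
      "(", nrow(x$host$reactions), "reactions )\n  microbes:",
      paste(x$tags, collapse = ", "), "\n  planted key co-metabolites:",
      paste(x$ground_truth$key_co_metabolites, collapse = ", "),
      "\n  decoys:", paste(x$ground_truth$decoys, collapse = ", "), "\n")
  invisible(x)
}

#' Write a community fixture to disk (models as JSON, expression as TSV,
#' ground truth as JSON)
#' @param fixture a `community_fixture`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_model(fixture$host, file.path(dir, "host.json"))
  for (tag in fixture$tags)
    write_model(fixture$microbes[[tag]], file.path(dir, paste0(tag, ".json")))
  utils::write.table(fixture$expression, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- fixture$ground_truth
  gt$diet <- as.list(fixture$diet)
  gt$tags <- fixture$tags
  gt$biomass_ids <- as.list(fixture$biomass_ids)
  gt$seed <- fixture$seed
  gt$params <- fixture$params
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
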