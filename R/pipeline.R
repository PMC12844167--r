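# Pipeline orchestration. The analysis follows the host-single-strain
# strategy: one pairwise joint model per microbe member, co-metabolite
# identification, baseline and per-restriction flux sampling, differential
# screening, biomass-effect classification, key co-metabolite screening, and
# per-scenario subsystem enrichment. run_stage()/run_pipeline() add the
# file-artifact layer with JSON metadata sidecars.

#' Run the co-metabolic analysis on a community fixture
#'
#' For every microbe member: assemble the pairwise host+microbe joint model,
#' identify co-metabolites, sample the unrestricted polytope, then for each
#' co-metabolite the member can take up, apply the zero-flux uptake
#' restriction, resample, and run the differential screen
#' (KS + BH, normalized flux change, bootstrap CI), classify the biomass
#' effect, and enrich significant member reactions over subsystems.
#'
#' @param fixture a `community_fixture` (or compatible list with `host`,
#'   `microbes`, `tags`, `biomass_ids`, `diet`).
#' @param n_samples,thinning sampler settings (defaults 2000 / 10, the
#'   desk-scale configuration).
#' @param alpha significance level (default 0.05).
#' @param fc_threshold normalized flux-change cutoff (default 0.82).
#' @param n_boot bootstrap replicates (default 1000).
#' @param enrichment_mode `"tail"` or `"point"`.
#' @param seed global seed; all per-scenario seeds derive from it.
#' @param members optional subset of member tags to analyse.
#' @return a `cometabolic_analysis` list: `co_metabolites` (per member),
#'   `classification` (lumen composition per member), `biomass_effects`
#'   (grid data frame), `key_co_metabolites`, `differential` (per scenario),
#'   `enrichment` (long data frame), `grid`, `params`.
#' @export
run_community_analysis <- function(fixture, n_samples = 2000, thinning = 10,
                                   alpha = 0.05, fc_threshold = 0.82,
                                   n_boot = 1000, enrichment_mode = "tail",
                                   seed = 1, members = NULL) {
  tags <- if (is.null(members)) fixture$tags else members
  co_tables <- list(); effects <- list(); diffs <- list(); enr <- list()
  for (tag in tags) {
    joint <- merge_models(members = fixture$microbes[tag],
                          biomass_ids = unname(fixture$biomass_ids[tag]),
                          tags = tag, host = fixture$host,
                          diet = fixture$diet, remove_futile = TRUE)
    biomass <- joint$members$biomass[!joint$members$is_host][1]
    cm <- identify_co_metabolites(joint)
    co_tables[[tag]] <- cm
    base_cfg <- sampler_config(n_samples = n_samples, thinning = thinning,
                               seed = .derive_seed(seed, paste0(tag, ":baseline")))
    baseline <- achr_sample(joint, base_cfg)
    member_rxns <- joint$reactions$id[!is.na(joint$reactions$member_tag) &
                                        joint$reactions$member_tag == tag]
    mine <- cm$co_metabolites[vapply(strsplit(cm$co_metabolites$members, ","),
                                     function(m) tag %in% m, logical(1)), ,
                              drop = FALSE]
    for (b in mine$base) {
      restricted <- apply_restriction(joint, b, tag)
      cfg <- sampler_config(n_samples = n_samples, thinning = thinning,
                            seed = .derive_seed(seed, paste(tag, b, sep = ":")))
      rs <- achr_sample(restricted, cfg)
      d <- differential_analysis(rs, baseline, alpha = alpha,
                                 fc_threshold = fc_threshold, n_boot = n_boot,
                                 seed = .derive_seed(seed, paste(tag, b, "boot", sep = ":")))
      diffs[[paste(tag, b, sep = ":")]] <- cbind(member = tag, co_metabolite = b, d)
      eff <- classify_biomass_effect(
        baseline, rs, biomass, alpha = alpha, fc_threshold = fc_threshold,
        n_boot = n_boot,
        seed = .derive_seed(seed, paste(tag, b, "bm", sep = ":")))
      effects[[paste(tag, b, sep = ":")]] <-
        cbind(member = tag, co_metabolite = b, eff)
      sig <- intersect(screen_reactions(d, alpha, fc_threshold), member_rxns)
      e <- enrich_subsystems(joint, sig, mode = enrichment_mode, alpha = alpha,
                             background = member_rxns)
      enr[[paste(tag, b, sep = ":")]] <- cbind(member = tag, co_metabolite = b, e)
    }
  }
  effects <- do.call(rbind, effects); rownames(effects) <- NULL
  enr_long <- do.call(rbind, enr); rownames(enr_long) <- NULL
  out <- list(
    co_metabolites = co_tables,
    biomass_effects = effects,
    key_co_metabolites = screen_key_co_metabolites(effects),
    differential = diffs,
    enrichment = enr_long,
    grid = if (!is.null(enr_long) && nrow(enr_long)) build_enrichment_grid(enr_long)
           else list(long = data.frame(), matrix = matrix(numeric(), 0, 0)),
    params = list(n_samples = n_samples, thinning = thinning, alpha = alpha,
                  fc_threshold = fc_threshold, n_boot = n_boot,
                  enrichment_mode = enrichment_mode, seed = seed))
  class(out) <- "cometabolic_analysis"
  out
}

#' @export
print.cometabolic_analysis <- function(x, ...) {
  cat("<cometabolic_analysis>\n  members:",
      paste(names(x$co_metabolites), collapse = ", "),
      "\n  restriction scenarios:", if (is.null(x$biomass_effects)) 0 else
        nrow(x$biomass_effects),
      "\n  key co-metabolites:", if (nrow(x$key_co_metabolites))
        paste(x$key_co_metabolites$co_metabolite, collapse = ", ") else "<none>",
      "\n")
  invisible(x)
}

# ---- file-artifact orchestration ----

#' Assemble a pipeline configuration
#'
#' @param outdir artifact directory.
#' @param seed global seed; per-stage seeds derive from it by a stable
#'   string-hash of the stage name.
#' @param n_microbes,panel_size,active_fraction fixture parameters.
#' @param n_samples,thinning sampler parameters.
#' @param alpha,fc_threshold,n_boot,enrichment_mode screening parameters.
#' @param tpm_threshold active-gene TPM cutoff (strict, default 1).
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1, n_microbes = 5, panel_size = 12,
                            active_fraction = 0.85, n_samples = 2000,
                            thinning = 10, alpha = 0.05, fc_threshold = 0.82,
                            n_boot = 1000, enrichment_mode = "tail",
                            tpm_threshold = 1) {
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              n_microbes = as.integer(n_microbes),
              panel_size = as.integer(panel_size),
              active_fraction = active_fraction,
              n_samples = as.integer(n_samples), thinning = as.integer(thinning),
              alpha = alpha, fc_threshold = fc_threshold,
              n_boot = as.integer(n_boot), enrichment_mode = enrichment_mode,
              tpm_threshold = tpm_threshold)
  .validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

.validate_config <- function(cfg) {
  schema <- list(outdir = "character", seed = "integer", n_microbes = "integer",
                 panel_size = "integer", active_fraction = "numeric",
                 n_samples = "integer", thinning = "integer", alpha = "numeric",
                 fc_threshold = "numeric", n_boot = "integer",
                 enrichment_mode = "character", tpm_threshold = "numeric")
  for (f in names(schema)) {
    if (is.null(cfg[[f]]))
      stop("config error at $", f, ": missing")
    ok <- switch(schema[[f]], integer = is.numeric(cfg[[f]]),
                 numeric = is.numeric(cfg[[f]]), character = is.character(cfg[[f]]))
    if (!ok) stop("config error at $", f, ": expected ", schema[[f]])
  }
  if (!cfg$enrichment_mode %in% c("tail", "point"))
    stop("config error at $enrichment_mode: must be 'tail' or 'point'")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.sidecar <- function(path, cfg, stage, inputs = character()) {
  meta <- list(stage = stage, config = unclass(cfg),
               stage_seed = .derive_seed(cfg$seed, stage),
               inputs = as.list(if (length(inputs))
                 vapply(inputs, function(f) unname(tools::md5sum(f)), character(1))
                 else stats::setNames(character(), character())),
               written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.need <- function(path, stage) {
  if (!file.exists(path))
    stop("missing artifact '", path, "'; run stage '", stage, "' first")
  path
}

.load_fixture_dir <- function(dir) {
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  tags <- gt$tags
  microbes <- lapply(tags, function(t) read_model(file.path(dir, paste0(t, ".json"))))
  names(microbes) <- tags
  structure(list(
    host = read_model(file.path(dir, "host.json")),
    microbes = microbes, tags = tags,
    biomass_ids = unlist(gt$biomass_ids),
    expression = read_expression(file.path(dir, "expression.tsv")),
    diet = unlist(gt$diet),
    ground_truth = list(key_co_metabolites = gt$key_co_metabolites,
                        decoys = gt$decoys, expected = gt$expected),
    seed = gt$seed, params = gt$params), class = "community_fixture")
}

#' Run one pipeline stage with file artifacts
#'
#' Stages: `"simulate"` (write the synthetic fixture), `"contextualize"`
#' (host expression contextualization + comparison), `"analyse"` (joint
#' assembly, sampling, differential screen, biomass classification,
#' enrichment — the merge/sample/diff/enrich block), `"report"` (key
#' co-metabolite table and summary). Artifacts carry `.meta.json` sidecars
#' with the config, the derived stage seed and input hashes.
#'
#' @param stage stage name.
#' @param config a `pipeline_config` (or YAML path).
#' @return invisible list of written artifact paths.
#' @export
run_stage <- function(stage = c("simulate", "contextualize", "analyse", "report"),
                      config) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_pipeline_config(config)
  .validate_config(config)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fixdir <- file.path(out, "fixture")
  written <- character()

  if (stage == "simulate") {
    fx <- generate_community_fixture(
      n_microbes = config$n_microbes, panel_size = config$panel_size,
      seed = .derive_seed(config$seed, "simulate"),
      active_fraction = config$active_fraction)
    write_fixture(fx, fixdir)
    written <- file.path(fixdir, c("host.json", "expression.tsv", "ground_truth.json"))
    .sidecar(file.path(fixdir, "ground_truth.json"), config, stage)
  } else if (stage == "contextualize") {
    .need(file.path(fixdir, "host.json"), "simulate")
    fx <- .load_fixture_dir(fixdir)
    prof <- aggregate_expression(fx$expression)
    active <- filter_active_genes(prof, config$tpm_threshold)
    ctx <- extract_context_model(fx$host, active, profile = prof)
    ctx <- apply_eflux(ctx, prof)
    cmp <- compare_models(fx$host, ctx)
    write_model(ctx, file.path(out, "host_context.json"))
    cmp_json <- file.path(out, "model_comparison.json")
    jsonlite::write_json(list(
      gene_reduction = cmp$gene_reduction,
      reaction_reduction = cmp$reaction_reduction,
      gpr_coverage = as.list(cmp$gpr_coverage),
      test = cmp$test,
      essential_generic = length(cmp$essential$generic),
      essential_specific = length(cmp$essential$specific)),
      cmp_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(cmp$fva_spans, file.path(out, "fva_spans.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(file.path(out, "host_context.json"), cmp_json,
                 file.path(out, "fva_spans.tsv"))
    .sidecar(cmp_json, config, stage,
             inputs = file.path(fixdir, c("host.json", "expression.tsv")))
  } else if (stage == "analyse") {
    .need(file.path(fixdir, "ground_truth.json"), "simulate")
    fx <- .load_fixture_dir(fixdir)
    an <- run_community_analysis(
      fx, n_samples = config$n_samples, thinning = config$thinning,
      alpha = config$alpha, fc_threshold = config$fc_threshold,
      n_boot = config$n_boot, enrichment_mode = config$enrichment_mode,
      seed = .derive_seed(config$seed, "analyse"))
    w <- function(df, name) {
      p <- file.path(out, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    written <- c(
      w(an$biomass_effects, "biomass_effects.tsv"),
      w(do.call(rbind, an$differential), "differential.tsv"),
      w(an$enrichment, "enrichment.tsv"),
      w(do.call(rbind, lapply(names(an$co_metabolites), function(tag)
        cbind(member = tag, an$co_metabolites[[tag]]$classification))),
        "lumen_classification.tsv"))
    .sidecar(written[1], config, stage,
             inputs = file.path(fixdir, "ground_truth.json"))
  } else if (stage == "report") {
    eff_path <- .need(file.path(out, "biomass_effects.tsv"), "analyse")
    eff <- utils::read.delim(eff_path, stringsAsFactors = FALSE)
    key <- screen_key_co_metabolites(eff)
    kp <- file.path(out, "key_co_metabolites.tsv")
    utils::write.table(key, kp, sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- file.path(out, "summary.json")
    jsonlite::write_json(list(
      n_scenarios = nrow(eff),
      n_key_co_metabolites = nrow(key),
      key_co_metabolites = key$co_metabolite,
      classes = as.list(table(eff$class))),
      summ, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(kp, summ)
    .sidecar(summ, config, stage, inputs = eff_path)
  }
  invisible(written)
}

#' Run the full pipeline (simulate, contextualize, analyse, report)
#' @param config a `pipeline_config` or YAML path.
#' @return invisible vector of artifact paths.
#' @export
run_pipeline <- function(config) {
  paths <- c(run_stage("simulate", config),
             run_stage("contextualize", config),
             run_stage("analyse", config),
             run_stage("report", config))
  invisible(paths)
}
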