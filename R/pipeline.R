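# End-to-end orchestration: filters -> Omega/outlier screen -> GEA ->
# assignment -> BLUP/RONA -> Shapley -> AGF plan -> validations, with a
# run manifest and TSV outputs.

#' Default pipeline configuration
#'
#' @param seed integer seed used for every stochastic stage.
#' @param min_pops,maf locus filter settings.
#' @param fdr FLK outlier screen false discovery rate.
#' @param log10bf_min,rho_quantile candidate-calling thresholds.
#' @param min_loci minimum assigned loci for a variable to get a BLUP fit.
#' @param z AGF confidence-band half-width in residual SDs.
#' @param agf_scenario scenario used for the AGF plan.
#' @param sim a [sim_config] for synthetic input, or NULL when reading
#'   files.
#' @param inputs list of file paths (`vcf`, `pop_map`, `pop_table`,
#'   `env_csv`, scenario CSVs in `scenario_csvs`) when not simulating.
#' @return A configuration list.
#' @export
pipeline_config <- function(seed = 1, min_pops = 8, maf = 0.05, fdr = 0.2,
                            log10bf_min = 1.0, rho_quantile = 0.90,
                            min_loci = 6, z = 1.96,
                            agf_scenario = "current",
                            sim = NULL, inputs = NULL) {
  as.list(environment())
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with keys matching [pipeline_config] arguments.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config,
                 raw[intersect(names(raw), names(formals(pipeline_config)))])
  if (!is.null(raw$sim)) cfg$sim <- do.call(sim_config, raw$sim)
  cfg
}

#' Run the full local-adaptation assessment pipeline
#'
#' Executes every stage on either a simulated dataset (when `config$sim` is
#' set) or on files named in `config$inputs`, writes all module outputs
#' under `outdir`, and returns the result bundle invisibly. Stage failures
#' abort with the stage name.
#'
#' @param config list from [pipeline_config] / [read_pipeline_config].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with every intermediate object and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("adaptrona")),
                   seed = config$seed,
                   thresholds = config[c("min_pops", "maf", "fdr",
                                         "log10bf_min", "rho_quantile",
                                         "min_loci", "z")])

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- stage("simulate", {
      cfg <- config$sim; cfg$seed <- config$seed
      simulate_dataset(cfg)
    })
    counts <- sim$counts
    pop_table <- stage("phenotypes", simulate_phenotypes(sim))
    env <- stage("standardize_env",
                 standardize_env(sim$env_raw, sim$scenario_raw))
  } else {
    inp <- config$inputs
    if (is.null(inp)) stopf("config must set either sim or inputs")
    sim <- NULL
    counts <- stage("read_vcf", read_genotype_vcf(
      inp$vcf, utils::read.table(inp$pop_map, header = TRUE, sep = "\t")))
    pop_table <- stage("read_pop_table",
                       validate_pop_table(utils::read.csv(inp$pop_table)))
    scen <- lapply(inp$scenario_csvs %||% list(), utils::read.csv)
    env <- stage("standardize_env",
                 standardize_env(utils::read.csv(inp$env_csv), scen))
  }
  if (config$agf_scenario != "current" &&
      !config$agf_scenario %in% names(env$scenarios))
    stopf("unknown scenario '%s' requested for the AGF plan",
          config$agf_scenario)

  # --- filters and structure ----------------------------------------------
  freqs <- stage("frequency_filter",
                 compute_frequencies(counts, config$min_pops, config$maf))
  env <- stage("align_env", {
    if (!all(freqs$pops %in% env$pops)) stopf("env table lacks populations")
    idx <- match(freqs$pops, env$pops)
    env$E <- env$E[idx, , drop = FALSE]
    env$scenarios <- lapply(env$scenarios, function(S) S[idx, , drop = FALSE])
    env$pops <- freqs$pops
    env
  })
  omega0 <- stage("omega_initial", estimate_omega(freqs))
  screen <- stage("flk_screen", flk_outlier_screen(freqs, omega0, config$fdr))
  omega <- stage("omega_refined",
                 estimate_omega(freqs, excluded_loci = screen$flagged))

  # --- GEA ----------------------------------------------------------------
  gea <- stage("gea_scan", gea_scan(freqs, env, omega))
  gea <- stage("call_candidates",
               call_candidates(gea, config$log10bf_min, config$rho_quantile))
  assign <- stage("assign_loci", assign_loci(gea))

  # --- BLUP / RONA --------------------------------------------------------
  fits <- stage("blup", {
    vars <- names(assign$counts)[assign$counts >= config$min_loci]
    if (!length(vars)) stopf("no variable has >= %d assigned loci", config$min_loci)
    stats::setNames(lapply(vars, function(v) {
      loci <- assign$assignment$locus[assign$assignment$variable == v]
      fit_blup(freqs$f[, loci, drop = FALSE],
               stats::setNames(env$E[, v], env$pops), variable = v)
    }), vars)
  })
  rona <- stage("rona", rona_table(fits, env))
  rona_summary <- stage("combine_rona", combine_rona(rona))

  # --- prioritization -----------------------------------------------------
  adaptive_loci <- assign$assignment$locus
  neutral_loci <- setdiff(freqs$loci, unique(gea$locus[gea$candidate]))
  counts_kept <- freq_to_counts(freqs)
  sv_neutral <- stage("shapley_neutral",
                      shapley_index(counts_kept, neutral_loci, "neutral"))
  sv_adaptive <- stage("shapley_adaptive",
                       shapley_index(counts_kept, adaptive_loci, "adaptive"))
  consensus <- stage("consensus_rank", consensus_rank(
    stats::setNames(rona_summary$mean_c_rona, rona_summary$pop), sv_adaptive))

  # --- AGF ----------------------------------------------------------------
  plan <- stage("agf_plan", plan_agf(fits, env, pop_table,
                                     scenario = config$agf_scenario,
                                     z = config$z))

  # --- validation ---------------------------------------------------------
  validation <- stage("fitness_validation", {
    if ("catkin_mean" %in% names(pop_table))
      fitness_validation(rona, pop_table)
    else NULL
  })

  manifest$counts <- list(
    populations = length(freqs$pops),
    loci_input = length(counts$loci),
    loci_retained = length(freqs$loci),
    outliers_flagged = length(screen$flagged),
    candidates = nrow(assign$assignment),
    assigned_per_variable = as.list(assign$counts),
    variables_fitted = length(fits))

  # --- outputs ------------------------------------------------------------
  w <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_freq_tsv(freqs, file.path(outdir, "frequencies.tsv"))
  w(data.frame(pop = omega$pops, signif(omega$W, 8), check.names = FALSE),
    "omega.tsv")
  w(screen$stats, "flk_outliers.tsv")
  w(cbind(gea, candidate = gea$candidate)[, c("locus", "variable", "bf",
                                              "log10_bf", "rho", "candidate")],
    "gea_results.tsv")
  w(assign$assignment, "assignments.tsv")
  w(do.call(rbind, lapply(fits, function(f)
    data.frame(variable = f$variable, locus = f$loci, beta = f$beta,
               mu = f$mu, delta_ridge = f$delta_ridge,
               residual_sd = f$residual_sd, row.names = NULL))),
    "blup_fits.tsv")
  w(rona, "rona.tsv")
  w(rona_summary, "rona_summary.tsv")
  sv_tab <- merge(stats::setNames(sv_neutral$scores, c("pop", "sv_neutral")),
                  stats::setNames(sv_adaptive$scores, c("pop", "sv_adaptive")),
                  by = "pop")
  sv_tab$total_length_neutral <- sv_neutral$total_length
  sv_tab$total_length_adaptive <- sv_adaptive$total_length
  w(sv_tab, "shapley.tsv")
  w(consensus, "consensus_rank.tsv")
  w(plan, "agf_plan.tsv")
  write_agf_geojson(plan, pop_table, file.path(outdir, "agf_plan.geojson"))
  if (!is.null(validation)) w(validation, "validation.tsv")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sim = sim, counts = counts, freqs = freqs, env = env,
                 pop_table = pop_table, omega = omega, screen = screen,
                 gea = gea, assignment = assign, fits = fits, rona = rona,
                 rona_summary = rona_summary, shapley_neutral = sv_neutral,
                 shapley_adaptive = sv_adaptive, consensus = consensus,
                 agf_plan = plan, validation = validation,
                 manifest = manifest))
}
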