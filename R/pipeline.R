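#' Simulate a decision table to disk
#'
#' Runs [simulate_experiment] and writes the decision table, the latent
#' truth sidecar (`larva_id,final_state`), and a JSON manifest carrying
#' the configuration, its hash, and the package version, so a run can be
#' reproduced bit-for-bit from the manifest alone.
#'
#' @param config a [generative_config] (or a path to a YAML file for one).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of the written paths (`decisions`, `truth`,
#'   `manifest`).
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_generative_config(config)
  stopifnot(inherits(config, "generative_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(config)
  if (sum(config$cycle_doses$n_larvae) == 0)
    warning("configuration yields 0 larvae; writing header-only table")
  paths <- list(decisions = file.path(out_dir, "decisions.csv"),
                truth = file.path(out_dir, "truth.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_decision_table(sim$groups, paths$decisions)
  truth <- if (is.null(sim$truth))
    data.frame(larva_id = character(), final_state = character())
  else sim$truth[, c("larva_id", "final_state")]
  utils::write.table(truth, paths$truth, sep = ",", row.names = FALSE,
                     quote = FALSE)
  write_manifest(paths$manifest, "simulate", config)
  invisible(paths)
}

#' Preference, bootstrap, and test report for a decision table
#'
#' For every group with decisions in both compared phases: pooled counts,
#' decision-weighted preferences, bootstrap standard deviations, and the
#' four significance measures used for this assay (hierarchical bootstrap
#' p, animal-only bootstrap p, Fisher exact on pooled counts,
#' Mann-Whitney U on per-animal preferences).
#'
#' @param input path to a decision table, or a list of
#'   [experiment_group] objects.
#' @param phases the two phases to compare (default PRE vs POST).
#' @param B bootstrap replicates.
#' @param seed RNG seed for the bootstraps.
#' @param out_dir optional: when given, writes `counts.csv`, `tests.csv`,
#'   and `report.json` there.
#' @return Invisibly, a list with `counts` and `tests` data.frames.
#' @export
run_analyze <- function(input, phases = c("PRE", "POST"), B = 10000,
                        seed = 1L, out_dir = NULL) {
  groups <- if (is.character(input)) read_decision_table(input) else input
  if (inherits(groups, "experiment_group")) groups <- list(groups)
  counts <- do.call(rbind, lapply(groups, function(g)
    as.data.frame(counts_summary(g))))
  tests <- list()
  for (g in groups) {
    cs <- counts_summary(g)
    if (cs$approach[phases[1]] + cs$avoid[phases[1]] == 0 ||
        cs$approach[phases[2]] + cs$avoid[phases[2]] == 0) next
    hb <- hierarchical_bootstrap(g, phases, B = B, seed = seed)
    ab <- animal_bootstrap(g, phases, B = B, seed = seed)
    pa <- preference_data(g, phases[1]); pb <- preference_data(g, phases[2])
    tests[[g$name]] <- data.frame(
      group = g$name, n_larvae = cs$n_larvae,
      pref_a = hb$conditions[[1]]$point, sd_a = hb$conditions[[1]]$sd,
      pref_b = hb$conditions[[2]]$point, sd_b = hb$conditions[[2]]$sd,
      p_hierarchical = hb$p_value, p_animal = ab$p_value,
      p_fisher = fisher_pre_post(
        c(cs$approach[phases[1]], cs$avoid[phases[1]]),
        c(cs$approach[phases[2]], cs$avoid[phases[2]])),
      p_utest = if (nrow(pa) && nrow(pb))
        mannwhitney_groups(pa$p, pb$p) else NA_real_)
  }
  tests <- if (length(tests))
    do.call(rbind, c(tests, list(make.row.names = FALSE))) else
      data.frame()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(counts, file.path(out_dir, "counts.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(tests, file.path(out_dir, "tests.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(phases = phases, B = B, seed = seed,
                              tests = tests),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(file.path(out_dir, "manifest.json"), "analyze",
                   list(phases = phases, B = B, seed = seed))
  }
  invisible(list(counts = counts, tests = tests))
}

#' Model fits, comparison table, and trained-fraction report
#'
#' Fits the requested learning models to the per-animal preferences of
#' one phase, tabulates the AIC/BIC comparison, and -- when the QUANTIZED
#' model is among them -- the per-dose untrained fractions with
#' profile-likelihood intervals (plus the memoryless overlay when
#' ALL_OR_NONE is also fitted).
#'
#' @param input path to a decision table, or a list of
#'   [experiment_group] objects.
#' @param models model names (default all five; see [MODEL_NAMES]).
#' @param phase phase whose preferences are modeled (default `"POST"`).
#' @param n_starts,seed passed to [fit_model].
#' @param out_dir optional: writes `model_comparison.csv`, `fits.json`,
#'   and `untrained_fraction.csv` there.
#' @return Invisibly, a list with `comparison` (a `model_comparison`),
#'   `fits`, and `untrained_curve` (or `NULL`).
#' @export
run_fit <- function(input, models = MODEL_NAMES, phase = "POST",
                    n_starts = 20, seed = 1L, out_dir = NULL) {
  groups <- if (is.character(input)) read_decision_table(input) else input
  dat <- preference_data(groups, phase)
  cmp <- compare_models(dat, models = models, n_starts = n_starts,
                        seed = seed)
  fits <- attr(cmp, "fits")
  curve <- NULL
  if (!is.null(fits$QUANTIZED))
    curve <- untrained_fraction_curve(fits$QUANTIZED, dat,
                                      all_or_none_fit = fits$ALL_OR_NONE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(cmp),
                       file.path(out_dir, "model_comparison.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    report <- lapply(fits, function(f)
      list(model = f$spec$name, theta = f$theta, loglik = f$loglik,
           k = f$k, n_obs = f$n_obs, aic = f$aic, bic = f$bic,
           seed = f$seed, n_starts = f$n_starts))
    jsonlite::write_json(report, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(curve))
      utils::write.table(curve, file.path(out_dir, "untrained_fraction.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
    write_manifest(file.path(out_dir, "manifest.json"), "fit",
                   list(models = models, phase = phase,
                        n_starts = n_starts, seed = seed))
  }
  invisible(list(comparison = cmp, fits = fits, untrained_curve = curve))
}

write_manifest <- function(path, command, config) {
  cfg <- unclass(config)
  jsonlite::write_json(
    list(command = command, config = cfg,
         config_hash = content_hash(paste(deparse(cfg), collapse = "")),
         package = "larvalearn",
         version = as.character(utils::packageVersion("larvalearn"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
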