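#' Read an experiment configuration
#'
#' Reads a YAML config mirroring the experiment structure and fills
#' defaults. Top-level keys: `seed`; `cohort` (either `csv: path` or
#' synthetic-generator fields `n_subjects`, `n_days`, `strata`, plus
#' any [cohortSpec()] argument in snake_case); `grid` (`scenarios`,
#' `n_days`, `handlings`); `thresholds` (`rest_mg`, `icc`, `mape`);
#' `stratify` (label columns, optional).
#'
#' @param path YAML file path.
#' @return a config list.
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaultConfig(cfg)
}

#' @rdname readExperimentConfig
#' @param cfg a partial config list.
#' @export
defaultConfig <- function(cfg = list()) {
  dflt <- list(
    seed = 1L,
    cohort = list(n_subjects = 100, n_days = 7, strata = FALSE),
    grid = list(scenarios = 1:3, n_days = 1:7,
                handlings = c("omit", "impute")),
    thresholds = list(rest_mg = 40, icc = 0.75, mape = 15),
    stratify = character(0))
  for (k in names(dflt)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- dflt[[k]]
    else if (is.list(dflt[[k]]))
      for (k2 in names(dflt[[k]]))
        if (is.null(cfg[[k]][[k2]])) cfg[[k]][[k2]] <- dflt[[k]][[k2]]
  }
  if (!is.null(cfg$grid$batches)) {
    bad <- vapply(cfg$grid$batches,
                  function(b) b$scenario == 3 && b$n_days == max(cfg$grid$n_days),
                  logical(1))
    if (any(bad))
      stop("config error: scenario 3 with the full number of days is the reference, never a batch")
  }
  cfg
}

snakeToCamel <- function(x) {
  gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
}

cohortFromConfig <- function(cfg) {
  cc <- cfg$cohort
  if (!is.null(cc$csv)) return(readEpochCSV(cc$csv))
  args <- cc[setdiff(names(cc), "csv")]
  names(args) <- snakeToCamel(names(args))
  if (is.null(args$seed))
    args$seed <- (cfg$seed * 7927 + 11) %% 2147483647
  generateCohort(do.call(cohortSpec, args))
}

#' Run the full pseudo-simulation experiment
#'
#' Generates (or reads) a cohort; computes the reference metric
#' vectors on complete data over the full day grid; builds every
#' batch of the scenario x retained-days grid (the reference cell
#' excluded); computes the eight fragmentation metrics per subject
#' under each non-wear handling; assembles the reliability table, the
#' minimum-valid-days decisions and the non-wear profile; and, when
#' requested, writes the whole bundle to `outDir`. Scenario 3 batches
#' contain no non-wear, so omission and imputation coincide and are
#' computed once. All randomness derives from the master seed through
#' per-batch and per-subject substreams, so identical config and seed
#' give byte-identical decision output.
#'
#' @param config a config list (see [readExperimentConfig()]).
#' @param outDir output directory, or `NULL` to skip writing.
#' @param verbose log progress to stderr.
#' @return (invisibly) a list: `cohort`, `refMetrics`,
#'   `batchMetrics`, `reliability`, `minDays`, `profile`,
#'   `stratified`.
#' @export
runExperiment <- function(config = defaultConfig(), outDir = NULL,
                          verbose = FALSE) {
  config <- defaultConfig(config)
  logmsg <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  thr <- config$thresholds
  cohort <- cohortFromConfig(config)
  maxDays <- max(config$grid$n_days)
  logmsg("cohort ready: %d subjects", length(cohortSeries(cohort)))

  refCohort <- applyScenarioBatch(cohort, 3, maxDays, seed)
  refMetrics <- computeCohortMetrics(refCohort, "omit", thr$rest_mg)
  logmsg("reference metrics computed")

  grid <- batchGrid(config$grid$scenarios, config$grid$n_days)
  batchRows <- list(); profiles <- list()
  for (i in seq_len(nrow(grid))) {
    sc <- grid$scenario[i]; nd <- grid$n_days[i]
    # one mask stream per scenario: the n-day batch carries the first n
    # masked days of the scenario's full mask set (nested protocols),
    # so comparisons across retained days are not blurred by mask
    # redraws
    bseed <- (seed * 1009 + sc * 101) %% 2147483647
    masked <- applyScenarioBatch(cohort, sc, nd, bseed)
    if (sc %in% c(1, 2) && nd == maxDays)
      profiles[[as.character(sc)]] <- profileNonwear(masked)
    handlings <- if (sc == 3) "omit" else config$grid$handlings
    for (h in handlings) {
      m <- computeCohortMetrics(masked, h, thr$rest_mg)
      hs <- if (sc == 3) config$grid$handlings else h
      for (h2 in hs) {
        m2 <- m; m2$scenario <- sc; m2$n_days <- nd; m2$handling <- h2
        m2$batch_id <- grid$batch_id[i]
        batchRows[[paste(grid$batch_id[i], h2)]] <- m2
      }
    }
    logmsg("batch %s done", grid$batch_id[i])
  }
  batchMetrics <- do.call(rbind, c(batchRows, list(make.row.names = FALSE)))

  rel <- reliabilityTable(batchMetrics, refMetrics, thr$icc, thr$mape)
  minDays <- minimumValidDays(rel)
  strat <- NULL
  if (length(config$stratify) && nrow(cohortStrata(cohort))) {
    strat <- do.call(rbind, lapply(config$stratify, function(by) {
      tab <- stratifiedReliability(batchMetrics, refMetrics,
                                   cohortStrata(cohort), by,
                                   thr$icc, thr$mape)
      if (!is.null(tab) && nrow(tab)) tab$stratum_var <- by
      tab
    }))
  }

  result <- list(cohort = cohort, refMetrics = refMetrics,
                 batchMetrics = batchMetrics, reliability = rel,
                 minDays = minDays, profile = profiles,
                 stratified = strat)
  if (!is.null(outDir)) writeExperimentBundle(result, grid, config, outDir)
  invisible(result)
}

writeExperimentBundle <- function(result, grid, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- grid
  manifest$handling <- paste(config$grid$handlings, collapse = "+")
  manifest$seed <- (config$seed * 1009 + manifest$scenario * 101) %% 2147483647
  utils::write.csv(manifest, file.path(outDir, "batch_manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(result$batchMetrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$refMetrics, file.path(outDir, "reference_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$reliability, file.path(outDir, "reliability.csv"),
                   row.names = FALSE)
  if (!is.null(result$stratified))
    utils::write.csv(result$stratified,
                     file.path(outDir, "reliability_stratified.csv"),
                     row.names = FALSE)
  decisions <- list(
    cut_points = list(icc = config$thresholds$icc,
                      mape = config$thresholds$mape),
    seed = config$seed,
    n_subjects = length(cohortSeries(result$cohort)),
    min_valid_days = result$minDays)
  jsonlite::write_json(decisions, file.path(outDir, "min_days_decision.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (sc in names(result$profile)) {
    p <- result$profile[[sc]]
    utils::write.csv(p$blockCounts,
                     file.path(outDir, sprintf("nonwear_blocks_s%s.csv", sc)),
                     row.names = FALSE)
    utils::write.csv(p$percentNonwear,
                     file.path(outDir, sprintf("nonwear_pct_s%s.csv", sc)),
                     row.names = FALSE)
  }
  log <- c(sprintf("actifrag %s", as.character(utils::packageVersion("actifrag"))),
           sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed %d", config$seed),
           sprintf("subjects %d", length(cohortSeries(result$cohort))),
           sprintf("batches %d", nrow(grid)),
           sprintf("reliability rows %d", nrow(result$reliability)))
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(outDir)
}
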