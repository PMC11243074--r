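#' Assemble a reproducible run configuration
#'
#' A declarative description of one end-to-end run: simulate a synthetic
#' dataset, preprocess it, classify it, and (for dose-series runs) compute
#' dose-response statistics. Every stochastic stage derives its own seed
#' deterministically from the single global seed via [stageSeed()], so
#' re-running a config reproduces all numeric outputs bit-identically and
#' stages can be re-run in isolation.
#'
#' @param seed global integer seed.
#' @param mode `"two_class"` (control vs ligand) or `"dose_series"`.
#' @param design named list of scalar overrides passed to
#'   [syntheticDesign()] (e.g. `noise_scale`, `n_per_group`, `emax`).
#' @param simulate list: `ganglion`, `k_cells`, `ligand_dose_um`
#'   (`NA` = top of the dose grid).
#' @param preprocess named list of overrides passed to [preprocessConfig()].
#' @param chemometrics list: `n_components`, `train_fraction`, `kfold_k`.
#' @param dose list: `alpha`, `n_null`, `calcium` (logical; also simulate
#'   calcium traces per dose).
#' @return a validated run-config list.
#' @export
runConfig <- function(seed = 1L, mode = c("two_class", "dose_series"),
                      design = list(),
                      simulate = list(ganglion = FALSE, k_cells = 10L,
                                      ligand_dose_um = NA),
                      preprocess = list(),
                      chemometrics = list(n_components = 5L,
                                          train_fraction = 0.8, kfold_k = 5L),
                      dose = list(alpha = 0.05, n_null = 2000L,
                                  calcium = TRUE)) {
  cfg <- list(seed = as.integer(seed), mode = match.arg(mode),
              design = design,
              simulate = utils::modifyList(list(ganglion = FALSE,
                                                k_cells = 10L,
                                                ligand_dose_um = NA),
                                           simulate),
              preprocess = preprocess,
              chemometrics = utils::modifyList(list(n_components = 5L,
                                                    train_fraction = 0.8,
                                                    kfold_k = 5L),
                                               chemometrics),
              dose = utils::modifyList(list(alpha = 0.05, n_null = 2000L,
                                            calcium = TRUE), dose))
  validateRunConfig(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Builds the stage objects implied by the config so their class validity
#' methods run, and rejects out-of-range values with the offending field
#' named.
#'
#' @param cfg a run-config list as from [runConfig()] or [readRunConfig()].
#' @return `cfg`, invisibly, on success.
#' @export
validateRunConfig <- function(cfg) {
  fail <- function(field, msg) stop("config field '", field, "': ", msg,
                                    call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    fail("seed", "must be a single integer")
  if (!cfg$mode %in% c("two_class", "dose_series"))
    fail("mode", "must be 'two_class' or 'dose_series'")
  allowed <- setdiff(names(formals(syntheticDesign)), c("bands", "grid_cm1"))
  bad <- setdiff(names(cfg$design), allowed)
  if (length(bad)) fail(paste0("design.", bad[1]), "unknown design parameter")
  tryCatch(do.call(syntheticDesign, cfg$design),
           error = function(e) fail("design", conditionMessage(e)))
  bad <- setdiff(names(cfg$preprocess), names(formals(preprocessConfig)))
  if (length(bad)) fail(paste0("preprocess.", bad[1]),
                        "unknown preprocessing parameter")
  tryCatch(do.call(preprocessConfig, cfg$preprocess),
           error = function(e) fail("preprocess", conditionMessage(e)))
  ch <- cfg$chemometrics
  if (ch$n_components < 1L) fail("chemometrics.n_components", "must be >= 1")
  if (ch$train_fraction <= 0 || ch$train_fraction >= 1)
    fail("chemometrics.train_fraction", "must lie in (0, 1)")
  if (ch$kfold_k < 2L) fail("chemometrics.kfold_k", "must be >= 2")
  if (cfg$dose$alpha <= 0 || cfg$dose$alpha >= 0.5)
    fail("dose.alpha", "must lie in (0, 0.5)")
  if (cfg$dose$n_null < 100L) fail("dose.n_null", "must be >= 100")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' The file form round-trips losslessly: writing, reading and writing again
#' yields an identical file.
#'
#' @param path YAML file path.
#' @return [readRunConfig()]: a validated run-config list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- runConfig(seed = raw$seed, mode = raw$mode,
                   design = if (is.null(raw$design)) list() else raw$design,
                   simulate = if (is.null(raw$simulate)) list() else raw$simulate,
                   preprocess = if (is.null(raw$preprocess)) list() else raw$preprocess,
                   chemometrics = if (is.null(raw$chemometrics)) list() else raw$chemometrics,
                   dose = if (is.null(raw$dose)) list() else raw$dose)
  cfg
}

#' @param cfg a run-config list.
#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
  validateRunConfig(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Execute a full reproducible analysis run
#'
#' Runs simulate -> preprocess -> classify (and, for dose-series configs,
#' dose-response statistics) on synthetic data, writing a metrics JSON, a
#' per-spectrum score CSV and a run manifest (config echo, config hash,
#' stage seeds, stage timings, package version) into `out_dir`. All numeric
#' outputs are pure functions of the config.
#'
#' @param config a run-config list (from [runConfig()]) or the path to a
#'   YAML config file.
#' @param out_dir output directory, created if missing.
#' @return invisibly, a list with `metrics`, `manifest` and output `paths`.
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config)) config <- readRunConfig(config)
  validateRunConfig(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(simulate = stageSeed(config$seed, "simulate"),
                classify = stageSeed(config$seed, "classify"),
                dose = stageSeed(config$seed, "dose"),
                calcium = stageSeed(config$seed, "calcium"))
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  design <- do.call(syntheticDesign, config$design)
  ch <- config$chemometrics

  t0 <- tic()
  ligand_dose <- config$simulate$ligand_dose_um
  if (is.null(ligand_dose) || is.na(ligand_dose))
    ligand_dose <- max(design@dose_grid_um)
  dataset <- generateDataset(design, mode = config$mode,
                             ligand_dose_um = ligand_dose,
                             ganglion = isTRUE(config$simulate$ganglion),
                             k_cells = as.integer(config$simulate$k_cells),
                             seed = seeds$simulate)
  timings$simulate <- tic() - t0

  t0 <- tic()
  ppc <- do.call(preprocessConfig, config$preprocess)
  pp <- preprocessPipeline(dataset, ppc)
  timings$preprocess <- tic() - t0

  labels <- spectrumLabels(pp)
  doses <- spectrumDoses(pp)
  metrics <- list(seed = config$seed, mode = config$mode)

  t0 <- tic()
  pca <- fitPCA(pp, n_components = min(ch$n_components, ncol(pp) - 1L))
  metrics$pc_explained_variance_ratio <- as.numeric(pca@evr)
  if (config$mode == "two_class") {
    ev <- plsdaEvaluate(pp, labels, train_fraction = ch$train_fraction,
                        n_components = ch$n_components, seed = seeds$classify)
    kf <- kfoldPCAClassify(pp, labels, k = ch$kfold_k,
                           n_components = ch$n_components,
                           seed = seeds$classify)
    metrics$auc <- ev$auc
    metrics$rmse <- ev$rmse
    metrics$sensitivity <- ev$sensitivity
    metrics$specificity <- ev$specificity
    metrics$accuracy <- ev$accuracy
    metrics$kfold_mean_accuracy <- kf$mean_accuracy
    score_tab <- data.frame(label = labels, dose_um = doses,
                            pca@scores)
  } else {
    control <- doses == min(doses)
    per_dose <- sort(unique(doses[!control]))
    auc <- vapply(seq_along(per_dose), function(i) {
      sel <- control | doses == per_dose[i]
      plsdaEvaluate(intensityMatrix(pp)[sel, , drop = FALSE],
                    factor(ifelse(doses[sel] == min(doses), "control", "dose"),
                           levels = c("control", "dose")),
                    train_fraction = ch$train_fraction,
                    n_components = ch$n_components,
                    seed = seeds$classify + i)$auc
    }, numeric(1))
    metrics$dose_um <- per_dose
    metrics$auc_vs_control <- auc
    pls_all <- fitPLSDA(intensityMatrix(pp),
                        factor(ifelse(control, "control", "treated"),
                               levels = c("control", "treated")),
                        n_components = ch$n_components)
    score1 <- plsdaScores(pls_all, pp)[, 1]
    wt <- williamsTrendTest(score1, doses, alpha = config$dose$alpha,
                            n_null = as.integer(config$dose$n_null),
                            seed = seeds$dose)
    metrics$williams_significant <- wt$table$significant
    metrics$williams_t_bar <- wt$table$t_bar
    score_tab <- data.frame(label = labels, dose_um = doses,
                            pls_score1 = score1, pca@scores)
    if (isTRUE(config$dose$calcium)) {
      cal <- calciumDesign(seed = seeds$calcium)
      folds_by_dose <- lapply(seq_along(design@dose_grid_um), function(i) {
        tr <- generateCalciumTraces(cal, design@dose_grid_um[i], design,
                                    seed = seeds$calcium + i)
        vapply(tr, function(x) deltaFOverF(x)$peak_fold, numeric(1))
      })
      metrics$calcium_responder_pct <-
        vapply(folds_by_dose, responderFraction, numeric(1))
      cw <- williamsTrendTest(unlist(folds_by_dose),
                              rep(design@dose_grid_um,
                                  lengths(folds_by_dose)),
                              alpha = config$dose$alpha,
                              n_null = as.integer(config$dose$n_null),
                              seed = seeds$dose + 1000L)
      metrics$calcium_williams_significant <- cw$table$significant
    }
  }
  timings$analyse <- tic() - t0

  paths <- list(metrics = file.path(out_dir, "metrics.json"),
                scores = file.path(out_dir, "scores.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(score_tab, paths$scores, row.names = FALSE)
  manifest <- list(config = config,
                   config_hash = textHash(paste(deparse(config),
                                                collapse = "")),
                   seeds = seeds, timings = timings,
                   package_version = as.character(utils::packageVersion("neuroraman")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(metrics = metrics, manifest = manifest, paths = paths))
}
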