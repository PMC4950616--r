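#' Build and validate a pipeline configuration
#'
#' Collects the settings of all five pipeline stages into a single validated
#' configuration. Every stochastic stage derives its seed deterministically
#' from the one master seed, so a configuration identifies its outputs
#' bit-for-bit.
#'
#' @param landscape named list of [generate_landscape()] arguments.
#' @param species named list of [species_response()] objects (or coefficient
#'   lists accepted by it), one per virtual species.
#' @param ensemble named list: `techniques`, `n_repetitions`,
#'   `calibration_fraction`.
#' @param scenarios named list: `n_simulations`, `k_select`, `warming_range`,
#'   `precip_change_range`, `coarse_cell_km`, `spatial_sd_frac`.
#' @param thresholds named list: `change_threshold` (default 0.15) and
#'   `threshold_basis` (`"baseline"`, the default, or `"future"` to compute
#'   the common suitability threshold against the future consensus instead).
#' @param outdir output directory for the run's artifacts.
#' @param seed master integer seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(landscape = list(), species = list(),
                            ensemble = list(), scenarios = list(),
                            thresholds = list(), outdir = tempfile("tsrun"),
                            seed = 1) {
  defaults <- list(
    ensemble = list(techniques = sdm_techniques(), n_repetitions = 10,
                    calibration_fraction = 0.7),
    scenarios = list(n_simulations = 70, k_select = 7,
                     warming_range = c(1.9, 8),
                     precip_change_range = c(0.03, 0.26),
                     coarse_cell_km = 250, spatial_sd_frac = 0.1),
    thresholds = list(change_threshold = 0.15, threshold_basis = "baseline")
  )
  ensemble <- modifyList(defaults$ensemble, ensemble)
  scenarios <- modifyList(defaults$scenarios, scenarios)
  thresholds <- modifyList(defaults$thresholds, thresholds)
  if (scenarios$k_select > scenarios$n_simulations)
    stop_config("invalid configuration: scenarios$k_select (%s) exceeds scenarios$n_simulations (%s)",
                scenarios$k_select, scenarios$n_simulations)
  if (!thresholds$threshold_basis %in% c("baseline", "future"))
    stop_config("thresholds$threshold_basis must be 'baseline' or 'future'")
  check_number(thresholds$change_threshold, "thresholds$change_threshold",
               lower = 1e-12, upper = 1 - 1e-12)
  if (!length(species)) stop_config("at least one species must be configured")
  if (is.null(names(species)) || any(names(species) == ""))
    stop_config("species must be a named list")
  species <- lapply(species, function(sp) {
    if (inherits(sp, "species_response")) sp
    else do.call(species_response, sp)
  })
  structure(list(landscape = landscape, species = species,
                 ensemble = ensemble, scenarios = scenarios,
                 thresholds = thresholds, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the [pipeline_config()] argument structure (keys
#' `landscape`, `species`, `ensemble`, `scenarios`, `thresholds`, `seed`);
#' species entries are coefficient lists for [species_response()].
#'
#' @param path YAML file path.
#' @param outdir,seed optional overrides of the file's values.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL, seed = NULL) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  sp <- lapply(y$species, function(s) {
    for (f in c("linear", "quadratic")) {
      if (!is.null(s[[f]])) s[[f]] <- unlist(s[[f]])
    }
    if (!is.null(s$edaphic)) s$edaphic <- as.numeric(unlist(s$edaphic))
    do.call(species_response, s)
  })
  for (f in c("warming_range", "precip_change_range"))
    if (!is.null(y$scenarios[[f]])) y$scenarios[[f]] <- as.numeric(y$scenarios[[f]])
  pipeline_config(landscape = if (is.null(y$landscape)) list() else y$landscape,
                  species = sp,
                  ensemble = if (is.null(y$ensemble)) list() else y$ensemble,
                  scenarios = if (is.null(y$scenarios)) list() else y$scenarios,
                  thresholds = if (is.null(y$thresholds)) list() else y$thresholds,
                  outdir = if (is.null(outdir)) {
                    if (is.null(y$outdir)) tempfile("tsrun") else y$outdir
                  } else outdir,
                  seed = if (is.null(seed)) {
                    if (is.null(y$seed)) 1L else y$seed
                  } else seed)
}

#' The bundled demonstration configuration
#'
#' A self-contained run on a 2,000-cell synthetic landscape with three
#' virtual species (a cold-adapted conifer-like species, a warm-temperate
#' species and a broad generalist), a 10-member climate-simulation ensemble
#' reduced to 7 representatives by k-means, and a reduced
#' 8-technique x 3-repetition ensemble sized for quick interactive runs.
#'
#' @param outdir,seed overrides passed to [read_pipeline_config()].
#' @return a `pipeline_config`.
#' @export
demo_config <- function(outdir = tempfile("tsdemo"), seed = 1) {
  read_pipeline_config(system.file("extdata", "demo_config.yml",
                                   package = "treeshift"),
                       outdir = outdir, seed = seed)
}

log_stage <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run the five-stage vulnerability pipeline end to end
#'
#' Generates (or loads) the landscape, simulates species occurrences, builds
#' and subsets the climate-simulation ensemble, fits the SDM ensemble per
#' species, projects baseline and future suitability, forms the AUC-weighted
#' consensus, selects the common suitability threshold, classifies the
#' baseline range into UH/LSH/PH with per-cell agreement, and writes all
#' artifacts (delimited tables) plus a JSON run manifest with seeds, stage
#' counts and per-file MD5 digests to the configured output directory.
#' Re-running the same configuration reproduces identical digests.
#'
#' @param config a `pipeline_config`.
#' @param verbose emit stage-boundary log messages (default TRUE).
#' @return invisibly, a list with the in-memory stage results (`grid`,
#'   `occurrences`, `scenario_summary`, `selected`, `ensembles`, `cubes`,
#'   `consensus`, `thresholds`, `classifications`, `summaries`, `overlay`,
#'   `sensitivity`, `uncertainty`, `manifest`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  master <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  ## 1. landscape ------------------------------------------------------------
  grid <- stage("landscape", do.call(generate_landscape,
    modifyList(config$landscape, list(seed = derive_seed(master, "landscape")))))
  log_stage(verbose, "[landscape] %d cells (%d x %d), %d regions",
            nrow(grid), attr(grid, "n_rows"), attr(grid, "n_cols"),
            length(unique(grid$region)))
  write_grid_table(grid, file.path(config$outdir, "landscape.csv"))

  ## 2. species occurrences --------------------------------------------------
  occurrences <- stage("occurrence", {
    out <- list()
    for (i in seq_along(config$species)) {
      nm <- names(config$species)[i]
      out[[nm]] <- generate_occurrence(grid, config$species[[i]],
                                       seed = derive_seed(master, "occ", i))
      write_occurrence(out[[nm]], grid,
                       file.path(config$outdir,
                                 sprintf("occurrence_%s.csv", nm)))
    }
    out
  })
  log_stage(verbose, "[occurrence] %d species; prevalence: %s",
            length(occurrences),
            paste(sprintf("%s=%.2f", names(occurrences),
                          vapply(occurrences,
                                 function(o) mean(o$occurrence), 0)),
                  collapse = ", "))

  ## 3. climate simulations + scenario selection -----------------------------
  sc <- config$scenarios
  deltas <- stage("simulation_ensemble",
    generate_simulation_ensemble(grid, n_simulations = sc$n_simulations,
                                 warming_range = sc$warming_range,
                                 precip_change_range = sc$precip_change_range,
                                 coarse_cell_km = sc$coarse_cell_km,
                                 spatial_sd_frac = sc$spatial_sd_frac,
                                 seed = derive_seed(master, "scenarios")))
  summaries <- stage("scenario_summary", scenario_summary(grid, deltas))
  selected <- stage("select_scenarios",
    select_scenarios(summaries, k = sc$k_select,
                     seed = derive_seed(master, "kmeans")))
  write_csv_utf8(summaries, file.path(config$outdir, "scenario_summary.csv"))
  write_csv_utf8(data.frame(sim_id = selected),
                 file.path(config$outdir, "selected_scenarios.csv"))
  log_stage(verbose, "[climate] %d simulations generated, %d selected (%s)",
            length(deltas), length(selected), paste(selected, collapse = ", "))

  ## 4. downscaled future predictors -----------------------------------------
  baseline_pred <- grid_predictors(grid, drop_last_edaphic = TRUE)
  future_pred <- stage("downscale", {
    sel <- deltas[vapply(deltas, `[[`, "", "sim_id") %in% selected]
    setNames(lapply(sel, function(d) {
      fut <- suppressMessages(delta_downscale(grid, d))
      grid_predictors(grid, monthly = fut, drop_last_edaphic = TRUE)
    }), vapply(sel, `[[`, "", "sim_id"))
  })
  log_stage(verbose, "[downscale] %d future climate layers on %d cells",
            length(future_pred), nrow(grid))

  ## 5. per-species modelling and classification ------------------------------
  f <- stats::as.formula(paste("occurrence ~",
                               paste(colnames(baseline_pred),
                                     collapse = " + ")))
  ens <- cubes <- cons <- thr <- classi <- regsum <- sens <- unc <- list()
  for (i in seq_along(occurrences)) {
    nm <- names(occurrences)[i]
    d <- cbind(occurrence = occurrences[[nm]]$occurrence, baseline_pred)
    e <- stage(paste0("fit:", nm),
      fit_sdm_ensemble(f, d, techniques = config$ensemble$techniques,
                       n_repetitions = config$ensemble$n_repetitions,
                       calibration_fraction = config$ensemble$calibration_fraction,
                       seed = derive_seed(master, "fit", i)))
    log_stage(verbose,
              "[fit:%s] %d models (%d techniques x %d repetitions), mean AUC %.3f",
              nm, length(e$models), length(e$techniques), e$n_repetitions,
              mean(e$performance$auc))
    cube <- stage(paste0("project:", nm),
      project_cube(e, baseline_pred, future_pred, cell_id = grid$cell_id))
    log_stage(verbose, "[project:%s] %d baseline + %d future probability layers",
              nm, ncol(cube$baseline),
              ncol(cube$baseline) * length(cube$sim_ids))
    cm <- weighted_average(cube)
    basis <- if (config$thresholds$threshold_basis == "baseline")
      cm$wap_baseline else cm$wap_2080
    th <- stage(paste0("threshold:", nm),
      select_threshold(occurrences[[nm]]$occurrence, basis))
    cl <- classify_cells(cm, th$threshold,
                         config$thresholds$change_threshold)
    ag <- agreement_value(cube, cl)
    rs <- summarize_by_region(cl, grid$region, cell_area_km2 =
                                attr(grid, "cell_size_km")^2,
                              agreement = ag)
    sv <- sensitivity_analysis(cm, th$threshold)
    up <- partition_uncertainty(cube)
    log_stage(verbose,
              "[classify:%s] threshold %.3f; baseline range %d cells; UH %d, LSH %d, PH %d",
              nm, th$threshold, sum(cl$category %in% c("UH", "LSH", "PH")),
              sum(cl$category == "UH"), sum(cl$category == "LSH"),
              sum(cl$category == "PH"))

    write_csv_utf8(e$performance,
                   file.path(config$outdir, sprintf("performance_%s.csv", nm)))
    write_consensus(cm, file.path(config$outdir,
                                  sprintf("consensus_%s.csv", nm)))
    write_classification(cl, grid,
                         file.path(config$outdir,
                                   sprintf("classification_%s.csv", nm)),
                         agreement = ag)
    write_csv_utf8(rs, file.path(config$outdir,
                                 sprintf("regional_summary_%s.csv", nm)))
    write_csv_utf8(sv, file.path(config$outdir,
                                 sprintf("sensitivity_%s.csv", nm)))
    write_csv_utf8(up$ratios, file.path(config$outdir,
                                        sprintf("uncertainty_%s.csv", nm)))
    ens[[nm]] <- e; cubes[[nm]] <- cube; cons[[nm]] <- cm; thr[[nm]] <- th
    classi[[nm]] <- cl; regsum[[nm]] <- rs; sens[[nm]] <- sv; unc[[nm]] <- up
  }

  overlay <- NULL
  if (length(classi) >= 2) {
    overlay <- stage("overlay", risk_overlay(classi))
    write_csv_utf8(overlay, file.path(config$outdir, "overlay.csv"))
    log_stage(verbose, "[overlay] %d cells suitable for all %d species",
              nrow(overlay), length(classi))
  }

  ## manifest ----------------------------------------------------------------
  files <- sort(list.files(config$outdir, pattern = "\\.csv$"))
  digests <- as.list(tools::md5sum(file.path(config$outdir, files)))
  names(digests) <- files
  manifest <- list(
    package = "treeshift",
    version = as.character(utils::packageVersion("treeshift")),
    seed = master,
    n_cells = nrow(grid),
    n_species = length(occurrences),
    n_simulations = length(deltas),
    n_selected = length(selected),
    n_models = vapply(ens, function(e) length(e$models), 0L),
    n_future_layers = vapply(cubes, function(cb)
      ncol(cb$baseline) * length(cb$sim_ids), 0L),
    thresholds = vapply(thr, function(t) t$threshold, 0),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    digests = digests
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage(verbose, "[done] %d artifact files in %s (%.1f s)",
            length(files) + 1L, config$outdir, manifest$elapsed_s)

  invisible(list(grid = grid, occurrences = occurrences,
                 scenario_summary = summaries, selected = selected,
                 ensembles = ens, cubes = cubes, consensus = cons,
                 thresholds = thr, classifications = classi,
                 summaries = regsum, overlay = overlay, sensitivity = sens,
                 uncertainty = unc, manifest = manifest))
}
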