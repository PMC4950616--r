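#' Repeated split-sample partitions for model calibration/evaluation
#'
#' Draws `n_repetitions` independent random partitions of the grid cells into
#' a calibration set and an evaluation set. The calibration size is
#' round-half-up of `calibration_fraction * n` (so a 6,418-cell grid split
#' 70/30 yields 4,493 calibration and 1,925 evaluation cells).
#'
#' @param ids vector of cell identifiers, or a single integer n (expanded to
#'   `1:n`).
#' @param calibration_fraction fraction of cells used for calibration,
#'   in (0, 1); default 0.7.
#' @param n_repetitions number of independent splits; default 10.
#' @param seed integer RNG seed.
#' @return list of length `n_repetitions`; each element a list with
#'   `calibration` and `evaluation` id vectors (disjoint, exhaustive).
#' @export
#' @examples
#' s <- split_sample(6418, 0.7, n_repetitions = 1, seed = 1)
#' lengths(s[[1]])  # 4493, 1925
split_sample <- function(ids, calibration_fraction = 0.7, n_repetitions = 10,
                         seed = 1) {
  if (length(ids) == 1L && is.numeric(ids)) ids <- seq_len(ids)
  n <- length(ids)
  if (n < 10) stop_config("need at least 10 cells to split (got %d)", n)
  check_number(calibration_fraction, "calibration_fraction",
               lower = 1e-9, upper = 1 - 1e-9)
  check_number(n_repetitions, "n_repetitions", lower = 1)
  n_cal <- as.integer(round_half_up(calibration_fraction * n))
  if (n_cal < 1L || n_cal >= n)
    stop_config("degenerate split: calibration size %d of %d", n_cal, n)
  with_seed(seed, {
    lapply(seq_len(n_repetitions), function(k) {
      cal <- sort(sample(ids, n_cal))
      list(calibration = cal, evaluation = setdiff(ids, cal))
    })
  })
}

#' Fit a multi-technique, multi-repetition SDM ensemble
#'
#' The central fitting function. For each of `n_repetitions` random 70/30
#' split-sample partitions and each modelling technique, a species
#' distribution model is calibrated on the calibration cells and evaluated on
#' the held-out cells, yielding `length(techniques) * n_repetitions` fitted
#' models (80 under the defaults), each carrying its held-out AUC (the weight
#' it will contribute to the consensus), sensitivity and specificity at its
#' own optimal threshold, and an accuracy grade. A model whose fit fails is
#' retried once under a perturbed seed and then dropped with a warning; the
#' consensus weights adjust automatically since every downstream weighted
#' average runs over the models actually retained.
#'
#' @param formula model formula, e.g. `occ ~ TEM + PRE + PRATIO + elevation`;
#'   the response must be 0/1 occurrence and the right-hand side plain
#'   predictor columns of `data` (apply transformations beforehand).
#' @param data data.frame containing the response and predictors, one row per
#'   grid cell.
#' @param techniques character vector of technique identifiers (see
#'   [sdm_techniques()]); default all eight.
#' @param n_repetitions number of split-sample repetitions (default 10).
#' @param calibration_fraction calibration share of cells (default 0.7).
#' @param seed master RNG seed; all splits and technique fits derive their
#'   seeds deterministically from it.
#' @return An object of class `sdm_ensemble`: list with `models` (per fitted
#'   model: technique, repetition, adapter fit), `performance` (data.frame of
#'   AUC, sensitivity, specificity, grade per model), `splits`, `terms`,
#'   `predictors`, `call`.
#' @seealso [predict.sdm_ensemble()], [project_cube()], [weighted_average()]
#' @export
fit_sdm_ensemble <- function(formula, data, techniques = sdm_techniques(),
                             n_repetitions = 10, calibration_fraction = 0.7,
                             seed = 1) {
  cl <- match.call()
  if (length(techniques) == 0 || anyDuplicated(techniques))
    stop_config("techniques must be a non-empty set of distinct identifiers")
  mf <- model.frame(formula, data)
  y <- as.integer(model.response(mf))
  if (!all(y %in% 0:1)) stop_config("response must be 0/1 occurrence")
  x <- mf[, -1, drop = FALSE]
  if (!all(vapply(x, is.numeric, TRUE)))
    stop_config("all predictors must be numeric")
  n <- nrow(x)
  splits <- split_sample(seq_len(n), calibration_fraction, n_repetitions,
                         seed = derive_seed(seed, "split"))
  models <- list(); perf <- list()
  for (k in seq_len(n_repetitions)) {
    cal <- splits[[k]]$calibration; ev <- splits[[k]]$evaluation
    if (length(unique(y[cal])) < 2)
      stop_config("calibration set of repetition %d contains a single class", k)
    for (j in seq_along(techniques)) {
      tech <- techniques[j]
      ad <- technique_adapter(tech)
      sd1 <- derive_seed(seed, "fit", j * 1000L + k)
      fit <- tryCatch(ad$fit(x[cal, , drop = FALSE], y[cal], sd1),
                      error = function(e) e)
      if (inherits(fit, "error"))  # one retry with a perturbed seed
        fit <- tryCatch(ad$fit(x[cal, , drop = FALSE], y[cal], sd1 + 7919L),
                        error = function(e) e)
      if (inherits(fit, "error")) {
        warning(sprintf("technique %s, repetition %d failed twice and was excluded (%s)",
                        tech, k, conditionMessage(fit)), call. = FALSE)
        next
      }
      p_ev <- ad$predict(fit, x[ev, , drop = FALSE])
      roc <- evaluate_roc(y[ev], p_ev)
      ss <- if (length(unique(y[ev])) == 2) {
        th <- select_threshold(y[ev], p_ev)
        c(th$sensitivity, th$specificity)
      } else c(NA_real_, NA_real_)
      models[[length(models) + 1L]] <-
        list(technique = tech, repetition = k, fit = fit)
      perf[[length(perf) + 1L]] <-
        data.frame(technique = tech, repetition = k, auc = roc$auc,
                   sensitivity = ss[1], specificity = ss[2],
                   grade = roc$grade)
    }
  }
  if (!length(models)) stop_config("no model could be fitted")
  structure(list(models = models, performance = do.call(rbind, perf),
                 splits = splits, techniques = techniques,
                 n_repetitions = n_repetitions,
                 predictors = colnames(x), terms = terms(mf),
                 n_cells = n, seed = seed, call = cl),
            class = "sdm_ensemble")
}

check_schema <- function(object, newdata) {
  miss <- setdiff(object$predictors, colnames(newdata))
  if (length(miss))
    stop_config("newdata is missing predictor(s): %s",
                paste(miss, collapse = ", "))
  newdata[, object$predictors, drop = FALSE]
}

#' Predict habitat suitability from a fitted ensemble
#'
#' @param object an `sdm_ensemble`.
#' @param newdata data.frame with the training predictors.
#' @param type `"consensus"` (default) for the AUC-weighted average
#'   probability per cell, or `"matrix"` for the full cell x model
#'   probability matrix.
#' @param ... unused.
#' @return numeric vector (consensus) or matrix (cells x models).
#' @export
predict.sdm_ensemble <- function(object, newdata,
                                 type = c("consensus", "matrix"), ...) {
  type <- match.arg(type)
  x <- check_schema(object, newdata)
  pm <- vapply(object$models, function(m) {
    technique_adapter(m$technique)$predict(m$fit, x)
  }, numeric(nrow(x)))
  if (nrow(x) == 1) pm <- matrix(pm, nrow = 1)
  colnames(pm) <- vapply(object$models,
                         function(m) sprintf("%s.%d", m$technique,
                                             m$repetition), "")
  if (type == "matrix") return(pm)
  w <- object$performance$auc
  as.numeric(pm %*% w / sum(w))
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("SDM ensemble: %d models (%d technique(s) x %d repetition(s)) on %d cells\n",
              length(x$models), length(x$techniques), x$n_repetitions,
              x$n_cells))
  cat(sprintf("held-out AUC: %.3f-%.3f (mean %.3f)\n",
              min(x$performance$auc), max(x$performance$auc),
              mean(x$performance$auc)))
  invisible(x)
}

#' @export
summary.sdm_ensemble <- function(object, ...) {
  p <- object$performance
  s <- do.call(rbind, lapply(split(p, p$technique), function(d) {
    data.frame(technique = d$technique[1], n_models = nrow(d),
               mean_auc = mean(d$auc), min_auc = min(d$auc),
               max_auc = max(d$auc),
               mean_sensitivity = mean(d$sensitivity),
               mean_specificity = mean(d$specificity),
               grade = auc_grade(mean(d$auc)))
  }))
  s <- s[match(object$techniques, s$technique), ]
  rownames(s) <- NULL
  structure(list(by_technique = s, overall_mean_auc = mean(p$auc),
                 n_models = nrow(p)), class = "summary.sdm_ensemble")
}

#' @export
print.summary.sdm_ensemble <- function(x, ...) {
  cat("Held-out performance by modelling technique\n")
  df <- x$by_technique
  df[, sapply(df, is.numeric)] <- round(df[, sapply(df, is.numeric)], 3)
  print(df, row.names = FALSE)
  cat(sprintf("overall mean AUC %.3f over %d models\n",
              x$overall_mean_auc, x$n_models))
  invisible(x)
}

#' @export
plot.sdm_ensemble <- function(x, ...) {
  p <- x$performance
  boxplot(auc ~ technique, data = p,
          ylab = "held-out AUC", xlab = "modelling technique",
          main = "Ensemble performance", ...)
  invisible(x)
}

#' Project the ensemble onto baseline and future climate layers
#'
#' Runs every fitted model of the ensemble over the baseline predictor table
#' and over one predictor table per future climate simulation, producing the
#' projection cube of per-cell suitability probabilities indexed by cell,
#' technique, repetition and (for the future block) simulation. With the
#' default ensemble and seven simulations this is 80 baseline layers and
#' 560 future layers.
#'
#' @param object a fitted `sdm_ensemble`.
#' @param baseline data.frame of baseline predictors (training schema).
#' @param future named list of data.frames, one per climate simulation, same
#'   schema; may be `NULL` for a baseline-only cube.
#' @param cell_id optional cell identifiers (default row sequence).
#' @return An object of class `projection_cube`: `baseline` (cells x models
#'   matrix), `future` (cells x models x simulations array or `NULL`), `auc`
#'   weights, `technique`/`repetition` per model, `sim_ids`, `cell_id`.
#' @export
project_cube <- function(object, baseline, future = NULL, cell_id = NULL) {
  stopifnot(inherits(object, "sdm_ensemble"))
  if (is.null(cell_id)) cell_id <- seq_len(nrow(baseline))
  pb <- predict(object, baseline, type = "matrix")
  fut <- NULL; sim_ids <- character(0)
  if (!is.null(future) && length(future)) {
    sim_ids <- names(future)
    if (is.null(sim_ids)) sim_ids <- sprintf("sim%02d", seq_along(future))
    fut <- array(NA_real_, dim = c(nrow(pb), ncol(pb), length(future)),
                 dimnames = list(NULL, colnames(pb), sim_ids))
    for (l in seq_along(future)) {
      if (nrow(future[[l]]) != nrow(baseline))
        stop_config("future layer %s has %d rows; expected %d",
                    sim_ids[l], nrow(future[[l]]), nrow(baseline))
      fut[, , l] <- predict(object, future[[l]], type = "matrix")
    }
  }
  structure(list(baseline = pb, future = fut,
                 auc = object$performance$auc,
                 technique = object$performance$technique,
                 repetition = object$performance$repetition,
                 sim_ids = sim_ids, cell_id = cell_id),
            class = "projection_cube")
}

#' @export
print.projection_cube <- function(x, ...) {
  cat(sprintf("<projection_cube: %d cells x %d models baseline%s>\n",
              nrow(x$baseline), ncol(x$baseline),
              if (is.null(x$future)) ""
              else sprintf(", %d future layers (%d simulations)",
                           ncol(x$baseline) * length(x$sim_ids),
                           length(x$sim_ids))))
  invisible(x)
}

#' AUC-weighted consensus of a projection cube
#'
#' Collapses the per-model probabilities into the weighted average
#' probability of habitat suitability (WAP), using each model's held-out AUC
#' as its weight. For the baseline block,
#' \deqn{WAP_i = \sum_{jk} AUC_{jk} P_{ijk} / \sum_{jk} AUC_{jk},}
#' and for the future block the same weights are applied to every simulation
#' and the total divided by \eqn{L \sum_{jk} AUC_{jk}} where \eqn{L} is the
#' simulation count — equivalently the mean over simulations of the
#' per-simulation weighted averages.
#'
#' @param cube a `projection_cube`.
#' @param weights optional positive weight vector overriding the stored AUCs.
#' @return data.frame of class `consensus_map`: `cell_id`, `wap_baseline`
#'   and, when the cube has a future block, `wap_2080`.
#' @export
weighted_average <- function(cube, weights = NULL) {
  stopifnot(inherits(cube, "projection_cube"))
  w <- if (is.null(weights)) cube$auc else weights
  if (length(w) != ncol(cube$baseline))
    stop_config("need one weight per model (%d)", ncol(cube$baseline))
  if (any(!is.finite(w)) || any(w <= 0) || sum(w) == 0)
    stop_config("weights must be strictly positive and finite")
  out <- data.frame(cell_id = cube$cell_id,
                    wap_baseline = as.numeric(cube$baseline %*% w / sum(w)))
  if (!is.null(cube$future)) {
    L <- dim(cube$future)[3]
    num <- numeric(nrow(out))
    for (l in seq_len(L)) {
      slice <- matrix(cube$future[, , l], nrow = nrow(out))
      num <- num + as.numeric(slice %*% w)
    }
    out$wap_2080 <- num / (L * sum(w))
  }
  class(out) <- c("consensus_map", "data.frame")
  out
}
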