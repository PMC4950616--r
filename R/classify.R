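#' Select the suitability threshold maximizing sensitivity + specificity
#'
#' Scans every distinct predicted probability as a candidate cut-off and
#' returns the one that jointly maximizes sensitivity and specificity of the
#' implied presence/absence prediction (presence when probability >=
#' threshold). Ties are broken toward the smallest candidate. The selected
#' threshold is meant to be reused unchanged for both the baseline and the
#' future binarization.
#'
#' @param observed 0/1 occurrence vector.
#' @param probabilities predicted probabilities (same length).
#' @return object of class `threshold_result`: `threshold`, `sensitivity`,
#'   `specificity`, `candidates` (the scanned values) and `degenerate`
#'   (TRUE when all probabilities are equal, in which case any cut-off is
#'   equivalent).
#' @export
#' @examples
#' select_threshold(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.1))$threshold  # 0.8
select_threshold <- function(observed, probabilities) {
  obs <- as.integer(observed)
  if (length(obs) != length(probabilities))
    stop_config("observed and probabilities differ in length")
  n1 <- sum(obs == 1L); n0 <- sum(obs == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_config("both presences and absences are required to select a threshold")
  cand <- sort(unique(probabilities))
  tp <- vapply(cand, function(t) sum(probabilities >= t & obs == 1L), 0L)
  tn <- vapply(cand, function(t) sum(probabilities < t & obs == 0L), 0L)
  # integer score = (sens + spec) * n1 * n0: exact arithmetic, so true ties
  # are resolved deterministically toward the smallest candidate
  score <- tp * n0 + tn * n1
  best <- which(score == max(score))[1]  # candidates ascending: first = smallest
  sens <- tp / n1; spec <- tn / n0
  structure(list(threshold = cand[best], sensitivity = sens[best],
                 specificity = spec[best], candidates = cand,
                 degenerate = length(cand) == 1L),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold = %.4f (sensitivity %.3f, specificity %.3f%s)\n",
              x$threshold, x$sensitivity, x$specificity,
              if (x$degenerate) "; degenerate: all probabilities equal" else ""))
  invisible(x)
}

# Vectorized classification of (baseline, future) probability pairs.
# Baseline range: base >= threshold. Within it: UH when the future
# probability falls below the threshold; LSH when suitability persists but
# drops by at least `change_threshold`; PH otherwise (small decline or any
# non-decline). Outside the range: GAINED when the future probability
# reaches the threshold, OUTSIDE_BASELINE otherwise.
classify_pair <- function(base, future, threshold, change_threshold) {
  d <- future - base
  in_range <- base >= threshold
  cat <- character(length(base))
  cat[!in_range] <- ifelse(future[!in_range] >= threshold,
                           "GAINED", "OUTSIDE_BASELINE")
  uh <- in_range & future < threshold
  lsh <- in_range & !uh & d < 0 & abs(d) >= change_threshold
  ph <- in_range & !uh & !lsh
  cat[uh] <- "UH"; cat[lsh] <- "LSH"; cat[ph] <- "PH"
  factor(cat, levels = c("UH", "LSH", "PH", "GAINED", "OUTSIDE_BASELINE"))
}

#' Classify baseline-range cells as unsuitable / less suitable / persistent
#'
#' Applies the vulnerability rules to a consensus map. A cell belongs to the
#' species' baseline range when its baseline consensus probability meets the
#' suitability threshold. Within the baseline range, a cell becomes
#' unsuitable habitat (UH) when its future consensus probability falls below
#' the threshold; otherwise it is less suitable habitat (LSH) when the
#' probability declines by at least `change_threshold` (default 0.15, an
#' absolute probability difference), and persistent habitat (PH) when the
#' decline is smaller or the probability does not decline. Cells outside the
#' baseline range are tracked as GAINED (future probability reaches the
#' threshold) or OUTSIDE_BASELINE, and are excluded from vulnerability
#' statistics.
#'
#' @param consensus a `consensus_map` (columns `cell_id`, `wap_baseline`,
#'   `wap_2080`).
#' @param threshold common suitability cut-off in (0, 1), typically from
#'   [select_threshold()].
#' @param change_threshold minimum absolute decline in probability for LSH,
#'   in (0, 1); default 0.15.
#' @return data.frame of class `cell_classification`: `cell_id`,
#'   `wap_baseline`, `wap_2080`, `delta_wap`, `category` (factor UH, LSH,
#'   PH, GAINED, OUTSIDE_BASELINE).
#' @export
classify_cells <- function(consensus, threshold, change_threshold = 0.15) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop_config("threshold must lie strictly within (0, 1)")
  check_number(change_threshold, "change_threshold",
               lower = 1e-12, upper = 1 - 1e-12)
  if (!all(c("wap_baseline", "wap_2080") %in% colnames(consensus)))
    stop_config("consensus must have wap_baseline and wap_2080 columns")
  out <- data.frame(
    cell_id = consensus$cell_id,
    wap_baseline = consensus$wap_baseline,
    wap_2080 = consensus$wap_2080,
    delta_wap = consensus$wap_2080 - consensus$wap_baseline,
    category = classify_pair(consensus$wap_baseline, consensus$wap_2080,
                             threshold, change_threshold)
  )
  attr(out, "threshold") <- threshold
  attr(out, "change_threshold") <- change_threshold
  class(out) <- c("cell_classification", "data.frame")
  out
}

#' Per-cell agreement of single projections with the consensus category
#'
#' For every baseline-range cell, classifies each single projection — one
#' model (technique x repetition) paired with one future climate simulation,
#' each future probability matched against the same model's own baseline
#' probability — under the same rules and threshold, and reports the
#' percentage of those single projections whose category agrees with the
#' consensus classification (560 single projections under the default
#' ensemble). `mode = "binary"` instead compares only the binary
#' suitable/unsuitable outcome of the future probability.
#'
#' @param cube a `projection_cube` with a future block.
#' @param classification a `cell_classification` from [classify_cells()],
#'   aligned with the cube's cells.
#' @param threshold,change_threshold the same values used for the consensus
#'   classification (defaults are read from the classification attributes).
#' @param mode `"category"` (default, three-way agreement) or `"binary"`.
#' @return numeric vector of agreement percentages in \[0, 100\], aligned
#'   with `classification` rows; `NA` outside the baseline range.
#' @export
agreement_value <- function(cube, classification,
                            threshold = attr(classification, "threshold"),
                            change_threshold = attr(classification,
                                                    "change_threshold"),
                            mode = c("category", "binary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cube, "projection_cube"))
  if (is.null(cube$future))
    stop_config("cube has no future projections")
  if (nrow(cube$baseline) != nrow(classification))
    stop_config("cube and classification are not aligned (%d vs %d cells)",
                nrow(cube$baseline), nrow(classification))
  M <- ncol(cube$baseline); L <- dim(cube$future)[3]
  in_range <- classification$category %in% c("UH", "LSH", "PH")
  cons_cat <- as.character(classification$category)
  cons_bin <- classification$wap_2080 >= threshold
  matches <- numeric(nrow(classification))
  for (l in seq_len(L)) {
    for (m in seq_len(M)) {
      if (mode == "category") {
        sc <- classify_pair(cube$baseline[, m], cube$future[, m, l],
                            threshold, change_threshold)
        matches <- matches + (as.character(sc) == cons_cat)
      } else {
        matches <- matches + ((cube$future[, m, l] >= threshold) == cons_bin)
      }
    }
  }
  pct <- 100 * matches / (M * L)
  pct[!in_range] <- NA_real_
  pct
}

#' Regional vulnerability summary (areas, shares of baseline, agreement)
#'
#' Aggregates a per-cell classification by reporting region: for each region
#' and habitat category (UH, LSH, PH) the absolute area, the share of the
#' region's baseline range, and the mean agreement value of the cells in
#' that region-category; a final `All` row covers the whole domain. Only
#' baseline-range cells enter the summary (GAINED and OUTSIDE_BASELINE cells
#' are excluded).
#'
#' @param classification a `cell_classification`.
#' @param regions character/factor vector of region labels aligned with
#'   `classification` rows; every baseline-range cell must be assigned.
#' @param cell_area_km2 area of one analysis cell (default 400, a 20 x 20-km
#'   cell).
#' @param agreement optional per-cell agreement percentages from
#'   [agreement_value()].
#' @return data.frame with one row per region plus `All`: baseline cell
#'   count and area, and per category the area (km2), percent of the
#'   regional baseline range, and mean agreement (NA when no agreement
#'   vector is supplied or the category is empty).
#' @export
summarize_by_region <- function(classification, regions, cell_area_km2 = 400,
                                agreement = NULL) {
  if (length(regions) != nrow(classification))
    stop_config("regions must align with classification rows")
  in_range <- classification$category %in% c("UH", "LSH", "PH")
  if (any(is.na(regions) & in_range))
    stop_config("baseline-range cell(s) without a region: %s",
                paste(head(classification$cell_id[is.na(regions) & in_range],
                           10), collapse = ", "))
  if (is.null(agreement)) agreement <- rep(NA_real_, nrow(classification))
  lev <- unique(as.character(regions[!is.na(regions)]))
  lev <- lev[order(lev)]
  one_region <- function(sel, label) {
    base <- sel & in_range
    nb <- sum(base)
    row <- data.frame(region = label, baseline_cells = nb,
                      baseline_area_km2 = nb * cell_area_km2)
    for (cat in c("UH", "LSH", "PH")) {
      idx <- base & classification$category == cat
      nc <- sum(idx)
      row[[paste0(tolower(cat), "_area_km2")]] <- nc * cell_area_km2
      row[[paste0(tolower(cat), "_pct")]] <-
        if (nb > 0) 100 * nc / nb else 0
      row[[paste0(tolower(cat), "_agreement")]] <-
        if (nc > 0) mean(agreement[idx], na.rm = TRUE) else NA_real_
    }
    row
  }
  rows <- lapply(lev, function(r) one_region(!is.na(regions) & regions == r, r))
  rows[[length(rows) + 1L]] <- one_region(rep(TRUE, nrow(classification)),
                                          "All")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count species at risk per cell across several classifications
#'
#' Restricts to the cells belonging to every species' baseline range and
#' counts, per cell, how many species are classified UH or LSH there.
#'
#' @param classifications named list (>= 2) of `cell_classification` objects
#'   on the same grid.
#' @return data.frame `cell_id`, `n_species_at_risk` (0..n species), only
#'   for cells inside all baseline ranges.
#' @export
risk_overlay <- function(classifications) {
  if (length(classifications) < 2)
    stop_config("need at least two species classifications")
  ids <- classifications[[1]]$cell_id
  for (cl in classifications[-1])
    if (!identical(cl$cell_id, ids))
      stop_config("classifications are not on the same grid (cell ids differ)")
  in_all <- Reduce(`&`, lapply(classifications, function(cl)
    cl$category %in% c("UH", "LSH", "PH")))
  at_risk <- Reduce(`+`, lapply(classifications, function(cl)
    as.integer(cl$category %in% c("UH", "LSH"))))
  data.frame(cell_id = ids[in_all], n_species_at_risk = at_risk[in_all])
}

#' Sensitivity of the classification to the change threshold
#'
#' Re-runs the classification across a grid of change thresholds (default 5%
#' to 25% in steps of 5%) and reports the share of the baseline range
#' falling in each category. The UH share cannot depend on the change
#' threshold (the UH rule only involves the suitability threshold); this is
#' asserted. The LSH share is non-increasing in the threshold, with the
#' displaced cells absorbed by PH.
#'
#' @param consensus a `consensus_map`.
#' @param threshold common suitability threshold.
#' @param change_thresholds numeric vector of thresholds to sweep.
#' @return data.frame: `change_threshold`, `uh_pct`, `lsh_pct`, `ph_pct`,
#'   `n_baseline`.
#' @export
sensitivity_analysis <- function(consensus, threshold,
                                 change_thresholds = seq(0.05, 0.25,
                                                         by = 0.05)) {
  rows <- lapply(change_thresholds, function(ct) {
    cl <- classify_cells(consensus, threshold, ct)
    base <- cl$category %in% c("UH", "LSH", "PH")
    nb <- sum(base)
    data.frame(change_threshold = ct,
               uh_pct = 100 * sum(cl$category == "UH") / max(nb, 1),
               lsh_pct = 100 * sum(cl$category == "LSH") / max(nb, 1),
               ph_pct = 100 * sum(cl$category == "PH") / max(nb, 1),
               n_baseline = nb)
  })
  out <- do.call(rbind, rows)
  if (length(unique(round(out$uh_pct, 10))) > 1)
    stop("internal error: UH share varied with the change threshold")
  out
}

#' Partition projection uncertainty among its sources
#'
#' Relates the future suitability probabilities of a projection cube to the
#' three uncertainty factors — data split (repetition), modelling technique,
#' and climate simulation — through a main-effects analysis of variance over
#' all cube entries, and reports per factor the ratio of its explained sum
#' of squares to the total (null-deviance) sum of squares. The design is
#' balanced (full factorial), so the per-factor sums of squares are
#' order-independent. Residual variation (cell-to-cell spatial variation and
#' all interactions) makes up the remainder.
#'
#' @param cube a `projection_cube` with a future block.
#' @return object of class `uncertainty_partition`: data.frame `ratios`
#'   (factor, ratio), `residual`, and `note` flagging degenerate inputs
#'   (constant probabilities, or a factor with a single level, whose ratio
#'   is reported as 0).
#' @export
partition_uncertainty <- function(cube) {
  stopifnot(inherits(cube, "projection_cube"))
  if (is.null(cube$future)) stop_config("cube has no future projections")
  p <- cube$future                       # cells x models x sims
  grand <- mean(p)
  tss <- sum((p - grand)^2)
  note <- character(0)
  # explained SS of one factor living on the model axis (2) or the
  # simulation axis (3); balanced design, so this is the usual between-group SS
  ss_for <- function(labels, axis) {
    lv <- unique(labels)
    if (length(lv) < 2) return(list(ss = 0, single = TRUE))
    mu <- vapply(lv, function(g) {
      if (axis == 2) mean(p[, labels == g, , drop = FALSE])
      else mean(p[, , labels == g, drop = FALSE])
    }, 0)
    n_per <- length(p) / length(lv)
    list(ss = sum(n_per * (mu - grand)^2), single = FALSE)
  }
  comps <- list(
    repetition = ss_for(cube$repetition, 2),
    technique = ss_for(cube$technique, 2),
    simulation = ss_for(seq_along(cube$sim_ids), 3)
  )
  if (tss == 0) {
    note <- c(note, "probabilities are constant: null deviance is zero, all ratios reported as 0")
    ratios <- setNames(rep(0, 3), names(comps))
  } else {
    ratios <- vapply(comps, function(cc) cc$ss / tss, 0)
  }
  singles <- names(comps)[vapply(comps, `[[`, TRUE, "single")]
  if (length(singles))
    note <- c(note, sprintf("factor(s) with a single level reported as 0: %s",
                            paste(singles, collapse = ", ")))
  structure(list(ratios = data.frame(factor = names(ratios),
                                     ratio = as.numeric(ratios)),
                 residual = max(0, 1 - sum(ratios)),
                 total_ss = tss, note = note),
            class = "uncertainty_partition")
}

#' @export
print.uncertainty_partition <- function(x, ...) {
  cat("Deviance ratios of projection uncertainty factors:\n")
  df <- x$ratios; df$ratio <- round(df$ratio, 4)
  print(df, row.names = FALSE)
  cat(sprintf("residual (cells + interactions): %.4f\n", x$residual))
  for (n in x$note) cat("note:", n, "\n")
  invisible(x)
}
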