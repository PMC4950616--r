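#' Derive the three bioclimatic predictor variables
#'
#' From 12 monthly mean temperatures and 12 monthly precipitation totals,
#' computes annual mean temperature (`TEM`, degC), annual total precipitation
#' (`PRE`, mm), and the warm-season ("useful") precipitation fraction
#' (`PRATIO`): the June--September precipitation sum divided by the annual
#' total. When the annual total is zero `PRATIO` is undefined and returned as
#' `NA` (never a division by zero).
#'
#' @param temps numeric vector of 12 monthly temperatures, or an n x 12
#'   matrix/data.frame (one row per cell).
#' @param precips monthly precipitation in the same shape; all values must be
#'   non-negative.
#' @return data.frame with columns `TEM`, `PRE`, `PRATIO` (one row per cell).
#' @export
#' @examples
#' derive_climate_variables(rep(10, 12), rep(100, 12))  # PRATIO = 1/3
derive_climate_variables <- function(temps, precips) {
  tm <- as.matrix(temps); pm <- as.matrix(precips)
  if (nrow(tm) == 1 || ncol(tm) == 1) tm <- matrix(as.numeric(tm), ncol = 12)
  if (nrow(pm) == 1 || ncol(pm) == 1) pm <- matrix(as.numeric(pm), ncol = 12)
  if (ncol(tm) != 12 || ncol(pm) != 12 || nrow(tm) != nrow(pm))
    stop_config("need 12 monthly temperatures and 12 monthly precipitations per cell")
  if (any(pm < 0, na.rm = TRUE))
    stop_config("monthly precipitation must be non-negative")
  pre <- rowSums(pm)
  summer <- rowSums(pm[, 6:9, drop = FALSE])
  pratio <- ifelse(pre > 0, summer / pre, NA_real_)
  data.frame(TEM = rowMeans(tm), PRE = pre, PRATIO = pratio)
}

#' Assemble the SDM predictor table for a grid
#'
#' Derives `TEM`, `PRE`, `PRATIO` from the monthly climate columns of a grid
#' table (or from a replacement monthly climate table, e.g. a downscaled
#' future climate) and binds elevation and the edaphic fractions. One edaphic
#' fraction can be dropped since the fractions sum to one (they are perfectly
#' collinear for linear models).
#'
#' @param grid a `grid_table`.
#' @param monthly optional data.frame with `cell_id`, `tmp01..tmp12`,
#'   `pre01..pre12` replacing the grid's baseline monthly climate (rows are
#'   matched to the grid by `cell_id`).
#' @param drop_last_edaphic drop the last `ed_*` column (default FALSE).
#' @return data.frame of predictors, one row per grid cell.
#' @export
grid_predictors <- function(grid, monthly = NULL, drop_last_edaphic = FALSE) {
  src <- grid
  if (!is.null(monthly)) {
    m <- monthly[match(grid$cell_id, monthly$cell_id), , drop = FALSE]
    if (anyNA(m$cell_id))
      stop_config("monthly table is missing cells present in the grid")
    src <- m
  }
  cv <- derive_climate_variables(src[, month_cols("tmp")],
                                 src[, month_cols("pre")])
  ed <- grep("^ed_", colnames(grid), value = TRUE)
  if (drop_last_edaphic && length(ed) > 1) ed <- ed[-length(ed)]
  cbind(cv, elevation = grid$elevation,
        grid[, ed, drop = FALSE], row.names = NULL)
}

#' Select representative predictors by correlation clustering
#'
#' Groups candidate variables so that variables within a group are as
#' correlated as possible and variables across groups as uncorrelated as
#' possible, then keeps one representative per group. Implemented as
#' agglomerative (average-linkage) hierarchical clustering on the
#' dissimilarity 1 - |Pearson r|, cut into `n_clusters` groups; within each
#' group the variable with the highest mean absolute correlation to the rest
#' of its own group is retained (a singleton represents itself).
#'
#' @param x numeric matrix or data.frame, cells x candidate variables.
#' @param n_clusters number of groups to form (<= number of variables).
#' @return character vector of selected variable names, one per cluster,
#'   in cluster order.
#' @export
#' @examples
#' set.seed(1)
#' x <- data.frame(a = rnorm(50))
#' x$b <- x$a + rnorm(50, sd = 0.01); x$c <- rnorm(50)
#' cluster_select_predictors(x, 2)
cluster_select_predictors <- function(x, n_clusters) {
  x <- as.data.frame(x)
  if (ncol(x) < n_clusters)
    stop_config("need at least n_clusters = %d candidate variables (got %d)",
                n_clusters, ncol(x))
  sds <- vapply(x, sd, 0)
  if (any(sds == 0 | is.na(sds)))
    stop_config("constant candidate column(s): %s",
                paste(names(x)[sds == 0 | is.na(sds)], collapse = ", "))
  r <- abs(cor(as.matrix(x)))
  if (n_clusters == ncol(x)) return(colnames(x))
  h <- hclust(as.dist(1 - r), method = "average")
  grp <- cutree(h, k = n_clusters)
  vapply(seq_len(n_clusters), function(g) {
    members <- names(grp)[grp == g]
    if (length(members) == 1) return(members)
    own <- r[members, members, drop = FALSE]
    diag(own) <- NA
    members[which.max(rowMeans(own, na.rm = TRUE))]
  }, character(1))
}

#' Downscale a coarse anomaly field onto the analysis grid (change-field)
#'
#' Applies the change-field (delta) method: each monthly anomaly, known at
#' the coarse-grid centroids of one climate simulation, is interpolated to
#' every analysis-cell centroid with linear triangle-based (Delaunay
#' barycentric) interpolation and added to the cell's observed baseline
#' monthly value. Analysis cells outside the convex hull of the coarse
#' centroids receive the anomaly of the nearest coarse centroid. Future
#' monthly precipitation is floored at zero (a message reports how many
#' values were clamped). If the coarse centroids are collinear, the method
#' falls back to nearest-centroid assignment with a warning.
#'
#' @param grid a `grid_table` carrying the baseline monthly climate.
#' @param delta a `delta_field` (see [generate_simulation_ensemble()]).
#' @return data.frame with `cell_id` and future `tmp01..tmp12`,
#'   `pre01..pre12` columns on the analysis grid.
#' @export
delta_downscale <- function(grid, delta) {
  stopifnot(inherits(delta, "delta_field") || is.list(delta))
  cent <- delta$centroids
  if (nrow(cent) < 3)
    stop_config("delta field has %d coarse centroids; need at least 3 for triangulation",
                nrow(cent))
  qx <- grid$lon; qy <- grid$lat
  px <- cent$lon; py <- cent$lat
  near <- NULL   # lazily computed nearest-centroid index
  warned <- FALSE

  interp_one <- function(z) {
    res <- tryCatch(
      interp::interpp(px, py, z, xo = qx, yo = qy)$z,
      error = function(e) e, warning = function(w) w
    )
    if (inherits(res, "condition")) {
      if (!warned) {
        warning("triangulation failed (collinear coarse centroids?); falling back to nearest-centroid deltas",
                call. = FALSE)
        warned <<- TRUE
      }
      if (is.null(near)) near <<- nearest_index(qx, qy, px, py)
      return(z[near])
    }
    if (anyNA(res)) {  # outside the convex hull
      if (is.null(near)) near <<- nearest_index(qx, qy, px, py)
      res[is.na(res)] <- z[near][is.na(res)]
    }
    res
  }

  tmp_f <- matrix(NA_real_, nrow(grid), 12)
  pre_f <- matrix(NA_real_, nrow(grid), 12)
  base_t <- as.matrix(grid[, month_cols("tmp")])
  base_p <- as.matrix(grid[, month_cols("pre")])
  for (m in 1:12) {
    tmp_f[, m] <- base_t[, m] + interp_one(delta$dtemp[, m])
    pre_f[, m] <- base_p[, m] + interp_one(delta$dprec[, m])
  }
  n_clamp <- sum(pre_f < 0)
  if (n_clamp > 0) {
    message(sprintf("delta_downscale: %d negative future monthly precipitation value(s) clamped to 0",
                    n_clamp))
    pre_f[pre_f < 0] <- 0
  }
  colnames(tmp_f) <- month_cols("tmp"); colnames(pre_f) <- month_cols("pre")
  cbind(data.frame(cell_id = grid$cell_id), as.data.frame(tmp_f),
        as.data.frame(pre_f))
}

#' Summarize domain-averaged annual anomalies per climate simulation
#'
#' For each simulation in an ensemble, downscales its anomalies to the
#' analysis grid and reports the domain-averaged change in the three
#' bioclimatic variables: annual mean temperature (`dTEM`, degC), annual
#' precipitation (`dPRE`, mm) and the warm-season precipitation fraction
#' (`dPRATIO`).
#'
#' @param grid a `grid_table`.
#' @param deltas list of `delta_field` objects.
#' @return data.frame: `sim_id`, `emissions`, `dTEM`, `dPRE`, `dPRATIO`.
#' @export
scenario_summary <- function(grid, deltas) {
  base <- derive_climate_variables(grid[, month_cols("tmp")],
                                   grid[, month_cols("pre")])
  rows <- lapply(deltas, function(d) {
    fut <- delta_downscale(grid, d)
    cv <- derive_climate_variables(fut[, month_cols("tmp")],
                                   fut[, month_cols("pre")])
    data.frame(sim_id = d$sim_id,
               emissions = if (is.null(d$emissions)) NA_character_ else d$emissions,
               dTEM = mean(cv$TEM - base$TEM),
               dPRE = mean(cv$PRE - base$PRE),
               dPRATIO = mean(cv$PRATIO - base$PRATIO, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Select a representative subset of climate simulations by k-means
#'
#' Standardizes the per-simulation domain-averaged annual anomalies and runs
#' k-means (many restarts, fixed seed) to partition the ensemble into `k`
#' groups covering the spread of future uncertainty; from each group the
#' simulation nearest its centroid is returned. The selected simulations are
#' treated downstream as equiprobable.
#'
#' @param summaries data.frame from [scenario_summary()] (columns `sim_id`,
#'   `dTEM`, `dPRE`, `dPRATIO`; extra columns ignored).
#' @param k number of simulations to keep (default 7).
#' @param seed RNG seed for k-means restarts.
#' @param nstart number of k-means restarts (default 25).
#' @return character vector of `k` selected `sim_id`s (sorted).
#' @export
select_scenarios <- function(summaries, k = 7, seed = 1, nstart = 25) {
  n <- nrow(summaries)
  if (k > n)
    stop_config("k (%d) exceeds the number of simulations (%d)", k, n)
  feats <- intersect(c("dTEM", "dPRE", "dPRATIO"), colnames(summaries))
  z <- as.matrix(summaries[, feats, drop = FALSE])
  z <- apply(z, 2, function(col) {
    s <- sd(col)
    if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  if (k == n) return(sort(as.character(summaries$sim_id)))
  km <- with_seed(seed, kmeans(z, centers = k, nstart = nstart, iter.max = 100))
  picks <- vapply(seq_len(k), function(g) {
    idx <- which(km$cluster == g)
    d2 <- rowSums((z[idx, , drop = FALSE] -
                     matrix(km$centers[g, ], length(idx), ncol(z),
                            byrow = TRUE))^2)
    idx[which.min(d2)]
  }, integer(1))
  sort(as.character(summaries$sim_id[picks]))
}
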