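#' Generate a synthetic gridded landscape with baseline climate normals
#'
#' Builds a rectangular analysis grid of square cells and simulates, for each
#' cell, monthly baseline (normal-period) climate, elevation, compositional
#' edaphic (surficial deposit / drainage) fractions and a reporting region.
#' The simulated world mimics a northeastern-North-America modelling domain:
#' a strong latitudinal temperature gradient (annual means running from about
#' +20 degC at the southern edge to below -5 degC in the north under the
#' defaults), a weaker precipitation gradient, a summer-weighted precipitation
#' seasonality, and elevation as a smooth random surface capped at 1,250 m.
#'
#' @param n_rows,n_cols grid dimensions (cells); both must be >= 2.
#' @param cell_size_km cell side length in km (default 20, i.e. 400 km^2).
#' @param lat_range,lon_range numeric length-2, decimal degrees spanned by
#'   cell centroids (south to north, west to east).
#' @param temp_gradient change in annual mean temperature per degree of
#'   latitude northwards (degC/deg; negative means colder northwards).
#' @param temp_south annual mean temperature at the southern edge (degC).
#' @param seasonal_amplitude half-range of the monthly temperature cycle
#'   (degC); July is the warmest month.
#' @param precip_annual_south,precip_annual_north approximate annual total
#'   precipitation (mm) at the southern and northern edges.
#' @param monthly_noise_sd standard deviation of independent cell-by-month
#'   noise, applied in degC to temperature and in mm to precipitation.
#' @param edaphic_classes number of compositional edaphic fractions per cell.
#' @param n_regions number of reporting regions ("bioclimatic domains"),
#'   realized as equal-width latitude bands, labelled `R1` (southernmost)
#'   to `R<n>`.
#' @param seed integer RNG seed; the same seed reproduces the landscape
#'   bit-for-bit.
#'
#' @return A `data.frame` (class `grid_table`) with one row per cell:
#'   `cell_id`, `row`, `col`, `lat`, `lon`, `region`, `elevation`,
#'   monthly mean temperatures `tmp01..tmp12` (degC), monthly precipitation
#'   `pre01..pre12` (mm), and edaphic fractions `ed_1..ed_K` summing to 1.
#'   Grid geometry is attached as attributes (`cell_size_km`, `n_rows`,
#'   `n_cols`).
#' @seealso [generate_occurrence()], [generate_simulation_ensemble()],
#'   [derive_climate_variables()]
#' @export
#' @examples
#' g <- generate_landscape(n_rows = 6, n_cols = 5, seed = 1)
#' head(g[, c("cell_id", "lat", "lon", "elevation", "region")])
generate_landscape <- function(n_rows = 50, n_cols = 40, cell_size_km = 20,
                               lat_range = c(30, 53), lon_range = c(-93, -60),
                               temp_gradient = -1.1, temp_south = 20,
                               seasonal_amplitude = 16,
                               precip_annual_south = 1100,
                               precip_annual_north = 850,
                               monthly_noise_sd = 1,
                               edaphic_classes = 10, n_regions = 5,
                               seed = 1) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 2 || n_cols < 2)
    stop_config("grid dimensions must be at least 2 x 2 (got %s x %s)",
                n_rows, n_cols)
  check_number(cell_size_km, "cell_size_km", lower = 1e-6)
  check_number(monthly_noise_sd, "monthly_noise_sd", lower = 0)
  check_number(edaphic_classes, "edaphic_classes", lower = 1)
  check_number(n_regions, "n_regions", lower = 1)
  stopifnot(length(lat_range) == 2, length(lon_range) == 2)

  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n <- n_rows * n_cols
  row_i <- rep(seq_len(n_rows), each = n_cols)   # row 1 = south
  col_i <- rep(seq_len(n_cols), times = n_rows)
  lat <- lat_range[1] + (row_i - 1) / (n_rows - 1) * diff(lat_range)
  lon <- lon_range[1] + (col_i - 1) / (n_cols - 1) * diff(lon_range)
  latz <- (lat - lat_range[1]) / max(diff(lat_range), 1e-12)  # 0 south, 1 north
  lonz <- (lon - lon_range[1]) / max(diff(lon_range), 1e-12)

  with_seed(seed, {
    # Elevation: smooth low-frequency random surface + northward trend,
    # shifted non-negative and capped at 1,250 m.
    ph <- runif(6, 0, 2 * pi)
    surf <- 250 * cos(2 * pi * latz * 1.3 + ph[1]) * cos(2 * pi * lonz + ph[2]) +
      150 * sin(2 * pi * latz * 2.1 + ph[3]) +
      100 * sin(2 * pi * lonz * 1.7 + ph[4])
    elevation <- surf + 200 * latz + 300
    elevation <- pmin(pmax(elevation, 0), 1250)

    # Monthly mean temperature: latitudinal gradient + seasonal cycle +
    # elevational lapse (-6.5 degC/km) + iid noise.
    ann_t <- temp_south + temp_gradient * (lat - lat_range[1]) -
      6.5 * elevation / 1000
    mth <- 1:12
    season <- seasonal_amplitude * cos(2 * pi * (mth - 7) / 12)
    tmp <- outer(ann_t, season, "+")
    if (monthly_noise_sd > 0)
      tmp <- tmp + matrix(rnorm(n * 12, 0, monthly_noise_sd), n, 12)

    # Monthly precipitation: weak latitudinal gradient in the annual total,
    # summer-weighted seasonality (higher PRATIO in warm months), iid noise,
    # floored at zero.
    ann_p <- precip_annual_south +
      (precip_annual_north - precip_annual_south) * latz +
      30 * sin(2 * pi * lonz)                     # mild longitudinal texture
    wgt <- 1 + 0.45 * cos(2 * pi * (mth - 7.5) / 12)  # mean 1 over months
    wgt <- wgt / sum(wgt)
    pre <- outer(ann_p, wgt, "*")
    if (monthly_noise_sd > 0)
      pre <- pre + matrix(rnorm(n * 12, 0, monthly_noise_sd), n, 12)
    pre <- pmax(pre, 0)

    # Compositional edaphic fractions: normalized gammas whose concentrations
    # drift smoothly with latitude, so classes have spatial structure.
    K <- as.integer(edaphic_classes)
    a_base <- runif(K, 0.5, 2); a_lat <- rnorm(K, 0, 1.2)
    alpha <- exp(outer(latz, a_lat) + rep(log(a_base), each = n))
    gam <- matrix(rgamma(n * K, shape = alpha, rate = 1), n, K)
    # guard against an all-zero draw (possible for tiny shapes)
    zero <- rowSums(gam) == 0
    if (any(zero)) gam[zero, ] <- 1
    ed <- gam / rowSums(gam)

    region_band <- pmin(floor(latz * n_regions) + 1L, as.integer(n_regions))
    out <- data.frame(
      cell_id = seq_len(n), row = row_i, col = col_i, lat = lat, lon = lon,
      region = paste0("R", region_band), elevation = elevation
    )
    colnames(tmp) <- month_cols("tmp"); colnames(pre) <- month_cols("pre")
    colnames(ed) <- paste0("ed_", seq_len(K))
    out <- cbind(out, as.data.frame(tmp), as.data.frame(pre),
                 as.data.frame(ed))
    attr(out, "cell_size_km") <- cell_size_km
    attr(out, "n_rows") <- n_rows
    attr(out, "n_cols") <- n_cols
    class(out) <- c("grid_table", "data.frame")
    out
  })
}

#' Define a virtual species' true suitability response
#'
#' Specifies the logistic ("true") habitat suitability surface of a virtual
#' species as coefficients on standardized bioclimatic predictors: linear and
#' quadratic terms in annual mean temperature (`TEM`), annual precipitation
#' (`PRE`), warm-season precipitation fraction (`PRATIO`) and elevation, plus
#' linear terms on the edaphic fractions. Predictors are standardized
#' (centered/scaled) against the landscape at occurrence-generation time, and
#' the standardization is frozen into the calibrated response so the same
#' surface can be evaluated under future climate.
#'
#' @param intercept logit-scale intercept.
#' @param linear named numeric vector of linear coefficients; names among
#'   `TEM`, `PRE`, `PRATIO`, `elevation`.
#' @param quadratic named numeric vector of quadratic coefficients on the same
#'   standardized predictors.
#' @param edaphic numeric vector of linear coefficients on the edaphic
#'   fractions (recycled/zero-padded to the landscape's class count), or NULL.
#' @param prevalence_target optional fraction in (0,1); when set,
#'   [generate_occurrence()] shifts the intercept so the mean true probability
#'   over the landscape equals this value.
#' @return An object of class `species_response`.
#' @export
#' @examples
#' sp <- species_response(linear = c(TEM = 2), quadratic = c(TEM = -1),
#'                        prevalence_target = 0.35)
species_response <- function(intercept = 0,
                             linear = c(TEM = 0, PRE = 0, PRATIO = 0,
                                        elevation = 0),
                             quadratic = NULL, edaphic = NULL,
                             prevalence_target = NULL) {
  allowed <- c("TEM", "PRE", "PRATIO", "elevation")
  chk <- function(v, what) {
    if (is.null(v)) return(numeric(0))
    if (is.null(names(v)) || !all(names(v) %in% allowed))
      stop_config("%s coefficients must be named among: %s", what,
                  paste(allowed, collapse = ", "))
    v
  }
  if (!is.null(prevalence_target))
    check_number(prevalence_target, "prevalence_target",
                 lower = 1e-9, upper = 1 - 1e-9)
  structure(list(intercept = intercept, linear = chk(linear, "linear"),
                 quadratic = chk(quadratic, "quadratic"),
                 edaphic = edaphic, prevalence_target = prevalence_target,
                 scaling = NULL),
            class = "species_response")
}

# Evaluate the logit of a (possibly calibrated) response on a predictor table
# containing TEM, PRE, PRATIO, elevation and ed_* columns.
response_logit <- function(response, predictors) {
  sc <- response$scaling
  if (is.null(sc))
    stop_config("response has no stored predictor scaling; call generate_occurrence() first or supply a calibrated response")
  need <- unique(c(names(response$linear), names(response$quadratic)))
  miss <- setdiff(need, colnames(predictors))
  if (length(miss))
    stop_config("predictors missing from the table: %s",
                paste(miss, collapse = ", "))
  eta <- rep(response$intercept, nrow(predictors))
  for (v in names(response$linear)) {
    z <- (predictors[[v]] - sc$center[v]) / sc$scale[v]
    eta <- eta + response$linear[v] * z
  }
  for (v in names(response$quadratic)) {
    z <- (predictors[[v]] - sc$center[v]) / sc$scale[v]
    eta <- eta + response$quadratic[v] * z^2
  }
  if (!is.null(response$edaphic)) {
    edc <- grep("^ed_", colnames(predictors), value = TRUE)
    if (length(edc)) {
      b <- rep_len(response$edaphic, length(edc))
      eta <- eta + as.matrix(predictors[, edc, drop = FALSE]) %*% b
    }
  }
  as.numeric(eta)
}

#' Evaluate a calibrated species response as a suitability probability
#'
#' Applies the frozen standardization and logistic response of a calibrated
#' `species_response` (as returned inside [generate_occurrence()]) to any
#' predictor table — in particular to future-climate predictors — yielding
#' the species' true probability of suitability there.
#'
#' @param response a calibrated `species_response` (with stored scaling).
#' @param predictors data.frame with columns `TEM`, `PRE`, `PRATIO`,
#'   `elevation` and (optionally) `ed_*` fractions.
#' @return numeric vector of true suitability probabilities in \[0,1\].
#' @export
response_probability <- function(response, predictors) {
  plogis(response_logit(response, predictors))
}

#' Simulate species occurrence from a known suitability surface
#'
#' Computes the species' true probability of suitability on the landscape and
#' draws per-cell presence/absence as independent Bernoulli trials. Both the
#' realized 0/1 occurrence and the true probabilities are returned so that
#' downstream recovery can be measured against ground truth. If the response
#' carries a `prevalence_target`, the intercept is shifted (monotone root
#' finding) so the mean true probability matches the target exactly.
#'
#' @param grid a `grid_table` from [generate_landscape()].
#' @param response a [species_response()].
#' @param seed integer RNG seed for the Bernoulli draws.
#' @return list with `occurrence` (integer 0/1 per cell), `prob` (true
#'   probability per cell), and `response` (the calibrated response with the
#'   standardization and any intercept shift frozen in).
#' @export
#' @examples
#' g <- generate_landscape(n_rows = 10, n_cols = 8, seed = 1)
#' sp <- species_response(linear = c(TEM = 3), prevalence_target = 0.4)
#' occ <- generate_occurrence(g, sp, seed = 2)
#' mean(occ$occurrence)
generate_occurrence <- function(grid, response, seed = 1) {
  stopifnot(inherits(response, "species_response"))
  pred <- grid_predictors(grid)
  cont <- c("TEM", "PRE", "PRATIO", "elevation")
  sc <- list(center = vapply(pred[cont], mean, 0),
             scale = vapply(pred[cont], function(x) max(sd(x), 1e-12), 0))
  response$scaling <- sc
  eta <- response_logit(response, pred)
  if (!is.null(response$prevalence_target)) {
    tgt <- response$prevalence_target
    f <- function(c0) mean(plogis(eta + c0)) - tgt
    sh <- uniroot(f, lower = -60, upper = 60, tol = 1e-10)$root
    response$intercept <- response$intercept + sh
    eta <- eta + sh
  }
  p <- plogis(eta)
  occ <- with_seed(seed, rbinom(length(p), 1L, p))
  list(occurrence = as.integer(occ), prob = p, response = response)
}

#' Generate an ensemble of synthetic climate-simulation anomaly fields
#'
#' Emulates a multi-model ensemble of climate simulations as per-simulation
#' monthly anomaly ("delta") fields on a coarse grid overlaying the analysis
#' landscape. Each simulation carries a domain-mean annual warming and a
#' relative precipitation change; across the ensemble these annual anomalies
#' span exactly the configured ranges. Temperature deltas are additive degC
#' with a winter-amplified seasonal profile; precipitation deltas are
#' converted to additive mm per month against the landscape's domain-mean
#' monthly normals (one additive code path downstream). Deltas vary in space
#' only at the coarse-grid scale, through a smooth zero-mean surface whose
#' relative amplitude is `spatial_sd_frac`.
#'
#' @param grid a `grid_table` from [generate_landscape()].
#' @param n_simulations ensemble size (default 70).
#' @param warming_range length-2 numeric, min/max domain annual warming degC
#'   (default `c(1.9, 8)`).
#' @param precip_change_range length-2 numeric, min/max relative annual
#'   precipitation change (default `c(0.03, 0.26)`, i.e. +3% to +26%).
#' @param coarse_cell_km coarse-grid cell side (default 250); must exceed the
#'   analysis-grid cell size.
#' @param spatial_sd_frac relative amplitude of the smooth spatial variation
#'   of the deltas (0 gives spatially constant fields).
#' @param seed integer RNG seed.
#' @return list of `delta_field` objects, each with `sim_id`, `emissions`
#'   label, `centroids` (coarse_id, lat, lon) and 12-column matrices `dtemp`
#'   (degC) and `dprec` (mm).
#' @export
generate_simulation_ensemble <- function(grid, n_simulations = 70,
                                         warming_range = c(1.9, 8),
                                         precip_change_range = c(0.03, 0.26),
                                         coarse_cell_km = 250,
                                         spatial_sd_frac = 0.1,
                                         seed = 1) {
  stopifnot(inherits(grid, "data.frame"))
  check_number(n_simulations, "n_simulations", lower = 1)
  if (warming_range[1] > warming_range[2])
    stop_config("warming_range must be increasing")
  if (precip_change_range[1] > precip_change_range[2])
    stop_config("precip_change_range must be increasing")
  cell_km <- attr(grid, "cell_size_km")
  if (!is.null(cell_km) && coarse_cell_km <= cell_km)
    stop_config("coarse_cell_km (%s) must exceed the analysis cell size (%s)",
                coarse_cell_km, cell_km)
  n_sim <- as.integer(n_simulations)

  # Coarse lattice covering the landscape extent plus a half-cell margin so
  # analysis centroids sit inside the convex hull.
  lat_r <- range(grid$lat); lon_r <- range(grid$lon)
  # approximate degree extent of one coarse cell (1 deg lat ~ 111 km)
  dlat <- coarse_cell_km / 111
  mid_lat <- mean(lat_r)
  dlon <- coarse_cell_km / (111 * max(cos(mid_lat * pi / 180), 0.2))
  lat_c <- seq(lat_r[1] - dlat / 2, lat_r[2] + dlat / 2,
               length.out = max(2L, ceiling(diff(lat_r) / dlat) + 1L))
  lon_c <- seq(lon_r[1] - dlon / 2, lon_r[2] + dlon / 2,
               length.out = max(2L, ceiling(diff(lon_r) / dlon) + 1L))
  cent <- expand.grid(lon = lon_c, lat = lat_c, KEEP.OUT.ATTRS = FALSE)
  cent <- data.frame(coarse_id = seq_len(nrow(cent)),
                     lat = cent$lat, lon = cent$lon)
  nc <- nrow(cent)

  # Domain-mean baseline monthly precipitation, for relative -> additive mm.
  pbar <- colMeans(as.matrix(grid[, month_cols("pre")]))

  # Per-simulation domain anomalies: evenly spread over the configured range
  # (so the ensemble spans it exactly), independently permuted.
  spread <- function(rg, n) {
    if (n == 1) return(mean(rg))
    seq(rg[1], rg[2], length.out = n)
  }
  mth <- 1:12
  t_season <- 1 + 0.35 * cos(2 * pi * (mth - 1) / 12)  # winter-amplified, mean 1
  t_season <- t_season / mean(t_season)
  emis <- rep(c("B1", "A1B", "A2"), length.out = n_sim)

  with_seed(seed, {
    dT <- spread(warming_range, n_sim)[sample.int(n_sim)]
    dPrel <- spread(precip_change_range, n_sim)[sample.int(n_sim)]
    latz <- (cent$lat - lat_r[1]) / max(diff(lat_r), 1e-12)
    lonz <- (cent$lon - lon_r[1]) / max(diff(lon_r), 1e-12)
    lapply(seq_len(n_sim), function(s) {
      # smooth zero-mean spatial pattern, fixed per simulation
      ph <- runif(2, 0, 2 * pi)
      pat <- cos(pi * latz + ph[1]) + 0.6 * sin(pi * lonz + ph[2])
      pat <- pat - mean(pat)
      dtemp <- outer(rep(1, nc), dT[s] * t_season) +
        spatial_sd_frac * dT[s] * outer(pat, rep(1, 12))
      dprec <- outer(rep(1, nc), dPrel[s] * pbar) +
        spatial_sd_frac * dPrel[s] * outer(pat, pbar)
      colnames(dtemp) <- month_cols("dtmp")
      colnames(dprec) <- month_cols("dpre")
      structure(list(sim_id = sprintf("sim%02d", s), emissions = emis[s],
                     centroids = cent, dtemp = dtemp, dprec = dprec),
                class = "delta_field")
    })
  })
}

#' @export
print.delta_field <- function(x, ...) {
  cat(sprintf("<delta_field %s (%s): %d coarse centroids, annual dT = %.2f degC, annual dP = %.0f mm>\n",
              x$sim_id, x$emissions, nrow(x$centroids),
              mean(rowMeans(x$dtemp)), mean(rowSums(x$dprec))))
  invisible(x)
}
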