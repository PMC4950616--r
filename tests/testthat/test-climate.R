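# Bioclimatic variable derivation, predictor clustering, change-field
# downscaling and scenario selection.

test_that("bioclimatic variables follow their defining arithmetic", {
  cv <- derive_climate_variables(rep(10, 12), rep(100, 12))
  expect_equal(cv$TEM, 10)
  expect_equal(cv$PRE, 1200)
  expect_equal(cv$PRATIO, 400 / 1200)

  pre <- rep(50, 12); pre[6:9] <- 0
  expect_equal(derive_climate_variables(rep(0, 12), pre)$PRATIO, 0)

  expect_true(is.na(derive_climate_variables(rep(0, 12), rep(0, 12))$PRATIO))
  expect_error(derive_climate_variables(rep(0, 12), rep(-1, 12)),
               "non-negative")
})

test_that("PRATIO depends on non-summer months only through their sum", {
  set.seed(1)
  pre <- runif(12, 10, 120)
  base <- derive_climate_variables(rep(5, 12), pre)
  perm <- pre
  perm[c(1:5, 10:12)] <- pre[c(10:12, 1:5)]  # permute non-summer months
  expect_equal(derive_climate_variables(rep(5, 12), perm)$PRATIO,
               base$PRATIO)
})

test_that("correlation clustering selects one representative per group", {
  set.seed(7)
  x <- data.frame(a = rnorm(80), c = rnorm(80))
  x$b <- x$a + rnorm(80, sd = 0.01)
  sel2 <- cluster_select_predictors(x[, c("a", "b", "c")], 2)
  expect_length(sel2, 2)
  expect_true("c" %in% sel2)
  expect_length(intersect(sel2, c("a", "b")), 1)

  # three near-independent variables, three clusters: all retained
  y <- data.frame(a = rnorm(100), b = rnorm(100), d = rnorm(100))
  expect_setequal(cluster_select_predictors(y, 3), c("a", "b", "d"))
  # identity when every variable is its own cluster
  expect_identical(cluster_select_predictors(x, 3), colnames(x))
  expect_error(cluster_select_predictors(cbind(x, k = 1), 2), "constant")
  expect_error(cluster_select_predictors(x, 5), "at least")
})

test_that("downscaling reproduces constant anomaly fields exactly", {
  g <- tiny_grid()
  d <- generate_simulation_ensemble(g, n_simulations = 1,
                                    warming_range = c(3, 3),
                                    precip_change_range = c(0, 0),
                                    spatial_sd_frac = 0, seed = 1)[[1]]
  d$dtemp[] <- 3; d$dprec[] <- 0
  fut <- delta_downscale(g, d)
  for (m in sprintf("tmp%02d", 1:12))
    expect_equal(fut[[m]], g[[m]] + 3, tolerance = 1e-12)
  for (m in sprintf("pre%02d", 1:12))
    expect_equal(fut[[m]], g[[m]], tolerance = 1e-12)
})

test_that("downscaling reproduces linear anomaly fields to machine precision", {
  g <- tiny_grid()
  d <- generate_simulation_ensemble(g, n_simulations = 1, seed = 2)[[1]]
  lin <- function(lat, lon) 0.8 * lat - 0.3 * lon + 1
  for (m in 1:12) {
    d$dtemp[, m] <- lin(d$centroids$lat, d$centroids$lon)
    d$dprec[, m] <- 0
  }
  fut <- delta_downscale(g, d)
  got <- fut$tmp01 - g$tmp01
  expect_equal(got, lin(g$lat, g$lon), tolerance = 1e-9)
})

test_that("a cell coincident with a coarse centroid receives that centroid's delta", {
  g <- tiny_grid()
  cent <- data.frame(coarse_id = 1:4,
                     lat = c(g$lat[5], min(g$lat) - 1, max(g$lat) + 1,
                             min(g$lat) - 1),
                     lon = c(g$lon[5], min(g$lon) - 1, min(g$lon) - 1,
                             max(g$lon) + 1))
  d <- structure(list(sim_id = "s", emissions = "A2", centroids = cent,
                      dtemp = matrix(c(5, 1, 2, 3), 4, 12),
                      dprec = matrix(0, 4, 12)),
                 class = "delta_field")
  fut <- delta_downscale(g, d)
  expect_equal(fut$tmp01[5] - g$tmp01[5], 5, tolerance = 1e-9)
})

test_that("degenerate coarse geometries are handled as specified", {
  g <- tiny_grid()
  cent2 <- data.frame(coarse_id = 1:2, lat = c(30, 40), lon = c(-80, -70))
  d2 <- structure(list(sim_id = "s", emissions = "A2", centroids = cent2,
                       dtemp = matrix(1, 2, 12), dprec = matrix(0, 2, 12)),
                  class = "delta_field")
  expect_error(delta_downscale(g, d2), "at least 3")

  cent3 <- data.frame(coarse_id = 1:3, lat = c(30, 40, 50),
                      lon = c(-75, -75, -75))  # collinear
  d3 <- structure(list(sim_id = "s", emissions = "A2", centroids = cent3,
                       dtemp = matrix(rep(c(1, 2, 3), 12), 3, 12),
                       dprec = matrix(0, 3, 12)),
                  class = "delta_field")
  expect_warning(fut <- delta_downscale(g, d3), "nearest")
  # nearest-centroid fallback still adds a valid delta everywhere
  got <- fut$tmp01 - g$tmp01
  dist_to_deltas <- vapply(got, function(v) min(abs(v - c(1, 2, 3))), 0)
  expect_lt(max(dist_to_deltas), 1e-9)
})

test_that("scenario selection covers the anomaly space as specified", {
  g <- tiny_grid()
  ens <- generate_simulation_ensemble(g, n_simulations = 10, seed = 3)
  summ <- scenario_summary(g, ens)
  expect_equal(nrow(summ), 10)

  # k = n returns everything
  expect_setequal(select_scenarios(summ, k = 10), summ$sim_id)
  expect_error(select_scenarios(summ, k = 11), "exceeds")

  # k = 1: brute-force nearest simulation to the standardized grand centroid
  z <- scale(as.matrix(summ[, c("dTEM", "dPRE", "dPRATIO")]))
  d2 <- rowSums(scale(z, center = colMeans(z), scale = FALSE)^2)
  expect_identical(select_scenarios(summ, k = 1, seed = 1),
                   as.character(summ$sim_id[which.min(d2)]))
})

test_that("two well-separated anomaly blobs each contribute a representative", {
  blob <- data.frame(
    sim_id = sprintf("s%02d", 1:10),
    dTEM = c(rnorm(5, 2, 0.05), rnorm(5, 7, 0.05)),
    dPRE = c(rnorm(5, 10, 0.5), rnorm(5, 80, 0.5)),
    dPRATIO = c(rnorm(5, -0.01, 0.001), rnorm(5, 0.03, 0.001))
  )
  picks <- select_scenarios(blob, k = 2, seed = 4)
  expect_length(intersect(picks, blob$sim_id[1:5]), 1)
  expect_length(intersect(picks, blob$sim_id[6:10]), 1)

  # duplicating a non-selected simulation does not change the choice
  extra <- blob$sim_id[!blob$sim_id %in% picks][1]
  dup <- rbind(blob, transform(blob[blob$sim_id == extra, ],
                               sim_id = "s99"))
  picks_dup <- select_scenarios(dup, k = 2, seed = 4)
  expect_setequal(picks_dup, picks)
})
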