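# Split-sample machinery, ensemble fitting, projection and the AUC-weighted
# consensus.

test_that("split sizes use round-half-up of the calibration fraction", {
  s <- split_sample(6418, 0.7, n_repetitions = 3, seed = 1)
  for (k in 1:3) {
    expect_length(s[[k]]$calibration, 4493)
    expect_length(s[[k]]$evaluation, 1925)
  }
})

test_that("splits are disjoint, exhaustive and reproducible", {
  s <- split_sample(10, 0.5, n_repetitions = 2, seed = 9)
  expect_length(s[[1]]$calibration, 5)
  expect_length(s[[1]]$evaluation, 5)
  expect_setequal(c(s[[1]]$calibration, s[[1]]$evaluation), 1:10)
  expect_length(intersect(s[[1]]$calibration, s[[1]]$evaluation), 0)
  expect_identical(s, split_sample(10, 0.5, n_repetitions = 2, seed = 9))
  expect_error(split_sample(5, 0.7), "at least 10")
  expect_error(split_sample(100, 1.2), "calibration_fraction")
})

test_that("the ensemble fits techniques x repetitions models with held-out scores", {
  set.seed(2)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$occ <- rbinom(n, 1, plogis(2 * d$x1 - d$x2))
  e <- fit_sdm_ensemble(occ ~ x1 + x2, d, techniques = c("GLM", "CTA"),
                        n_repetitions = 3, seed = 5)
  expect_s3_class(e, "sdm_ensemble")
  expect_length(e$models, 6)
  expect_equal(nrow(e$performance), 6)
  expect_true(all(e$performance$auc >= 0 & e$performance$auc <= 1))
  expect_setequal(unique(e$performance$technique), c("GLM", "CTA"))

  pm <- predict(e, d, type = "matrix")
  expect_equal(dim(pm), c(n, 6))
  expect_true(all(pm >= 0 & pm <= 1))
  wap <- predict(e, d)
  expect_true(all(wap >= 0 & wap <= 1))

  s <- summary(e)
  expect_equal(s$n_models, 6)
  expect_output(print(e), "6 models")
})

test_that("a strongly separable species is recovered with excellent AUC", {
  set.seed(3)
  n <- 1000
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$occ <- rbinom(n, 1, plogis(6 * d$x1))
  e <- fit_sdm_ensemble(occ ~ x1 + x2, d, techniques = "GLM",
                        n_repetitions = 2, seed = 1)
  expect_true(all(e$performance$auc >= 0.95))
})

test_that("permuted labels give chance-level held-out AUC", {
  set.seed(4)
  n <- 500
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$occ <- sample(rbinom(n, 1, 0.5))   # independent of the predictors
  e <- fit_sdm_ensemble(occ ~ x1 + x2, d, techniques = "GLM",
                        n_repetitions = 10, seed = 2)
  expect_gte(mean(e$performance$auc), 0.45)
  expect_lte(mean(e$performance$auc), 0.55)
})

test_that("schema violations are rejected with the missing predictors named", {
  set.seed(5)
  d <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
  d$occ <- rbinom(50, 1, plogis(d$x1))
  e <- fit_sdm_ensemble(occ ~ x1 + x2, d, techniques = "CTA",
                        n_repetitions = 1, seed = 1)
  expect_error(predict(e, d[, "x1", drop = FALSE]), "x2")
  expect_error(fit_sdm_ensemble(occ ~ x1, transform(d, occ = 0),
                                techniques = "CTA", n_repetitions = 1),
               "single class|0/1")
})

test_that("projecting onto the calibration climate reproduces baseline probabilities", {
  set.seed(6)
  d <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
  d$occ <- rbinom(80, 1, plogis(2 * d$x1))
  e <- fit_sdm_ensemble(occ ~ x1 + x2, d, techniques = c("GLM", "RF"),
                        n_repetitions = 2, seed = 3)
  cube <- project_cube(e, d, future = list(s1 = d, s2 = d))
  expect_equal(dim(cube$future), c(80, 4, 2))
  expect_identical(cube$future[, , 1], cube$baseline)
  expect_identical(cube$future[, , 2], cube$baseline)
  expect_true(all(cube$baseline >= 0 & cube$baseline <= 1))
})

test_that("weighted consensus follows the defining arithmetic", {
  # two models, weights (0.9, 0.6), probabilities (1, 0): WAP = 0.9/1.5
  cube <- make_cube(matrix(c(1, 0), 1, 2), auc = c(0.9, 0.6))
  expect_equal(weighted_average(cube)$wap_baseline, 0.6)

  # equal weights reduce to the arithmetic mean
  set.seed(7)
  b <- matrix(runif(12), 3, 4)
  expect_equal(weighted_average(make_cube(b, auc = rep(0.8, 4)))$wap_baseline,
               rowMeans(b))

  # the future consensus equals the mean over simulations of per-simulation
  # weighted averages
  f <- array(runif(24), c(3, 4, 2))
  w <- runif(4, 0.5, 1)
  cc <- make_cube(b, f, auc = w)
  per_sim <- sapply(1:2, function(l) as.numeric(f[, , l] %*% w / sum(w)))
  expect_equal(weighted_average(cc)$wap_2080, rowMeans(per_sim),
               tolerance = 1e-12)

  expect_error(weighted_average(make_cube(b, auc = c(1, 1, 0, 1))),
               "positive")
})

test_that("consensus is bounded by and monotone in its inputs", {
  set.seed(8)
  for (i in 1:10) {
    b <- matrix(runif(20), 5, 4)
    w <- runif(4, 0.5, 1)
    wap <- weighted_average(make_cube(b, auc = w))$wap_baseline
    expect_true(all(wap >= apply(b, 1, min) - 1e-12))
    expect_true(all(wap <= apply(b, 1, max) + 1e-12))
    b2 <- b
    b2[2, 3] <- min(1, b2[2, 3] + 0.1)
    wap2 <- weighted_average(make_cube(b2, auc = w))$wap_baseline
    expect_gte(wap2[2], wap[2])
    expect_equal(wap2[-2], wap[-2])
  }
})
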