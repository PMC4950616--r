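# Threshold selection, UH/LSH/PH classification, agreement, regional
# aggregation, overlay, sensitivity sweep and uncertainty partition.

test_that("threshold selection maximizes sensitivity + specificity", {
  t1 <- select_threshold(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.1))
  expect_equal(t1$threshold, 0.8)
  expect_equal(t1$sensitivity, 1)
  expect_equal(t1$specificity, 1)

  # perfectly separated classes always reach sens = spec = 1
  t2 <- select_threshold(c(0, 0, 1, 1, 1), c(0.1, 0.2, 0.6, 0.7, 0.9))
  expect_equal(t2$sensitivity + t2$specificity, 2)

  # degenerate: all probabilities equal
  t3 <- select_threshold(c(1, 0, 1), c(0.4, 0.4, 0.4))
  expect_true(t3$degenerate)
  expect_equal(t3$threshold, 0.4)
  expect_equal(t3$sensitivity + t3$specificity, 1)

  expect_error(select_threshold(c(1, 1), c(0.2, 0.4)), "presences and absences")
})

test_that("threshold selection equals an exhaustive scan on random data", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    obs <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(obs)) < 2) obs[1:2] <- c(0, 1)
    prob <- round(plogis(obs * runif(1, 0, 3) + rnorm(n)), 2)
    expect_identical(select_threshold(obs, prob)$threshold,
                     threshold_oracle(obs, prob))
  }
})

test_that("classification rules follow the UH/LSH/PH definitions", {
  cm <- structure(data.frame(cell_id = 1:5,
                             wap_baseline = c(0.7, 0.9, 0.7, 0.6, 0.3),
                             wap_2080 = c(0.3, 0.7, 0.6, 0.6, 0.6)),
                  class = c("consensus_map", "data.frame"))
  cl <- classify_cells(cm, threshold = 0.5)
  expect_equal(as.character(cl$category),
               c("UH", "LSH", "PH", "PH", "GAINED"))
  # |delta| = 0.15 exactly is LSH (the rule uses >=)
  cm2 <- structure(data.frame(cell_id = 1, wap_baseline = 0.8,
                              wap_2080 = 0.65),
                   class = c("consensus_map", "data.frame"))
  expect_equal(as.character(classify_cells(cm2, 0.5)$category), "LSH")
  expect_error(classify_cells(cm, threshold = 1.2), "within")
})

test_that("classification matches an independent transcription on random pairs", {
  set.seed(12)
  n <- 10000
  cm <- structure(data.frame(cell_id = seq_len(n),
                             wap_baseline = runif(n), wap_2080 = runif(n)),
                  class = c("consensus_map", "data.frame"))
  thr <- 0.42; ct <- 0.15
  cl <- classify_cells(cm, thr, ct)
  oracle <- vapply(seq_len(n), function(i)
    classify_oracle_one(cm$wap_baseline[i], cm$wap_2080[i], thr, ct), "")
  expect_identical(as.character(cl$category), oracle)
  # UH, LSH, PH partition the baseline range exactly
  in_range <- cm$wap_baseline >= thr
  expect_equal(sum(cl$category %in% c("UH", "LSH", "PH")), sum(in_range))
})

test_that("raising the suitability threshold never grows the baseline range", {
  set.seed(13)
  cm <- structure(data.frame(cell_id = 1:2000, wap_baseline = runif(2000),
                             wap_2080 = runif(2000)),
                  class = c("consensus_map", "data.frame"))
  sizes <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    sum(classify_cells(cm, th)$category %in% c("UH", "LSH", "PH")), 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("agreement counts single projections matching the consensus category", {
  # one cell, one model, three simulations: categories UH, UH, PH vs UH
  base <- matrix(0.8, 1, 1)
  fut <- array(c(0.3, 0.4, 0.75), c(1, 1, 3))
  cube <- make_cube(base, fut, auc = 0.9)
  cm <- weighted_average(cube)
  # consensus future = mean(0.3, 0.4, 0.75) < 0.5 -> UH
  cl <- classify_cells(cm, 0.5)
  expect_equal(as.character(cl$category), "UH")
  ag <- agreement_value(cube, cl)
  expect_equal(ag, 100 * 2 / 3, tolerance = 1e-12)

  # all single projections identical to the consensus inputs -> 100%
  b2 <- matrix(0.9, 4, 2)
  f2 <- array(0.8, c(4, 2, 2))
  cube2 <- make_cube(b2, f2)
  cl2 <- classify_cells(weighted_average(cube2), 0.5)
  expect_equal(agreement_value(cube2, cl2), rep(100, 4))

  # agreement is only defined inside the baseline range
  b3 <- matrix(c(0.2, 0.8), 2, 1)
  f3 <- array(c(0.2, 0.8), c(2, 1, 1))
  cube3 <- make_cube(b3, f3)
  cl3 <- classify_cells(weighted_average(cube3), 0.5)
  ag3 <- agreement_value(cube3, cl3)
  expect_true(is.na(ag3[1]))
  expect_equal(ag3[2], 100)
})

test_that("regional summaries report areas, baseline shares and agreement", {
  cats <- c(rep("UH", 2), rep("LSH", 3), rep("PH", 5), rep("UH", 10),
            "OUTSIDE_BASELINE")
  n <- length(cats)
  cl <- structure(data.frame(cell_id = seq_len(n), wap_baseline = 0.9,
                             wap_2080 = 0.1, delta_wap = -0.8,
                             category = factor(cats,
                               levels = c("UH", "LSH", "PH", "GAINED",
                                          "OUTSIDE_BASELINE"))),
                  class = c("cell_classification", "data.frame"))
  regions <- c(rep("A", 10), rep("B", 10), "B")
  ag <- c(rep(80, 10), rep(60, 10), NA)
  s <- summarize_by_region(cl, regions, cell_area_km2 = 400, agreement = ag)

  a <- s[s$region == "A", ]
  expect_equal(a$uh_pct, 20); expect_equal(a$lsh_pct, 30)
  expect_equal(a$ph_pct, 50)
  expect_equal(a$uh_pct + a$lsh_pct + a$ph_pct, 100, tolerance = 0.1)
  expect_equal(a$uh_area_km2, 800)
  expect_equal(a$uh_agreement, 80)

  b <- s[s$region == "B", ]
  expect_equal(b$uh_area_km2, 4000)   # 10 UH cells x 400 km2
  expect_equal(b$uh_pct, 100)

  all_row <- s[s$region == "All", ]
  expect_equal(all_row$baseline_area_km2, 20 * 400)

  # an empty region yields a zero row, not an error
  s2 <- summarize_by_region(cl, c(rep("A", 20), "C"), agreement = ag)
  expect_equal(s2[s2$region == "C", "baseline_cells"], 0)

  # a cell outside the baseline range may be unassigned
  expect_no_error(summarize_by_region(cl, c(rep("A", 20), NA)))
  expect_error(summarize_by_region(cl, c(NA, rep("A", 20))), "without a region")
})

test_that("the risk overlay counts UH/LSH species on jointly suitable cells", {
  mk <- function(cats) structure(
    data.frame(cell_id = seq_along(cats), wap_baseline = 0.9, wap_2080 = 0.5,
               delta_wap = -0.4,
               category = factor(cats, levels = c("UH", "LSH", "PH",
                                                  "GAINED",
                                                  "OUTSIDE_BASELINE"))),
    class = c("cell_classification", "data.frame"))
  a <- mk(c("PH", "UH", "LSH", "OUTSIDE_BASELINE"))
  b <- mk(c("PH", "LSH", "PH", "PH"))
  ov <- risk_overlay(list(a = a, b = b))
  # cell 4 is outside species a's baseline range -> excluded
  expect_equal(ov$cell_id, 1:3)
  expect_equal(ov$n_species_at_risk, c(0, 2, 1))
  expect_error(risk_overlay(list(a)), "at least two")
  b2 <- b; b2$cell_id <- 5:8
  expect_error(risk_overlay(list(a, b2)), "same grid")
})

test_that("the change-threshold sweep behaves as the rules dictate", {
  set.seed(14)
  n <- 3000
  cm <- structure(data.frame(cell_id = seq_len(n), wap_baseline = runif(n),
                             wap_2080 = runif(n)),
                  class = c("consensus_map", "data.frame"))
  sweep <- sensitivity_analysis(cm, threshold = 0.45)
  expect_equal(nrow(sweep), 5)
  expect_equal(length(unique(sweep$uh_pct)), 1)       # UH share invariant
  expect_true(all(diff(sweep$lsh_pct) <= 1e-12))      # LSH non-increasing
  expect_true(all(diff(sweep$ph_pct) >= -1e-12))      # absorbed by PH
  # as the change threshold approaches 0, every declining persistent cell
  # becomes LSH: PH keeps only non-declining cells
  tiny <- sensitivity_analysis(cm, 0.45, change_thresholds = 1e-9)
  cl <- classify_cells(cm, 0.45, 1e-9)
  ph <- cl$category == "PH"
  expect_true(all(cl$delta_wap[ph] >= -1e-9))
  expect_equal(tiny$lsh_pct + tiny$ph_pct + tiny$uh_pct, 100)
})

test_that("uncertainty partition attributes deviance to the right factor", {
  # probabilities a pure function of the simulation id
  b <- matrix(0.5, 20, 6)
  f <- array(0, c(20, 6, 3))
  for (l in 1:3) f[, , l] <- 0.2 * l
  cube <- make_cube(b, f, technique = rep(c("A", "B"), 3),
                    repetition = rep(1:3, each = 2))
  up <- partition_uncertainty(cube)
  r <- setNames(up$ratios$ratio, up$ratios$factor)
  expect_gte(r[["simulation"]], 0.99)
  expect_lte(r[["technique"]], 0.01)
  expect_lte(r[["repetition"]], 0.01)

  # constant probabilities: zero null deviance, flagged, all ratios zero
  f0 <- array(0.4, c(20, 6, 3))
  up0 <- partition_uncertainty(make_cube(b, f0,
                                         technique = rep(c("A", "B"), 3),
                                         repetition = rep(1:3, each = 2)))
  expect_true(all(up0$ratios$ratio == 0))
  expect_match(paste(up0$note, collapse = " "), "constant")
})

test_that("uncertainty ratios match a main-effects ANOVA and decompose", {
  set.seed(15)
  b <- matrix(runif(40), 10, 4)
  f <- array(runif(10 * 4 * 3), c(10, 4, 3))
  cube <- make_cube(b, f, technique = rep(c("A", "B"), 2),
                    repetition = rep(1:2, each = 2))
  up <- partition_uncertainty(cube)
  expect_true(all(up$ratios$ratio >= 0 & up$ratios$ratio <= 1))
  expect_lte(sum(up$ratios$ratio), 1)
  expect_gte(up$residual, 0)

  # oracle: sequential ANOVA sums of squares on the long layout (balanced
  # design, so order does not matter)
  long <- data.frame(
    p = as.vector(f),
    tech = factor(rep(rep(cube$technique, each = 10), 3)),
    rep = factor(rep(rep(cube$repetition, each = 10), 3)),
    sim = factor(rep(1:3, each = 40))
  )
  an <- anova(aov(p ~ rep + tech + sim, data = long))
  tss <- sum(an$`Sum Sq`)
  r <- setNames(up$ratios$ratio, up$ratios$factor)
  expect_equal(r[["repetition"]], an["rep", "Sum Sq"] / tss, tolerance = 1e-9)
  expect_equal(r[["technique"]], an["tech", "Sum Sq"] / tss, tolerance = 1e-9)
  expect_equal(r[["simulation"]], an["sim", "Sum Sq"] / tss, tolerance = 1e-9)
})
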