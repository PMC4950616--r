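# Independent oracles and fixture constructors shared across test files.

# Build a projection_cube directly from matrices/arrays (bypasses model
# fitting so consensus/classification arithmetic can be tested in isolation).
make_cube <- function(baseline, future = NULL, auc = NULL,
                      technique = NULL, repetition = NULL,
                      sim_ids = NULL, cell_id = NULL) {
  M <- ncol(baseline)
  if (is.null(auc)) auc <- rep(1, M)
  if (is.null(technique)) technique <- paste0("T", seq_len(M))
  if (is.null(repetition)) repetition <- rep(1L, M)
  if (is.null(sim_ids) && !is.null(future))
    sim_ids <- sprintf("sim%02d", seq_len(dim(future)[3]))
  if (is.null(cell_id)) cell_id <- seq_len(nrow(baseline))
  structure(list(baseline = baseline, future = future, auc = auc,
                 technique = technique, repetition = repetition,
                 sim_ids = if (is.null(sim_ids)) character(0) else sim_ids,
                 cell_id = cell_id),
            class = "projection_cube")
}

# Naive triple/quadruple-loop transcription of the weighted-average consensus.
naive_wap <- function(cube, w) {
  n <- nrow(cube$baseline); M <- ncol(cube$baseline)
  wb <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (m in seq_len(M)) {
      num <- num + w[m] * cube$baseline[i, m]
      den <- den + w[m]
    }
    wb[i] <- num / den
  }
  out <- data.frame(cell_id = cube$cell_id, wap_baseline = wb)
  if (!is.null(cube$future)) {
    L <- dim(cube$future)[3]
    wf <- numeric(n)
    for (i in seq_len(n)) {
      num <- 0
      for (l in seq_len(L))
        for (m in seq_len(M))
          num <- num + w[m] * cube$future[i, m, l]
      wf[i] <- num / (L * sum(w))
    }
    out$wap_2080 <- wf
  }
  out
}

# Straight-line transcription of the classification rules for one cell.
classify_oracle_one <- function(base, fut, thr, ct) {
  if (base >= thr) {
    if (fut < thr) return("UH")
    d <- fut - base
    if (d < 0 && abs(d) >= ct) return("LSH")
    if ((d < 0 && abs(d) < ct) || d >= 0) return("PH")
  }
  if (fut >= thr) "GAINED" else "OUTSIDE_BASELINE"
}

# Exhaustive-scan threshold oracle: evaluate sens+spec at every unique
# probability and return the smallest maximizer. True ties are merged with a
# 1e-9 band: with n <= a few hundred, distinct rational scores differ by far
# more than that, so the band only absorbs floating-point noise.
threshold_oracle <- function(obs, prob) {
  cand <- sort(unique(prob))
  ss <- vapply(cand, function(t)
    mean(prob[obs == 1] >= t) + mean(prob[obs == 0] < t), 0)
  cand[ss >= max(ss) - 1e-9][1]
}

# Small landscape used by several files.
tiny_grid <- function(seed = 1, ...) {
  generate_landscape(n_rows = 10, n_cols = 8, seed = seed, ...)
}
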