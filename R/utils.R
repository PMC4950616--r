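# Internal helpers: seeding, validation, small numerics.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-stage/per-unit seed derivation from one master seed.
# Kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  stage_id <- sum(utf8ToInt(as.character(stage)))
  as.integer((abs(master) %% 1000003L) * 1009L + stage_id * 131L + index) %% 2147483629L
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_config("'%s' must be a single number in [%s, %s]", name,
                format(lower), format(upper))
  x
}

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

month_cols <- function(prefix) sprintf("%s%02d", prefix, 1:12)

# Nearest-point index lookup: for each query (qx, qy) the index of the
# nearest (px, py) in plain Euclidean coordinates.
nearest_index <- function(qx, qy, px, py) {
  vapply(seq_along(qx), function(i) {
    which.min((px - qx[i])^2 + (py - qy[i])^2)
  }, integer(1))
}
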