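# Delimited-text readers/writers for every pipeline artifact. All tables are
# UTF-8, comma-delimited with a header row, and round-trip through their
# readers.

write_csv_utf8 <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a grid table
#'
#' @param grid a `grid_table` from [generate_landscape()].
#' @param path file path.
#' @return the path (writer) or the `grid_table` (reader).
#' @export
write_grid_table <- function(grid, path) {
  write_csv_utf8(as.data.frame(grid), path)
}

#' @rdname write_grid_table
#' @param cell_size_km cell size to re-attach on read (default 20).
#' @export
read_grid_table <- function(path, cell_size_km = 20) {
  g <- read.csv(path, encoding = "UTF-8")
  attr(g, "cell_size_km") <- cell_size_km
  attr(g, "n_rows") <- length(unique(g$row))
  attr(g, "n_cols") <- length(unique(g$col))
  class(g) <- c("grid_table", "data.frame")
  g
}

#' Write / read a species occurrence table
#'
#' One file per species: `cell_id`, 0/1 `occurrence` and, when available,
#' the generator's `true_prob`.
#'
#' @param occurrence list from [generate_occurrence()] or a 0/1 vector.
#' @param grid the grid the occurrence lives on (for cell ids).
#' @param path file path.
#' @export
write_occurrence <- function(occurrence, grid, path) {
  if (is.list(occurrence)) {
    df <- data.frame(cell_id = grid$cell_id,
                     occurrence = occurrence$occurrence,
                     true_prob = occurrence$prob)
  } else {
    df <- data.frame(cell_id = grid$cell_id, occurrence = occurrence)
  }
  write_csv_utf8(df, path)
}

#' @rdname write_occurrence
#' @export
read_occurrence <- function(path) read.csv(path, encoding = "UTF-8")

#' Write / read a delta field in long format
#'
#' Long rows of (`coarse_id`, `lat`, `lon`, `month`, `var`, `delta`) with
#' `var` in `temp` (degC) / `prec` (mm).
#'
#' @param delta a `delta_field`.
#' @param path file path.
#' @export
write_delta_field <- function(delta, path) {
  nc <- nrow(delta$centroids)
  long <- rbind(
    data.frame(sim_id = delta$sim_id, emissions = delta$emissions,
               coarse_id = rep(delta$centroids$coarse_id, 12),
               lat = rep(delta$centroids$lat, 12),
               lon = rep(delta$centroids$lon, 12),
               month = rep(1:12, each = nc), var = "temp",
               delta = as.vector(delta$dtemp)),
    data.frame(sim_id = delta$sim_id, emissions = delta$emissions,
               coarse_id = rep(delta$centroids$coarse_id, 12),
               lat = rep(delta$centroids$lat, 12),
               lon = rep(delta$centroids$lon, 12),
               month = rep(1:12, each = nc), var = "prec",
               delta = as.vector(delta$dprec))
  )
  write_csv_utf8(long, path)
}

#' @rdname write_delta_field
#' @export
read_delta_field <- function(path) {
  long <- read.csv(path, encoding = "UTF-8")
  cent <- unique(long[long$var == "temp" & long$month == 1,
                      c("coarse_id", "lat", "lon")])
  cent <- cent[order(cent$coarse_id), ]
  rownames(cent) <- NULL
  pick <- function(v) {
    m <- matrix(NA_real_, nrow(cent), 12)
    for (mm in 1:12) {
      sub <- long[long$var == v & long$month == mm, ]
      m[, mm] <- sub$delta[match(cent$coarse_id, sub$coarse_id)]
    }
    m
  }
  dtemp <- pick("temp"); dprec <- pick("prec")
  colnames(dtemp) <- month_cols("dtmp"); colnames(dprec) <- month_cols("dpre")
  structure(list(sim_id = long$sim_id[1], emissions = long$emissions[1],
                 centroids = cent, dtemp = dtemp, dprec = dprec),
            class = "delta_field")
}

#' Write / read a projection cube in long format
#'
#' Long rows of (`cell_id`, `technique`, `repetition`, `simulation`,
#' `probability`) with `simulation = "baseline"` for the baseline block.
#'
#' @param cube a `projection_cube`.
#' @param path file path.
#' @return the path (writer); the reader returns the long data.frame.
#' @export
write_projection_cube <- function(cube, path) {
  n <- nrow(cube$baseline); M <- ncol(cube$baseline)
  base <- data.frame(cell_id = rep(cube$cell_id, M),
                     technique = rep(cube$technique, each = n),
                     repetition = rep(cube$repetition, each = n),
                     simulation = "baseline",
                     probability = as.vector(cube$baseline))
  out <- base
  if (!is.null(cube$future)) {
    futs <- lapply(seq_along(cube$sim_ids), function(l) {
      data.frame(cell_id = rep(cube$cell_id, M),
                 technique = rep(cube$technique, each = n),
                 repetition = rep(cube$repetition, each = n),
                 simulation = cube$sim_ids[l],
                 probability = as.vector(cube$future[, , l]))
    })
    out <- rbind(base, do.call(rbind, futs))
  }
  write_csv_utf8(out, path)
}

#' @rdname write_projection_cube
#' @export
read_projection_cube <- function(path) read.csv(path, encoding = "UTF-8")

#' Write / read a consensus map
#'
#' @param consensus a `consensus_map`.
#' @param path file path.
#' @export
write_consensus <- function(consensus, path) {
  write_csv_utf8(as.data.frame(consensus), path)
}

#' @rdname write_consensus
#' @export
read_consensus <- function(path) {
  x <- read.csv(path, encoding = "UTF-8")
  class(x) <- c("consensus_map", "data.frame")
  x
}

#' Write a per-cell classification table
#'
#' Columns: `cell_id`, `lat`, `lon`, `region`, `category`, `wap_baseline`,
#' `wap_2080`, `delta_wap`, `agreement_pct`, `confidence` (the agreement
#' band: poor <= 50 < medium <= 75 < high).
#'
#' @param classification a `cell_classification`.
#' @param grid the grid (for lat/lon/region).
#' @param path file path.
#' @param agreement optional per-cell agreement vector.
#' @export
write_classification <- function(classification, grid, path,
                                 agreement = NULL) {
  m <- match(classification$cell_id, grid$cell_id)
  if (is.null(agreement)) agreement <- rep(NA_real_, nrow(classification))
  df <- data.frame(cell_id = classification$cell_id,
                   lat = grid$lat[m], lon = grid$lon[m],
                   region = grid$region[m],
                   category = as.character(classification$category),
                   wap_baseline = classification$wap_baseline,
                   wap_2080 = classification$wap_2080,
                   delta_wap = classification$delta_wap,
                   agreement_pct = agreement,
                   confidence = agreement_band(agreement))
  write_csv_utf8(df, path)
}

#' @rdname write_classification
#' @export
read_classification <- function(path) read.csv(path, encoding = "UTF-8")
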