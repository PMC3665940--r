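#' Six-channel elevation-angle time series
#'
#' Container for sagittal elevation angles (degrees) of the thigh, shank and
#' foot of both legs, sampled on a uniform grid. This is the kinematic object
#' every other operation in the package consumes: the synthetic generator
#' produces it, cycle detection and harmonic extraction read it, and network
#' predictions are compared against it.
#'
#' @param angles numeric matrix, samples in rows, 6 columns named
#'   `left_thigh, left_shank, left_foot, right_thigh, right_shank, right_foot`
#'   (reordered if all names are present; positional otherwise).
#' @param sample_rate sampling frequency in Hz.
#' @param velocity_kmh walking-speed tag in km/h (may be `NA`).
#' @param meta named list of provenance tags (seed, generator config, ...).
#' @return An object of class `elevation_series`: list with elements
#'   `angles` (matrix), `time` (seconds), `sample_rate`, `velocity_kmh`,
#'   `meta`.
#' @export
elevation_series <- function(angles, sample_rate, velocity_kmh = NA_real_,
                             meta = list()) {
  angles <- as.matrix(angles)
  if (ncol(angles) != 6L)
    stop("elevation series must have exactly 6 channels, got ", ncol(angles))
  chn <- elevation_channels()
  if (!is.null(colnames(angles)) && all(chn %in% colnames(angles))) {
    angles <- angles[, chn, drop = FALSE]
  } else {
    colnames(angles) <- chn
  }
  if (!all(is.finite(angles)))
    stop("elevation angles must all be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(
    list(angles = angles,
         time = (seq_len(nrow(angles)) - 1L) / sample_rate,
         sample_rate = sample_rate,
         velocity_kmh = velocity_kmh,
         meta = meta),
    class = "elevation_series")
}

#' @export
print.elevation_series <- function(x, ...) {
  cat(sprintf(
    "<elevation_series> %d samples @ %g Hz (%.2f s), velocity %s km/h\n",
    nrow(x$angles), x$sample_rate, nrow(x$angles) / x$sample_rate,
    format(x$velocity_kmh)))
  cat("channels:", paste(colnames(x$angles), collapse = ", "), "\n")
  rng <- range(x$angles)
  cat(sprintf("angle range: [%.2f, %.2f] deg\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
as.data.frame.elevation_series <- function(x, ...) {
  data.frame(time_s = x$time, x$angles, check.names = FALSE)
}

#' Write / read an elevation-angle trial as CSV with a JSON sidecar
#'
#' The CSV has a mandatory header `time_s,left_thigh,...,right_foot`, angles
#' in degrees. Sample rate, velocity and meta tags travel in `<path>.json`.
#'
#' @param series an [elevation_series()].
#' @param path CSV file path.
#' @return `write_elevation_csv` returns `path` invisibly;
#'   `read_elevation_csv` returns an [elevation_series()].
#' @export
write_elevation_csv <- function(series, path) {
  stopifnot(inherits(series, "elevation_series"))
  write.csv(as.data.frame(series), path, row.names = FALSE)
  sidecar <- list(sample_rate = series$sample_rate,
                  velocity_kmh = series$velocity_kmh,
                  meta = series$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_elevation_csv
#' @export
read_elevation_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("time_s", elevation_channels())
  if (!all(need %in% names(df)))
    stop("CSV is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  dt <- diff(df$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop("time grid is not uniform")
  sidecar_path <- paste0(path, ".json")
  velocity <- NA_real_; meta <- list(); rate <- 1 / mean(dt)
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    velocity <- sc$velocity_kmh %||% NA_real_
    meta <- as.list(sc$meta %||% list())
    rate <- sc$sample_rate %||% rate
  }
  elevation_series(as.matrix(df[, elevation_channels()]), rate,
                   velocity_kmh = velocity, meta = meta)
}
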