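#' A per-frame geometry metric series
#'
#' Carrier for one metric evaluated along a trajectory, with units and an
#' optional pre-equilibration discard window used by
#' \code{\link{series_summary}}.
#'
#' @param metric metric name (e.g. \code{"angle_A1_A2_A3"}).
#' @param unit \code{"angstrom"} or \code{"degrees"}.
#' @param values numeric per-frame values (finite).
#' @param time_ps optional per-frame times in ps.
#' @param discard_ps pre-equilibration window excluded from summaries
#'   (default 10 ns = 10000 ps).
#' @return An object of class \code{geometry_series}.
#' @export
geometry_series <- function(metric, unit = c("degrees", "angstrom"),
                            values, time_ps = NULL, discard_ps = 10000) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  .check_finite(values, sprintf("series '%s'", metric))
  if (!is.null(time_ps) && length(time_ps) != length(values))
    .stopf("time_ps and values lengths differ")
  structure(list(metric = metric, unit = unit, values = values,
                 time_ps = time_ps, discard_ps = discard_ps),
            class = "geometry_series")
}

#' @export
print.geometry_series <- function(x, ...) {
  cat(sprintf("<geometry_series> %s [%s], %d frames\n",
              x$metric, x$unit, length(x$values)))
  invisible(x)
}

#' Unwrap an angular series
#'
#' Removes 360-degree jumps by nearest-image continuation: each value is
#' shifted by a multiple of 360 to minimise the frame-to-frame difference.
#' Needed before averaging series that may cross the +/-180 branch cut
#' (steered torsions in principle do).
#'
#' @param x numeric vector of angles in degrees.
#' @return unwrapped vector (first value unchanged).
#' @export
unwrap_angles <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  x[1L] + c(0, cumsum(d))
}

#' Mean and standard deviation of a metric series
#'
#' Frames earlier than \code{discard_ps} (pre-equilibration) are excluded;
#' when the series has no times, \code{discard_frames} must be supplied
#' explicitly instead.  Angular series are unwrapped before averaging; the
#' sample standard deviation uses the n-1 denominator.
#'
#' @param s a \code{geometry_series}.
#' @param discard_ps override for the series' discard window (ps).
#' @param discard_frames number of leading frames to drop when the series
#'   carries no times.
#' @return named list with \code{mean}, \code{sd} and \code{n} (retained
#'   frames).
#' @export
series_summary <- function(s, discard_ps = NULL, discard_frames = NULL) {
  stopifnot(inherits(s, "geometry_series"))
  v <- s$values
  if (!is.null(s$time_ps)) {
    dp <- if (is.null(discard_ps)) s$discard_ps else discard_ps
    keep <- s$time_ps >= dp
  } else {
    if (is.null(discard_frames))
      .stopf("series has no frame times; supply discard_frames explicitly")
    keep <- seq_along(v) > discard_frames
  }
  v <- v[keep]
  if (length(v) < 2L)
    .stopf("fewer than 2 frames retained after discard; cannot summarise")
  if (s$unit == "degrees") v <- unwrap_angles(v)
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Tidy data.frame view of one or more series
#'
#' @param series a \code{geometry_series} or list of them.
#' @return data.frame with columns frame, time_ps, metric, value, unit.
#' @export
series_table <- function(series) {
  if (inherits(series, "geometry_series")) series <- list(series)
  do.call(rbind, lapply(series, function(s)
    data.frame(frame = seq_along(s$values),
               time_ps = if (is.null(s$time_ps)) NA_real_ else s$time_ps,
               metric = s$metric, value = s$values, unit = s$unit,
               stringsAsFactors = FALSE)))
}
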