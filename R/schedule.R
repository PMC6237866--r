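#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule holds the start and end time of every frame of a dynamic
#' acquisition. All times are stored in minutes internally; inputs given in
#' seconds are converted at the boundary. Frames must be strictly increasing,
#' non-overlapping, contiguous, and of positive duration.
#'
#' @param start,end Numeric vectors of frame start/end times.
#' @param unit Unit of the supplied times, `"min"` (default) or `"sec"`.
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `start` and `end` in minutes.
#' @export
#' @examples
#' frame_schedule(c(0, 1, 2), c(1, 2, 5))
frame_schedule <- function(start, end, unit = c("min", "sec")) {
  unit <- match.arg(unit)
  if (length(start) != length(end) || length(start) == 0L)
    stop("start and end must be non-empty vectors of equal length")
  if (!is.numeric(start) || !is.numeric(end) || anyNA(start) || anyNA(end))
    stop("frame times must be finite numeric values")
  if (unit == "sec") {
    start <- start / 60
    end <- end / 60
  }
  if (any(end - start <= 0))
    stop("all frame durations must be > 0")
  if (is.unsorted(start, strictly = TRUE))
    stop("frame start times must be strictly increasing")
  n <- length(start)
  if (n > 1L && any(abs(start[-1] - end[-n]) > 1e-9))
    stop("frames must be contiguous (each frame starts where the previous ends)")
  structure(data.frame(start = start, end = end),
            class = c("frame_schedule", "data.frame"))
}

#' @rdname frame_schedule
#' @param schedule A `frame_schedule`.
#' @export
frame_midpoints <- function(schedule) (schedule$start + schedule$end) / 2

#' @rdname frame_schedule
#' @export
frame_durations <- function(schedule) schedule$end - schedule$start

#' @rdname frame_schedule
#' @export
n_frames <- function(schedule) nrow(schedule)

#' Standard 60-minute acquisition schedule
#'
#' The 38-frame schedule used throughout: 6 x 10 s, 6 x 30 s, 11 x 60 s and
#' 15 x 180 s frames, spanning 60 minutes from injection.
#'
#' @return A [frame_schedule] with 38 frames totalling 60 minutes.
#' @export
standard_frame_schedule <- function() {
  dur <- c(rep(10, 6), rep(30, 6), rep(60, 11), rep(180, 15))
  end <- cumsum(dur)
  frame_schedule(c(0, end[-length(end)]), end, unit = "sec")
}

#' Time-activity curve
#'
#' A decay-corrected time-activity curve: activity concentration (kBq/mL)
#' at a set of strictly increasing times (minutes), for one brain region or
#' blood compartment.
#'
#' @param times Sample times or frame midpoints, minutes, strictly increasing.
#' @param activity Activity concentrations, kBq/mL; must be finite.
#' @param label Region or compartment name.
#' @return An object of class `tac`.
#' @export
tac <- function(times, activity, label = "") {
  if (length(times) != length(activity))
    stop("times and activity must have equal length")
  if (!is.numeric(times) || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (!all(is.finite(activity)))
    stop("activity must be finite")
  structure(list(times = as.numeric(times), activity = as.numeric(activity),
                 label = as.character(label)[1]),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s: %d samples, %.2f-%.2f min, peak %.3g kBq/mL\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$times), min(x$times), max(x$times), max(x$activity)))
  invisible(x)
}

# Linear interpolator for a tac; errors if asked outside its support and
# extrapolate = FALSE.
tac_fun <- function(x, extrapolate = FALSE) {
  stopifnot(inherits(x, "tac"))
  rule <- if (extrapolate) 2L else 1L
  stats::approxfun(x$times, x$activity, rule = rule)
}

#' Arterial and venous blood sampling times
#'
#' The blood sampling grids used by the acquisition protocol: arterial samples
#' every 10 s up to 3 min then at 4, 5, 10, 20, 30, 45 and 60 min (25 samples);
#' venous samples at 5, 10, 20, 30, 45 and 60 min. Metabolite (parent-fraction)
#' measurements use the samples from 5 min onwards.
#'
#' @return Numeric vector of times in minutes.
#' @export
arterial_sample_times <- function() {
  c(seq(10, 180, by = 10) / 60, 4, 5, 10, 20, 30, 45, 60)
}

#' @rdname arterial_sample_times
#' @export
venous_sample_times <- function() c(5, 10, 20, 30, 45, 60)
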