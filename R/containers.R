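#' Frame stack
#'
#' An ordered grayscale time-lapse: a list of numeric matrices (rows = y,
#' columns = x) on a uniform time base. Intensities must be finite and
#' non-negative; all frames share one shape.
#'
#' @param frames List of numeric matrices, all the same dimension.
#' @param frame_interval Seconds between consecutive frames (> 0).
#' @param pixel_size Optional pixel size in micrometres per pixel.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_interval, pixel_size = NULL) {
  stopifnot(is.list(frames), length(frames) >= 2)
  stopifnot(is.numeric(frame_interval), frame_interval > 0)
  dims <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), dims)) {
      stop("all frames must be matrices of identical shape")
    }
    if (!all(is.finite(f)) || any(f < 0)) {
      stop("frame intensities must be finite and non-negative")
    }
  }
  structure(
    list(frames = frames, frame_interval = frame_interval,
         pixel_size = pixel_size),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %dx%d px, %g s/frame\n",
              length(x$frames), d[1], d[2], x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [frame_stack()].
#' @export
n_frames <- function(stack) length(stack$frames)

#' Rectangular region of interest
#'
#' Pixel coordinates are 0-based with x = column and y = row; the rectangle
#' is half-open, covering columns `[x0, x1)` and rows `[y0, y1)`.
#'
#' @param x0,y0 Inclusive lower corner (0-based).
#' @param x1,y1 Exclusive upper corner.
#' @return An object of class `roi`.
#' @export
roi <- function(x0, y0, x1, y1) {
  stopifnot(x1 > x0, y1 > y0, x0 >= 0, y0 >= 0)
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> [%g, %g) x [%g, %g) px (%g x %g)\n",
              x$x0, x$x1, x$y0, x$y1, x$x1 - x$x0, x$y1 - x$y0))
  invisible(x)
}

roi_width <- function(r) r$x1 - r$x0
roi_height <- function(r) r$y1 - r$y0

check_roi_in_frame <- function(r, dims) {
  # dims = c(nrow, ncol) = c(height, width)
  if (r$x1 > dims[2] || r$y1 > dims[1]) {
    stop("ROI extends beyond the frame bounds")
  }
  invisible(TRUE)
}

#' Displacement trace
#'
#' Per-frame mean Euclidean distance of the tracked ROI points from their
#' resting (frame 0) positions. Frame 0 defines the zero point, so
#' `displacement[1] == 0` and all values are non-negative.
#'
#' @param times Frame times in seconds.
#' @param displacement Mean distance from rest per frame, in `units`.
#' @param n_points_alive Number of surviving tracked features per frame;
#'   `NA` for traces not produced by the tracker.
#' @param units `"px"` or `"um"`.
#' @return An object of class `displacement_trace`.
#' @export
displacement_trace <- function(times, displacement,
                               n_points_alive = rep(NA_integer_, length(times)),
                               units = c("px", "um")) {
  units <- match.arg(units)
  stopifnot(length(times) == length(displacement),
            length(times) == length(n_points_alive))
  if (length(displacement) > 0) {
    stopifnot(abs(displacement[1]) < 1e-9, all(displacement >= 0))
  }
  structure(
    list(times = as.numeric(times), displacement = as.numeric(displacement),
         n_points_alive = as.integer(n_points_alive), units = units),
    class = "displacement_trace"
  )
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf(
    "<displacement_trace> %d samples over %.2f s, max %.3f %s\n",
    length(x$times), diff(range(x$times)), max(x$displacement), x$units
  ))
  invisible(x)
}

#' @export
as.data.frame.displacement_trace <- function(x, ...) {
  data.frame(time_s = x$times, displacement = x$displacement,
             units = x$units, n_points_alive = x$n_points_alive)
}

trace_interval <- function(trace) {
  dt <- diff(trace$times)
  if (length(dt) == 0) stop("trace has fewer than 2 samples")
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("trace sampling is not uniform")
  }
  mean(dt)
}

#' Convert a pixel trace to physical units
#'
#' @param trace A [displacement_trace()] in pixels.
#' @param pixel_size Micrometres per pixel (> 0).
#' @return The trace with displacement in micrometres.
#' @export
to_physical_units <- function(trace, pixel_size) {
  stopifnot(inherits(trace, "displacement_trace"), pixel_size > 0)
  if (trace$units != "px") stop("trace is already in physical units")
  displacement_trace(trace$times, trace$displacement * pixel_size,
                     trace$n_points_alive, units = "um")
}
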