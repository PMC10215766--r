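#' Front and gap traces
#'
#' A front trace records the position of the advancing detachment / diffusion
#' front over time; a gap trace records the cumulative detached interface
#' length of the mechanical model.  Both are plain data frames in assay units
#' (`t_min` in minutes, `X_mm` / `gap_mm` in millimetres) so they round-trip
#' through the CSV schemas of [read_trace()] / [write_trace()].
#'
#' @param t_min times, minutes; strictly increasing, starting at 0.
#' @param X_mm,gap_mm front position / detached length, mm; nondecreasing.
#' @return A data frame of class `"front_trace"` or `"gap_trace"`.
#' @examples
#' front_trace(c(0, 1, 4), c(0, 0.027, 0.054))
#' @export
front_trace <- function(t_min, X_mm) {
  stopifnot(is.numeric(t_min), is.numeric(X_mm), length(t_min) == length(X_mm))
  if (length(t_min) && any(diff(t_min) <= 0)) {
    stop_bad("front trace times must be strictly increasing",
             "delamsim_bad_trace")
  }
  if (length(t_min) && any(diff(X_mm) < -1e-12)) {
    stop_bad("front positions must be nondecreasing", "delamsim_bad_trace")
  }
  structure(data.frame(t_min = t_min, X_mm = X_mm),
            class = c("front_trace", "data.frame"))
}

#' @rdname front_trace
#' @export
gap_trace <- function(t_min, gap_mm) {
  stopifnot(is.numeric(t_min), is.numeric(gap_mm),
            length(t_min) == length(gap_mm))
  if (length(t_min) && any(diff(t_min) <= 0)) {
    stop_bad("gap trace times must be strictly increasing",
             "delamsim_bad_trace")
  }
  if (length(gap_mm) && any(diff(gap_mm) < -1e-12)) {
    stop_bad("gap lengths must be nondecreasing", "delamsim_bad_trace")
  }
  structure(data.frame(t_min = t_min, gap_mm = gap_mm),
            class = c("gap_trace", "data.frame"))
}

#' @export
plot.front_trace <- function(x, ...,
                             xlab = "t [min]", ylab = "front position [mm]") {
  plot(x$t_min, x$X_mm, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
plot.gap_trace <- function(x, ...,
                           xlab = "t [min]", ylab = "detached gap [mm]") {
  plot(x$t_min, x$gap_mm, type = "s", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
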