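#' Time-activity curve
#'
#' Container for tracer activity sampled over time in plasma or a tissue
#' region. Times are minutes post injection, activities kBq/mL.
#'
#' @param times numeric, strictly increasing, >= 0 (min).
#' @param activities numeric, same length, finite (kBq/mL).
#' @param label curve label: `"plasma"` or a region name.
#' @return An object of class `tac`.
#' @examples
#' tac(c(1, 5, 10), c(50, 30, 20), "plasma")
#' @export
tac <- function(times, activities, label = "plasma") {
  times <- as.numeric(times)
  activities <- as.numeric(activities)
  if (length(times) < 3L)
    stop_config("a time-activity curve needs at least 3 samples (got %d)",
                length(times))
  if (length(activities) != length(times))
    stop_config("times and activities must have equal length")
  if (any(!is.finite(times)) || any(times < 0))
    stop_config("times must be finite and >= 0")
  if (any(diff(times) <= 0))
    stop_config("times must be strictly increasing")
  if (any(!is.finite(activities)))
    stop_config("activities must be finite")
  structure(list(times = times, activities = activities,
                 label = as.character(label)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac '%s': %d samples, %.2f-%.2f min, peak %.3g kBq/mL>\n",
              x$label, length(x$times), min(x$times), max(x$times),
              max(x$activities)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(region = x$label, time_min = x$times,
             activity_kbq_ml = x$activities)
}

# Linear interpolation of a TAC (and of its running integral) at new times.
tac_interp <- function(x, at) {
  if (any(at < min(x$times) - 1e-9) || any(at > max(x$times) + 1e-9))
    stop_config("evaluation time outside the support of curve '%s'", x$label)
  approx(x$times, x$activities, xout = at, rule = 1)$y
}
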