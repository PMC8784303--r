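#' Build a two-band frequency grid
#'
#' EEG time-frequency decompositions commonly use a finer frequency step for
#' low frequencies (where Hanning tapers are typical) and a coarser step for
#' high frequencies (multitapers). The grid is the concatenation of two
#' inclusive arithmetic sequences, low band first.
#'
#' @param low,high Numeric length-3 vectors `c(start, stop, step)` in Hz.
#'   Defaults give the canonical 31-bin grid: 2-20 Hz in steps of 2 plus
#'   25-125 Hz in steps of 5.
#' @return A `freq_grid` object: list with `freqs_hz`, `low_band`, `high_band`.
#' @examples
#' fg <- build_frequency_grid()
#' length(fg$freqs_hz) # 31
#' @export
build_frequency_grid <- function(low = c(2, 20, 2), high = c(25, 125, 5)) {
  band_seq <- function(b, name) {
    if (length(b) != 3 || !is.numeric(b)) {
      stop("invalid grid: ", name, " band must be numeric c(start, stop, step)")
    }
    if (b[3] <= 0) stop("invalid grid: ", name, " band step must be > 0")
    if (b[1] > b[2]) stop("invalid grid: ", name, " band is descending")
    seq(b[1], b[2], by = b[3])
  }
  lo <- band_seq(low, "low")
  hi <- band_seq(high, "high")
  if (max(lo) >= min(hi)) stop("invalid grid: low and high bands overlap")
  freqs <- c(lo, hi)
  if (any(freqs <= 0)) stop("invalid grid: frequencies must be positive")
  structure(
    list(freqs_hz = freqs, low_band = low, high_band = high),
    class = "freq_grid"
  )
}

#' Build a uniform time grid
#'
#' Sample times in seconds relative to stimulus onset (onset = 0). The span
#' must be an integer multiple of the step.
#'
#' @param start_s,stop_s,step_s Start, stop and step in seconds. Defaults give
#'   the 326-point axis from -0.6 s to 2 s at 8 ms.
#' @return A `time_grid` object: list with `times_s`, `step_s`.
#' @examples
#' tg <- build_time_grid()
#' length(tg$times_s) # 326
#' @export
build_time_grid <- function(start_s = -0.6, stop_s = 2.0, step_s = 0.008) {
  if (!(start_s < stop_s)) stop("invalid grid: start must be before stop")
  if (step_s <= 0) stop("invalid grid: step must be > 0")
  n_span <- (stop_s - start_s) / step_s
  if (abs(n_span - round(n_span)) > 1e-6) {
    stop("invalid grid: time span is not an integer multiple of the step")
  }
  n <- round(n_span) + 1L
  structure(
    list(times_s = start_s + (seq_len(n) - 1L) * step_s, step_s = step_s),
    class = "time_grid"
  )
}

#' @export
print.freq_grid <- function(x, ...) {
  f <- x$freqs_hz
  cat(sprintf(
    "<freq_grid> %d bins, %g-%g Hz (low band step %g, high band step %g)\n",
    length(f), min(f), max(f), x$low_band[3], x$high_band[3]
  ))
  invisible(x)
}

#' @export
print.time_grid <- function(x, ...) {
  t <- x$times_s
  cat(sprintf(
    "<time_grid> %d samples, %.3f to %.3f s, step %g ms\n",
    length(t), min(t), max(t), x$step_s * 1000
  ))
  invisible(x)
}

# coerce freq_grid / time_grid / bare numeric to a numeric axis
as_axis <- function(x) {
  if (inherits(x, "freq_grid")) return(x$freqs_hz)
  if (inherits(x, "time_grid")) return(x$times_s)
  as.numeric(x)
}
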