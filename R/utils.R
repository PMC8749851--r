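# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cumulative trapezoid integral with constant sampling interval
#'
#' @param y numeric vector to integrate.
#' @param dt sampling interval in seconds.
#' @return numeric vector of the same length; first element is 0.
#' @keywords internal
cumtrapz_dt <- function(y, dt) {
  if (length(y) == 0L) return(numeric(0))
  as.numeric(pracma::cumtrapz(y)) * dt
}

#' Trapezoid integral with constant sampling interval
#' @inheritParams cumtrapz_dt
#' @keywords internal
trapz_dt <- function(y, dt) {
  if (length(y) < 2L) return(0)
  pracma::trapz(y) * dt
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth applied forward and backward
#' (`signal::filtfilt`), so the filter adds no group delay and the timing of
#' extrema is preserved.
#'
#' @param x numeric vector.
#' @param cutoff_hz cutoff frequency, Hz; must be below `fs / 2`.
#' @param fs sampling frequency, Hz.
#' @param order filter order before the forward-backward pass (default 2).
#' @return filtered numeric vector, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, cutoff_hz, fs, order = 2) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop(sprintf("cutoff (%g Hz) must lie in (0, fs/2 = %g Hz)", cutoff_hz, fs / 2))
  }
  if (length(x) <= 3 * (order + 1)) {
    stop("signal too short to filter (need more than ", 3 * (order + 1), " samples)")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Local minima below a threshold; returns indices ordered by position.
# Ties within a flat extremum resolve to the first sample.
local_minima_below <- function(x, threshold) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  left <- c(Inf, x[-n])
  right <- c(x[-1L], Inf)
  idx <- which(x < threshold & x <= left & x < right)
  idx
}
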