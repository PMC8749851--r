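# Touch-down / toe-off detection from the medial-lateral gyroscope axis,
# and tap-based time synchronization of a sensor pair.
#
# Detection rule: the medial-lateral angular rate of a running foot shows a
# large positive burst during mid-swing and sharp opposite-sign troughs at
# touch-down and toe-off. Mid-swing bursts are located on a 10 Hz zero-phase
# low-passed copy of the signal; the touch-down of a cycle is the first deep
# trough of the raw signal after a swing peak, and the toe-off of the next
# cycle is the last deep trough before the following swing peak.

#' Construct gait events
#'
#' Ordered touch-down (TD) and toe-off (TO) sample indices of one foot.
#' Events must strictly alternate in time (a standing start yields the
#' sequence TO, TD, TO, TD, ...: the first toe-off lacks a preceding
#' touch-down).
#'
#' @param td integer touch-down sample indices, strictly increasing.
#' @param to integer toe-off sample indices, strictly increasing.
#' @param foot foot label.
#' @return object of class `gait_events`.
#' @export
gait_events <- function(td, to, foot = c("left", "right")) {
  foot <- match.arg(foot)
  td <- as.integer(td); to <- as.integer(to)
  if (length(td) && any(diff(td) <= 0)) stop("touch-down indices must be strictly increasing")
  if (length(to) && any(diff(to) <= 0)) stop("toe-off indices must be strictly increasing")
  if (length(td) && length(to)) {
    all_idx <- c(td, to)
    typ <- c(rep("td", length(td)), rep("to", length(to)))
    ord <- order(all_idx)
    if (any(duplicated(all_idx))) stop("touch-down and toe-off indices overlap")
    runs <- rle(typ[ord])$lengths
    if (any(runs > 1L)) {
      bad <- all_idx[ord][cumsum(rle(typ[ord])$lengths)[which(runs > 1L)]]
      stop("events do not alternate TD/TO; offending indices: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(td = td, to = to, foot = foot), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> foot=%s  %d touch-downs, %d toe-offs\n",
              x$foot, length(x$td), length(x$to)))
  invisible(x)
}

#' Detect touch-down and toe-off from the medial-lateral angular rate
#'
#' @param gyr_x angular rate about the medial-lateral axis, rad/s.
#' @param fs sampling frequency, Hz.
#' @param foot foot label attached to the result.
#' @param cfg configuration; relevant keys `events.lowpass_hz`,
#'   `events.swing_prominence` (minimum swing-peak height, rad/s),
#'   `events.depth_frac` (trough depth as a fraction of the median swing
#'   peak) and `events.min_stride_s` (minimum swing-peak spacing).
#' @return [gait_events()]. With no detectable swing peaks an empty event
#'   set is returned with a warning.
#' @export
detect_events <- function(gyr_x, fs, foot = "left", cfg = ss_config()) {
  if (length(gyr_x) < fs) stop("need at least 1 s of signal")
  lp <- lowpass_zero_phase(gyr_x, cfg[["events.lowpass_hz"]], fs)
  min_dist <- max(1L, round(cfg[["events.min_stride_s"]] * fs))
  pk <- pracma::findpeaks(lp, minpeakheight = cfg[["events.swing_prominence"]],
                          minpeakdistance = min_dist)
  if (is.null(pk)) {
    warning("no swing peaks found; returning empty gait events")
    return(gait_events(integer(0), integer(0), foot = foot))
  }
  peaks <- sort(pk[, 2L])
  depth <- -cfg[["events.depth_frac"]] * median(pk[, 1L])

  trough_in <- function(lo, hi, which = c("first", "last")) {
    which <- match.arg(which)
    if (hi - lo < 2L) return(NA_integer_)
    seg <- gyr_x[lo:hi]
    cand <- local_minima_below(seg, depth)
    if (!length(cand)) return(NA_integer_)
    i <- if (which == "first") cand[1L] else cand[length(cand)]
    lo + i - 1L
  }

  n <- length(gyr_x)
  td <- integer(0); to <- integer(0)
  # toe-off preceding the first swing (standing start)
  first_to <- trough_in(1L, peaks[1L], "last")
  if (!is.na(first_to)) to <- c(to, first_to)
  if (length(peaks) > 1L) {
    for (k in seq_len(length(peaks) - 1L)) {
      lo <- peaks[k]; hi <- peaks[k + 1L]
      td_k <- trough_in(lo, hi, "first")
      to_k <- trough_in(lo, hi, "last")
      if (!is.na(td_k)) td <- c(td, td_k)
      if (!is.na(to_k) && !identical(to_k, td_k)) to <- c(to, to_k)
    }
  }
  # final touch-down after the last swing
  last_td <- trough_in(peaks[length(peaks)], n, "first")
  if (!is.na(last_td)) td <- c(td, last_td)
  gait_events(td = td, to = to, foot = foot)
}

#' Estimate the time lag between two sensors from the shared tap transient
#'
#' Both sensors are tapped together on a hard surface before mounting; the
#' lag maximizing the cross-correlation of the acceleration norms inside the
#' search window aligns the tap peaks within one sample.
#'
#' @param rec_a,rec_b [imu_recording()] objects containing the tap within
#'   the first `sync.window_s` seconds.
#' @param cfg configuration; keys `sync.window_s`, `sync.threshold_g`.
#' @param g gravitational constant used for the detection threshold.
#' @return integer lag in samples: `rec_b` lags `rec_a` by the returned
#'   number of samples (negative when `rec_b` leads).
#' @export
detect_sync_tap <- function(rec_a, rec_b, cfg = ss_config(), g = G_DEFAULT) {
  win_n <- round(cfg[["sync.window_s"]] * min(rec_a$fs, rec_b$fs))
  norm_of <- function(rec) {
    n <- min(length(rec$t), win_n)
    sqrt(rowSums(rec$acc[seq_len(n), , drop = FALSE]^2))
  }
  na <- norm_of(rec_a); nb <- norm_of(rec_b)
  thr <- cfg[["sync.threshold_g"]] * g
  if (max(na) < thr || max(nb) < thr) {
    stop(sprintf("no tap transient above %.1f g inside the %.1f s search window",
                 cfg[["sync.threshold_g"]], cfg[["sync.window_s"]]))
  }
  na <- na - mean(na); nb <- nb - mean(nb)
  max_lag <- length(na) - 1L
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(na[seq_len(length(na) - l)] * nb[seq_len(length(nb) - l) + l])
    else sum(na[seq_len(length(na) + l) - l] * nb[seq_len(length(nb) + l)])
  }, numeric(1))
  lags[which.max(cc)]
}

#' Ground contact times
#'
#' Stance durations: for every touch-down, the time to the next toe-off of
#' the same foot. Touch-downs without a subsequent toe-off are skipped.
#'
#' @param ev [gait_events()].
#' @param fs sampling frequency, Hz.
#' @return numeric vector of stance durations, seconds.
#' @export
ground_contact_times <- function(ev, fs) {
  if (!length(ev$td) || !length(ev$to)) return(numeric(0))
  out <- numeric(0)
  for (td in ev$td) {
    nxt <- ev$to[ev$to > td]
    if (length(nxt)) out <- c(out, (nxt[1L] - td) / fs)
  }
  out
}
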