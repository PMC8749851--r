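# Core stride-length algorithm: stride segmentation, touch-down-artefact
# velocity correction (zero-velocity update), and double integration of
# horizontal global-frame acceleration.
#
# A stride runs from touch-down of one foot to the next touch-down of the
# same foot. The first stride of each foot has no preceding touch-down
# (standing start); its integration starts 280 ms before the first toe-off
# with zero initial velocity and receives no offset correction. For all
# later strides, the impact at touch-down leaves a spurious offset in the
# integrated velocity; the offset is read from a guarded, 40 Hz low-passed
# "temporary" copy of the velocity as the minimum in a 20-100 ms window
# after touch-down (20-160 ms for stride 2, whose ground contact is the
# longest), subtracted from the unfiltered velocity, and the samples before
# the detected minimum are zeroed.

#' Segment a sprint into strides
#'
#' @param ev [gait_events()]; the first event must be a toe-off (standing
#'   start).
#' @param fs sampling frequency, Hz.
#' @param n_samples number of samples in the signal the events index into.
#' @param cfg configuration; key `start.pre_toeoff_s` (default 0.280 s)
#'   fixes where integration of the first stride starts.
#' @return list of `stride_segment` lists with fields `foot`,
#'   `stride_index`, `start_idx`, `end_idx` (half-open `[start, end)`),
#'   `td_idx` and `contact_end_idx` (both `NA` for stride 1). Strides
#'   truncated by the end of the signal are dropped with a warning.
#' @export
segment_strides <- function(ev, fs, n_samples, cfg = ss_config()) {
  if (!length(ev$to)) stop("no toe-off events; cannot segment")
  if (length(ev$td) && min(ev$td) < min(ev$to)) {
    stop("first event must be a toe-off (standing start); got a touch-down at ",
         min(ev$td))
  }
  pre_n <- round(cfg[["start.pre_toeoff_s"]] * fs)
  start1 <- ev$to[1L] - pre_n
  if (start1 < 1L) {
    stop(sprintf("insufficient pre-start samples: first toe-off at %d needs %d samples before it",
                 ev$to[1L], pre_n))
  }
  if (!length(ev$td)) stop("no touch-down events; cannot segment")
  bounds <- c(start1, ev$td)  # stride k spans [bounds[k], bounds[k+1])
  segs <- list()
  dropped <- 0L
  for (k in seq_len(length(bounds) - 1L)) {
    start_idx <- bounds[k]; end_idx <- bounds[k + 1L]
    if (end_idx > n_samples + 1L) { dropped <- dropped + 1L; next }
    if (k == 1L) {
      td_idx <- NA_integer_
      contact_end_idx <- ev$to[1L]
    } else {
      td_idx <- ev$td[k - 1L]
      nxt_to <- ev$to[ev$to > td_idx]
      contact_end_idx <- if (length(nxt_to)) nxt_to[1L] else NA_integer_
    }
    segs[[length(segs) + 1L]] <- structure(
      list(foot = ev$foot, stride_index = k, start_idx = start_idx,
           end_idx = end_idx, td_idx = td_idx,
           contact_end_idx = contact_end_idx),
      class = "stride_segment")
  }
  if (dropped > 0L) {
    warning(dropped, " stride(s) truncated by the end of the signal were dropped")
  }
  segs
}

#' Integrate stride acceleration and mirror negative-running axes
#'
#' Cumulative trapezoid integration (zero initial velocity) of the
#' unfiltered horizontal acceleration over one stride. An axis whose mean
#' velocity over the stride is negative is negated so that both axes run
#' positive; the flags record which axes were mirrored. Stride length is
#' unaffected by mirroring (it is a norm).
#'
#' @param seg `stride_segment` from [segment_strides()].
#' @param sprint [global_sprint()].
#' @return list with `vx`, `vz` ("original" velocities, m/s), and logical
#'   `mirrored_x`, `mirrored_z`.
#' @export
integrate_and_mirror <- function(seg, sprint) {
  n <- length(sprint$t)
  if (seg$start_idx < 1L || seg$end_idx > n + 1L) {
    stop("stride segment out of bounds of the sprint signal")
  }
  idx <- seg$start_idx:(seg$end_idx - 1L)
  dt <- 1 / sprint$fs
  out <- list()
  for (axis in c("x", "z")) {
    v <- cumtrapz_dt(sprint[[paste0("acc_", axis)]][idx], dt)
    mirrored <- mean(v) < 0
    if (mirrored) v <- -v
    out[[paste0("v", axis)]] <- v
    out[[paste0("mirrored_", axis)]] <- mirrored
  }
  out
}

#' Temporary (guard-filtered) velocity used for offset detection
#'
#' Copy of the original stride velocity, low-pass filtered at 40 Hz (zero
#' phase) to remove impact-related high-frequency oscillation, in which the
#' first `round(0.020*fs)` samples are then set to the value of the last
#' clamped sample plus a +1 m/s guard. The guard forces the signal to
#' decline after 20 ms, so the minimum found in the search window always
#' falls after the touch-down artefact. The clamp is applied after the
#' filter so that the guard step cannot ring through the filter and bias
#' the minimum; on an artefact-free stride the detected offset is then
#' exactly the (near-zero) early-stance velocity. The original velocity is
#' left untouched.
#'
#' @param v_orig stride velocity, m/s.
#' @param fs sampling frequency, Hz.
#' @param cfg configuration; keys `zvu.guard_m_s` (default 1.0) and
#'   `zvu.lowpass_hz` (default 40).
#' @return guarded, filtered temporary velocity, same length as `v_orig`.
#' @export
temporary_velocity <- function(v_orig, fs, cfg = ss_config()) {
  clamp_n <- round(0.020 * fs)
  if (length(v_orig) <= clamp_n) stop("stride shorter than the 20 ms clamp window")
  tmp <- lowpass_zero_phase(v_orig, cfg[["zvu.lowpass_hz"]], fs)
  tmp[seq_len(clamp_n)] <- tmp[clamp_n] + cfg[["zvu.guard_m_s"]]
  tmp
}

#' Locate the velocity offset after touch-down
#'
#' Minimum of the temporary velocity over the inclusive window
#' `[round(lo*fs), round(hi*fs)]` samples after touch-down; the first sample
#' wins on ties. The minimum marks the first index after the touch-down
#' artefact that is followed by a consistent velocity increase.
#'
#' @param v_tmp temporary velocity from [temporary_velocity()].
#' @param fs sampling frequency, Hz.
#' @param lo,hi window bounds, seconds after touch-down.
#' @param td_rel_idx offset (samples) of the touch-down from the start of
#'   the stride; 0 for strides >= 2, whose first sample is the touch-down.
#' @return list with `value` (m/s) and `idx` (1-based index into the
#'   stride).
#' @export
find_offset <- function(v_tmp, fs, lo = 0.020, hi = 0.100, td_rel_idx = 0L) {
  w <- (td_rel_idx + round(lo * fs) + 1L):(td_rel_idx + round(hi * fs) + 1L)
  if (max(w) > length(v_tmp)) {
    stop(sprintf("offset search window [%g, %g] s exceeds the stride (%d samples)",
                 lo, hi, length(v_tmp)))
  }
  i <- w[which.min(v_tmp[w])]
  list(value = v_tmp[i], idx = i)
}

#' Zero-velocity update
#'
#' Subtracts the detected velocity offset from the original (unfiltered)
#' stride velocity and zeroes all samples strictly before the detection
#' index: the foot is taken to be stationary until the offset instant.
#'
#' @param v_orig original stride velocity, m/s.
#' @param offset_value offset to subtract, m/s.
#' @param offset_idx 1-based detection index.
#' @return corrected ("final") velocity, same length as `v_orig`.
#' @export
zero_velocity_update <- function(v_orig, offset_value, offset_idx) {
  if (offset_idx < 1L || offset_idx > length(v_orig)) {
    stop("offset index out of range")
  }
  out <- v_orig - offset_value
  if (offset_idx > 1L) out[seq_len(offset_idx - 1L)] <- 0
  out
}

#' Stride displacement and length from final velocities
#'
#' @param v_final_x,v_final_z corrected velocities, m/s, equal length.
#' @param fs sampling frequency, Hz.
#' @return list with `dx`, `dz` (m) and `length = sqrt(dx^2 + dz^2)` (m).
#' @export
stride_length <- function(v_final_x, v_final_z, fs) {
  if (length(v_final_x) != length(v_final_z)) {
    stop("final velocities must have equal length")
  }
  dt <- 1 / fs
  dx <- trapz_dt(v_final_x, dt)
  dz <- trapz_dt(v_final_z, dt)
  list(dx = dx, dz = dz, length = sqrt(dx^2 + dz^2))
}

# Linear dedrift: attribute any nonzero velocity at the stride end (the next
# touch-down, where the foot is again momentarily stationary) to integration
# drift and remove it as a linear ramp.
linear_dedrift <- function(v) {
  n <- length(v)
  if (n < 2L) return(v)
  v - (seq_len(n) - 1L) / (n - 1L) * v[n]
}

#' Process one sprint into a stride table
#'
#' Runs the full per-foot pipeline: stride segmentation, per-axis
#' integration and mirroring, touch-down-artefact offset detection, the
#' zero-velocity update, and double integration to stride length. Stride
#' speed is stride length divided by stride duration; the maximum over the
#' sprint is stored in the `max_stride_speed` attribute.
#'
#' @param sprint [global_sprint()].
#' @param ev [gait_events()]; defaults to the events carried by `sprint`.
#' @param cfg configuration, see [ss_config()]. Set `zvu.enabled = FALSE`
#'   to bypass the offset correction (for mechanism studies) and
#'   `dedrift.linear = TRUE` to additionally remove a linear velocity drift
#'   over each corrected stride.
#' @param participant,sprint_id,effort labels copied into the table;
#'   `effort` one of 60, 80, 100 or `"unknown"`.
#' @return data.frame of class `stride_table`, one row per complete stride,
#'   stride indices consecutive from 1. Columns: `participant`, `sprint`,
#'   `effort`, `foot`, `stride_index`, `td_time_s`, `to_time_s`,
#'   `duration_s`, `length_m`, `speed_m_s`, `dx_m`, `dz_m`,
#'   `offset_vx_m_s`, `offset_vz_m_s`, `offset_index_x`, `offset_index_z`,
#'   `mirrored_x`, `mirrored_z`, `qc_flags`.
#' @export
process_sprint <- function(sprint, ev = NULL, cfg = ss_config(),
                           participant = "P01", sprint_id = "S01",
                           effort = "unknown") {
  ev <- ev %||% sprint$events
  if (is.null(ev)) {
    stop("no gait events: supply `ev` or a sprint with events ",
         "(detect them from the raw recording with detect_events())")
  }
  effort <- as.character(effort)
  if (!effort %in% c("60", "80", "100", "unknown")) {
    stop("effort must be one of 60, 80, 100, unknown")
  }
  fs <- sprint$fs
  segs <- segment_strides(ev, fs, length(sprint$t), cfg = cfg)
  lo <- cfg[["zvu.window_lo_s"]]
  rows <- list()
  for (seg in segs) {
    qc <- character(0)
    res <- tryCatch({
      v <- integrate_and_mirror(seg, sprint)
      correction_applies <- seg$stride_index >= 2L && isTRUE(cfg[["zvu.enabled"]])
      off_x <- off_z <- list(value = NA_real_, idx = NA_integer_)
      if (correction_applies) {
        contact_s <- (seg$contact_end_idx - seg$td_idx) / fs
        if (!is.na(contact_s) && contact_s < lo) {
          stop("stance shorter than the offset-search lower bound (",
               round(contact_s * 1e3), " ms)")
        }
        hi <- if (seg$stride_index == 2L) cfg[["zvu.window_hi_stride2_s"]]
              else cfg[["zvu.window_hi_s"]]
        tmp_x <- temporary_velocity(v$vx, fs, cfg)
        tmp_z <- temporary_velocity(v$vz, fs, cfg)
        off_x <- find_offset(tmp_x, fs, lo, hi)
        off_z <- find_offset(tmp_z, fs, lo, hi)
        vfx <- zero_velocity_update(v$vx, off_x$value, off_x$idx)
        vfz <- zero_velocity_update(v$vz, off_z$value, off_z$idx)
      } else {
        vfx <- v$vx; vfz <- v$vz
        if (seg$stride_index >= 2L) qc <- c(qc, "zvu_bypassed")
      }
      if (isTRUE(cfg[["dedrift.linear"]])) {
        vfx <- linear_dedrift(vfx); vfz <- linear_dedrift(vfz)
        qc <- c(qc, "linear_dedrift")
      }
      geom <- stride_length(vfx, vfz, fs)
      duration <- (seg$end_idx - seg$start_idx) / fs
      if (seg$stride_index == 1L) qc <- c(qc, "stride1_no_td")
      data.frame(
        participant = participant, sprint = sprint_id, effort = effort,
        foot = seg$foot, stride_index = seg$stride_index,
        td_time_s = if (is.na(seg$td_idx)) NA_real_ else sprint$t[seg$td_idx],
        to_time_s = if (is.na(seg$contact_end_idx)) NA_real_
                    else sprint$t[seg$contact_end_idx],
        duration_s = duration, length_m = geom$length,
        speed_m_s = geom$length / duration,
        dx_m = geom$dx, dz_m = geom$dz,
        offset_vx_m_s = off_x$value, offset_vz_m_s = off_z$value,
        offset_index_x = off_x$idx, offset_index_z = off_z$idx,
        mirrored_x = v$mirrored_x, mirrored_z = v$mirrored_z,
        qc_flags = paste(qc, collapse = ";"),
        stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("stride %d (%s) skipped: %s", seg$stride_index,
                      seg$foot, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_stride_table()
  class(out) <- c("stride_table", "data.frame")
  attr(out, "max_stride_speed") <- if (nrow(out)) max(out$speed_m_s) else NA_real_
  out
}

empty_stride_table <- function() {
  data.frame(participant = character(0), sprint = character(0),
             effort = character(0), foot = character(0),
             stride_index = integer(0), td_time_s = numeric(0),
             to_time_s = numeric(0), duration_s = numeric(0),
             length_m = numeric(0), speed_m_s = numeric(0),
             dx_m = numeric(0), dz_m = numeric(0),
             offset_vx_m_s = numeric(0), offset_vz_m_s = numeric(0),
             offset_index_x = integer(0), offset_index_z = integer(0),
             mirrored_x = logical(0), mirrored_z = logical(0),
             qc_flags = character(0), stringsAsFactors = FALSE)
}

#' Maximal stride speed of a stride table
#'
#' The highest stride speed reached over a sprint (length / duration of the
#' fastest stride), the per-sprint summary measure of sprint performance.
#'
#' @param table stride table from [process_sprint()].
#' @return numeric scalar, m/s (`NA` for an empty table).
#' @export
max_stride_speed <- function(table) {
  if (!nrow(table)) return(NA_real_)
  max(table$speed_m_s)
}
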