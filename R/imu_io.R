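# Reading raw IMU logs and global-frame sprint files; writing stride tables.
#
# All readers tolerate '#'-prefixed comment lines (used for provenance
# stamping of files written by this package).

G_DEFAULT <- 9.81       # m/s^2 per g, configurable in the readers
ACC_RANGE_G <- 16.0     # sensor specific-force range, g
GYR_RANGE_DPS <- 2000   # sensor angular-rate range, deg/s

#' Construct an IMU recording
#'
#' Container for the time-synchronized raw streams of one foot-mounted
#' sensor, in SI units (specific force in m/s^2, angular rate in rad/s,
#' magnetic field in uT). Samples whose magnitude reaches the sensor range
#' (±16 g, ±2000 deg/s) are flagged as saturated, never clipped.
#'
#' @param t time stamps, seconds, strictly increasing.
#' @param acc n x 3 specific force, m/s^2.
#' @param gyr n x 3 angular rate, rad/s.
#' @param mag optional n x 3 magnetic field, uT.
#' @param fs sampling frequency, Hz.
#' @param foot `"left"` or `"right"`.
#' @param g gravitational constant used for the saturation threshold.
#' @return object of class `imu_recording`.
#' @export
imu_recording <- function(t, acc, gyr, mag = NULL, fs, foot = c("left", "right"),
                          g = G_DEFAULT) {
  foot <- match.arg(foot)
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  dimnames(acc) <- NULL; dimnames(gyr) <- NULL
  n <- length(t)
  if (nrow(acc) != n || nrow(gyr) != n) {
    stop("t, acc and gyr must have the same number of samples")
  }
  if (ncol(acc) != 3L || ncol(gyr) != 3L) stop("acc and gyr must have 3 columns")
  if (!is.null(mag)) {
    mag <- as.matrix(mag)
    dimnames(mag) <- NULL
    if (nrow(mag) != n || ncol(mag) != 3L) stop("mag must be n x 3")
  }
  if (n == 0L) stop("empty recording")
  if (any(diff(t) <= 0)) stop("time stamps must be strictly increasing")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  sat <- list(
    acc = abs(acc) >= ACC_RANGE_G * g - 1e-9,
    gyr = abs(gyr) >= GYR_RANGE_DPS * pi / 180 - 1e-9
  )
  structure(list(t = as.numeric(t), acc = acc, gyr = gyr, mag = mag,
                 fs = fs, foot = foot, saturation = sat),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> foot=%s  n=%d  fs=%g Hz  duration=%.2f s\n",
              x$foot, length(x$t), x$fs, diff(range(x$t))))
  n_sat <- sum(x$saturation$acc) + sum(x$saturation$gyr)
  cat(sprintf("  magnetometer: %s   saturated samples: %d\n",
              if (is.null(x$mag)) "absent" else "present", n_sat))
  invisible(x)
}

#' Read a raw IMU log from delimited text
#'
#' Expects a header naming (at least) an accelerometer triplet
#' `acc_x, acc_y, acc_z` and a gyroscope triplet `gyr_x, gyr_y, gyr_z`;
#' optionally `t` (seconds) and `mag_x, mag_y, mag_z`. Input units are
#' declared via `unit_spec` and converted to SI on read. When the log has no
#' time column, time stamps are reconstructed from `fs`.
#'
#' @param path file path (CSV, or TSV when the header contains tabs).
#' @param unit_spec list with elements `acc` (`"g"` or `"m_s2"`) and `gyr`
#'   (`"deg_s"` or `"rad_s"`).
#' @param fs sampling frequency, Hz; required when the file has no `t`
#'   column, otherwise inferred from the median time step when `NULL`.
#' @param foot foot label.
#' @param g conversion constant, m/s^2 per g (default 9.81).
#' @return [imu_recording()]. Gaps longer than 2 nominal sample periods are
#'   reported with a warning.
#' @export
read_raw_log <- function(path, unit_spec = list(acc = "g", gyr = "deg_s"),
                         fs = NULL, foot = "left", g = G_DEFAULT) {
  df <- read_delimited(path)
  if (nrow(df) == 0L) stop("empty file: ", path)
  need_acc <- c("acc_x", "acc_y", "acc_z")
  need_gyr <- c("gyr_x", "gyr_y", "gyr_z")
  missing_cols <- setdiff(c(need_acc, need_gyr), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  acc <- as.matrix(df[need_acc])
  gyr <- as.matrix(df[need_gyr])
  acc_unit <- match.arg(unit_spec$acc %||% "g", c("g", "m_s2"))
  gyr_unit <- match.arg(unit_spec$gyr %||% "deg_s", c("deg_s", "rad_s"))
  if (acc_unit == "g") acc <- acc * g
  if (gyr_unit == "deg_s") gyr <- gyr * pi / 180
  mag <- NULL
  if (all(c("mag_x", "mag_y", "mag_z") %in% names(df))) {
    mag <- as.matrix(df[c("mag_x", "mag_y", "mag_z")])
  }
  if ("t" %in% names(df)) {
    t <- df$t
    if (any(diff(t) <= 0)) stop("non-monotonic time stamps in ", path)
    if (is.null(fs)) fs <- 1 / median(diff(t))
    gap <- which(diff(t) > 2 / fs)
    if (length(gap)) {
      warning(sprintf("%d gap(s) longer than 2 sample periods (first after t = %.4f s)",
                      length(gap), t[gap[1L]]))
    }
  } else {
    if (is.null(fs)) stop("file has no time column; supply `fs`")
    t <- (seq_len(nrow(df)) - 1) / fs
  }
  imu_recording(t, acc, gyr, mag, fs = fs, foot = foot, g = g)
}

#' Construct a global-frame sprint
#'
#' Acceleration of one foot expressed in the earth-fixed global frame
#' (y up, x along the initial horizontal reference direction, z transverse),
#' with gravity removed. The horizontal components `acc_x` and `acc_z` are
#' the integrands of the stride-length pipeline; `acc_y` is carried but
#' unused by the core.
#'
#' @param t time stamps, seconds.
#' @param acc_x,acc_y,acc_z global-frame acceleration components, m/s^2.
#' @param fs sampling frequency, Hz.
#' @param foot foot label.
#' @param events optional [gait_events()] with indices into the signal.
#' @return object of class `global_sprint`.
#' @export
global_sprint <- function(t, acc_x, acc_y, acc_z, fs, foot = c("left", "right"),
                          events = NULL) {
  foot <- match.arg(foot)
  n <- length(t)
  if (length(acc_x) != n || length(acc_y) != n || length(acc_z) != n) {
    stop("all acceleration components must match the length of t")
  }
  if (n == 0L) stop("empty sprint")
  if (fs <= 0) stop("fs must be positive")
  if (!is.null(events)) {
    idx <- c(events$td, events$to)
    if (length(idx) && (min(idx) < 1L || max(idx) > n)) {
      stop("event indices out of range of the signal (n = ", n, ")")
    }
  }
  structure(list(t = as.numeric(t), acc_x = as.numeric(acc_x),
                 acc_y = as.numeric(acc_y), acc_z = as.numeric(acc_z),
                 fs = fs, foot = foot, events = events),
            class = "global_sprint")
}

#' @export
print.global_sprint <- function(x, ...) {
  cat(sprintf("<global_sprint> foot=%s  n=%d  fs=%g Hz  duration=%.2f s  events: %s\n",
              x$foot, length(x$t), x$fs, diff(range(x$t)),
              if (is.null(x$events)) "none"
              else sprintf("%d TD / %d TO", length(x$events$td), length(x$events$to))))
  invisible(x)
}

#' Read a global-frame sprint file
#'
#' Dispatches by sniffing the header over two layouts: (a) a column-named
#' delimited file with `t, acc_x, acc_y, acc_z` and optional metadata in
#' `#`-comment lines (`# fs:`, `# foot:`); (b) the same matrix with gait
#' events in a sidecar file `<stem>_events.csv` holding columns
#' `type` (`td`/`to`) and `index` (1-based sample index). `fs` is inferred
#' from the time stamps when not given in a header comment.
#'
#' @param path file path.
#' @return [global_sprint()] with `events` populated when a sidecar is found.
#' @export
read_global_sprint <- function(path) {
  meta <- read_comment_meta(path)
  df <- read_delimited(path)
  need <- c("t", "acc_x", "acc_y", "acc_z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("unparseable global sprint layout in ", path,
         " (missing: ", paste(missing_cols, collapse = ", "), ")")
  }
  fs <- meta$fs %||% (1 / median(diff(df$t)))
  foot <- meta$foot %||% "left"
  events <- NULL
  sidecar <- paste0(tools::file_path_sans_ext(path), "_events.csv")
  if (file.exists(sidecar)) {
    ev <- read_delimited(sidecar)
    if (!all(c("type", "index") %in% names(ev))) {
      stop("unparseable events sidecar: ", sidecar)
    }
    td <- sort(as.integer(ev$index[ev$type == "td"]))
    to <- sort(as.integer(ev$index[ev$type == "to"]))
    if (length(c(td, to)) && max(c(td, to)) > nrow(df)) {
      stop("event index out of range in ", sidecar,
           " (max ", max(c(td, to)), " > n = ", nrow(df), ")")
    }
    events <- gait_events(td = td, to = to, foot = foot)
  }
  global_sprint(df$t, df$acc_x, df$acc_y, df$acc_z, fs = fs, foot = foot,
                events = events)
}

#' Write a global-frame sprint file (+ events sidecar)
#'
#' Writes the deposit-style layout understood by [read_global_sprint()].
#' Numeric values are written with 17 significant digits so a read-back
#' reproduces them bit for bit.
#'
#' @param sprint [global_sprint()].
#' @param path output CSV path; events, when present, go to
#'   `<stem>_events.csv`.
#' @param cfg optional configuration stamped into the header.
#' @return `path`, invisibly.
#' @export
write_global_sprint <- function(sprint, path, cfg = NULL) {
  header <- c(provenance_header(cfg),
              sprintf("# fs: %s", format(sprint$fs, digits = 17)),
              sprintf("# foot: %s", sprint$foot))
  df <- data.frame(t = sprint$t, acc_x = sprint$acc_x,
                   acc_y = sprint$acc_y, acc_z = sprint$acc_z)
  write_precise_csv(df, path, header)
  if (!is.null(sprint$events)) {
    ev <- sprint$events
    sidecar <- paste0(tools::file_path_sans_ext(path), "_events.csv")
    edf <- data.frame(
      type = c(rep("td", length(ev$td)), rep("to", length(ev$to))),
      index = c(ev$td, ev$to))
    edf <- edf[order(edf$index), , drop = FALSE]
    write_precise_csv(edf, sidecar, provenance_header(cfg))
  }
  invisible(path)
}

#' Write a stride table to CSV
#'
#' One row per stride; numeric columns keep full (17 significant digits)
#' precision so that a read-back reproduces the values exactly.
#'
#' @param table stride table from [process_sprint()].
#' @param path output CSV path.
#' @param cfg optional configuration stamped into the header.
#' @return `path`, invisibly. Writing an empty table produces a header-only
#'   file with a warning.
#' @export
write_stride_table <- function(table, path, cfg = NULL) {
  if (nrow(table) == 0L) warning("writing an empty stride table: ", path)
  write_precise_csv(as.data.frame(table), path, provenance_header(cfg))
  invisible(path)
}

#' Read a stride table written by [write_stride_table()]
#' @param path CSV path.
#' @return data.frame of class `stride_table`.
#' @export
read_stride_table <- function(path) {
  df <- read_delimited(path)
  dbl_cols <- c("td_time_s", "to_time_s", "duration_s", "length_m",
                "speed_m_s", "dx_m", "dz_m", "offset_vx_m_s", "offset_vz_m_s")
  int_cols <- c("stride_index", "offset_index_x", "offset_index_z")
  chr_cols <- c("participant", "sprint", "effort", "foot", "qc_flags")
  for (col in intersect(dbl_cols, names(df))) df[[col]] <- as.double(df[[col]])
  for (col in intersect(int_cols, names(df))) df[[col]] <- as.integer(df[[col]])
  for (col in intersect(chr_cols, names(df))) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  for (col in c("mirrored_x", "mirrored_z")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  class(df) <- c("stride_table", "data.frame")
  df
}

# --- internal text helpers -------------------------------------------------

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!startsWith(first, "#")]
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", first[1L])) "\t" else ","
  df <- utils::read.csv(path, sep = sep, comment.char = "#",
                        stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- trimws(tolower(names(df)))
  df
}

read_comment_meta <- function(path) {
  lines <- readLines(path, n = 20L, warn = FALSE)
  lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*(fs|foot)\\s*:\\s*(\\S+)", ln))[[1L]]
    if (length(m) == 3L) {
      meta[[m[2L]]] <- if (m[2L] == "fs") as.numeric(m[3L]) else m[3L]
    }
  }
  meta
}

write_precise_csv <- function(df, path, header_lines = character(0)) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  utils::write.table(out, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
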