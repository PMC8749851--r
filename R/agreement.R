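# Agreement between IMU-derived and reference stride lengths: per-stride
# percentage errors and Bland-Altman bias / limits of agreement with a
# repeated-measures variance decomposition (multiple strides per
# participant).

#' Per-stride percentage errors
#'
#' `100 * (sl_imu - sl_ref) / sl_ref` for every paired stride.
#'
#' @param pairs data.frame with numeric columns `sl_imu` and `sl_ref`
#'   (metres); typically also `participant`, `effort`, `foot`,
#'   `stride_index`.
#' @return numeric vector of percentage differences.
#' @export
percent_errors <- function(pairs) {
  if (!all(c("sl_imu", "sl_ref") %in% names(pairs))) {
    stop("`pairs` must have columns sl_imu and sl_ref")
  }
  if (any(pairs$sl_ref <= 0)) stop("sl_ref must be positive for percentage errors")
  100 * (pairs$sl_imu - pairs$sl_ref) / pairs$sl_ref
}

#' Bland-Altman agreement with repeated measures within participants
#'
#' Bias is the mean of the per-stride differences; the SD entering the
#' limits of agreement combines within- and between-participant variance
#' components obtained from a one-way random-effects (ANOVA) decomposition
#' of the differences over participants, so that repeated strides from the
#' same athlete do not narrow the limits artificially. For unbalanced data
#' the effective cluster size `m0 = (N - sum(n_i^2)/N) / (k - 1)` scales the
#' between-participant mean square. LOA = 1.96 * total SD. With fewer than
#' two participants, or a single stride per participant, the classic
#' Bland-Altman SD of the differences is used with a warning.
#'
#' @param pairs data.frame with `participant`, `sl_imu`, `sl_ref` (and any
#'   grouping columns).
#' @param scale `"percent"` (differences as % of the reference, the
#'   reporting scale of sprint stride-length validation) or `"absolute"`
#'   (metres).
#' @param by optional name of a column (e.g. `"effort"`) for per-group
#'   sub-reports.
#' @return object of class `agreement_report`: list with `bias`, `loa`,
#'   `sd_total`, `sd_within`, `sd_between`, `n_strides`, `n_participants`,
#'   `method` (`"repeated"` or `"classic"`), `scale`, and `groups` (named
#'   list of sub-reports when `by` is given).
#' @export
bland_altman_repeated <- function(pairs, scale = c("percent", "absolute"),
                                  by = NULL) {
  scale <- match.arg(scale)
  if (!"participant" %in% names(pairs)) stop("`pairs` must have a participant column")
  d <- if (scale == "percent") percent_errors(pairs)
       else pairs$sl_imu - pairs$sl_ref
  report <- .ba_core(d, as.factor(pairs$participant))
  report$scale <- scale
  if (!is.null(by)) {
    if (!by %in% names(pairs)) stop("grouping column not found: ", by)
    report$groups <- lapply(split(pairs, pairs[[by]]), function(g) {
      bland_altman_repeated(g, scale = scale)
    })
  }
  report
}

.ba_core <- function(d, participant) {
  stopifnot(length(d) == length(participant))
  participant <- droplevels(participant)
  k <- nlevels(participant)
  n_i <- as.integer(table(participant))
  N <- length(d)
  if (N == 0L) stop("no paired strides")
  bias <- mean(d)
  if (k < 2L || all(n_i == 1L)) {
    warning("fewer than 2 participants or one stride per participant: ",
            "falling back to the classic Bland-Altman SD")
    sd_tot <- if (N > 1L) sd(d) else 0
    return(structure(list(bias = bias, loa = 1.96 * sd_tot, sd_total = sd_tot,
                          sd_within = NA_real_, sd_between = NA_real_,
                          n_strides = N, n_participants = k,
                          method = "classic", groups = NULL),
                     class = "agreement_report"))
  }
  fit <- stats::aov(d ~ participant)
  ms <- summary(fit)[[1L]][["Mean Sq"]]
  msb <- ms[1L]; msw <- ms[2L]
  m0 <- (N - sum(n_i^2) / N) / (k - 1L)
  var_between <- max(0, (msb - msw) / m0)
  var_total <- var_between + msw
  sd_tot <- sqrt(var_total)
  structure(list(bias = bias, loa = 1.96 * sd_tot, sd_total = sd_tot,
                 sd_within = sqrt(msw), sd_between = sqrt(var_between),
                 n_strides = N, n_participants = k,
                 method = "repeated", groups = NULL),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  unit <- if (identical(x$scale, "absolute")) "m" else "%"
  cat(sprintf("<agreement_report> %s scale, %s method\n", x$scale, x$method))
  cat(sprintf("  bias %+.3f%s  (±%.3f%s LOA)   n = %d strides, %d participants\n",
              x$bias, unit, x$loa, unit, x$n_strides, x$n_participants))
  if (!is.null(x$groups)) {
    for (nm in names(x$groups)) {
      g <- x$groups[[nm]]
      cat(sprintf("  [%s] bias %+.3f%s (±%.3f%s), n = %d\n",
                  nm, g$bias, unit, g$loa, unit, g$n_strides))
    }
  }
  invisible(x)
}

#' Convert an agreement report to a plain list (for JSON output)
#' @param x `agreement_report`.
#' @export
agreement_as_list <- function(x) {
  out <- x[c("bias", "loa", "sd_total", "sd_within", "sd_between",
             "n_strides", "n_participants", "method", "scale")]
  if (!is.null(x$groups)) out$groups <- lapply(x$groups, agreement_as_list)
  out
}

#' Simulate paired stride lengths with known agreement structure
#'
#' Generates IMU/reference stride-length pairs whose percentage differences
#' have a known bias and a known total SD split into between-participant
#' and within-participant components — the recovery target for validating
#' [bland_altman_repeated()].
#'
#' @param n_participants number of participants.
#' @param n_strides strides per participant.
#' @param bias true mean percentage difference.
#' @param sd_total true total SD of the percentage differences.
#' @param sd_between between-participant SD component (must be below
#'   `sd_total`); the within component is
#'   `sqrt(sd_total^2 - sd_between^2)`.
#' @param seed RNG seed.
#' @return data.frame with `participant`, `stride_index`, `sl_ref`,
#'   `sl_imu`.
#' @export
simulate_agreement_pairs <- function(n_participants = 20, n_strides = 50,
                                     bias = -1.0, sd_total = 3.5,
                                     sd_between = 1.0, seed = 1) {
  if (sd_between >= sd_total) stop("sd_between must be below sd_total")
  sd_within <- sqrt(sd_total^2 - sd_between^2)
  with_seed(seed, {
    rows <- lapply(seq_len(n_participants), function(i) {
      b_i <- rnorm(1L, 0, sd_between)
      sl_ref <- runif(n_strides, 2.0, 4.5)
      d_pct <- bias + b_i + rnorm(n_strides, 0, sd_within)
      data.frame(participant = sprintf("P%02d", i),
                 stride_index = seq_len(n_strides),
                 sl_ref = sl_ref,
                 sl_imu = sl_ref * (1 + d_pct / 100),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
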