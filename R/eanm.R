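#' Constants of the closed-form SOP single-time-point estimator
#'
#' The standard-operating-procedure estimator maps one late retention
#' measurement directly to a TIA with fixed constants: an early window
#' (1-3 days) using a 0.97 scale factor and a 5.5-day reference effective
#' half-life, and a late window (4-8 days) dividing by 0.357. Between 3 and
#' 4 days no formula is defined.
#'
#' @return A list with `scale_early` (0.97), `halflife_early_d` (5.5),
#'   `denom_late` (0.357), `early_window_d` (c(1, 3)), `late_window_d`
#'   (c(4, 8)).
#' @export
sop_constants <- function() {
  list(scale_early = 0.97, halflife_early_d = 5.5, denom_late = 0.357,
       early_window_d = c(1, 3), late_window_d = c(4, 8))
}

#' Closed-form SOP single-time-point TIA (hTIA)
#'
#' Converts a single measured retention fraction \eqn{A(t)} into a TIA:
#' \deqn{hTIA = 0.97\, A(t)\, 2^{t/5.5\,d}\; 5.5\,d/\ln 2
#'   \quad (1\,d \le t \le 3\,d)}
#' \deqn{hTIA = A(t)\; t / 0.357 \quad (4\,d \le t \le 8\,d)}
#' Window boundaries are inclusive; in the undefined gap (3, 4) days and
#' outside 1-8 days the estimator raises an error rather than
#' interpolating. Input times are in hours (converted to days internally);
#' the result is returned in hours. No physical-decay correction is added:
#' the measured activity already includes decay, which is exactly what the
#' formulas expect.
#'
#' @param activity Measured retention fraction(s) `A(t)`, >= 0.
#' @param time_h Measurement time(s) in hours, > 0 (recycled against
#'   `activity`).
#' @return Numeric vector of TIAs in hours.
#' @examples
#' htia(0.4, 48)    # early window
#' htia(0.3, 120)   # late window
#' @export
htia <- function(activity, time_h) {
  if (any(!is.finite(activity)) || any(activity < 0))
    stop("activity must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(time_h)) || any(time_h <= 0))
    stop("time_h must be finite and > 0", call. = FALSE)
  n <- max(length(activity), length(time_h))
  activity <- rep_len(activity, n)
  time_h <- rep_len(time_h, n)
  k <- sop_constants()
  t_d <- time_h / 24
  early <- t_d >= k$early_window_d[1] & t_d <= k$early_window_d[2]
  late <- t_d >= k$late_window_d[1] & t_d <= k$late_window_d[2]
  if (any(!early & !late))
    stop("measurement time outside the defined SOP windows ",
         "[1, 3] d and [4, 8] d: ",
         paste(unique(time_h[!early & !late]), collapse = ", "), " h",
         call. = FALSE)
  out <- numeric(n)
  out[early] <- k$scale_early * activity[early] *
    2^(t_d[early] / k$halflife_early_d) *
    (k$halflife_early_d * 24) / log(2)
  out[late] <- activity[late] * time_h[late] / k$denom_late
  out
}

#' SOP hTIA estimates for a record table
#'
#' Applies [htia()] to every record whose measurement time lies in one of
#' the defined SOP windows and among the requested time points. Records at
#' undefined times are refused with a warning listing them, not silently
#' dropped. By convention the estimator is applied only to late
#' measurements (default 24, 48, 96 and 120 h).
#'
#' @param records Records data frame (`patient_id`, `time_h`, `retention`).
#' @param time_points Time points (h) at which to compute hTIAs.
#' @return A [tia_estimates()] table (method `hTIA`), one row per usable
#'   record. Records with zero retention (TIA 0) are refused with a
#'   warning since a TIA estimate must be positive.
#' @export
eanm_tias <- function(records, time_points = c(24, 48, 96, 120)) {
  sel <- records[records$time_h %in% time_points, , drop = FALSE]
  if (!nrow(sel))
    stop("no records at the requested SOP time points", call. = FALSE)
  k <- sop_constants()
  t_d <- sel$time_h / 24
  in_win <- (t_d >= k$early_window_d[1] & t_d <= k$early_window_d[2]) |
    (t_d >= k$late_window_d[1] & t_d <= k$late_window_d[2])
  if (any(!in_win)) {
    warning(sprintf("refusing %d record(s) outside the SOP windows (times: %s h)",
                    sum(!in_win),
                    paste(unique(sel$time_h[!in_win]), collapse = ", ")),
            call. = FALSE)
    sel <- sel[in_win, , drop = FALSE]
  }
  zero <- sel$retention <= 0
  if (any(zero)) {
    warning(sprintf("refusing %d record(s) with zero retention", sum(zero)),
            call. = FALSE)
    sel <- sel[!zero, , drop = FALSE]
  }
  if (!nrow(sel))
    stop("no usable records for the SOP estimator", call. = FALSE)
  tia_estimates(sel$patient_id, "hTIA", sel$time_h,
                htia(sel$retention, sel$time_h))
}
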