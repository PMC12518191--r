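#' Relative deviation of an estimate from its reference
#'
#' \eqn{RD = (sTIA - rTIA)/rTIA}, the per-patient accuracy measure used
#' throughout the evaluation. Vectorised; references must be positive.
#'
#' @param stia Estimated TIA value(s).
#' @param rtia Reference TIA value(s), > 0.
#' @return Numeric vector of relative deviations (fractions).
#' @examples
#' relative_deviation(1.1, 1.0)  # 0.1
#' @export
relative_deviation <- function(stia, rtia) {
  if (any(!is.finite(rtia)) || any(rtia <= 0))
    stop("reference TIA must be finite and > 0", call. = FALSE)
  (stia - rtia) / rtia
}

#' Summary accuracy statistics for a set of relative deviations
#'
#' Computes the mean RD, the SD of RDs, the RMSE
#' \eqn{\sqrt{SD^2 + mean^2}}, the MAPE (mean absolute RD), and the counts
#' of patients whose |RD| strictly exceeds 5%, 10% and 20%. The SD is the
#' population SD (divide by n) by default, which makes the RMSE identity
#' \eqn{RMSE = \sqrt{mean(RD^2)}} exact; the sample SD (divide by n-1) is
#' available for sensitivity checks.
#'
#' @param rds Numeric vector of relative deviations (fractions), length
#'   >= 1.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A one-row data frame: `n`, `mean_rd`, `sd_rd`, `rmse`, `mape`,
#'   `n_rd5`, `n_rd10`, `n_rd20` (fractions, not percent).
#' @examples
#' summarize_rd(c(0.1, -0.1))
#' @export
summarize_rd <- function(rds, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!length(rds) || any(!is.finite(rds)))
    stop("rds must be a non-empty vector of finite values", call. = FALSE)
  n <- length(rds)
  m <- mean(rds)
  s <- if (sd_type == "population") sqrt(mean((rds - m)^2))
       else stats::sd(rds)
  if (n == 1 && sd_type == "sample") s <- 0
  data.frame(n = n, mean_rd = m, sd_rd = s, rmse = sqrt(s^2 + m^2),
             mape = mean(abs(rds)),
             n_rd5 = sum(abs(rds) > 0.05),
             n_rd10 = sum(abs(rds) > 0.10),
             n_rd20 = sum(abs(rds) > 0.20))
}

#' Paired Wilcoxon signed-rank comparison of two RD sets
#'
#' Matched-pairs signed-rank test between two sets of per-patient values
#' (e.g. the RDs of two STP methods at one time point), plus the median of
#' the paired differences. Zero differences are dropped (standard signed
#' -rank convention); the exact distribution is used for n <= 25 pairs
#' without ties, otherwise the normal approximation with tie correction.
#'
#' @param rds_a,rds_b Equal-length numeric vectors, paired by patient.
#' @param exact_limit Largest n (after dropping zeros) for which the exact
#'   distribution is requested.
#' @return A list: `statistic` (V, sum of positive ranks), `p_value`
#'   (two-sided), `median_diff` (median of all paired differences,
#'   including zeros), `n_used` (pairs after dropping zeros), `degenerate`
#'   (TRUE when every difference is zero; the test is then undefined and
#'   `statistic`/`p_value` are NA).
#' @export
wilcoxon_paired <- function(rds_a, rds_b, exact_limit = 25L) {
  if (length(rds_a) != length(rds_b))
    stop("paired vectors must have equal length", call. = FALSE)
  d <- rds_a - rds_b
  if (any(!is.finite(d)))
    stop("differences must be finite", call. = FALSE)
  nz <- d[d != 0]
  if (!length(nz))
    return(list(statistic = NA_real_, p_value = NA_real_,
                median_diff = 0, n_used = 0L, degenerate = TRUE))
  if (length(nz) < 3)
    stop("need at least 3 non-zero paired differences", call. = FALSE)
  n <- length(nz)
  r <- rank(abs(nz))  # midranks for ties
  v <- sum(r[nz > 0])
  if (n <= exact_limit) {
    p <- .signed_rank_exact_p(r, v)
  } else {
    # normal approximation with tie correction and continuity correction
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = v, p_value = p,
       median_diff = stats::median(d), n_used = n,
       degenerate = FALSE)
}

# Exact two-sided p of the signed-rank statistic under equiprobable signs,
# valid with midrank ties: dynamic programming over the distribution of
# 2 x (sum of selected ranks), which is integer-valued.
.signed_rank_exact_p <- function(ranks, v) {
  s <- as.integer(round(2 * ranks))
  total <- sum(s)
  f <- numeric(total + 1)  # f[w+1] = #sign assignments with statistic w/2
  f[1] <- 1
  for (si in s) {
    g <- f
    g[(si + 1):(total + 1)] <- g[(si + 1):(total + 1)] + f[1:(total + 1 - si)]
    f <- g
  }
  f <- f / sum(f)
  w2 <- as.integer(round(2 * v))
  p_le <- sum(f[seq_len(w2 + 1)])
  p_ge <- sum(f[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Accuracy table of STP/NTP estimates against the reference TIAs
#'
#' Joins each estimate to its patient's reference TIA, computes the
#' relative deviations, and summarises them per (method, time point) group
#' with [summarize_rd()]. Rows are ordered in method blocks (`s1TIA`,
#' `s2TIA`, `hTIA`, `nTIA`) with ascending time within each block, the
#' layout of the study's performance table.
#'
#' @param estimates A [tia_estimates()] table of STP/NTP estimates.
#' @param references A [tia_estimates()] table of `rTIA` values (one per
#'   patient).
#' @param sd_type Passed to [summarize_rd()].
#' @return A data frame of class `accuracy_table`: `method`,
#'   `time_point_h`, and the [summarize_rd()] columns (fractions).
#' @export
build_accuracy_table <- function(estimates, references,
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!nrow(estimates)) stop("no estimates supplied", call. = FALSE)
  if (!nrow(references)) stop("no references supplied", call. = FALSE)
  refs <- references[references$method == "rTIA", , drop = FALSE]
  if (anyDuplicated(refs$patient_id))
    stop("multiple reference TIAs for one patient", call. = FALSE)
  missing_ref <- setdiff(unique(estimates$patient_id), refs$patient_id)
  if (length(missing_ref))
    stop("no reference TIA for patient(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  rtia <- stats::setNames(refs$tia_h, refs$patient_id)
  est <- estimates[estimates$method != "rTIA", , drop = FALSE]
  if (!nrow(est)) stop("no non-reference estimates supplied", call. = FALSE)
  est$rd <- relative_deviation(est$tia_h, rtia[est$patient_id])
  key_tp <- ifelse(is.na(est$time_point_h), -1, est$time_point_h)
  groups <- split(est, list(est$method, key_tp), drop = TRUE)
  rows <- lapply(groups, function(g)
    cbind(data.frame(method = g$method[1], time_point_h = g$time_point_h[1]),
          summarize_rd(g$rd, sd_type = sd_type)))
  out <- do.call(rbind, rows)
  method_order <- c("s1TIA", "s2TIA", "hTIA", "nTIA")
  out <- out[order(match(out$method, method_order),
                   ifelse(is.na(out$time_point_h), Inf, out$time_point_h)), ]
  rownames(out) <- NULL
  class(out) <- c("accuracy_table", "data.frame")
  out
}

#' Percent-formatted accuracy table
#'
#' Converts the fraction-valued columns of an [build_accuracy_table()]
#' result to percent for reporting (the internal representation stays in
#' fractions).
#'
#' @param tab An `accuracy_table`.
#' @param digits Rounding applied to the percent columns.
#' @return A plain data frame with `mean_rd_pct`, `sd_rd_pct`, `rmse_pct`,
#'   `mape_pct` and the counts.
#' @export
format_accuracy_table <- function(tab, digits = 1) {
  stopifnot(inherits(tab, "accuracy_table"))
  data.frame(method = tab$method, time_point_h = tab$time_point_h,
             n = tab$n,
             mean_rd_pct = round(100 * tab$mean_rd, digits),
             sd_rd_pct = round(100 * tab$sd_rd, digits),
             rmse_pct = round(100 * tab$rmse, digits),
             mape_pct = round(100 * tab$mape, digits),
             n_rd5 = tab$n_rd5, n_rd10 = tab$n_rd10, n_rd20 = tab$n_rd20)
}
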