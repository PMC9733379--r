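## Accuracy metrics for measured-vs-estimated series. Two coefficients of
## determination are reported side by side: the variance-ratio form used in
## parts of the phenotyping literature, and the conventional 1 - SSres/SStot.

check_paired <- function(measured, estimated, min_n = 1) {
  if (length(measured) != length(estimated))
    stop_validation("measured (%d) and estimated (%d) lengths differ",
                    length(measured), length(estimated))
  if (length(measured) < min_n)
    stop_validation("need at least %d paired values", min_n)
  if (anyNA(measured) || anyNA(estimated))
    stop_validation("paired series contain missing values")
  invisible(TRUE)
}

#' Mean absolute error
#' @param measured,estimated Numeric vectors of equal length.
#' @return `mean(|measured - estimated|)`.
#' @export
mae <- function(measured, estimated) {
  check_paired(measured, estimated)
  mean(abs(measured - estimated))
}

#' Root mean square error
#' @inheritParams mae
#' @return `sqrt(mean((measured - estimated)^2))`.
#' @export
rmse <- function(measured, estimated) {
  check_paired(measured, estimated)
  sqrt(mean((measured - estimated)^2))
}

#' Variance-ratio coefficient of determination
#'
#' \eqn{R^2 = \sum (e_i - \bar c)^2 / \sum (c_i - \bar c)^2} with
#' \eqn{\bar c} the mean of the measured series. Unlike the conventional
#' definition this is a dispersion ratio: it is not bounded above by 1 and
#' can exceed 1 when estimates over-disperse relative to measurements.
#'
#' @inheritParams mae
#' @return Non-negative ratio (1 when estimates equal measurements).
#' @export
r2_ratio <- function(measured, estimated) {
  check_paired(measured, estimated, min_n = 2)
  h_bar <- mean(measured)
  ss_meas <- sum((measured - h_bar)^2)
  if (ss_meas == 0)
    stop_degenerate("measured series has zero variance; R^2 undefined")
  sum((estimated - h_bar)^2) / ss_meas
}

#' Conventional coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum (c_i - e_i)^2 / \sum (c_i - \bar c)^2}; at most 1,
#' negative when the estimates are worse than the measured mean.
#'
#' @inheritParams mae
#' @export
r2_standard <- function(measured, estimated) {
  check_paired(measured, estimated, min_n = 2)
  h_bar <- mean(measured)
  ss_meas <- sum((measured - h_bar)^2)
  if (ss_meas == 0)
    stop_degenerate("measured series has zero variance; R^2 undefined")
  1 - sum((measured - estimated)^2) / ss_meas
}

#' Metrics block for a measured-vs-estimated comparison
#'
#' @inheritParams mae
#' @return One-row data frame: `mae`, `rmse`, `r2_ratio`, `r2_standard`, `n`.
#' @export
metrics_report <- function(measured, estimated) {
  data.frame(mae = mae(measured, estimated),
             rmse = rmse(measured, estimated),
             r2_ratio = r2_ratio(measured, estimated),
             r2_standard = r2_standard(measured, estimated),
             n = length(measured))
}
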