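#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value by the sum-of-small-probabilities rule: with
#' margins fixed, sum the hypergeometric probabilities of all tables whose
#' probability does not exceed that of the observed table (within a 1e-7
#' relative slack for floating point).
#'
#' @param tab 2x2 matrix of non-negative integer counts; rows are arms,
#'   columns outcome yes/no.
#' @return p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(matrix(c(6, 6, 2, 10), 2, byrow = TRUE))  # 0.193
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(tab) == 0) stop("empty table", call. = FALSE)
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Continuous-glucose-monitor time in range
#'
#' Percentage of sensor readings with glucose within `[lo, hi]` mmol/L
#' (bounds inclusive; defaults 3.9 and 10.0). Readings are weighted
#' equally; at the device's regular 15-min cadence this approximates
#' time-weighting.
#'
#' @param trace data.frame with `minute` (strictly increasing) and
#'   `glucose_mmol_l`, or a numeric vector of readings.
#' @param lo,hi range bounds in mmol/L.
#' @return percent in \[0, 100\].
#' @export
time_in_range <- function(trace, lo = 3.9, hi = 10.0) {
  g <- if (is.data.frame(trace)) {
    stop_if_not_cols(trace, c("minute", "glucose_mmol_l"), "trace")
    if (any(diff(trace$minute) <= 0))
      stop("timestamps must be strictly increasing", call. = FALSE)
    trace$glucose_mmol_l
  } else as.numeric(trace)
  if (length(g) == 0L) stop("empty trace", call. = FALSE)
  100 * mean(g >= lo & g <= hi)
}

ogtt_grid <- c(0, 15, 30, 45, 60, 90, 120)

#' Total area under an oral glucose tolerance test curve
#'
#' Trapezoidal rule over the standard sampling grid 0, 15, 30, 45, 60, 90,
#' 120 minutes. All seven timepoints must be present.
#'
#' @param curve data.frame with `minute` and `glucose_mmol_l` (any analyte
#'   in mmol/L works).
#' @return AUC in mmol/L x min.
#' @examples
#' curve <- data.frame(minute = c(0, 15, 30, 45, 60, 90, 120),
#'                     glucose_mmol_l = 5)
#' ogtt_auc(curve)  # 600
#' @export
ogtt_auc <- function(curve) {
  stop_if_not_cols(curve, c("minute", "glucose_mmol_l"), "curve")
  if (!setequal(curve$minute, ogtt_grid) ||
      nrow(curve) != length(ogtt_grid))
    stop("OGTT curve must contain exactly minutes 0,15,30,45,60,90,120",
         call. = FALSE)
  curve <- curve[order(curve$minute), , drop = FALSE]
  t <- curve$minute; g <- curve$glucose_mmol_l
  sum(diff(t) * (utils::head(g, -1) + utils::tail(g, -1)) / 2)
}

#' Homeostatic model assessment of insulin resistance (HOMA1-IR)
#'
#' `HOMA-IR = fasting glucose (mmol/L) x fasting insulin (uU/mL) / 22.5`.
#' Insulin must come with an explicit unit: `"uU_per_mL"`, `"pmol_per_L"`
#' (divided by 6.945) or `"nmol_per_L"` (x 1000, then divided by 6.945).
#'
#' @param glucose_mmol_l fasting glucose in mmol/L (> 0).
#' @param insulin fasting insulin (> 0) in the declared unit.
#' @param insulin_unit one of `"uU_per_mL"`, `"pmol_per_L"`, `"nmol_per_L"`.
#' @return HOMA-IR value.
#' @examples
#' homa_ir(5.0, 12, "uU_per_mL")  # 2.667
#' @export
homa_ir <- function(glucose_mmol_l, insulin,
                    insulin_unit = c("uU_per_mL", "pmol_per_L",
                                     "nmol_per_L")) {
  insulin_unit <- match.arg(insulin_unit)
  if (any(glucose_mmol_l <= 0) || any(insulin <= 0))
    stop("glucose and insulin must be positive", call. = FALSE)
  uu <- switch(insulin_unit,
               uU_per_mL = insulin,
               pmol_per_L = insulin / 6.945,
               nmol_per_L = insulin * 1000 / 6.945)
  glucose_mmol_l * uu / 22.5
}
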