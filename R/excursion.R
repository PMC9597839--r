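#' Mean of the values in a rank-percentile band
#'
#' Sorts the non-missing values ascending and averages those whose
#' rank-percentile falls inside \code{[lo, hi)}. The rank-percentile of the
#' value at 0-based sorted position \code{i} of \code{n} is
#' \code{100 * (i + 0.5) / n}, so for example the (90, 95) band of the
#' integers 1..100 is {91, ..., 95}. Trimming the extreme 5 percent at each
#' end before averaging the next 5-percent band makes the excursion
#' statistics robust to occasional gross marker misplacements.
#'
#' @param values numeric vector; \code{NA}s are ignored.
#' @param lo,hi band limits in percent, \code{0 <= lo < hi <= 100}.
#' @return The band mean (a single number).
#' @examples
#' percentile_band_mean(1:100, 90, 95)  # 93
#' percentile_band_mean(1:100, 0, 100)  # plain mean, 50.5
#' @export
percentile_band_mean <- function(values, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || hi > 100 || lo >= hi) {
    stop("band limits must satisfy 0 <= lo < hi <= 100")
  }
  v <- sort(values[!is.na(values)])
  n <- length(v)
  if (n == 0L) stop("insufficient data: no non-missing values")
  p <- 100 * (seq_len(n) - 0.5) / n
  keep <- p >= lo & p < hi
  if (!any(keep)) {
    stop("insufficient data: percentile band (", lo, ", ", hi, ") is empty ",
         "for n = ", n)
  }
  mean(v[keep])
}

#' Trimmed excursion statistics of one coordinate series
#'
#' Computes the trimmed maxima mean (rank-percentile band 90--95), the
#' trimmed minima mean (band 5--10) and their span for one axis of a
#' bodypart track. The extreme 5 percent at each end are excluded as likely
#' marker-placement errors; the adjacent 5-percent bands represent the
#' highest and lowest reliably measured values. The span is the excursion
#' length: horizontal travel for a protraction marker, vertical displacement
#' for a height marker.
#'
#' The series should already be likelihood-filtered
#' (\code{\link{filter_by_likelihood}}); missing frames are ignored.
#'
#' @param series a \code{\link{keypoint_series}}.
#' @param axis \code{"x"} (horizontal) or \code{"y"} (vertical).
#' @param bands list of two 2-vectors: the maxima and minima percentile
#'   bands.
#' @param context optional label (bodypart/trial) used in error messages.
#' @return An object of class \code{excursion_stats}: list with
#'   \code{max_mean}, \code{min_mean}, \code{span} (all px) and
#'   \code{n_used}.
#' @export
excursion_stats <- function(series, axis = c("x", "y"),
                            bands = list(max = c(90, 95), min = c(5, 10)),
                            context = NULL) {
  stopifnot(inherits(series, "keypoint_series"))
  axis <- match.arg(axis)
  v <- series[[axis]]
  n_used <- sum(!is.na(v))
  if (n_used < 20L) {
    stop("insufficient data", if (!is.null(context)) paste0(" for ", context),
         ": need >= 20 usable frames, have ", n_used)
  }
  max_mean <- percentile_band_mean(v, bands$max[1L], bands$max[2L])
  min_mean <- percentile_band_mean(v, bands$min[1L], bands$min[2L])
  structure(list(max_mean = max_mean, min_mean = min_mean,
                 span = abs(max_mean - min_mean), n_used = n_used,
                 axis = axis),
            class = "excursion_stats")
}

#' @export
print.excursion_stats <- function(x, ...) {
  cat(sprintf(
    "<excursion_stats> axis %s: max_mean %.2f, min_mean %.2f, span %.2f (n_used %d)\n",
    x$axis, x$max_mean, x$min_mean, x$span, x$n_used))
  invisible(x)
}

#' Round half away from zero
#'
#' Printed clinical tables round halves away from zero (0.545 becomes 0.55),
#' whereas base \code{round()} rounds half to even. A tiny epsilon absorbs
#' the binary representation error of decimal inputs.
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return \code{x} rounded.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
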