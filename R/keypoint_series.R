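#' Per-frame track of one bodypart
#'
#' A keypoint series holds one bodypart's pose-estimation output: pixel
#' coordinates \code{x}, \code{y} (image convention, y grows downward) and a
#' per-frame detection \code{likelihood} in [0, 1]. Frames excluded by the
#' likelihood filter are carried as \code{NA} coordinates so frame indices
#' stay aligned across bodyparts; they are never dropped.
#'
#' @param x,y numeric pixel coordinates, one value per frame; \code{NA}
#'   marks a missing frame.
#' @param likelihood numeric per-frame detection confidence in [0, 1].
#' @return An object of class \code{keypoint_series}: a list with fields
#'   \code{x}, \code{y}, \code{likelihood} and \code{n_frames}.
#' @examples
#' ks <- keypoint_series(x = c(10, 11, 12), y = c(20, 21, 22),
#'                       likelihood = c(0.9, 0.8, 0.7))
#' ks$n_frames
#' @export
keypoint_series <- function(x, y, likelihood) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  likelihood <- as.numeric(likelihood)
  n <- length(x)
  if (length(y) != n || length(likelihood) != n) {
    stop("x, y and likelihood must have equal length")
  }
  if (any(!is.na(x) & !is.finite(x)) || any(!is.na(y) & !is.finite(y))) {
    stop("coordinates must be finite or NA")
  }
  lik_ok <- is.na(likelihood) | (likelihood >= 0 & likelihood <= 1)
  if (!all(lik_ok)) {
    stop("likelihood values must lie in [0, 1] (offending frame ",
         which(!lik_ok)[1L], ")")
  }
  structure(list(x = x, y = y, likelihood = likelihood, n_frames = n),
            class = "keypoint_series")
}

#' @export
print.keypoint_series <- function(x, ...) {
  n_miss <- sum(is.na(x$x))
  cat("<keypoint_series> ", x$n_frames, " frames (", n_miss, " missing)\n",
      sep = "")
  invisible(x)
}

#' Mark low-confidence frames as missing
#'
#' Frames whose detection likelihood is strictly below \code{threshold} get
#' \code{NA} coordinates. The frame count and ordering are preserved so that
#' all bodyparts of a trial stay frame-aligned. The default cut of 0.60
#' discards detections the network itself is unsure about, at the cost of a
#' small fraction of frames.
#'
#' @param series a \code{\link{keypoint_series}}.
#' @param threshold confidence cut in [0, 1]; frames with
#'   \code{likelihood < threshold} are excluded (strict inequality, so a
#'   frame at exactly the threshold is kept).
#' @return The filtered \code{keypoint_series}; the number of usable frames
#'   is available as its \code{n_used} field.
#' @examples
#' ks <- keypoint_series(1:3, 1:3, c(0.9, 0.59, 0.61))
#' filter_by_likelihood(ks)$x   # frame 2 masked
#' @export
filter_by_likelihood <- function(series, threshold = 0.60) {
  stopifnot(inherits(series, "keypoint_series"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0, 1]")
  }
  drop <- !is.na(series$likelihood) & series$likelihood < threshold
  out <- series
  out$x[drop] <- NA_real_
  out$y[drop] <- NA_real_
  out$n_used <- sum(!is.na(out$x))
  out
}

#' Apply the likelihood filter to every bodypart of a trial
#'
#' @param trial a \code{\link{trial_recording}}.
#' @param threshold confidence cut, see \code{\link{filter_by_likelihood}}.
#' @return The trial with every series filtered.
#' @export
filter_trial <- function(trial, threshold = 0.60) {
  stopifnot(inherits(trial, "trial_recording"))
  trial$series <- lapply(trial$series, filter_by_likelihood,
                         threshold = threshold)
  trial
}
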