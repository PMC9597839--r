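#' Detect stance onsets from a limb protraction trace
#'
#' At trot, the beginning of a forelimb's stance phase coincides with its
#' maximal protraction, so stance onsets are the local maxima of the limb
#' marker's horizontal coordinate. A candidate frame is an onset when it
#' holds the maximum of a centred window of half-width equal to half the
#' expected stride period (ties broken toward the earlier frame), which
#' enforces the minimum peak separation. A candidate must also be followed,
#' within its window, by at least one lower observed value: a trace that
#' merely rises into the end of the recording has not yet reached its
#' protraction maximum and produces no onset there. Missing frames
#' (likelihood-filtered) are ignored inside windows, so dropout gaps do not
#' split or shift peaks.
#'
#' @param limb_series a likelihood-filtered \code{\link{keypoint_series}} of
#'   a distal limb marker (os carpi accessorium or tarsus).
#' @param fps video frame rate.
#' @param expected_rate expected strides per minute (sets the minimum peak
#'   separation; the default 74 suits a Warmblood trot).
#' @return Integer vector of onset frame indices, strictly increasing.
#' @examples
#' th <- 2 * pi * 1.25 * (0:1799) / 30
#' ks <- keypoint_series(sin(th), rep(0, 1800), rep(1, 1800))
#' length(detect_stance_onsets(ks, fps = 30, expected_rate = 75))  # 75
#' @export
detect_stance_onsets <- function(limb_series, fps, expected_rate = 74) {
  stopifnot(inherits(limb_series, "keypoint_series"), fps > 0,
            expected_rate > 0)
  v <- limb_series$x
  n <- length(v)
  w <- ceiling(0.5 * fps * 60 / expected_rate)
  onsets <- integer(0L)
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    lo <- max(1L, i - w)
    hi <- min(n, i + w)
    win <- v[lo:hi]
    m <- suppressWarnings(max(win, na.rm = TRUE))
    if (!is.finite(m) || v[i] < m) next
    first <- lo + which(win == m)[1L] - 1L
    if (first != i) next
    after <- if (i < hi) v[(i + 1L):hi] else numeric(0L)
    if (!any(!is.na(after) & after < v[i])) next
    onsets <- c(onsets, i)
  }
  if (length(onsets) < 2L) {
    stop("insufficient strides: found ", length(onsets),
         " stance onset(s), need at least 2")
  }
  onsets
}

#' Segment strides of a trial into left and right forelimb stances
#'
#' Stance onsets of the circle-facing forelimb are detected from its os
#' carpi accessorium marker (\code{\link{detect_stance_onsets}}); the
#' contralateral forelimb, hidden behind the horse's body on a circle, is
#' inferred at half a stride period offset rather than tracked.
#'
#' @param trial a likelihood-filtered \code{\link{trial_recording}}.
#' @param expected_rate expected strides per minute.
#' @return An object of class \code{stride_segmentation}: list with
#'   \code{onsets_left}, \code{onsets_right}, \code{stride_period} (frames,
#'   median inter-onset gap of the tracked limb) and \code{n_strides}.
#' @export
segment_strides <- function(trial, expected_rate = 74) {
  stopifnot(inherits(trial, "trial_recording"))
  tracked_side <- if (trial$circle == "CL") "left" else "right"
  marker <- paste0("os_carpi_accessorium_", tracked_side)
  onsets <- detect_stance_onsets(get_series(trial, marker), trial$fps,
                                 expected_rate)
  period <- stats::median(diff(onsets))
  n <- n_frames(trial)
  other <- onsets + as.integer(round(period / 2))
  other <- other[other >= 1L & other <= n]
  seg <- if (tracked_side == "left") {
    list(onsets_left = onsets, onsets_right = other)
  } else {
    list(onsets_left = other, onsets_right = onsets)
  }
  seg$stride_period <- period
  seg$n_strides <- length(onsets)
  structure(seg, class = "stride_segmentation")
}

#' Stance-synchronous head-nod asymmetry
#'
#' A forelimb-lame trotting horse unloads the painful limb: its head is
#' lifted while the lame forelimb bears weight and dropped onto the sound
#' one. This function averages poll height (negated image-y, so larger =
#' higher) over each forelimb's stance windows — the half stride following
#' each stance onset — and reports their difference,
#' \code{nod_index = mean(left-stance height) - mean(right-stance height)}
#' in pixels. A positive index means the head rides higher during left
#' stance, implicating the left forelimb; symmetric trots give an index
#' near zero.
#'
#' @param poll_series the likelihood-filtered poll
#'   \code{\link{keypoint_series}}.
#' @param seg a \code{\link{segment_strides}} result with at least 5
#'   strides.
#' @param threshold decision threshold (px) on \code{|nod_index|}; the
#'   default comes from \code{\link{default_nod_threshold}}.
#' @return An object of class \code{head_nod_result}: list with
#'   \code{mean_height_left_stance}, \code{mean_height_right_stance},
#'   \code{nod_index}, \code{verdict} (\code{"sound"} or
#'   \code{"forelimb_lame"}) and \code{predicted_side} (\code{"left"},
#'   \code{"right"} or \code{"none"}).
#' @export
head_nod_index <- function(poll_series, seg,
                           threshold = default_nod_threshold()) {
  stopifnot(inherits(poll_series, "keypoint_series"),
            inherits(seg, "stride_segmentation"))
  if (seg$n_strides < 5L) {
    stop("need at least 5 strides for the head-nod analysis, have ",
         seg$n_strides)
  }
  height <- -poll_series$y
  half <- as.integer(floor(seg$stride_period / 2))
  n <- length(height)
  window_means <- function(onsets) {
    m <- vapply(onsets, function(o) {
      idx <- o:min(n, o + half - 1L)
      h <- height[idx]
      if (all(is.na(h))) NA_real_ else mean(h, na.rm = TRUE)
    }, numeric(1L))
    m[!is.na(m)]
  }
  left <- window_means(seg$onsets_left)
  right <- window_means(seg$onsets_right)
  if (length(left) == 0L || length(right) == 0L) {
    stop("no usable stance windows for one forelimb")
  }
  nod <- mean(left) - mean(right)
  lame <- abs(nod) > threshold
  structure(list(
    mean_height_left_stance = mean(left),
    mean_height_right_stance = mean(right),
    nod_index = nod,
    verdict = if (lame) "forelimb_lame" else "sound",
    predicted_side = if (!lame) "none" else if (nod > 0) "left" else "right",
    threshold = threshold
  ), class = "head_nod_result")
}

#' @export
print.head_nod_result <- function(x, ...) {
  cat(sprintf(
    "<head_nod_result> nod_index %.3f px (threshold %.3f): %s%s\n",
    x$nod_index, x$threshold, x$verdict,
    if (x$predicted_side != "none") paste0(", ", x$predicted_side) else ""))
  invisible(x)
}

#' Combine both circles into a forelimb verdict
#'
#' A horse is called forelimb-lame when either circle's head-nod verdict is
#' lame. When both circles flag the horse, the side follows their agreement;
#' on disagreement, the circle with the larger absolute nod index decides.
#'
#' @param cl,cr \code{\link{head_nod_index}} results for the left and right
#'   circle.
#' @return List with \code{status} (\code{"sound"} or
#'   \code{"forelimb_lame"}) and \code{side} (\code{"left"},
#'   \code{"right"} or \code{"none"}).
#' @export
classify_forelimb <- function(cl, cr) {
  stopifnot(inherits(cl, "head_nod_result"), inherits(cr, "head_nod_result"))
  lame_cl <- cl$verdict == "forelimb_lame"
  lame_cr <- cr$verdict == "forelimb_lame"
  if (!lame_cl && !lame_cr) {
    return(list(status = "sound", side = "none"))
  }
  side <- if (lame_cl && lame_cr) {
    if (cl$predicted_side == cr$predicted_side) cl$predicted_side
    else if (abs(cl$nod_index) >= abs(cr$nod_index)) cl$predicted_side
    else cr$predicted_side
  } else if (lame_cl) cl$predicted_side else cr$predicted_side
  list(status = "forelimb_lame", side = side)
}

#' Calibrate the head-nod decision threshold on a sound reference cohort
#'
#' Simulates \code{n} sound horses under the generator's default conditions,
#' computes the signed nod index of every trial (both circles) and returns
#' three standard deviations of those values. Under an approximately normal
#' sound-null distribution this keeps the per-horse false-positive rate
#' (either circle flagging) well below 5 percent.
#'
#' @param n number of sound reference horses.
#' @param gait,noise generator settings, see \code{\link{simulate_cohort}}.
#' @param seed integer seed for the reference cohort.
#' @return Threshold in pixels.
#' @export
calibrate_nod_threshold <- function(n = 20L, gait = gait_params(),
                                    noise = noise_spec(), seed = 20221017L) {
  cohort <- simulate_cohort(n_forelimb = 0L, n_hindlimb = 0L, n_sound = n,
                            gait = gait, noise = noise, seed = seed)
  nods <- unlist(lapply(cohort, function(h) {
    vapply(list(h$cl, h$cr), function(trial) {
      trial <- filter_trial(trial)
      seg <- segment_strides(trial, expected_rate = gait$stride_rate)
      head_nod_index(get_series(trial, "poll"), seg, threshold = Inf)$nod_index
    }, numeric(1L))
  }))
  3 * stats::sd(nods)
}

#' Default head-nod decision threshold
#'
#' The packaged constant (in pixels): the value of
#' \code{calibrate_nod_threshold(n = 20, seed = 20221017)} under the
#' generator defaults (0.4985), rounded up to 0.5. Recompute with
#' \code{\link{calibrate_nod_threshold}} for other recording conditions.
#'
#' @return Threshold in pixels.
#' @export
default_nod_threshold <- function() 0.5
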