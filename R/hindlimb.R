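#' Excursion span of the circle-facing hindlimb landmark
#'
#' For the stifle statistic this is the horizontal trimmed excursion span of
#' the circle-facing stifle point (a proxy for that hindlimb's stride
#' length); for the tuber coxae statistic it is the vertical trimmed span of
#' the circle-facing tuber coxae point (hip displacement). On the left-hand
#' circle (CL) the camera sees the horse's left side, on CR its right side,
#' so each circle measures one side only.
#'
#' @param trial a \code{\link{trial_recording}}.
#' @param statistic \code{"stifle"} or \code{"tuber_coxae"}.
#' @param likelihood_threshold confidence cut applied before the excursion
#'   statistics (set to 0 if the trial is already filtered).
#' @return Span in pixels (a single number).
#' @export
circle_span <- function(trial, statistic = c("stifle", "tuber_coxae"),
                        likelihood_threshold = 0.60) {
  stopifnot(inherits(trial, "trial_recording"))
  statistic <- match.arg(statistic)
  part <- facing_bodypart(statistic, trial$circle)
  axis <- if (statistic == "stifle") "x" else "y"
  s <- filter_by_likelihood(get_series(trial, part), likelihood_threshold)
  excursion_stats(s, axis = axis,
                  context = paste0(part, " of horse ", trial$horse_id,
                                   " (", trial$circle, ")"))$span
}

#' Circle-difference lameness score
#'
#' The score is the absolute difference between the two circles' excursion
#' spans, \code{|span_cl - span_cr|}, in pixels. The implicated side follows
#' the statistic's kinematics: a lame hindlimb shortens its stride, so for
#' the stifle the lame side is the side with the \emph{smaller} span; a lame
#' hindlimb hikes its hip, so for the tuber coxae it is the side with the
#' \emph{larger} span. CL measures the left side, CR the right.
#'
#' @param span_cl,span_cr spans (px) from \code{\link{circle_span}} on the
#'   left and right circle.
#' @param statistic \code{"stifle"} or \code{"tuber_coxae"}.
#' @return An object of class \code{lameness_score}: list with
#'   \code{statistic}, \code{span_cl}, \code{span_cr}, \code{score} and
#'   \code{predicted_side} (\code{"left"}, \code{"right"} or \code{"none"}
#'   when the spans tie). \code{predicted_status} is filled in by
#'   \code{\link{classify_stifle}} or \code{\link{classify_tuber_coxae}}.
#' @examples
#' compute_score(49.90, 38.55, "stifle")   # score 11.35, side right
#' compute_score(14.28, 19.06, "tuber_coxae")  # score 4.78, side right
#' @export
compute_score <- function(span_cl, span_cr,
                          statistic = c("stifle", "tuber_coxae")) {
  statistic <- match.arg(statistic)
  stopifnot(is.numeric(span_cl), is.numeric(span_cr),
            span_cl >= 0, span_cr >= 0)
  side <- if (span_cl == span_cr) {
    "none"
  } else if (statistic == "stifle") {
    # lame limb protracts less: smaller span marks the lame side
    if (span_cl < span_cr) "left" else "right"
  } else {
    # lame-side hip hikes more: larger span marks the lame side
    if (span_cl > span_cr) "left" else "right"
  }
  structure(list(statistic = statistic, span_cl = span_cl, span_cr = span_cr,
                 score = abs(span_cl - span_cr), predicted_side = side,
                 predicted_status = NA_character_),
            class = "lameness_score")
}

#' @export
print.lameness_score <- function(x, ...) {
  cat(sprintf(
    "<lameness_score> %s: spans CL %.2f / CR %.2f px, score %.2f, side %s%s\n",
    x$statistic, x$span_cl, x$span_cr, x$score, x$predicted_side,
    if (!is.na(x$predicted_status)) paste0(" -> ", x$predicted_status)
    else ""))
  invisible(x)
}

#' Classify hindlimb lameness from the stifle score
#'
#' A horse is called hindlimb-lame when its stifle score strictly exceeds
#' the threshold. The default of 1.2 px sits midway between the largest
#' ordinary sound-group score (0.87 px) and the smallest score flagged as
#' lame (1.23 px) in the clinical reference tables; it is a package-derived
#' operating point, not a published constant, and is configurable.
#'
#' @param score a \code{\link{compute_score}} result (statistic
#'   \code{"stifle"}) or a bare numeric score in px.
#' @param threshold decision threshold in px (strict \code{>}).
#' @return The \code{lameness_score} with \code{predicted_status} set
#'   (\code{"hindlimb_lame"} or \code{"sound"}); for numeric input, the
#'   status string alone.
#' @export
classify_stifle <- function(score, threshold = 1.2) {
  val <- if (inherits(score, "lameness_score")) score$score else score
  stopifnot(is.numeric(val), val >= 0)
  status <- if (val > threshold) "hindlimb_lame" else "sound"
  if (inherits(score, "lameness_score")) {
    score$predicted_status <- status
    if (status == "sound") score$predicted_side <- "none"
    score
  } else {
    status
  }
}

#' Evaluate the tuber coxae score the way the clinical study did
#'
#' The tuber coxae statistic was evaluated asymmetrically per group: a
#' clinically lame horse counts as correctly detected when the side with the
#' larger vertical span matches the clinically lame side; a control counts
#' as correctly sound when its score does not exceed \code{sound_threshold}
#' (default 1.0 px, separating the reference controls' ordinary scores,
#' at most 0.69 px, from their flagged ones, at least 1.14 px).
#'
#' @param score a \code{\link{compute_score}} result (statistic
#'   \code{"tuber_coxae"}).
#' @param clinical_side \code{"left"} or \code{"right"} for a clinically
#'   lame horse; \code{NULL} for a control.
#' @param sound_threshold control decision threshold in px.
#' @return The \code{lameness_score} with \code{predicted_status} set and a
#'   logical \code{correct} field recording agreement with the clinical
#'   assessment.
#' @export
classify_tuber_coxae <- function(score, clinical_side = NULL,
                                 sound_threshold = 1.0) {
  stopifnot(inherits(score, "lameness_score"),
            score$statistic == "tuber_coxae")
  if (is.null(clinical_side)) {
    sound <- score$score <= sound_threshold
    score$predicted_status <- if (sound) "sound" else "hindlimb_lame"
    if (sound) score$predicted_side <- "none"
    score$correct <- sound
  } else {
    clinical_side <- match.arg(clinical_side, c("left", "right"))
    score$predicted_status <- "hindlimb_lame"
    score$correct <- identical(score$predicted_side, clinical_side)
  }
  score
}

#' Unified tuber coxae classifier
#'
#' A symmetric alternative to the per-group evaluation of
#' \code{\link{classify_tuber_coxae}}: sound when the score is at most
#' \code{threshold}, otherwise hindlimb-lame on the larger-span side.
#'
#' @inheritParams classify_tuber_coxae
#' @param threshold decision threshold in px.
#' @return The \code{lameness_score} with \code{predicted_status} set.
#' @export
classify_tuber_coxae_unified <- function(score, threshold = 1.0) {
  stopifnot(inherits(score, "lameness_score"),
            score$statistic == "tuber_coxae")
  if (score$score <= threshold) {
    score$predicted_status <- "sound"
    score$predicted_side <- "none"
  } else {
    score$predicted_status <- "hindlimb_lame"
  }
  score
}

#' Group mean of lameness scores
#'
#' Arithmetic mean of a group's scores, reported rounded half away from zero
#' to \code{digits} decimals as clinical tables print it; use
#' \code{digits = NULL} for the exact mean.
#'
#' @param scores numeric vector of per-horse scores (px).
#' @param digits decimals of the reported value, or \code{NULL}.
#' @return Mean in pixels.
#' @export
group_mean <- function(scores, digits = 2) {
  if (length(scores) == 0L) stop("group_mean needs at least one score")
  m <- mean(scores)
  if (is.null(digits)) m else round_half_up(m, digits)
}
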