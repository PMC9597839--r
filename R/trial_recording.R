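#' One horse, one circle direction, one trot recording
#'
#' A trial recording bundles all tracked bodyparts of a single lunging video
#' (one horse on one circle direction at trot) with its acquisition metadata
#' and, when known, the clinical ground truth used for evaluation.
#'
#' @param horse_id character identifier.
#' @param circle \code{"CL"} (left-hand circle; the camera at the circle's
#'   centre sees the horse's left side) or \code{"CR"} (right-hand circle).
#' @param series named list of \code{\link{keypoint_series}}, one per
#'   bodypart; all must share the same frame count.
#' @param fps frames per second of the video (default 30).
#' @param resolution integer \code{c(width, height)} in pixels of the export
#'   resolution; coordinates are pixels at this resolution.
#' @param gait gait of the recording; only \code{"trot"} is analysed.
#' @param clinical_status optional ground truth: \code{"sound"},
#'   \code{"forelimb_lame"} or \code{"hindlimb_lame"}.
#' @param clinical_side optional \code{"left"} or \code{"right"}; must be
#'   absent for sound horses.
#' @param aaep_grade optional AAEP lameness grade, integer 1--5.
#' @return An object of class \code{trial_recording}.
#' @export
trial_recording <- function(horse_id, circle, series, fps = 30,
                            resolution = c(768L, 432L), gait = "trot",
                            clinical_status = NULL, clinical_side = NULL,
                            aaep_grade = NULL) {
  circle <- match.arg(circle, c("CL", "CR"))
  gait <- match.arg(gait, "trot")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("fps must be a single positive number")
  }
  if (length(resolution) != 2L || any(resolution <= 0)) {
    stop("resolution must be c(width, height) with positive entries")
  }
  if (!is.list(series) || is.null(names(series)) || any(names(series) == "")) {
    stop("series must be a named list of keypoint_series")
  }
  if (!all(vapply(series, inherits, logical(1L), "keypoint_series"))) {
    stop("every series element must be a keypoint_series")
  }
  n_frames <- vapply(series, function(s) s$n_frames, integer(1L))
  if (length(unique(n_frames)) > 1L) {
    stop("all bodypart series must share the same frame count")
  }
  if (!is.null(clinical_status)) {
    clinical_status <- match.arg(clinical_status,
                                 c("sound", "forelimb_lame", "hindlimb_lame"))
    if (clinical_status == "sound" && !is.null(clinical_side)) {
      stop("a sound horse cannot carry a clinical_side")
    }
  }
  if (!is.null(clinical_side)) {
    clinical_side <- match.arg(clinical_side, c("left", "right"))
  }
  if (!is.null(aaep_grade)) {
    aaep_grade <- as.integer(aaep_grade)
    if (is.na(aaep_grade) || aaep_grade < 1L || aaep_grade > 5L) {
      stop("aaep_grade must be an integer in 1..5")
    }
  }
  structure(
    list(horse_id = as.character(horse_id), circle = circle, gait = gait,
         fps = fps, resolution = as.integer(resolution), series = series,
         clinical_status = clinical_status, clinical_side = clinical_side,
         aaep_grade = aaep_grade),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  nf <- if (length(x$series)) x$series[[1L]]$n_frames else 0L
  cat("<trial_recording> horse ", x$horse_id, ", ", x$circle, ", ", x$gait,
      "\n  ", length(x$series), " bodyparts x ", nf, " frames @ ", x$fps,
      " fps (", x$resolution[1L], "x", x$resolution[2L], ")\n", sep = "")
  if (!is.null(x$clinical_status)) {
    cat("  clinical: ", x$clinical_status,
        if (!is.null(x$clinical_side)) paste0(" (", x$clinical_side, ")"),
        if (!is.null(x$aaep_grade)) paste0(", AAEP ", x$aaep_grade),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of frames in a trial
#' @param trial a \code{\link{trial_recording}}.
#' @return integer frame count shared by all series.
#' @export
n_frames <- function(trial) {
  stopifnot(inherits(trial, "trial_recording"))
  if (length(trial$series) == 0L) return(0L)
  trial$series[[1L]]$n_frames
}

# Fetch a bodypart series by name with a helpful error.
get_series <- function(trial, name) {
  s <- trial$series[[name]]
  if (is.null(s)) {
    stop("trial for horse ", trial$horse_id, " (", trial$circle,
         ") has no bodypart '", name, "'")
  }
  s
}
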