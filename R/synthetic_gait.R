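#' Parameters of the synthetic trot model
#'
#' The generator models a horse trotting on a 12 m lunging circle, filmed
#' from the circle's centre, as seen by a camera that keeps the horse near
#' frame centre. The trot is a two-beat diagonal gait: diagonal limb pairs
#' move in phase, contralateral limbs half a stride apart. Each limb
#' marker's horizontal coordinate is a sinusoid at the stride frequency
#' (protraction/retraction); the trunk and head oscillate vertically at
#' twice the stride frequency (one bounce per diagonal stance).
#'
#' Amplitudes are pixel half-excursions at the default 768 x 432 export
#' resolution, chosen so that the trimmed excursion spans land in the ranges
#' observed clinically: stifle horizontal spans of roughly 30--55 px and
#' tuber coxae vertical spans of roughly 8--21 px.
#'
#' @param stride_rate strides per minute; 74 is typical for a trotting
#'   Warmblood on a 12 m circle (German Riding Ponies trot nearer 84).
#' @param fps video frame rate (frames/second).
#' @param duration recording length in seconds.
#' @param limb_protraction_amp horizontal half-excursion (px) of the distal
#'   limb markers (carpus, os carpi accessorium, tarsus).
#' @param stifle_amp horizontal half-excursion (px) of the stifle.
#' @param tcox_amp vertical half-excursion (px) of the tuber coxae.
#' @param head_amp vertical half-excursion (px) of the poll at twice the
#'   stride frequency (the sound horse's symmetric head bob).
#' @param head_nod_gain ratio of the lameness-induced head-nod component
#'   (at stride frequency) to \code{head_amp}, per unit of asymmetry
#'   \code{grade_effect}; the default of 4 makes a moderate lameness
#'   (\code{grade_effect} 0.15) visually obvious in the poll trace.
#' @return A list of class \code{gait_params}.
#' @export
gait_params <- function(stride_rate = 74, fps = 30, duration = 60,
                        limb_protraction_amp = 25, stifle_amp = 21,
                        tcox_amp = 6.5, head_amp = 15, head_nod_gain = 4) {
  stopifnot(stride_rate > 0, fps > 0, duration > 0,
            limb_protraction_amp >= 0, stifle_amp >= 0, tcox_amp >= 0,
            head_amp >= 0, head_nod_gain >= 0)
  if (fps * duration < 2 * fps * 60 / stride_rate) {
    stop("recording must cover at least two strides")
  }
  structure(list(stride_rate = stride_rate, fps = fps, duration = duration,
                 limb_protraction_amp = limb_protraction_amp,
                 stifle_amp = stifle_amp, tcox_amp = tcox_amp,
                 head_amp = head_amp, head_nod_gain = head_nod_gain),
            class = "gait_params")
}

#' Lameness condition of a simulated horse
#'
#' \code{grade_effect} is the unitless asymmetry fraction applied to the
#' affected structures: a forelimb-lame horse gains a head-nod component at
#' stride frequency phased so the poll is highest during the lame limb's
#' stance; a hindlimb-lame horse has the lame-side stifle's horizontal
#' excursion shrunk by \code{(1 - grade_effect)} (shortened stride) and the
#' lame-side tuber coxae's vertical excursion grown by
#' \code{(1 + grade_effect)} (hip hike). As a rough clinical mapping, AAEP
#' grades 1--2 correspond to a grade_effect near 0.05 and grades 3--4 to
#' roughly 0.15.
#'
#' @param status \code{"sound"}, \code{"forelimb_lame"} or
#'   \code{"hindlimb_lame"}.
#' @param side \code{"left"} or \code{"right"}; required unless sound.
#' @param grade_effect asymmetry fraction in [0, 1); must be 0 when sound.
#' @return A list of class \code{lameness_spec}.
#' @export
lameness_spec <- function(status = "sound", side = NULL, grade_effect = 0) {
  status <- match.arg(status, c("sound", "forelimb_lame", "hindlimb_lame"))
  if (status == "sound") {
    if (grade_effect != 0) stop("a sound horse must have grade_effect 0")
    if (!is.null(side)) stop("a sound horse has no lame side")
  } else {
    if (is.null(side)) stop("a lame horse needs a side")
    side <- match.arg(side, c("left", "right"))
  }
  if (grade_effect < 0 || grade_effect >= 1) {
    stop("grade_effect must lie in [0, 1)")
  }
  structure(list(status = status, side = side, grade_effect = grade_effect),
            class = "lameness_spec")
}

#' Measurement noise model
#'
#' Gaussian per-frame jitter on every coordinate emulates pose-estimation
#' placement error; likelihood dropouts emulate frames the network is unsure
#' about. Sub-threshold frames draw their likelihood from Uniform(0, 0.6),
#' confident frames from Uniform(0.8, 1.0) — only the 0.60 exclusion cut
#' matters downstream.
#'
#' @param coord_sd standard deviation (px) of the coordinate jitter.
#' @param dropout_p probability that a frame's likelihood falls below 0.60.
#' @param seed integer RNG seed; the trial is fully deterministic given it.
#' @return A list of class \code{noise_spec}.
#' @export
noise_spec <- function(coord_sd = 1.0, dropout_p = 0.05, seed = 1L) {
  stopifnot(coord_sd >= 0, dropout_p >= 0, dropout_p < 1)
  structure(list(coord_sd = coord_sd, dropout_p = dropout_p,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate one trot trial on a lunging circle
#'
#' Generates per-frame (x, y, likelihood) tracks for the thirteen
#' analysis-critical bodyparts of \code{\link{default_bodypart_map}} under
#' the kinematic model of \code{\link{gait_params}}, with the lameness
#' asymmetries of \code{\link{lameness_spec}} and the noise of
#' \code{\link{noise_spec}} applied last. Coordinates are raw image pixels
#' (y grows downward). Both body sides are generated for every trial; which
#' side the downstream analysis consumes is decided by the circle direction
#' (CL exposes the left side, CR the right).
#'
#' @param gait a \code{\link{gait_params}}.
#' @param lameness a \code{\link{lameness_spec}}.
#' @param circle \code{"CL"} or \code{"CR"}.
#' @param noise a \code{\link{noise_spec}}.
#' @param horse_id identifier stored in the trial.
#' @return A \code{\link{trial_recording}} with the clinical ground truth of
#'   \code{lameness} recorded.
#' @examples
#' trial <- simulate_trial(circle = "CL",
#'                         lameness = lameness_spec("hindlimb_lame", "left",
#'                                                  grade_effect = 0.15),
#'                         noise = noise_spec(seed = 42))
#' trial
#' @export
simulate_trial <- function(gait = gait_params(),
                           lameness = lameness_spec(),
                           circle = c("CL", "CR"),
                           noise = noise_spec(),
                           horse_id = "synthetic") {
  stopifnot(inherits(gait, "gait_params"), inherits(lameness, "lameness_spec"),
            inherits(noise, "noise_spec"))
  circle <- match.arg(circle)
  set.seed(noise$seed)

  n <- round(gait$fps * gait$duration)
  t <- (seq_len(n) - 1L) / gait$fps
  f <- gait$stride_rate / 60
  theta <- 2 * pi * f * t

  # Limb phase convention: left fore at 0, diagonal partner (right hind)
  # in phase; contralateral limbs half a stride later.
  phase <- c(fore_left = 0, fore_right = pi, hind_left = pi, hind_right = 0)
  delta <- lameness$grade_effect

  stifle_amp <- c(left = gait$stifle_amp, right = gait$stifle_amp)
  tcox_amp <- c(left = gait$tcox_amp, right = gait$tcox_amp)
  if (lameness$status == "hindlimb_lame") {
    stifle_amp[lameness$side] <- stifle_amp[lameness$side] * (1 - delta)
    tcox_amp[lameness$side] <- tcox_amp[lameness$side] * (1 + delta)
  }

  # Poll height (positive up): symmetric bob at 2f, plus a stride-frequency
  # nod for forelimb lameness peaking mid-stance of the lame limb.
  height <- gait$head_amp * sin(2 * theta)
  if (lameness$status == "forelimb_lame") {
    lame_phase <- phase[[paste0("fore_", lameness$side)]]
    height <- height +
      delta * gait$head_nod_gain * gait$head_amp * sin(theta + lame_phase)
  }

  limb_x <- function(base, amp, ph) base + amp * cos(theta + ph)
  bounce <- function(base, amp) base - amp * sin(2 * theta)

  tracks <- list(
    poll = list(x = 340 + 5 * sin(2 * theta), y = 100 - height),
    elbow_left = list(
      x = limb_x(430, 0.5 * gait$limb_protraction_amp, phase["fore_left"]),
      y = bounce(230, 3)),
    elbow_right = list(
      x = limb_x(430, 0.5 * gait$limb_protraction_amp, phase["fore_right"]),
      y = bounce(230, 3)),
    os_carpi_accessorium_left = list(
      x = limb_x(428, gait$limb_protraction_amp, phase["fore_left"]),
      y = bounce(330, 4)),
    os_carpi_accessorium_right = list(
      x = limb_x(428, gait$limb_protraction_amp, phase["fore_right"]),
      y = bounce(330, 4)),
    carpus_left = list(
      x = limb_x(433, gait$limb_protraction_amp, phase["fore_left"]),
      y = bounce(325, 4)),
    carpus_right = list(
      x = limb_x(433, gait$limb_protraction_amp, phase["fore_right"]),
      y = bounce(325, 4)),
    tuber_coxae_left = list(
      x = 300 + 3 * cos(theta + phase["hind_left"]),
      y = bounce(180, tcox_amp["left"])),
    tuber_coxae_right = list(
      x = 300 + 3 * cos(theta + phase["hind_right"]),
      y = bounce(180, tcox_amp["right"])),
    stifle_left = list(
      x = limb_x(310, stifle_amp["left"], phase["hind_left"]),
      y = bounce(260, 4)),
    stifle_right = list(
      x = limb_x(310, stifle_amp["right"], phase["hind_right"]),
      y = bounce(260, 4)),
    tarsus_left = list(
      x = limb_x(290, 0.9 * gait$limb_protraction_amp, phase["hind_left"]),
      y = bounce(340, 4)),
    tarsus_right = list(
      x = limb_x(290, 0.9 * gait$limb_protraction_amp, phase["hind_right"]),
      y = bounce(340, 4))
  )

  series <- lapply(tracks, function(tr) {
    x <- tr$x + stats::rnorm(n, sd = noise$coord_sd)
    y <- tr$y + stats::rnorm(n, sd = noise$coord_sd)
    sub <- stats::runif(n) < noise$dropout_p
    lik <- ifelse(sub, stats::runif(n, 0, 0.6), stats::runif(n, 0.8, 1.0))
    keypoint_series(x = x, y = y, likelihood = lik)
  })

  trial_recording(
    horse_id = horse_id, circle = circle, series = series, fps = gait$fps,
    clinical_status = lameness$status,
    clinical_side = if (lameness$status == "sound") NULL else lameness$side,
    aaep_grade = if (delta == 0) NULL else if (delta < 0.10) 2L else 3L
  )
}

#' Simulate a cohort of horses, each recorded on both circles
#'
#' Mirrors the design of a clinical validation cohort: by default 13
#' forelimb-lame horses (7 left / 6 right; 10 mild, 3 moderate), 9
#' hindlimb-lame horses (5 left / 4 right; 4 mild, 5 moderate) and 8 sound
#' controls. Mild lameness uses \code{grade_effect} 0.05, moderate 0.15.
#' Horses vary moderately in build and cadence: per-horse amplitude scale
#' Uniform(0.85, 1.15) and stride-rate jitter Uniform(-3, 3) strides/min.
#' All randomness — horse traits and per-trial noise seeds — derives from
#' \code{seed}, so the cohort is fully reproducible.
#'
#' @param n_forelimb,n_hindlimb,n_sound group sizes.
#' @param gait baseline \code{\link{gait_params}} shared by the cohort.
#' @param noise baseline \code{\link{noise_spec}}; its seed is ignored in
#'   favour of per-trial seeds derived from \code{seed}.
#' @param seed master integer seed.
#' @param forelimb_deltas,hindlimb_deltas optional numeric vectors of
#'   per-horse \code{grade_effect} values (recycled to the group size).
#' @param forelimb_sides,hindlimb_sides optional character vectors of
#'   per-horse lame sides.
#' @return A list of horses, each a list with \code{horse_id},
#'   \code{status}, \code{side}, \code{grade_effect} and the two trials
#'   \code{cl}, \code{cr}.
#' @export
simulate_cohort <- function(n_forelimb = 13L, n_hindlimb = 9L, n_sound = 8L,
                            gait = gait_params(), noise = noise_spec(),
                            seed = 1L,
                            forelimb_deltas = NULL, hindlimb_deltas = NULL,
                            forelimb_sides = NULL, hindlimb_sides = NULL) {
  stopifnot(n_forelimb >= 0, n_hindlimb >= 0, n_sound >= 0)
  n_total <- n_forelimb + n_hindlimb + n_sound
  if (n_total == 0L) return(list())

  default_deltas <- function(n, n_mild) {
    c(rep(0.05, min(n, n_mild)), rep(0.15, max(0L, n - n_mild)))
  }
  fl_delta <- if (is.null(forelimb_deltas)) {
    default_deltas(n_forelimb, ceiling(n_forelimb * 10 / 13))
  } else rep_len(forelimb_deltas, n_forelimb)
  hl_delta <- if (is.null(hindlimb_deltas)) {
    default_deltas(n_hindlimb, floor(n_hindlimb * 4 / 9))
  } else rep_len(hindlimb_deltas, n_hindlimb)
  fl_side <- if (is.null(forelimb_sides)) {
    rep_len(c("left", "right"), n_forelimb)
  } else rep_len(forelimb_sides, n_forelimb)
  hl_side <- if (is.null(hindlimb_sides)) {
    rep_len(c("left", "right"), n_hindlimb)
  } else rep_len(hindlimb_sides, n_hindlimb)

  status <- c(rep("forelimb_lame", n_forelimb),
              rep("hindlimb_lame", n_hindlimb),
              rep("sound", n_sound))
  side <- c(fl_side, hl_side, rep(NA_character_, n_sound))
  delta <- c(fl_delta, hl_delta, rep(0, n_sound))

  set.seed(as.integer(seed))
  amp_scale <- stats::runif(n_total, 0.85, 1.15)
  rate_jitter <- stats::runif(n_total, -3, 3)
  trial_seeds <- matrix(sample.int(.Machine$integer.max, 2L * n_total),
                        ncol = 2L)

  lapply(seq_len(n_total), function(i) {
    g <- gait_params(
      stride_rate = gait$stride_rate + rate_jitter[i],
      fps = gait$fps, duration = gait$duration,
      limb_protraction_amp = gait$limb_protraction_amp * amp_scale[i],
      stifle_amp = gait$stifle_amp * amp_scale[i],
      tcox_amp = gait$tcox_amp * amp_scale[i],
      head_amp = gait$head_amp * amp_scale[i],
      head_nod_gain = gait$head_nod_gain)
    lam <- if (status[i] == "sound") lameness_spec() else {
      lameness_spec(status[i], side[i], delta[i])
    }
    id <- sprintf("%s_%02d", switch(status[i], forelimb_lame = "FL",
                                    hindlimb_lame = "HL", sound = "S"), i)
    cl <- simulate_trial(g, lam, "CL",
                         noise_spec(noise$coord_sd, noise$dropout_p,
                                    trial_seeds[i, 1L]), horse_id = id)
    cr <- simulate_trial(g, lam, "CR",
                         noise_spec(noise$coord_sd, noise$dropout_p,
                                    trial_seeds[i, 2L]), horse_id = id)
    list(horse_id = id, status = status[i],
         side = if (is.na(side[i])) NULL else side[i],
         grade_effect = delta[i], cl = cl, cr = cr)
  })
}
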