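nz_off <- noise_spec(coord_sd = 0, dropout_p = 0, seed = 1)

test_that("stance onsets of a pure sinusoid land on its maxima", {
  th <- 2 * pi * 1.25 * (0:1799) / 30   # 1.25 Hz at 30 fps for 60 s
  ks <- keypoint_series(sin(th), rep(0, 1800), rep(1, 1800))
  onsets <- detect_stance_onsets(ks, fps = 30, expected_rate = 75)
  expect_length(onsets, 75L)
  expect_equal(unique(diff(onsets)), 24L)
  expect_equal(onsets[1], 7L)
})

test_that("the detector matches the windowed-argmax oracle under noise and dropouts",
{
  set.seed(8)
  th <- 2 * pi * 1.25 * (0:1799) / 30
  v <- sin(th) + rnorm(1800, sd = 0.05)
  v[sample(1800, 90)] <- NA   # likelihood-filtered gaps
  ks <- keypoint_series(v, rep(0, 1800), rep(1, 1800))
  expect_identical(detect_stance_onsets(ks, 30, 75),
                   as.integer(oracle_onsets(v, 30, 75)))
})

test_that("the default 60 s trot simulation yields 74 +/- 2 strides", {
  for (seed in c(4, 19)) {
    trial <- filter_trial(simulate_trial(circle = "CL",
                                         noise = noise_spec(seed = seed)))
    seg <- segment_strides(trial)
    expect_true(abs(seg$n_strides - 74) <= 2)
    expect_true(all(diff(seg$onsets_left) > 0))
    expect_true(all(diff(seg$onsets_right) > 0))
  }
})

test_that("too few strides raise an insufficient-strides error", {
  flat <- keypoint_series(rep(1, 100), rep(1, 100), rep(1, 100))
  expect_error(detect_stance_onsets(flat, 30, 74), "insufficient strides")
})

test_that("a constant poll height gives a zero nod index and a sound verdict",
{
  trial <- filter_trial(simulate_trial(circle = "CL", noise = nz_off))
  seg <- segment_strides(trial)
  poll <- keypoint_series(rep(0, 1800), rep(100, 1800), rep(1, 1800))
  res <- head_nod_index(poll, seg)
  expect_equal(res$nod_index, 0)
  expect_equal(res$verdict, "sound")
  expect_equal(res$predicted_side, "none")
})

test_that("a lame forelimb lifts the head during its own stance", {
  lam <- lameness_spec("forelimb_lame", "left", grade_effect = 0.15)
  trial <- filter_trial(simulate_trial(lameness = lam, circle = "CL",
                                       noise = nz_off))
  seg <- segment_strides(trial)
  res <- head_nod_index(trial$series$poll, seg)
  expect_equal(res$verdict, "forelimb_lame")
  expect_equal(res$predicted_side, "left")
  # generator closed form: nod = (4/pi) * delta * gain * head_amp,
  # up to stance-window discretisation
  g <- gait_params()
  expect_equal(res$nod_index, 4 / pi * 0.15 * g$head_nod_gain * g$head_amp,
               tolerance = 0.05)
})

test_that("relabelling left and right negates the nod index and flips the side",
{
  lam <- lameness_spec("forelimb_lame", "left", grade_effect = 0.10)
  trial <- filter_trial(simulate_trial(lameness = lam, circle = "CL",
                                       noise = noise_spec(seed = 23)))
  seg <- segment_strides(trial)
  mirrored <- seg
  mirrored$onsets_left <- seg$onsets_right
  mirrored$onsets_right <- seg$onsets_left
  a <- head_nod_index(trial$series$poll, seg)
  b <- head_nod_index(trial$series$poll, mirrored)
  expect_equal(b$nod_index, -a$nod_index)
  expect_equal(a$predicted_side, "left")
  expect_equal(b$predicted_side, "right")
})

test_that("mirrored lameness under identical noise gives the mirrored result",
{
  mk <- function(side) {
    trial <- filter_trial(simulate_trial(
      lameness = lameness_spec("forelimb_lame", side, 0.10),
      circle = "CL", noise = noise_spec(seed = 77)))
    head_nod_index(trial$series$poll, segment_strides(trial))
  }
  left <- mk("left")
  right <- mk("right")
  # mirror holds up to the stance-window discretisation of the symmetric
  # two-beat head bob (windows are whole frames, the bob period is not)
  expect_equal(right$nod_index, -left$nod_index, tolerance = 0.1)
  expect_equal(left$predicted_side, "left")
  expect_equal(right$predicted_side, "right")
})

test_that("both circles combine into the documented forelimb verdicts", {
  res <- function(nod, verdict, side) {
    structure(list(nod_index = nod, verdict = verdict, predicted_side = side),
              class = "head_nod_result")
  }
  sound <- res(0.1, "sound", "none")
  lame_l <- res(3, "forelimb_lame", "left")
  lame_l2 <- res(2, "forelimb_lame", "left")
  lame_r <- res(-5, "forelimb_lame", "right")
  expect_equal(classify_forelimb(sound, sound)$status, "sound")
  expect_equal(classify_forelimb(lame_l, lame_l2),
               list(status = "forelimb_lame", side = "left"))
  expect_equal(classify_forelimb(sound, lame_r),
               list(status = "forelimb_lame", side = "right"))
  # disagreement: the circle with the larger |nod| decides
  expect_equal(classify_forelimb(lame_l, lame_r)$side, "right")
})

test_that("detection power is non-decreasing in the effect size", {
  nods <- vapply(c(0, 0.05, 0.10, 0.15), function(d) {
    lam <- if (d == 0) lameness_spec() else {
      lameness_spec("forelimb_lame", "left", d)
    }
    trial <- filter_trial(simulate_trial(lameness = lam, circle = "CL",
                                         noise = noise_spec(seed = 12)))
    abs(head_nod_index(trial$series$poll, segment_strides(trial),
                       threshold = Inf)$nod_index)
  }, numeric(1))
  expect_true(all(diff(nods) > 0))
})

test_that("the sound-null nod distribution is centred with few false alarms",
{
  cohort <- simulate_cohort(n_forelimb = 0, n_hindlimb = 0, n_sound = 20,
                            seed = 202)
  nods <- vapply(cohort, function(h) {
    trial <- filter_trial(h$cl)
    head_nod_index(trial$series$poll, segment_strides(trial),
                   threshold = Inf)$nod_index
  }, numeric(1))
  expect_lt(abs(mean(nods)), 0.2)
  expect_lte(mean(abs(nods) > default_nod_threshold()), 0.05)
})
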