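test_that("circle-difference scores reproduce printed clinical examples", {
  s1 <- compute_score(49.90, 38.55, "stifle")
  expect_equal(round_half_up(s1$score, 2), 11.35)
  expect_equal(s1$predicted_side, "right")  # clinically right-hind lame

  s2 <- compute_score(14.28, 19.06, "tuber_coxae")
  expect_equal(round_half_up(s2$score, 2), 4.78)

  s3 <- compute_score(40.18, 40.18, "stifle")
  expect_equal(s3$score, 0)
  expect_equal(s3$predicted_side, "none")
})

test_that("the implicated side follows each statistic's kinematics", {
  # stifle: shortened stride -> smaller span on the lame side
  expect_equal(compute_score(30, 40, "stifle")$predicted_side, "left")
  expect_equal(compute_score(40, 30, "stifle")$predicted_side, "right")
  # tuber coxae: hip hike -> larger span on the lame side
  expect_equal(compute_score(15, 12, "tuber_coxae")$predicted_side, "left")
  expect_equal(compute_score(12, 15, "tuber_coxae")$predicted_side, "right")
})

test_that("swapping the circles preserves the score and flips the side", {
  set.seed(14)
  for (stat in c("stifle", "tuber_coxae")) {
    for (i in 1:20) {
      a <- runif(1, 5, 55)
      b <- runif(1, 5, 55)
      s <- compute_score(a, b, stat)
      sw <- compute_score(b, a, stat)
      expect_equal(sw$score, s$score)
      expect_equal(sw$predicted_side,
                   switch(s$predicted_side, left = "right", right = "left",
                          none = "none"))
    }
  }
})

test_that("stifle classification applies a strict threshold", {
  expect_equal(classify_stifle(7.85), "hindlimb_lame")
  expect_equal(classify_stifle(0.07), "sound")
  expect_equal(classify_stifle(1.2), "sound")      # boundary: strict >
  expect_equal(classify_stifle(1.23), "hindlimb_lame")
  s <- classify_stifle(compute_score(42.17, 34.32, "stifle"))
  expect_equal(s$predicted_status, "hindlimb_lame")
  expect_equal(s$predicted_side, "right")
})

test_that("tuber coxae evaluation mirrors the per-group clinical rules", {
  # lame horse: correct iff the larger-span side matches the clinical side
  lame_ok <- classify_tuber_coxae(compute_score(11.81, 14.62, "tuber_coxae"),
                                  clinical_side = "right")
  expect_true(lame_ok$correct)
  lame_miss <- classify_tuber_coxae(compute_score(11.29, 19.21, "tuber_coxae"),
                                    clinical_side = "left")
  expect_false(lame_miss$correct)
  # control: sound iff the score stays at or below the control threshold
  ctrl_ok <- classify_tuber_coxae(compute_score(12.06, 11.55, "tuber_coxae"))
  expect_true(ctrl_ok$correct)
  expect_equal(ctrl_ok$predicted_status, "sound")
  ctrl_flag <- classify_tuber_coxae(compute_score(14.28, 19.06, "tuber_coxae"))
  expect_false(ctrl_flag$correct)
  # unified variant: one threshold, then side call
  uni <- classify_tuber_coxae_unified(compute_score(12, 15, "tuber_coxae"))
  expect_equal(uni$predicted_status, "hindlimb_lame")
  expect_equal(uni$predicted_side, "right")
  expect_equal(
    classify_tuber_coxae_unified(
      compute_score(12, 12.5, "tuber_coxae"))$predicted_status, "sound")
})

test_that("group means are arithmetic means rounded half away from zero", {
  ref <- clinical_reference_tables()
  expect_equal(group_mean(ref$stifle_sound$score), 0.55)
  expect_equal(group_mean(c(2.81, 0.73, 0.09)), 1.21)
  expect_equal(group_mean(5.5), 5.5)
  expect_equal(group_mean(c(0.545), digits = NULL), 0.545)
  expect_error(group_mean(numeric(0)), "at least one")
})

test_that("synthetic hindlimb lameness is recovered from the spans", {
  nz <- noise_spec(coord_sd = 0, dropout_p = 0, seed = 1)
  lam <- lameness_spec("hindlimb_lame", "left", 0.15)
  cl <- simulate_trial(lameness = lam, circle = "CL", noise = nz)
  cr <- simulate_trial(lameness = lam, circle = "CR", noise = nz)
  st <- classify_stifle(compute_score(circle_span(cl, "stifle"),
                                      circle_span(cr, "stifle"), "stifle"))
  expect_equal(st$predicted_status, "hindlimb_lame")
  expect_equal(st$predicted_side, "left")
  tc <- compute_score(circle_span(cl, "tuber_coxae"),
                      circle_span(cr, "tuber_coxae"), "tuber_coxae")
  expect_equal(tc$predicted_side, "left")
})
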