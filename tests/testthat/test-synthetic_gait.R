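nz_off <- noise_spec(coord_sd = 0, dropout_p = 0, seed = 1)

test_that("simulation is deterministic given the seed", {
  a <- simulate_trial(circle = "CL", noise = noise_spec(seed = 99))
  b <- simulate_trial(circle = "CL", noise = noise_spec(seed = 99))
  expect_identical(a, b)
  c1 <- simulate_cohort(n_forelimb = 1, n_hindlimb = 1, n_sound = 1, seed = 7)
  c2 <- simulate_cohort(n_forelimb = 1, n_hindlimb = 1, n_sound = 1, seed = 7)
  expect_identical(c1, c2)
})

test_that("a sound horse is symmetric: equal stifle spans, zero score", {
  cl <- simulate_trial(circle = "CL", noise = nz_off)
  cr <- simulate_trial(circle = "CR", noise = nz_off)
  span_cl <- circle_span(cl, "stifle")
  span_cr <- circle_span(cr, "stifle")
  expect_equal(span_cl, span_cr, tolerance = 1e-9)
  expect_equal(compute_score(span_cl, span_cr, "stifle")$score, 0,
               tolerance = 1e-9)
})

test_that("lameness asymmetries follow their closed forms", {
  lam <- lameness_spec("hindlimb_lame", "left", grade_effect = 0.15)
  cl <- simulate_trial(lameness = lam, circle = "CL", noise = nz_off)
  cr <- simulate_trial(lameness = lam, circle = "CR", noise = nz_off)
  # lame-left stifle protraction shrunk by (1 - delta), seen on CL only
  expect_equal(circle_span(cl, "stifle") / circle_span(cr, "stifle"),
               0.85, tolerance = 1e-9)
  # lame-side tuber coxae vertical excursion grown by (1 + delta)
  expect_equal(circle_span(cl, "tuber_coxae") / circle_span(cr, "tuber_coxae"),
               1.15, tolerance = 1e-9)
})

test_that("stifle and tuber coxae scores grow monotonically with the effect",
{
  deltas <- c(0, 0.05, 0.10, 0.15, 0.20)
  scores <- vapply(deltas, function(d) {
    lam <- if (d == 0) lameness_spec() else {
      lameness_spec("hindlimb_lame", "left", d)
    }
    nz <- noise_spec(seed = 31)  # same noise for every effect size
    st <- compute_score(
      circle_span(simulate_trial(lameness = lam, circle = "CL", noise = nz),
                  "stifle"),
      circle_span(simulate_trial(lameness = lam, circle = "CR", noise = nz),
                  "stifle"), "stifle")
    st$score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("likelihood dropouts hit the requested rate", {
  trial <- simulate_trial(circle = "CL",
                          noise = noise_spec(dropout_p = 0.1, seed = 13))
  frac <- mean(trial$series$poll$likelihood < 0.60)
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / 1800))
  kept <- filter_by_likelihood(trial$series$poll)
  expect_equal(kept$n_used / 1800, 1 - frac)
})

test_that("the default cohort mirrors the study design with ground truth", {
  cohort <- simulate_cohort(seed = 5)
  expect_length(cohort, 30L)
  status <- vapply(cohort, `[[`, character(1), "status")
  expect_equal(sum(status == "forelimb_lame"), 13L)
  expect_equal(sum(status == "hindlimb_lame"), 9L)
  expect_equal(sum(status == "sound"), 8L)
  for (h in cohort) {
    expect_equal(h$cl$circle, "CL")
    expect_equal(h$cr$circle, "CR")
    expect_equal(h$cl$clinical_status, h$status)
    if (h$status == "sound") {
      expect_null(h$cl$clinical_side)
      expect_equal(h$grade_effect, 0)
    } else {
      expect_equal(h$cl$clinical_side, h$side)
      expect_gt(h$grade_effect, 0)
    }
  }
})

test_that("invalid generator parameters are rejected", {
  expect_error(lameness_spec("sound", grade_effect = 0.1), "grade_effect 0")
  expect_error(lameness_spec("forelimb_lame"), "side")
  expect_error(noise_spec(dropout_p = 1), "dropout_p")
  expect_error(gait_params(duration = 0.5), "two strides")
})
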