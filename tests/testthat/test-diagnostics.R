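test_that("cross-tabulation reproduces the printed 2x2 counts", {
  ref <- clinical_reference_tables()
  st <- tabulate_confusion(
    clinical = rep(c("lame", "sound"), c(9, 8)),
    predicted = c(ifelse(ref$stifle_lame$classified_lame, "lame", "sound"),
                  ifelse(ref$stifle_sound$classified_sound, "sound", "lame")),
    labels = c("lame", "sound"))
  expect_equal(unclass(st)[], matrix(c(8L, 1L, 1L, 7L), 2,
                                     dimnames = dimnames(st)))
  tc <- confusion_2x2(tp = 3, fp = 3, fn = 6, tn = 5)
  expect_equal(sum(tc), 17L)
  expect_equal(tc[1, 1], 3L)   # TP
  expect_equal(tc[2, 1], 3L)   # FP (sound predicted lame)
  empty <- tabulate_confusion(character(0), character(0),
                              labels = c("lame", "sound"))
  expect_true(all(empty == 0L))
})

test_that("test characteristics reproduce the published metric rows", {
  stifle <- test_characteristics(confusion_2x2(8, 1, 1, 7))
  expect_equal(stifle, c(SE = 88.9, SP = 87.5, ACC = 88.2, PPV = 88.9,
                         NPV = 87.5))
  tcox <- test_characteristics(confusion_2x2(3, 3, 6, 5))
  expect_equal(tcox[c("SE", "SP", "ACC", "PPV")],
               c(SE = 33.3, SP = 62.5, ACC = 47.1, PPV = 50.0))
  expect_equal(tcox[["NPV"]], 45.5)  # 5/11, printed elsewhere truncated
  fore <- test_characteristics(confusion_2x2(13, 0, 0, 8))
  expect_true(all(fore == 100))
})

test_that("characteristics agree with first-principles recomputation", {
  set.seed(99)
  for (i in 1:25) {
    cnt <- rmultinom(1, size = sample(10:60, 1), prob = runif(4, 0.05, 1))
    t <- confusion_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    m <- test_characteristics(t)
    ref <- c(SE = cnt[1] / (cnt[1] + cnt[3]),
             SP = cnt[4] / (cnt[4] + cnt[2]),
             ACC = (cnt[1] + cnt[4]) / sum(cnt),
             PPV = cnt[1] / (cnt[1] + cnt[2]),
             NPV = cnt[4] / (cnt[4] + cnt[3])) * 100
    for (k in names(ref)) {
      if (is.nan(ref[[k]])) expect_true(is.na(m[[k]]))
      else expect_equal(m[[k]], ref[[k]], tolerance = 0.051)
    }
    # accuracy is the prevalence-weighted average of SE and SP
    if (!any(is.nan(ref[c("SE", "SP")]))) {
      expect_equal(ref[["ACC"]],
                   (ref[["SE"]] * (cnt[1] + cnt[3]) +
                    ref[["SP"]] * (cnt[2] + cnt[4])) / sum(cnt))
    }
  }
})

test_that("zero denominators flag metrics as undefined instead of crashing", {
  m <- test_characteristics(confusion_2x2(0, 0, 0, 10))
  expect_true(is.na(m[["SE"]]))
  expect_true(is.na(m[["PPV"]]))
  expect_equal(m[["SP"]], 100)
})

test_that("Cohen's kappa satisfies its defining properties", {
  perfect <- tabulate_confusion(rep(c("a", "b", "c"), 5),
                                rep(c("a", "b", "c"), 5))
  expect_equal(cohen_kappa(perfect), 1)
  # independence margins give zero agreement beyond chance
  chance <- structure(matrix(c(9L, 3L, 3L, 1L), 2,
                             dimnames = list(clinical = c("a", "b"),
                                             predicted = c("a", "b"))),
                      class = c("confusion_table", "matrix"))
  expect_equal(cohen_kappa(chance), 0)
  # the 3x3 table implied by the printed verdict columns
  t3 <- structure(matrix(c(13L, 0L, 0L, 0L, 8L, 1L, 0L, 1L, 7L), 3,
                         byrow = TRUE,
                         dimnames = list(clinical = c("f", "h", "s"),
                                         predicted = c("f", "h", "s"))),
                  class = c("confusion_table", "matrix"))
  expect_equal(cohen_kappa(t3), 0.8976, tolerance = 1e-4)
  expect_equal(cohen_kappa(t3), oracle_kappa(unclass(t3)))
  expect_equal(overall_accuracy(t3), 93.3)
})

test_that("kappa matches an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(rpois(9, 6), 3)
    t <- structure(m, dimnames = list(clinical = letters[1:3],
                                      predicted = letters[1:3]),
                   class = c("confusion_table", "matrix"))
    expect_equal(cohen_kappa(t), e1071::classAgreement(m)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("kappa is invariant under simultaneous category permutation and 1 only on diagonals",
{
  set.seed(21)
  m <- matrix(rpois(9, 4) + diag(3) * 5L, 3)
  t <- structure(m, dimnames = list(clinical = letters[1:3],
                                    predicted = letters[1:3]),
                 class = c("confusion_table", "matrix"))
  perm <- c(3, 1, 2)
  tp <- structure(m[perm, perm],
                  dimnames = list(clinical = letters[perm],
                                  predicted = letters[perm]),
                  class = c("confusion_table", "matrix"))
  expect_equal(cohen_kappa(tp), cohen_kappa(t))
  if (any(m[row(m) != col(m)] > 0)) expect_lt(cohen_kappa(t), 1)
})

test_that("removing off-diagonal mass strictly increases overall accuracy", {
  m <- matrix(c(13L, 0L, 0L, 0L, 8L, 1L, 0L, 1L, 7L), 3, byrow = TRUE)
  oa <- function(m) 100 * sum(diag(m)) / sum(m)
  m2 <- m; m2[2, 3] <- 0L
  m3 <- m2; m3[3, 2] <- 0L
  expect_true(oa(m) < oa(m2) && oa(m2) < oa(m3))
  expect_equal(oa(m3), 100)
})
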