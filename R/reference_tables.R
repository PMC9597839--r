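#' Clinical reference measurements
#'
#' Per-horse excursion spans, circle-difference scores and verdicts from a
#' clinical validation study of 30 lunged horses (13 forelimb-lame, 9
#' hindlimb-lame, 8 sound controls), as printed in its result tables. The
#' spans are trimmed excursion spans in pixels at the 768 x 432 export
#' resolution: horizontal stifle spans and vertical tuber coxae spans of the
#' circle-facing side on the left (CL) and right (CR) lunging circle.
#'
#' These values serve as fixtures: the package's score arithmetic, group
#' summaries and diagnostic metrics are checked by recomputing every derived
#' column from the printed span pairs.
#'
#' @return A list with elements:
#' \describe{
#'   \item{stifle_lame}{data frame for the 9 hindlimb-lame horses:
#'     \code{horse}, \code{clinical_side} (\code{"left"}/\code{"right"}),
#'     \code{grade_band} (\code{"1-2"} or \code{"3-4"}), \code{span_cl},
#'     \code{span_cr}, \code{score} (printed \code{|CL - CR|}),
#'     \code{classified_lame} (printed verdict).}
#'   \item{stifle_sound}{data frame for the 8 controls: \code{horse},
#'     \code{span_cl}, \code{span_cr}, \code{score},
#'     \code{classified_sound}.}
#'   \item{tcox_lame}{tuber coxae analogue of \code{stifle_lame}.}
#'   \item{tcox_sound}{tuber coxae analogue of \code{stifle_sound}.}
#'   \item{forelimb_counts}{named vector \code{tp, fp, fn, tn} of the
#'     forelimb head-nod evaluation (13 lame, 8 sound).}
#' }
#' @export
clinical_reference_tables <- function() {
  stifle_lame <- data.frame(
    horse = 1:9,
    clinical_side = c("left", "right", "right", "left", "right",
                      "left", "left", "left", "right"),
    grade_band = c("3-4", "3-4", "1-2", "3-4", "1-2",
                   "1-2", "3-4", "1-2", "3-4"),
    span_cl = c(42.50, 42.17, 31.16, 47.68, 43.32, 36.20, 48.03, 47.36, 49.90),
    span_cr = c(44.17, 34.32, 29.69, 54.61, 42.09, 38.21, 51.12, 49.60, 38.55),
    score = c(1.67, 7.85, 1.47, 6.93, 1.23, 2.01, 3.09, 2.24, 11.35),
    classified_lame = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  stifle_sound <- data.frame(
    horse = 1:8,
    span_cl = c(38.27, 35.82, 40.44, 46.58, 46.09, 42.35, 37.43, 40.18),
    span_cr = c(37.76, 34.95, 39.75, 46.51, 45.93, 41.53, 36.19, 40.18),
    score = c(0.51, 0.87, 0.69, 0.07, 0.16, 0.82, 1.24, 0.00),
    classified_sound = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  tcox_lame <- data.frame(
    horse = 1:9,
    clinical_side = c("left", "right", "right", "left", "right",
                      "left", "left", "left", "right"),
    grade_band = c("3-4", "3-4", "1-2", "3-4", "1-2",
                   "1-2", "3-4", "1-2", "3-4"),
    span_cl = c(11.29, 13.18, 11.81, 15.68, 9.22, 11.53, 13.69, 7.98, 11.18),
    span_cr = c(19.21, 12.17, 14.62, 20.89, 9.95, 12.13, 15.02, 10.36, 11.27),
    score = c(7.92, 1.01, 2.81, 5.21, 0.73, 0.60, 1.33, 2.38, 0.09),
    classified_lame = c(FALSE, FALSE, TRUE, FALSE, TRUE,
                        FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  tcox_sound <- data.frame(
    horse = 1:8,
    span_cl = c(11.13, 12.06, 14.28, 13.99, 11.38, 9.96, 8.45, 8.15),
    span_cr = c(11.82, 11.55, 19.06, 14.49, 11.81, 10.64, 9.59, 9.79),
    score = c(0.69, 0.51, 4.78, 0.50, 0.43, 0.68, 1.14, 1.64),
    classified_sound = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  list(
    stifle_lame = stifle_lame,
    stifle_sound = stifle_sound,
    tcox_lame = tcox_lame,
    tcox_sound = tcox_sound,
    forelimb_counts = c(tp = 13L, fp = 0L, fn = 0L, tn = 8L)
  )
}

#' Re-derive the clinical study's scores, summaries and metrics
#'
#' Recomputes, from the printed span pairs of
#' \code{\link{clinical_reference_tables}}, everything the study derived
#' from them: per-horse circle-difference scores and stifle verdicts (at the
#' default 1.2 px threshold), the group means, the per-statistic 2x2
#' confusion tables with their test characteristics, and the 3x3
#' forelimb/hindlimb/sound agreement table with Cohen's kappa and overall
#' accuracy (hindlimb predictions from the stifle statistic only; a lame
#' horse the stifle test misses maps to predicted \code{"sound"}, a flagged
#' control to predicted \code{"hindlimb_lame"}).
#'
#' @param stifle_threshold stifle decision threshold in px.
#' @param tcox_sound_threshold control threshold of the tuber coxae
#'   evaluation in px.
#' @return A list with \code{scores} (per-table recomputed scores and
#'   verdicts), \code{group_means}, \code{tables} (confusion tables),
#'   \code{metrics} (per-test characteristics), \code{kappa} and
#'   \code{overall_accuracy}.
#' @export
reference_reanalysis <- function(stifle_threshold = 1.2,
                                 tcox_sound_threshold = 1.0) {
  ref <- clinical_reference_tables()

  score_rows <- function(df, statistic) {
    lapply(seq_len(nrow(df)), function(i) {
      compute_score(df$span_cl[i], df$span_cr[i], statistic)
    })
  }
  st_lame <- score_rows(ref$stifle_lame, "stifle")
  st_sound <- score_rows(ref$stifle_sound, "stifle")
  tc_lame <- score_rows(ref$tcox_lame, "tuber_coxae")
  tc_sound <- score_rows(ref$tcox_sound, "tuber_coxae")

  stifle_verdict <- function(scores) {
    vapply(scores, function(s) {
      classify_stifle(s, stifle_threshold)$predicted_status
    }, character(1L))
  }
  st_lame_status <- stifle_verdict(st_lame)
  st_sound_status <- stifle_verdict(st_sound)

  tc_lame_correct <- vapply(seq_along(tc_lame), function(i) {
    classify_tuber_coxae(tc_lame[[i]],
                         clinical_side = ref$tcox_lame$clinical_side[i],
                         sound_threshold = tcox_sound_threshold)$correct
  }, logical(1L))
  tc_sound_correct <- vapply(tc_sound, function(s) {
    classify_tuber_coxae(s, sound_threshold = tcox_sound_threshold)$correct
  }, logical(1L))

  # The study-level evaluation uses the verdict columns as the study printed
  # them (including its one stifle verdict the threshold rule does not
  # reproduce); the recomputed verdicts are reported alongside in $scores.
  stifle_tab <- confusion_2x2(
    tp = sum(ref$stifle_lame$classified_lame),
    fp = sum(!ref$stifle_sound$classified_sound),
    fn = sum(!ref$stifle_lame$classified_lame),
    tn = sum(ref$stifle_sound$classified_sound))
  tcox_tab <- confusion_2x2(
    tp = sum(ref$tcox_lame$classified_lame),
    fp = sum(!ref$tcox_sound$classified_sound),
    fn = sum(!ref$tcox_lame$classified_lame),
    tn = sum(ref$tcox_sound$classified_sound))
  fore_tab <- do.call(confusion_2x2, as.list(ref$forelimb_counts))

  # 3x3 agreement table from the printed verdict columns: a lame horse the
  # stifle test missed maps to predicted "sound", a flagged control to
  # predicted "hindlimb_lame".
  labels3 <- c("forelimb_lame", "hindlimb_lame", "sound")
  clinical3 <- c(rep("forelimb_lame", sum(ref$forelimb_counts[c("tp", "fn")])),
                 rep("hindlimb_lame", nrow(ref$stifle_lame)),
                 rep("sound", nrow(ref$stifle_sound)))
  predicted3 <- c(
    rep("forelimb_lame", ref$forelimb_counts[["tp"]]),
    rep("sound", ref$forelimb_counts[["fn"]]),
    ifelse(ref$stifle_lame$classified_lame, "hindlimb_lame", "sound"),
    ifelse(ref$stifle_sound$classified_sound, "sound", "hindlimb_lame"))
  tab3 <- tabulate_confusion(clinical3, predicted3, labels = labels3)

  list(
    scores = list(
      stifle_lame = vapply(st_lame, `[[`, numeric(1L), "score"),
      stifle_sound = vapply(st_sound, `[[`, numeric(1L), "score"),
      tcox_lame = vapply(tc_lame, `[[`, numeric(1L), "score"),
      tcox_sound = vapply(tc_sound, `[[`, numeric(1L), "score"),
      stifle_lame_status = st_lame_status,
      stifle_sound_status = st_sound_status,
      tcox_lame_correct = tc_lame_correct,
      tcox_sound_correct = tc_sound_correct),
    group_means = c(
      stifle_sound = group_mean(ref$stifle_sound$score),
      tcox_sound = group_mean(ref$tcox_sound$score),
      tcox_lame_detected = group_mean(
        ref$tcox_lame$score[ref$tcox_lame$classified_lame]),
      tcox_lame_nondetected = group_mean(
        ref$tcox_lame$score[!ref$tcox_lame$classified_lame])),
    tables = list(forelimb = fore_tab, stifle = stifle_tab,
                  tuber_coxae = tcox_tab, three_way = tab3),
    metrics = list(forelimb = test_characteristics(fore_tab),
                   stifle = test_characteristics(stifle_tab),
                   tuber_coxae = test_characteristics(tcox_tab)),
    kappa = cohen_kappa(tab3),
    overall_accuracy = overall_accuracy(tab3)
  )
}
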