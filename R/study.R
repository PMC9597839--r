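#' Analysis configuration
#'
#' Bundles every tunable decision parameter of the pipeline with its
#' default: the likelihood exclusion cut (0.60), the percentile bands of the
#' excursion statistics (maxima 90--95, minima 5--10), the stifle decision
#' threshold (1.2 px), the tuber coxae control threshold (1.0 px), the
#' head-nod threshold (see \code{\link{default_nod_threshold}}) and the
#' expected stride rate used for peak separation (74 strides/min).
#'
#' @param likelihood_threshold confidence cut in [0, 1].
#' @param bands percentile bands, see \code{\link{excursion_stats}}.
#' @param stifle_threshold stifle decision threshold (px).
#' @param tcox_sound_threshold tuber coxae control threshold (px).
#' @param nod_threshold head-nod decision threshold (px).
#' @param expected_rate expected strides per minute.
#' @return A list of class \code{study_config}.
#' @export
study_config <- function(likelihood_threshold = 0.60,
                         bands = list(max = c(90, 95), min = c(5, 10)),
                         stifle_threshold = 1.2,
                         tcox_sound_threshold = 1.0,
                         nod_threshold = default_nod_threshold(),
                         expected_rate = 74) {
  structure(list(likelihood_threshold = likelihood_threshold, bands = bands,
                 stifle_threshold = stifle_threshold,
                 tcox_sound_threshold = tcox_sound_threshold,
                 nod_threshold = nod_threshold,
                 expected_rate = expected_rate),
            class = "study_config")
}

#' Analyse one horse from its two circle trials
#'
#' Runs the full per-horse pipeline: likelihood filtering, stride
#' segmentation and head-nod analysis on each circle, the stifle and tuber
#' coxae circle-difference scores, and the combined predicted category
#' (forelimb lameness takes precedence over the stifle call, which takes
#' precedence over sound).
#'
#' @param cl,cr \code{\link{trial_recording}}s of the same horse on the left
#'   and right circle.
#' @param config a \code{\link{study_config}}.
#' @return A list of class \code{horse_analysis} with fields
#'   \code{horse_id}, \code{nod} (per-circle head-nod results plus the
#'   combined forelimb call), \code{stifle} and \code{tuber_coxae}
#'   (\code{\link{compute_score}} results with statuses filled),
#'   \code{n_strides} (per circle) and \code{predicted} (list with
#'   \code{status} and \code{side}).
#' @export
analyze_horse <- function(cl, cr, config = study_config()) {
  stopifnot(inherits(cl, "trial_recording"), inherits(cr, "trial_recording"))
  if (cl$circle != "CL" || cr$circle != "CR") {
    stop("cl must be the CL trial and cr the CR trial")
  }
  if (cl$horse_id != cr$horse_id) {
    stop("cl and cr belong to different horses")
  }
  fcl <- filter_trial(cl, config$likelihood_threshold)
  fcr <- filter_trial(cr, config$likelihood_threshold)

  seg_cl <- segment_strides(fcl, config$expected_rate)
  seg_cr <- segment_strides(fcr, config$expected_rate)
  nod_cl <- head_nod_index(get_series(fcl, "poll"), seg_cl,
                           threshold = config$nod_threshold)
  nod_cr <- head_nod_index(get_series(fcr, "poll"), seg_cr,
                           threshold = config$nod_threshold)
  fore <- classify_forelimb(nod_cl, nod_cr)

  stifle <- classify_stifle(
    compute_score(circle_span(fcl, "stifle", 0),
                  circle_span(fcr, "stifle", 0), "stifle"),
    threshold = config$stifle_threshold)
  tcox <- classify_tuber_coxae_unified(
    compute_score(circle_span(fcl, "tuber_coxae", 0),
                  circle_span(fcr, "tuber_coxae", 0), "tuber_coxae"),
    threshold = config$tcox_sound_threshold)

  predicted <- if (fore$status == "forelimb_lame") {
    list(status = "forelimb_lame", side = fore$side)
  } else if (stifle$predicted_status == "hindlimb_lame") {
    list(status = "hindlimb_lame", side = stifle$predicted_side)
  } else {
    list(status = "sound", side = "none")
  }

  structure(list(horse_id = cl$horse_id,
                 nod = list(cl = nod_cl, cr = nod_cr, combined = fore),
                 stifle = stifle, tuber_coxae = tcox,
                 n_strides = c(cl = seg_cl$n_strides, cr = seg_cr$n_strides),
                 predicted = predicted),
            class = "horse_analysis")
}

#' @export
print.horse_analysis <- function(x, ...) {
  cat("<horse_analysis> ", x$horse_id, ": ", x$predicted$status,
      if (x$predicted$side != "none") paste0(" (", x$predicted$side, ")"),
      "\n", sep = "")
  cat(sprintf("  nod_index CL %.3f / CR %.3f px; DSt %.2f px; DTcox %.2f px\n",
              x$nod$cl$nod_index, x$nod$cr$nod_index,
              x$stifle$score, x$tuber_coxae$score))
  invisible(x)
}

#' Run the full cohort study
#'
#' Applies \code{\link{analyze_horse}} to every horse of a cohort, compares
#' predictions with the recorded clinical ground truth, and assembles the
#' study-level evaluation: per-test 2x2 confusion tables and
#' characteristics (forelimb head-nod on forelimb-lame + sound horses;
#' stifle and tuber coxae on hindlimb-lame + sound horses), the sound-group
#' score means, and the 3x3 forelimb/hindlimb/sound agreement table with
#' Cohen's kappa and overall accuracy (hindlimb category from the stifle
#' statistic only). Horses whose analysis fails are excluded with the error
#' recorded, never silently dropped.
#'
#' @param cohort a list of horses as produced by
#'   \code{\link{simulate_cohort}}: each element needs \code{cl}, \code{cr}
#'   trials carrying clinical ground truth in their metadata.
#' @param config a \code{\link{study_config}}.
#' @return A list of class \code{gait_study} with \code{horses} (per-horse
#'   result rows), \code{failures}, \code{group_means}, \code{tables},
#'   \code{metrics}, \code{kappa} and \code{overall_accuracy}.
#' @export
run_study <- function(cohort, config = study_config()) {
  results <- list()
  failures <- list()
  for (h in cohort) {
    res <- tryCatch(analyze_horse(h$cl, h$cr, config), error = identity)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(horse_id = h$cl$horse_id, reason = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- list(
        analysis = res,
        clinical_status = h$cl$clinical_status,
        clinical_side = if (is.null(h$cl$clinical_side)) "none"
                        else h$cl$clinical_side)
    }
  }
  if (length(results) == 0L) stop("no horse could be analysed")

  status <- vapply(results, `[[`, character(1L), "clinical_status")
  pred_status <- vapply(results, function(r) r$analysis$predicted$status,
                        character(1L))
  fore_pred <- vapply(results, function(r) r$analysis$nod$combined$status,
                      character(1L))
  stifle_pred <- vapply(results,
                        function(r) r$analysis$stifle$predicted_status,
                        character(1L))
  tcox_pred <- vapply(results,
                      function(r) r$analysis$tuber_coxae$predicted_status,
                      character(1L))
  dst <- vapply(results, function(r) r$analysis$stifle$score, numeric(1L))
  dtc <- vapply(results, function(r) r$analysis$tuber_coxae$score,
                numeric(1L))

  is_fore <- status == "forelimb_lame"
  is_hind <- status == "hindlimb_lame"
  is_sound <- status == "sound"

  tab2 <- function(truth_pos, pred, positive) {
    confusion_2x2(tp = sum(truth_pos & pred == positive),
                  fp = sum(is_sound & pred == positive),
                  fn = sum(truth_pos & pred != positive),
                  tn = sum(is_sound & pred != positive))
  }
  fore_tab <- tab2(is_fore, fore_pred, "forelimb_lame")
  stifle_tab <- tab2(is_hind, stifle_pred, "hindlimb_lame")
  tcox_tab <- tab2(is_hind, tcox_pred, "hindlimb_lame")

  labels3 <- c("forelimb_lame", "hindlimb_lame", "sound")
  pred3 <- ifelse(fore_pred == "forelimb_lame", "forelimb_lame",
                  ifelse(stifle_pred == "hindlimb_lame", "hindlimb_lame",
                         "sound"))
  tab3 <- tabulate_confusion(status, pred3, labels = labels3)

  group_means <- c(
    stifle_sound = if (any(is_sound)) group_mean(dst[is_sound]) else NA_real_,
    stifle_hindlimb = if (any(is_hind)) group_mean(dst[is_hind]) else NA_real_,
    tcox_sound = if (any(is_sound)) group_mean(dtc[is_sound]) else NA_real_,
    tcox_hindlimb = if (any(is_hind)) group_mean(dtc[is_hind]) else NA_real_)

  horses <- data.frame(
    horse_id = vapply(results, function(r) r$analysis$horse_id,
                      character(1L)),
    clinical_status = status,
    clinical_side = vapply(results, `[[`, character(1L), "clinical_side"),
    predicted_status = pred_status,
    predicted_side = vapply(results, function(r) r$analysis$predicted$side,
                            character(1L)),
    nod_cl = vapply(results, function(r) r$analysis$nod$cl$nod_index,
                    numeric(1L)),
    nod_cr = vapply(results, function(r) r$analysis$nod$cr$nod_index,
                    numeric(1L)),
    dst = dst,
    dtcox = dtc,
    n_strides_cl = vapply(results, function(r) r$analysis$n_strides[["cl"]],
                          integer(1L)),
    n_strides_cr = vapply(results, function(r) r$analysis$n_strides[["cr"]],
                          integer(1L)),
    stringsAsFactors = FALSE)

  structure(list(
    horses = horses,
    failures = failures,
    group_means = group_means,
    tables = list(forelimb = fore_tab, stifle = stifle_tab,
                  tuber_coxae = tcox_tab, three_way = tab3),
    metrics = list(forelimb = test_characteristics(fore_tab),
                   stifle = test_characteristics(stifle_tab),
                   tuber_coxae = test_characteristics(tcox_tab)),
    kappa = cohen_kappa(tab3),
    overall_accuracy = overall_accuracy(tab3),
    config = config
  ), class = "gait_study")
}

#' @export
print.gait_study <- function(x, ...) {
  cat("<gait_study> ", nrow(x$horses), " horses analysed",
      if (length(x$failures)) paste0(" (", length(x$failures), " failed)"),
      "\n\n", sep = "")
  cat("Test                TP  FP  FN  TN    SE    SP   ACC   PPV   NPV\n")
  row <- function(label, tab, m) {
    cat(sprintf("%-18s %3d %3d %3d %3d %5.1f %5.1f %5.1f %5.1f %5.1f\n",
                label, tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2],
                m[["SE"]], m[["SP"]], m[["ACC"]], m[["PPV"]], m[["NPV"]]))
  }
  row("Forelimb nod", x$tables$forelimb, x$metrics$forelimb)
  row("Hindlimb stifle", x$tables$stifle, x$metrics$stifle)
  row("Hindlimb t. coxae", x$tables$tuber_coxae, x$metrics$tuber_coxae)
  cat(sprintf("\nkappa (3x3, stifle-based) %.4f, overall accuracy %.1f%%\n",
              x$kappa, x$overall_accuracy))
  invisible(x)
}

#' Serialise a study report as JSON
#'
#' @param study a \code{\link{run_study}} result.
#' @param path output file; when \code{NULL} the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
write_study_json <- function(study, path = NULL) {
  stopifnot(inherits(study, "gait_study"))
  payload <- list(
    horses = study$horses,
    failures = study$failures,
    group_means = as.list(study$group_means),
    tables = lapply(study$tables, function(t) {
      list(labels = rownames(t), counts = unclass(t))
    }),
    metrics = lapply(study$metrics, as.list),
    kappa = study$kappa,
    overall_accuracy = study$overall_accuracy)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Plot poll and forelimb traces of a trial
#'
#' Draws the limb protraction traces of both forelimbs (the circle-facing
#' one tracked, the contralateral one inferred) and, below, the poll height
#' with the detected stance onsets — the chart a clinician reads the head
#' nod from.
#'
#' @param x a \code{\link{trial_recording}}.
#' @param frames frame range to display.
#' @param config a \code{\link{study_config}}.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.trial_recording <- function(x, frames = 1:300, config = study_config(),
                                 ...) {
  trial <- filter_trial(x, config$likelihood_threshold)
  side <- if (trial$circle == "CL") "left" else "right"
  limb <- get_series(trial, paste0("os_carpi_accessorium_", side))
  poll <- get_series(trial, "poll")
  seg <- segment_strides(trial, config$expected_rate)
  frames <- frames[frames <= n_frames(trial)]

  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(frames, limb$x[frames], type = "l", col = "grey40",
                 xlab = "frame", ylab = "limb x (px)",
                 main = paste0(trial$horse_id, " ", trial$circle,
                               ": forelimb protraction"), ...)
  onsets <- seg$onsets_left
  if (side == "right") onsets <- seg$onsets_right
  graphics::abline(v = onsets[onsets %in% frames], col = "grey70", lty = 3)
  graphics::plot(frames, -poll$y[frames], type = "l", col = "darkgreen",
                 xlab = "frame", ylab = "poll height (px)",
                 main = "poll height with stance onsets", ...)
  graphics::abline(v = onsets[onsets %in% frames], col = "grey70", lty = 3)
  invisible(x)
}
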