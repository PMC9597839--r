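#' Read a DeepLabCut-style trajectory CSV
#'
#' Parses the three-header-row CSV dialect the pose-estimation ecosystem
#' emits: a \code{scorer} row, a \code{bodyparts} row and a \code{coords}
#' row, followed by one data row per video frame. Each bodypart contributes
#' a column triplet \code{x}, \code{y}, \code{likelihood}. A leading
#' frame-index column is accepted and regenerated on write.
#'
#' Bodyparts present in the file but absent from \code{map} are skipped with
#' a warning; bodyparts are matched by name. Empty cells become missing
#' coordinates; non-numeric cells are an error.
#'
#' @param path CSV file path.
#' @param map a \code{\link{bodypart_map}} naming the bodyparts of interest.
#' @param meta named list of trial metadata: \code{horse_id}, \code{circle},
#'   optional \code{fps}, \code{resolution}, \code{clinical_status},
#'   \code{clinical_side}, \code{aaep_grade} (see
#'   \code{\link{trial_recording}}); typically from
#'   \code{\link{read_trial_metadata}}.
#' @return A \code{\link{trial_recording}}.
#' @seealso \code{\link{write_dlc_csv}}
#' @export
read_dlc_csv <- function(path, map = default_bodypart_map(), meta) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) {
    stop("malformed trajectory CSV: fewer than 3 header rows in ", path)
  }
  hdr <- lapply(lines[1:3], function(l) strsplit(l, ",", fixed = TRUE)[[1L]])
  labels <- vapply(hdr, `[`, character(1L), 1L)
  expected <- c("scorer", "bodyparts", "coords")
  bad <- which(labels != expected)
  if (length(bad) > 0L) {
    stop("malformed header row ", bad[1L], ": expected label '",
         expected[bad[1L]], "', found '", labels[bad[1L]], "'")
  }
  bodyparts <- hdr[[2L]][-1L]
  coords <- hdr[[3L]][-1L]
  if (length(bodyparts) != length(coords) || length(bodyparts) %% 3L != 0L) {
    stop("malformed header: bodyparts/coords rows must pair x, y, ",
         "likelihood triplets")
  }
  triplet_ok <- all(coords == rep(c("x", "y", "likelihood"),
                                  length(coords) / 3L))
  if (!triplet_ok) {
    stop("malformed header row 3: coords must repeat x, y, likelihood")
  }
  part_names <- bodyparts[seq(1L, length(bodyparts), by = 3L)]
  if (!all(bodyparts == rep(part_names, each = 3L))) {
    stop("malformed header row 2: each bodypart must span exactly ",
         "3 adjacent columns")
  }

  data_lines <- lines[-(1:3)]
  n <- length(data_lines)
  ncol_expect <- length(coords) + 1L
  vals <- matrix(NA_real_, nrow = n, ncol = length(coords))
  if (n > 0L) {
    cells <- strsplit(data_lines, ",", fixed = TRUE)
    for (i in seq_len(n)) {
      row <- cells[[i]]
      length(row) <- ncol_expect   # pad trailing empties
      body <- row[-1L]
      num <- suppressWarnings(as.numeric(body))
      bad_cell <- which(!is.na(body) & body != "" & is.na(num))
      if (length(bad_cell) > 0L) {
        stop("non-numeric cell at frame ", i, ", column ",
             bad_cell[1L] + 1L, " in ", path)
      }
      vals[i, ] <- num
    }
  }

  keep <- part_names %in% map$name
  if (any(!keep)) {
    warning("ignoring unmapped bodypart(s): ",
            paste(part_names[!keep], collapse = ", "))
  }
  series <- list()
  for (j in which(keep)) {
    col0 <- (j - 1L) * 3L
    lik <- vals[, col0 + 3L]
    if (any(!is.na(lik) & (lik < 0 | lik > 1))) {
      bad_frame <- which(!is.na(lik) & (lik < 0 | lik > 1))[1L]
      stop("likelihood outside [0, 1] for bodypart '", part_names[j],
           "' at frame ", bad_frame)
    }
    series[[part_names[j]]] <- keypoint_series(
      x = vals[, col0 + 1L], y = vals[, col0 + 2L], likelihood = lik)
  }

  args <- c(list(series = series), meta)
  do.call(trial_recording, args)
}

#' Write a trial as a DeepLabCut-style trajectory CSV
#'
#' Emits the three-header-row dialect read by \code{\link{read_dlc_csv}},
#' with a leading frame-index column (0-based, as the ecosystem writes it).
#' Coordinates are written with full precision so a read/write round trip
#' reproduces them exactly.
#'
#' @param trial a \code{\link{trial_recording}}.
#' @param path output file path.
#' @param scorer label for the scorer header row.
#' @return \code{path}, invisibly.
#' @export
write_dlc_csv <- function(trial, path, scorer = "equigait") {
  stopifnot(inherits(trial, "trial_recording"))
  parts <- names(trial$series)
  h1 <- paste(c("scorer", rep(scorer, 3L * length(parts))), collapse = ",")
  h2 <- paste(c("bodyparts", rep(parts, each = 3L)), collapse = ",")
  h3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))),
              collapse = ",")
  n <- n_frames(trial)
  lines <- c(h1, h2, h3)
  if (n > 0L) {
    cols <- vector("list", 1L + 3L * length(parts))
    cols[[1L]] <- format(seq_len(n) - 1L, trim = TRUE, scientific = FALSE)
    fmt <- function(v) {
      out <- vapply(v, function(z) {
        if (is.na(z)) "" else format(z, digits = 17, trim = TRUE,
                                     scientific = FALSE)
      }, character(1L))
      out
    }
    for (j in seq_along(parts)) {
      s <- trial$series[[j]]
      cols[[3L * j - 1L]] <- fmt(s$x)
      cols[[3L * j]] <- fmt(s$y)
      cols[[3L * j + 1L]] <- fmt(s$likelihood)
    }
    lines <- c(lines, do.call(paste, c(cols, sep = ",")))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read or write the trial metadata YAML sidecar
#'
#' The sidecar carries \code{horse_id}, \code{circle}, \code{fps},
#' \code{resolution} and, when known, \code{clinical_status},
#' \code{clinical_side} and \code{aaep_grade}.
#'
#' @param path YAML file path.
#' @param trial a \code{\link{trial_recording}} whose metadata to write.
#' @return \code{read_trial_metadata} returns a named list suitable as the
#'   \code{meta} argument of \code{\link{read_dlc_csv}};
#'   \code{write_trial_metadata} returns \code{path} invisibly.
#' @export
read_trial_metadata <- function(path) {
  meta <- yaml::read_yaml(path)
  if (is.null(meta$horse_id) || is.null(meta$circle)) {
    stop("trial metadata must name horse_id and circle")
  }
  if (!is.null(meta$resolution)) meta$resolution <- as.integer(meta$resolution)
  meta
}

#' @rdname read_trial_metadata
#' @export
write_trial_metadata <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  meta <- list(horse_id = trial$horse_id, circle = trial$circle,
               gait = trial$gait, fps = trial$fps,
               resolution = as.integer(trial$resolution))
  if (!is.null(trial$clinical_status)) {
    meta$clinical_status <- trial$clinical_status
  }
  if (!is.null(trial$clinical_side)) meta$clinical_side <- trial$clinical_side
  if (!is.null(trial$aaep_grade)) meta$aaep_grade <- trial$aaep_grade
  yaml::write_yaml(meta, path)
  invisible(path)
}
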