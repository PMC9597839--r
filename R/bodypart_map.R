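#' Bodypart naming maps
#'
#' A bodypart map binds the numeric reference-point indices used by the pose
#' estimation model (1--58) to stable anatomical names, a body side and a
#' body region. The analyses in this package address bodyparts by name
#' (e.g. \code{"stifle_left"}), so the map is the single place where a
#' user's labelling scheme is reconciled with the package's expectations.
#'
#' @details
#' Thirteen reference points are analysis-critical and must be present in
#' every map: the poll (index 4), the left/right elbow (17/18), os carpi
#' accessorium (19/20), carpus (21/22), tuber coxae (33/34), stifle (43/44)
#' and tarsus (45/46). The remaining points of the 58-point scheme are
#' optional; unmapped bodyparts in a trajectory file are ignored with a
#' warning. The tuber coxae indices are a package convention (the full
#' published index list is not machine-readable); override them in a custom
#' map if your labelling differs.
#'
#' @param entries data frame with columns \code{index}, \code{name},
#'   \code{side} (one of \code{"left"}, \code{"right"}, \code{"midline"})
#'   and \code{region} (one of \code{"head"}, \code{"neck_trunk"},
#'   \code{"forelimb"}, \code{"hindlimb"}).
#' @return An object of class \code{bodypart_map} (a validated data frame).
#' @examples
#' map <- default_bodypart_map()
#' map[map$name == "stifle_left", ]
#' @export
bodypart_map <- function(entries) {
  stopifnot(is.data.frame(entries))
  required_cols <- c("index", "name", "side", "region")
  missing_cols <- setdiff(required_cols, names(entries))
  if (length(missing_cols) > 0L) {
    stop("bodypart map lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  entries$index <- as.integer(entries$index)
  entries$name <- as.character(entries$name)
  if (anyNA(entries$index) || any(entries$index < 1L | entries$index > 58L)) {
    stop("bodypart indices must be integers in 1..58")
  }
  if (anyDuplicated(entries$index)) {
    stop("duplicate bodypart indices in map")
  }
  if (anyDuplicated(entries$name)) {
    stop("duplicate bodypart names in map")
  }
  if (!all(entries$side %in% c("left", "right", "midline"))) {
    stop("bodypart side must be left, right or midline")
  }
  if (!all(entries$region %in% c("head", "neck_trunk", "forelimb", "hindlimb"))) {
    stop("bodypart region must be head, neck_trunk, forelimb or hindlimb")
  }
  crit <- critical_bodyparts()
  missing_crit <- setdiff(crit$index, entries$index)
  if (length(missing_crit) > 0L) {
    stop("map lacks analysis-critical reference point(s): ",
         paste(missing_crit, collapse = ", "))
  }
  entries <- entries[order(entries$index), required_cols]
  rownames(entries) <- NULL
  class(entries) <- c("bodypart_map", "data.frame")
  entries
}

# The thirteen reference points every analysis path consumes.
critical_bodyparts <- function() {
  data.frame(
    index = c(4L, 17L, 18L, 19L, 20L, 21L, 22L, 33L, 34L, 43L, 44L, 45L, 46L),
    name = c("poll",
             "elbow_left", "elbow_right",
             "os_carpi_accessorium_left", "os_carpi_accessorium_right",
             "carpus_left", "carpus_right",
             "tuber_coxae_left", "tuber_coxae_right",
             "stifle_left", "stifle_right",
             "tarsus_left", "tarsus_right"),
    side = c("midline",
             "left", "right", "left", "right", "left", "right",
             "left", "right", "left", "right", "left", "right"),
    region = c("head",
               "forelimb", "forelimb", "forelimb", "forelimb",
               "forelimb", "forelimb",
               "hindlimb", "hindlimb", "hindlimb", "hindlimb",
               "hindlimb", "hindlimb"),
    stringsAsFactors = FALSE
  )
}

#' @rdname bodypart_map
#' @export
default_bodypart_map <- function() {
  bodypart_map(critical_bodyparts())
}

#' Read or write a bodypart map as YAML
#'
#' The YAML layout is a list of entries, each with keys \code{index},
#' \code{name}, \code{side} and \code{region}.
#'
#' @param path file path of the YAML map.
#' @param map a \code{\link{bodypart_map}}.
#' @return \code{read_bodypart_map} returns a \code{bodypart_map};
#'   \code{write_bodypart_map} returns \code{path} invisibly.
#' @export
read_bodypart_map <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || length(raw) == 0L) {
    stop("bodypart map YAML must be a non-empty list of entries")
  }
  entries <- do.call(rbind, lapply(raw, function(e) {
    data.frame(index = as.integer(e$index), name = as.character(e$name),
               side = as.character(e$side), region = as.character(e$region),
               stringsAsFactors = FALSE)
  }))
  bodypart_map(entries)
}

#' @rdname read_bodypart_map
#' @export
write_bodypart_map <- function(map, path) {
  stopifnot(inherits(map, "bodypart_map"))
  entries <- lapply(seq_len(nrow(map)), function(i) {
    list(index = map$index[i], name = map$name[i],
         side = map$side[i], region = map$region[i])
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

# Name of the circle-facing bodypart for a paired landmark.
# CL (left-hand circle) exposes the horse's left side to the camera,
# CR its right side.
facing_bodypart <- function(base, circle) {
  side <- if (circle == "CL") "left" else "right"
  paste0(base, "_", side)
}
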