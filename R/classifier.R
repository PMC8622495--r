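#' Per-level diagnostic band table
#'
#' Numeric thresholds that split each level's sagittal translation and
#' rotation into three bands: below the sub-threshold lower bound is normal
#' motion, from the lower bound up to (and including) the instability
#' threshold is the sub-threshold lumbar instability (STLI) band, and above
#' the instability threshold is radiological lumbar instability (LI).
#'
#' @param translation_stli_low,translation_li Numeric length-5 vectors (mm),
#'   one entry per level in [lumbar_levels()] order.
#' @param rotation_stli_low,rotation_li Numeric length-5 vectors (degrees).
#' @return A data frame of class `"band_table"` with one row per level.
#' @seealso [default_band_table()] for the published thresholds.
#' @export
band_table <- function(translation_stli_low, translation_li,
                       rotation_stli_low, rotation_li) {
  args <- list(translation_stli_low = translation_stli_low,
               translation_li = translation_li,
               rotation_stli_low = rotation_stli_low,
               rotation_li = rotation_li)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 5L || !all(is.finite(v)) || any(v <= 0)) {
      stop("'", nm, "' must be 5 finite positive thresholds, one per level",
           call. = FALSE)
    }
  }
  if (any(translation_stli_low >= translation_li) ||
      any(rotation_stli_low >= rotation_li)) {
    stop("each STLI lower bound must lie strictly below its LI threshold",
         call. = FALSE)
  }
  out <- data.frame(level = lumbar_levels(), args,
                    stringsAsFactors = FALSE, row.names = lumbar_levels())
  class(out) <- c("band_table", "data.frame")
  out
}

#' Published diagnostic band thresholds
#'
#' The default [band_table()]: STLI lower bounds are the upper limits of
#' asymptomatic segmental motion (Staub et al.'s reference ranges) and LI
#' thresholds are the White & Panjabi radiographic instability criteria
#' (translation > 4.5 mm at every level; rotation > 15 degrees at L1/L2
#' through L3/L4, > 20 degrees at L4/L5, > 25 degrees at L5/S1).
#'
#' @return A `"band_table"` data frame.
#' @export
#' @examples
#' default_band_table()
default_band_table <- function() {
  band_table(
    translation_stli_low = c(1.9, 2.4, 2.7, 2.8, 0.5),
    translation_li = rep(4.5, 5),
    rotation_stli_low = c(11.0, 12.6, 13.3, 14.7, 12.8),
    rotation_li = c(15, 15, 15, 20, 25)
  )
}

band_for <- function(value, stli_low, li) {
  if (value > li) "LI" else if (value >= stli_low) "STLI" else "normal"
}

#' Band assignment for one translation value
#'
#' @param level Segment identifier, one of [lumbar_levels()].
#' @param translation_mm Absolute sagittal translation excursion (mm, >= 0).
#' @param bands A [band_table()]; defaults to the published thresholds.
#' @return `"normal"`, `"STLI"` or `"LI"`. The STLI band is closed at both
#'   ends: the lower bound and the 4.5 mm LI threshold itself are STLI,
#'   values strictly above the threshold are LI.
#' @export
#' @examples
#' translation_band("L1L2", 1.9) # "STLI": lower bound is inclusive
#' translation_band("L3L4", 5.0) # "LI"
translation_band <- function(level, translation_mm, bands = default_band_table()) {
  check_level(level)
  stopifnot(inherits(bands, "band_table"))
  if (!is.finite(translation_mm) || translation_mm < 0) {
    stop("'translation_mm' must be a finite nonnegative excursion",
         call. = FALSE)
  }
  band_for(translation_mm, bands[level, "translation_stli_low"],
           bands[level, "translation_li"])
}

#' Band assignment for one rotation value
#'
#' @param level Segment identifier, one of [lumbar_levels()].
#' @param rotation_deg Absolute sagittal rotation excursion (degrees, >= 0).
#' @inheritParams translation_band
#' @return `"normal"`, `"STLI"` or `"LI"`, with the same closed-band
#'   convention as [translation_band()].
#' @export
#' @examples
#' rotation_band("L4L5", 14.7) # "STLI"
#' rotation_band("L5S1", 26.0) # "LI"
rotation_band <- function(level, rotation_deg, bands = default_band_table()) {
  check_level(level)
  stopifnot(inherits(bands, "band_table"))
  if (!is.finite(rotation_deg) || rotation_deg < 0) {
    stop("'rotation_deg' must be a finite nonnegative excursion", call. = FALSE)
  }
  band_for(rotation_deg, bands[level, "rotation_stli_low"],
           bands[level, "rotation_li"])
}

as_kinematics_frame <- function(kinematics) {
  if (is.data.frame(kinematics)) {
    need <- c("level", "rotation", "translation")
    if (!all(need %in% names(kinematics))) {
      stop("kinematics data frame needs columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    kin <- kinematics[, need]
  } else if (is.list(kinematics) &&
             all(vapply(kinematics, inherits, TRUE, "segment_kinematics"))) {
    kin <- data.frame(
      level = vapply(kinematics, `[[`, "", "level"),
      rotation = vapply(kinematics, `[[`, 0, "rotation"),
      translation = vapply(kinematics, `[[`, 0, "translation"),
      stringsAsFactors = FALSE
    )
  } else {
    stop("'kinematics' must be a data frame or a list of segment_kinematics",
         call. = FALSE)
  }
  if (anyDuplicated(kin$level)) {
    stop("duplicate lumbar level in kinematics", call. = FALSE)
  }
  if (!setequal(kin$level, lumbar_levels())) {
    stop("kinematics must cover exactly the five levels ",
         paste(lumbar_levels(), collapse = ", "), call. = FALSE)
  }
  kin[match(lumbar_levels(), kin$level), ]
}

#' Radiographic STLI diagnosis for one participant
#'
#' Applies the composite diagnosis rule to a participant's five-segment
#' kinematics. Any single measurement beyond its LI threshold classifies
#' the participant as `LI`. Otherwise the participant is `STLI` when
#' STLI-band criteria (rotation and translation counted separately) occur
#' in at least two distinct segments, or when both rotation and translation
#' fall in the STLI band within the same single segment; `normal`
#' otherwise. Measurements are treated as absolute excursions, so signs are
#' dropped before banding.
#'
#' Participants labelled `LI` met the study's radiological exclusion
#' criterion; they still receive a label so the caller can flag and exclude
#' them.
#'
#' @param kinematics Either a data frame with columns `level`, `rotation`
#'   (degrees) and `translation` (mm) covering exactly the five levels, or
#'   a list of five [segment_kinematics()] records.
#' @param bands A [band_table()]; defaults to the published thresholds.
#' @return An object of class `"stli_diagnosis"`: a list with `label`
#'   (`"normal"`, `"STLI"` or `"LI"`), `bands` (per-level band assignments
#'   for both measures), `criterion_count` (number of STLI-band criteria
#'   met) and `trigger` (which clause of the rule fired).
#' @export
#' @examples
#' kin <- data.frame(level = lumbar_levels(),
#'                   rotation = c(5, 5, 5, 16, 5),
#'                   translation = c(1, 1, 1, 3.0, 0.2))
#' classify_participant(kin)$label # both measures STLI at L4/L5 -> "STLI"
classify_participant <- function(kinematics, bands = default_band_table()) {
  kin <- as_kinematics_frame(kinematics)
  tb <- vapply(seq_len(5), function(i) {
    translation_band(kin$level[i], abs(kin$translation[i]), bands)
  }, "")
  rb <- vapply(seq_len(5), function(i) {
    rotation_band(kin$level[i], abs(kin$rotation[i]), bands)
  }, "")
  assignments <- data.frame(level = kin$level, translation_band = tb,
                            rotation_band = rb, stringsAsFactors = FALSE)
  stli_t <- tb == "STLI"
  stli_r <- rb == "STLI"
  criterion_count <- sum(stli_t) + sum(stli_r)
  if (any(tb == "LI") || any(rb == "LI")) {
    label <- "LI"
    trigger <- "LI threshold exceeded"
  } else if (sum(stli_t | stli_r) >= 2L) {
    label <- "STLI"
    trigger <- "criteria in two segments"
  } else if (any(stli_t & stli_r)) {
    label <- "STLI"
    trigger <- "rotation and translation in one segment"
  } else {
    label <- "normal"
    trigger <- "no clause satisfied"
  }
  structure(list(label = label, bands = assignments,
                 criterion_count = criterion_count, trigger = trigger),
            class = "stli_diagnosis")
}

#' @export
print.stli_diagnosis <- function(x, ...) {
  cat("Radiographic diagnosis:", x$label,
      sprintf("(%d STLI-band criteria; %s)\n", x$criterion_count, x$trigger))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Classify every participant in a long kinematics table
#'
#' @param kinematics Data frame with columns `participant`, `level`,
#'   `rotation`, `translation`; five rows per participant.
#' @inheritParams classify_participant
#' @return Data frame with one row per participant: `participant`, `label`,
#'   `trigger`, `criterion_count`.
#' @export
classify_cohort <- function(kinematics, bands = default_band_table()) {
  stopifnot(is.data.frame(kinematics),
            all(c("participant", "level", "rotation", "translation") %in%
                  names(kinematics)))
  ids <- unique(kinematics$participant)
  if (length(ids) == 0L) {
    return(data.frame(participant = character(0), label = character(0),
                      trigger = character(0), criterion_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(ids, function(id) {
    d <- classify_participant(kinematics[kinematics$participant == id, ], bands)
    data.frame(participant = id, label = d$label, trigger = d$trigger,
               criterion_count = d$criterion_count, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
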