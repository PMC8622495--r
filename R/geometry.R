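#' Lumbar segment levels
#'
#' The five lumbar motion segments, from L1/L2 down to the lumbosacral
#' junction, in canonical cranio-caudal order. All per-level tables in the
#' package use these identifiers.
#'
#' @return Character vector of length five:
#'   `"L1L2", "L2L3", "L3L4", "L4L5", "L5S1"`.
#' @export
#' @examples
#' lumbar_levels()
lumbar_levels <- function() {
  c("L1L2", "L2L3", "L3L4", "L4L5", "L5S1")
}

check_level <- function(level) {
  if (length(level) != 1L || !level %in% lumbar_levels()) {
    stop("unknown lumbar level: ", paste(level, collapse = ", "),
         " (expected one of ", paste(lumbar_levels(), collapse = ", "), ")",
         call. = FALSE)
  }
  level
}

check_point <- function(p, name) {
  if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p))) {
    stop("landmark '", name, "' must be a finite 2-D point (x, y) in mm",
         call. = FALSE)
  }
  as.numeric(p)
}

#' Vertebral landmark set for one motion segment on one film
#'
#' Bundles the sagittal-plane landmarks digitised on a single lateral
#' radiograph (flexion or extension) for one lumbar motion segment: the
#' endplate baseline of the upper vertebra (its inferior endplate, adjacent
#' to the disc), the superior endplate baseline of the lower vertebra, and
#' the posterior corner of each vertebral body. Coordinates are in mm in the
#' sagittal image plane, x increasing anteriorly and y cranially.
#'
#' @param level Segment identifier, one of [lumbar_levels()].
#' @param phase `"flexion"` or `"extension"`.
#' @param upper_endplate_anterior,upper_endplate_posterior Numeric length-2
#'   points (mm) on the upper vertebra's endplate baseline.
#' @param lower_endplate_anterior,lower_endplate_posterior Numeric length-2
#'   points (mm) on the lower vertebra's superior endplate baseline.
#' @param upper_posterior_corner,lower_posterior_corner Numeric length-2
#'   posterior body corners (mm) used for the translation measurement.
#'
#' @return An object of class `"vertebral_landmarks"`.
#' @seealso [endplate_angle()], [posterior_offset()], [sample_landmarks()]
#' @export
vertebral_landmarks <- function(level, phase,
                                upper_endplate_anterior,
                                upper_endplate_posterior,
                                lower_endplate_anterior,
                                lower_endplate_posterior,
                                upper_posterior_corner,
                                lower_posterior_corner) {
  check_level(level)
  phase <- match.arg(phase, c("flexion", "extension"))
  pts <- list(
    upper_endplate_anterior = check_point(upper_endplate_anterior, "upper_endplate_anterior"),
    upper_endplate_posterior = check_point(upper_endplate_posterior, "upper_endplate_posterior"),
    lower_endplate_anterior = check_point(lower_endplate_anterior, "lower_endplate_anterior"),
    lower_endplate_posterior = check_point(lower_endplate_posterior, "lower_endplate_posterior"),
    upper_posterior_corner = check_point(upper_posterior_corner, "upper_posterior_corner"),
    lower_posterior_corner = check_point(lower_posterior_corner, "lower_posterior_corner")
  )
  if (identical(pts$upper_endplate_anterior, pts$upper_endplate_posterior) ||
      identical(pts$lower_endplate_anterior, pts$lower_endplate_posterior)) {
    stop("degenerate geometry: anterior and posterior endplate points coincide",
         call. = FALSE)
  }
  structure(c(list(level = level, phase = phase), pts),
            class = "vertebral_landmarks")
}

#' @export
print.vertebral_landmarks <- function(x, ...) {
  cat("Vertebral landmarks:", x$level, "(", x$phase, "film )\n")
  for (nm in setdiff(names(x), c("level", "phase"))) {
    cat(sprintf("  %-25s (%8.3f, %8.3f) mm\n", nm, x[[nm]][1], x[[nm]][2]))
  }
  invisible(x)
}

# Signed angle (degrees) of the anterior-pointing direction of a baseline.
baseline_angle <- function(anterior, posterior, what) {
  d <- anterior - posterior
  if (sqrt(sum(d^2)) < sqrt(.Machine$double.eps)) {
    stop("degenerate geometry: ", what, " baseline points coincide",
         call. = FALSE)
  }
  atan2(d[2], d[1]) * 180 / pi
}

# Wrap an angle in degrees to (-180, 180].
wrap_angle <- function(theta) {
  w <- theta - 360 * floor((theta + 180) / 360)
  ifelse(w <= -180, w + 360, w)
}

#' Intervertebral endplate angle on one film
#'
#' Signed angle, in degrees, between the upper vertebra's endplate baseline
#' and the lower vertebra's superior endplate baseline, the per-film
#' angular quantity of the sagittal-rotation measurement. Positive when the
#' upper baseline is rotated counter-clockwise (anterior end cranially)
#' relative to the lower, in the anterior-x / cranial-y image frame.
#' Invariant under any rigid motion applied to both vertebrae together.
#'
#' @param landmarks A [vertebral_landmarks()] object.
#' @return Signed angle in degrees, in (-180, 180].
#' @export
#' @examples
#' lm <- sample_landmarks(rotation = 10, translation = 2)$flexion
#' endplate_angle(lm)
endplate_angle <- function(landmarks) {
  stopifnot(inherits(landmarks, "vertebral_landmarks"))
  upper <- baseline_angle(landmarks$upper_endplate_anterior,
                          landmarks$upper_endplate_posterior, "upper endplate")
  lower <- baseline_angle(landmarks$lower_endplate_anterior,
                          landmarks$lower_endplate_posterior, "lower endplate")
  wrap_angle(upper - lower)
}

#' Posterior-edge offset on one film
#'
#' Signed anteroposterior offset, in mm, between the posterior body corners
#' of the upper and lower vertebrae, the per-film linear quantity of the
#' sagittal-translation measurement. Both corners are projected
#' perpendicularly onto the lower vertebra's superior endplate line and the
#' distance between the projections is measured along that line; positive
#' when the upper vertebra's corner lies anterior to the lower vertebra's.
#'
#' @param landmarks A [vertebral_landmarks()] object.
#' @return Signed offset in mm.
#' @export
posterior_offset <- function(landmarks) {
  stopifnot(inherits(landmarks, "vertebral_landmarks"))
  d <- landmarks$lower_endplate_anterior - landmarks$lower_endplate_posterior
  len <- sqrt(sum(d^2))
  if (len < sqrt(.Machine$double.eps)) {
    stop("degenerate geometry: lower endplate baseline points coincide",
         call. = FALSE)
  }
  u <- d / len
  sum((landmarks$upper_posterior_corner - landmarks$lower_posterior_corner) * u)
}

check_signed_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  as.numeric(x)
}

#' Sagittal rotation of a segment from its two film angles
#'
#' Total angular excursion of the segment between the flexion and extension
#' films, rotation = A - (-a), evaluated on the magnitude convention: `A` is
#' the flexion-film angulation recorded as positive and `a` the magnitude of
#' the extension-film angulation on the opposite side, so the excursion is
#' `A + a` degrees. When both film angles carry the same sign convention
#' (as returned by [endplate_angle()]), use their difference instead, which
#' is what [measure_segment()] does.
#'
#' @param A Flexion-film angulation, degrees (positive by convention).
#' @param a Magnitude of the extension-film angulation, degrees.
#' @return Sagittal rotation in degrees.
#' @export
#' @examples
#' segment_rotation(8, 6) # 14 degrees of total excursion
segment_rotation <- function(A, a) {
  check_signed_scalar(A, "A") + check_signed_scalar(a, "a")
}

#' Sagittal translation of a segment from its two film offsets
#'
#' Total anteroposterior excursion between the flexion and extension films,
#' translation = B - (-b) evaluated as `B + b` mm, with `B` the flexion-film
#' posterior-edge offset and `b` the magnitude of the extension-film offset
#' on the opposite side. See [segment_rotation()] for the sign convention.
#'
#' @param B Flexion-film offset, mm.
#' @param b Magnitude of the extension-film offset, mm.
#' @return Sagittal translation in mm.
#' @export
#' @examples
#' segment_translation(2.5, 1.5) # 4.0 mm
segment_translation <- function(B, b) {
  check_signed_scalar(B, "B") + check_signed_scalar(b, "b")
}

#' Segment kinematics record
#'
#' Holds the measured sagittal rotation (degrees) and translation (mm) of
#' one lumbar segment, each the mean of `n_repeats` raw measurements.
#'
#' @param level Segment identifier, one of [lumbar_levels()].
#' @param rotation Mean sagittal rotation, degrees.
#' @param translation Mean sagittal translation, mm.
#' @param n_repeats Number of raw measurements averaged (>= 1).
#' @return An object of class `"segment_kinematics"`.
#' @export
segment_kinematics <- function(level, rotation, translation, n_repeats = 1L) {
  check_level(level)
  rotation <- check_signed_scalar(rotation, "rotation")
  translation <- check_signed_scalar(translation, "translation")
  if (!is.numeric(n_repeats) || length(n_repeats) != 1L || n_repeats < 1) {
    stop("'n_repeats' must be a single count >= 1", call. = FALSE)
  }
  structure(list(level = level, rotation = rotation,
                 translation = translation, n_repeats = as.integer(n_repeats)),
            class = "segment_kinematics")
}

#' @export
print.segment_kinematics <- function(x, ...) {
  cat(sprintf("%s: rotation %.3f deg, translation %.3f mm (mean of %d)\n",
              x$level, x$rotation, x$translation, x$n_repeats))
  invisible(x)
}

#' Measure a segment once from a flexion/extension film pair
#'
#' Applies [endplate_angle()] and [posterior_offset()] to both films and
#' takes the flexion-minus-extension difference, which equals the
#' range-of-motion formulas rotation = A - (-a) and translation = B - (-b)
#' when the extension-film quantities carry the opposite sign.
#'
#' @param flexion,extension [vertebral_landmarks()] for the same segment on
#'   the flexion and extension films.
#' @return A [segment_kinematics()] record with `n_repeats = 1`.
#' @export
measure_segment <- function(flexion, extension) {
  stopifnot(inherits(flexion, "vertebral_landmarks"),
            inherits(extension, "vertebral_landmarks"))
  if (!identical(flexion$level, extension$level)) {
    stop("flexion and extension landmarks belong to different levels",
         call. = FALSE)
  }
  if (flexion$phase != "flexion" || extension$phase != "extension") {
    stop("expected a flexion film and an extension film, in that order",
         call. = FALSE)
  }
  rotation <- wrap_angle(endplate_angle(flexion) - endplate_angle(extension))
  translation <- posterior_offset(flexion) - posterior_offset(extension)
  segment_kinematics(flexion$level, rotation, translation, n_repeats = 1L)
}

#' Triplicate measurement of a segment
#'
#' Emulates the study protocol of measuring each level three times and
#' comparing the mean of the three measurements with the diagnostic bands.
#' Each repeat re-measures the same film pair with an additive perturbation
#' representing manual re-digitisation error; the returned rotation and
#' translation are the arithmetic means over repeats.
#'
#' @inheritParams measure_segment
#' @param rotation_noise,translation_noise Numeric vectors of per-repeat
#'   additive measurement errors (degrees, mm). Must have equal length
#'   >= 1; defaults are three exact repeats (zero noise).
#' @return A [segment_kinematics()] record with `n_repeats` equal to the
#'   number of repeats.
#' @export
#' @examples
#' lm <- sample_landmarks(rotation = 12, translation = 3)
#' measure_segment_triplicate(lm$flexion, lm$extension)
measure_segment_triplicate <- function(flexion, extension,
                                       rotation_noise = rep(0, 3),
                                       translation_noise = rep(0, 3)) {
  if (length(rotation_noise) != length(translation_noise)) {
    stop("rotation and translation noise vectors must have equal length",
         call. = FALSE)
  }
  if (length(rotation_noise) < 1L) {
    stop("at least one measurement repeat is required", call. = FALSE)
  }
  base <- measure_segment(flexion, extension)
  segment_kinematics(base$level,
                     mean(base$rotation + rotation_noise),
                     mean(base$translation + translation_noise),
                     n_repeats = length(rotation_noise))
}
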