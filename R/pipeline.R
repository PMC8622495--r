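#' Pipeline run configuration
#'
#' Collects the inputs and settings of one end-to-end validation run.
#' Exactly one of `landmarks` / `kinematics` must be supplied: either a
#' landmark-level coordinate table (measured into kinematics by
#' [measure_landmark_table()]) or a pre-measured kinematics table.
#'
#' @param responses Path to (or data frame of) the questionnaire response
#'   table: `participant`, `q1` .. `q14`.
#' @param landmarks Path/data frame of the long landmark table:
#'   `participant`, `level`, `phase`, `point`, `x`, `y` (one digitised
#'   point per row), as emitted by [write_cohort()].
#' @param kinematics Path/data frame of the kinematics table:
#'   `participant`, `level`, `rotation`, `translation`.
#' @param demographics Optional path/data frame of a participant table for
#'   the demographic summary.
#' @param bands A [band_table()] override; default published thresholds.
#' @param cutoffs Cut-off range for the accuracy table (within 0..15).
#' @param ci_level Confidence level for the AUC interval.
#' @param out_dir Output directory for the report bundle (`NULL` = do not
#'   write files).
#' @param verbose Print the run log to the console as it is produced.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(responses, landmarks = NULL, kinematics = NULL,
                       demographics = NULL, bands = default_band_table(),
                       cutoffs = 5:15, ci_level = 0.95, out_dir = NULL,
                       verbose = FALSE) {
  if (is.null(landmarks) == is.null(kinematics)) {
    stop("supply exactly one of 'landmarks' or 'kinematics'", call. = FALSE)
  }
  stopifnot(inherits(bands, "band_table"),
            all(cutoffs >= 0 & cutoffs <= 15), !is.unsorted(cutoffs),
            ci_level > 0, ci_level < 1)
  for (nm in c("responses", "landmarks", "kinematics", "demographics")) {
    val <- get(nm)
    if (is.character(val) && !file.exists(val)) {
      stop("input file for '", nm, "' does not exist: ", val, call. = FALSE)
    }
  }
  structure(list(responses = responses, landmarks = landmarks,
                 kinematics = kinematics, demographics = demographics,
                 bands = bands, cutoffs = cutoffs, ci_level = ci_level,
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

read_table_input <- function(x, what, required) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  if (!is.data.frame(x)) {
    stop("'", what, "' must be a data frame or a CSV path", call. = FALSE)
  }
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("'", what, "' table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x
}

#' Measure a long landmark table into segment kinematics
#'
#' Reassembles [vertebral_landmarks()] objects from a long coordinate
#' table (one digitised point per row) and measures every
#' (participant, level) film pair with [measure_segment_triplicate()]
#' semantics: rows may carry a `repeat` column, in which case each repeat
#' is measured separately and the mean is reported.
#'
#' @param landmarks Data frame `participant`, `level`, `phase`, `point`,
#'   `x`, `y`, optionally `repeat`.
#' @return Data frame `participant`, `level`, `rotation`, `translation`,
#'   `n_repeats`.
#' @export
measure_landmark_table <- function(landmarks) {
  landmarks <- read_table_input(landmarks, "landmarks",
                                c("participant", "level", "phase",
                                  "point", "x", "y"))
  if (!"repeat" %in% names(landmarks)) landmarks[["repeat"]] <- 1L
  build <- function(rows, level, phase) {
    get_pt <- function(nm) {
      r <- rows[rows$point == nm, , drop = FALSE]
      if (nrow(r) != 1L) {
        stop("landmark table needs exactly one '", nm, "' point per ",
             "(participant, level, phase, repeat); see participant ",
             rows$participant[1], " level ", level, call. = FALSE)
      }
      c(r$x, r$y)
    }
    vertebral_landmarks(
      level, phase,
      upper_endplate_anterior = get_pt("upper_endplate_anterior"),
      upper_endplate_posterior = get_pt("upper_endplate_posterior"),
      lower_endplate_anterior = get_pt("lower_endplate_anterior"),
      lower_endplate_posterior = get_pt("lower_endplate_posterior"),
      upper_posterior_corner = get_pt("upper_posterior_corner"),
      lower_posterior_corner = get_pt("lower_posterior_corner")
    )
  }
  keys <- unique(landmarks[, c("participant", "level")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- landmarks[landmarks$participant == keys$participant[i] &
                       landmarks$level == keys$level[i], ]
    reps <- sort(unique(sub[["repeat"]]))
    meas <- vapply(reps, function(r) {
      sr <- sub[sub[["repeat"]] == r, ]
      m <- measure_segment(
        build(sr[sr$phase == "flexion", ], keys$level[i], "flexion"),
        build(sr[sr$phase == "extension", ], keys$level[i], "extension")
      )
      c(m$rotation, m$translation)
    }, numeric(2))
    data.frame(participant = keys$participant[i], level = keys$level[i],
               rotation = mean(meas[1, ]), translation = mean(meas[2, ]),
               n_repeats = length(reps), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the full screening-validation pipeline
#'
#' Orchestrates measurement, radiographic classification, questionnaire
#' scoring and diagnostic-accuracy evaluation, and renders the report
#' bundle. Participants classified radiologically unstable (`LI`) met the
#' study's exclusion criterion: they are flagged in the diagnosis table
#' and excluded from the accuracy analysis. The reference standard for
#' the accuracy table is STLI vs normal.
#'
#' @param config A [run_config()].
#' @return List of class `"stli_run"`: `diagnosis` (per-participant
#'   radiographic labels), `scores` (questionnaire scores joined to
#'   labels), `accuracy` (the [accuracy_table()]), `roc` (the
#'   [roc_and_auc()] object), `summary` (selected cut-off, AUC, CI,
#'   prevalence, group sizes), `demographics` (when demographics were
#'   supplied), `log` (character vector recording the defaults in force).
#'   When `config$out_dir` is set, writes `diagnosis.csv`,
#'   `accuracy.csv`, `roc.csv`, `summary.json` and `run.log` there;
#'   re-running the same configuration is bit-identical.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_participants = 60, seed = 7))
#' run <- run_pipeline(run_config(responses = cohort$responses,
#'                                kinematics = cohort$kinematics))
#' run$summary$selected_cutoff
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (isTRUE(config$verbose)) message(line)
    invisible(NULL)
  }
  say("stliscreen pipeline run, ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  say("band thresholds: ",
      if (identical(config$bands, default_band_table()))
        "published defaults" else "user override")
  say("STLI band convention: lower bounds inclusive, LI thresholds exclusive")
  say("composite rule: STLI-band criteria in >= 2 segments, or rotation and ",
      "translation in one segment")
  say("cut-off selection rule: maximum sensitivity subject to ",
      "specificity > 0; ties toward the higher cut-off")

  if (!is.null(config$landmarks)) {
    say("input: landmark-level table; measuring film pairs")
    kin <- measure_landmark_table(config$landmarks)
  } else {
    say("input: pre-measured kinematics table")
    kin <- read_table_input(config$kinematics, "kinematics",
                            c("participant", "level", "rotation",
                              "translation"))
  }
  diagnosis <- classify_cohort(kin, config$bands)
  n_li <- sum(diagnosis$label == "LI")
  if (n_li > 0) {
    say(n_li, " participant(s) classified LI: flagged and excluded from ",
        "the accuracy analysis (radiological exclusion criterion)")
  }

  responses <- read_table_input(config$responses, "responses",
                                c("participant", paste0("q", 1:14)))
  scores <- score_response_table(responses)
  scores <- merge(scores, diagnosis[, c("participant", "label")],
                  by = "participant", sort = TRUE)
  if (nrow(scores) < nrow(diagnosis)) {
    say("warning: ", nrow(diagnosis) - nrow(scores),
        " participant(s) lack questionnaire responses and were dropped")
  }
  eligible <- scores[scores$label != "LI", ]
  if (nrow(eligible) == 0L || all(eligible$label == "STLI") ||
      all(eligible$label == "normal")) {
    stop("accuracy analysis needs both STLI-positive and negative ",
         "participants after exclusions", call. = FALSE)
  }
  stli <- eligible$label == "STLI"
  say("reference standard: ", sum(stli), " STLI-positive vs ",
      sum(!stli), " negative participants")

  accuracy <- accuracy_table(eligible$score, stli, config$cutoffs)
  roc <- roc_and_auc(eligible$score, stli, ci_level = config$ci_level)
  selected <- select_cutoff(accuracy)
  say(sprintf("selected cut-off: >= %d of 14", selected))
  say(sprintf("AUC %.4f (%.0f%% CI %.4f-%.4f, Hanley-McNeil)",
              roc$auc, 100 * roc$ci_level, roc$ci_low, roc$ci_high))

  summary <- list(
    n = nrow(eligible), n_pos = sum(stli), n_neg = sum(!stli),
    n_excluded_li = n_li,
    prevalence = sum(stli) / nrow(eligible),
    selected_cutoff = selected,
    auc = roc$auc, auc_ci_low = roc$ci_low, auc_ci_high = roc$ci_high,
    ci_level = roc$ci_level
  )

  demographics <- NULL
  if (!is.null(config$demographics)) {
    demo <- read_table_input(config$demographics, "demographics",
                             "participant")
    demo <- merge(demo[, setdiff(names(demo), "label")],
                  diagnosis[, c("participant", "label")], by = "participant")
    demographics <- render_demographics(demo)
  }

  out <- structure(list(diagnosis = diagnosis, scores = scores,
                        accuracy = accuracy, roc = roc, summary = summary,
                        demographics = demographics, log = log_lines),
                   class = "stli_run")
  if (!is.null(config$out_dir)) write_run_bundle(out, config$out_dir)
  out
}

write_run_bundle <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$diagnosis, file.path(dir, "diagnosis.csv"),
                   row.names = FALSE)
  acc <- as.data.frame(run$accuracy)
  acc$sensitivity_pct <- round_half_up(100 * acc$sensitivity, 2)
  acc$specificity_pct <- round_half_up(100 * acc$specificity, 2)
  utils::write.csv(acc, file.path(dir, "accuracy.csv"), row.names = FALSE)
  utils::write.csv(run$roc$points, file.path(dir, "roc.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.stli_run <- function(x, ...) {
  cat(sprintf(
    "Screening validation run: n = %d (%d STLI / %d normal, %d LI excluded)\n",
    x$summary$n, x$summary$n_pos, x$summary$n_neg, x$summary$n_excluded_li))
  cat(sprintf("  selected cut-off >= %d; AUC %.2f (%.0f%% CI %.2f-%.2f)\n",
              x$summary$selected_cutoff, x$summary$auc,
              100 * x$summary$ci_level, x$summary$auc_ci_low,
              x$summary$auc_ci_high))
  invisible(x)
}

fmt_mean_sd <- function(x) {
  if (length(x) == 0L) return("-")
  if (length(x) == 1L) return(sprintf("%.2f ± NA", x))
  sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
}

fmt_count_pct <- function(k, n) {
  if (n == 0L) return("0 (0.00)")
  sprintf("%d (%.2f)", k, round_half_up(100 * k / n, 2))
}

#' Group-wise demographic summary
#'
#' Mean +/- SD for continuous variables and count (percentage) for
#' categorical ones, by diagnosis group and in total. Between-group
#' inferential tests are intentionally not computed. A group of one
#' renders its SD as `NA`; an empty group renders zero counts.
#'
#' @param participants Data frame with columns `label` plus any of `age`,
#'   `bmi`, `duration_months`, `nrs` (continuous) and `sex`, `smoker`
#'   (categorical).
#' @return Data frame of class `"demographic_table"`: `variable`,
#'   `total`, `stli`, `without_stli`.
#' @export
render_demographics <- function(participants) {
  stopifnot(is.data.frame(participants), "label" %in% names(participants))
  groups <- list(total = participants,
                 stli = participants[participants$label == "STLI", ],
                 without_stli = participants[participants$label != "STLI", ])
  rows <- list()
  add_row <- function(variable, values) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, total = values[1], stli = values[2],
      without_stli = values[3], stringsAsFactors = FALSE)
  }
  add_row("n", vapply(groups, function(g) sprintf("%d", nrow(g)), ""))
  cont <- c(age = "Age (years)", bmi = "BMI (kg/m2)",
            duration_months = "Duration of current symptoms (months)",
            nrs = "NRS (pain)")
  for (v in names(cont)) {
    if (v %in% names(participants)) {
      add_row(cont[[v]], vapply(groups, function(g) fmt_mean_sd(g[[v]]), ""))
    }
  }
  if ("sex" %in% names(participants)) {
    for (s in c("male", "female")) {
      add_row(paste0("Sex: ", s),
              vapply(groups, function(g) {
                fmt_count_pct(sum(g$sex == s), nrow(g))
              }, ""))
    }
  }
  if ("smoker" %in% names(participants)) {
    add_row("Smoking history: yes",
            vapply(groups, function(g) {
              fmt_count_pct(sum(g$smoker), nrow(g))
            }, ""))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("demographic_table", "data.frame")
  out
}

#' @export
print.demographic_table <- function(x, ...) {
  cat("Demographic characteristics (mean ± SD or n (%))\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
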