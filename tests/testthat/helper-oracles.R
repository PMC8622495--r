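# Independent oracles used across the suite. These re-derive expected
# behaviour by routes deliberately different from the package internals.

# Literal clause-by-clause reading of the composite diagnosis rule,
# enumerating all 10 (level x measure) band assignments.
oracle_classify <- function(kin, bands = default_band_table()) {
  assignments <- list()
  for (i in seq_len(nrow(kin))) {
    lvl <- kin$level[i]
    row <- bands[bands$level == lvl, ]
    for (measure in c("rotation", "translation")) {
      val <- abs(kin[[measure]][i])
      lo <- row[[paste0(measure, "_stli_low")]]
      hi <- row[[paste0(measure, "_li")]]
      band <- if (val > hi) "LI" else if (val >= lo) "STLI" else "normal"
      assignments[[paste(lvl, measure)]] <- list(level = lvl, band = band)
    }
  }
  bands_vec <- vapply(assignments, `[[`, "", "band")
  if (any(bands_vec == "LI")) return("LI")
  stli <- assignments[bands_vec == "STLI"]
  stli_levels <- unique(vapply(stli, `[[`, "", "level"))
  clause_two_segments <- length(stli_levels) >= 2
  clause_one_segment <- any(vapply(unique(vapply(stli, `[[`, "", "level")),
                                   function(l) {
    sum(vapply(stli, function(a) a$level == l, TRUE)) == 2
  }, TRUE))
  if (clause_two_segments || clause_one_segment) "STLI" else "normal"
}

# Pairwise Mann-Whitney probability, ties counted half (brute force).
oracle_auc <- function(score, stli) {
  pos <- score[as.logical(stli)]
  neg <- score[!as.logical(stli)]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Random five-level kinematics spanning all three bands.
fuzz_kinematics <- function(bands = default_band_table()) {
  data.frame(
    level = lumbar_levels(),
    rotation = runif(5, 0, 1.3 * bands$rotation_li),
    translation = runif(5, 0, 1.3 * bands$translation_li),
    stringsAsFactors = FALSE
  )
}

reference_scores <- function() {
  acc <- stli_reference_accuracy()
  histogram_scores(reconstruct_counts(acc$sensitivity, acc$specificity,
                                      acc$cutoff, attr(acc, "n_pos"),
                                      attr(acc, "n_neg")))
}
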