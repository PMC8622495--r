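#' The 14 screening-tool items
#'
#' Canonical wording of the 14-item lumbar-instability screening
#' questionnaire. Items are answered yes (1) / no (0) by interview; item
#' numbers are 1-based and used throughout the package (`q1` .. `q14` in
#' response tables).
#'
#' @return Data frame with columns `item` (integer 1..14) and `text`.
#' @export
#' @examples
#' li_screening_items()$text[3]
li_screening_items <- function() {
  path <- system.file("extdata", "li_screening_items.csv",
                      package = "stliscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

check_responses <- function(responses) {
  if (is.data.frame(responses)) responses <- unlist(responses, use.names = FALSE)
  if (length(responses) != 14L) {
    stop("a complete response set has exactly 14 items, got ",
         length(responses), call. = FALSE)
  }
  if (anyNA(responses)) {
    stop("missing item responses are not accepted (no imputation)",
         call. = FALSE)
  }
  if (!is.numeric(responses) || !all(responses %in% c(0, 1))) {
    stop("item responses must be binary: 1 = yes, 0 = no", call. = FALSE)
  }
  as.integer(responses)
}

#' Questionnaire total score
#'
#' Sum of the 14 binary item responses, 0 (no instability-related symptoms
#' endorsed) to 14 (all endorsed). Incomplete or non-binary response sets
#' are rejected rather than imputed.
#'
#' @param responses Numeric/integer vector of exactly 14 values in
#'   \{0, 1\}, ordered by item number (or a one-row data frame `q1..q14`).
#' @return Integer score in 0..14.
#' @export
#' @examples
#' score_responses(c(0, 0, 1, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0)) # 3
score_responses <- function(responses) {
  sum(check_responses(responses))
}

#' Screening decision at a cut-off
#'
#' A participant screens positive when their questionnaire score is at
#' least the cut-off ("at least `cutoff` of 14 positive responses").
#'
#' @param score Integer score(s) in 0..14.
#' @param cutoff Integer cut-off in 0..14; the validated default is 6.
#' @return Logical, `TRUE` when `score >= cutoff`.
#' @export
#' @examples
#' screen_positive(6) # TRUE at the validated cut-off 6/14
#' screen_positive(5) # FALSE
screen_positive <- function(score, cutoff = 6L) {
  if (!is.numeric(score) || any(!is.finite(score)) ||
      any(score < 0) || any(score > 14)) {
    stop("'score' must be in 0..14", call. = FALSE)
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 14) {
    stop("'cutoff' must be a single value in 0..14", call. = FALSE)
  }
  score >= cutoff
}

#' Score a wide response table
#'
#' @param responses Data frame with a participant identifier column and
#'   columns `q1` .. `q14` of binary responses.
#' @param id_col Name of the identifier column.
#' @return Data frame `participant`, `score`.
#' @export
score_response_table <- function(responses, id_col = "participant") {
  qcols <- paste0("q", 1:14)
  stopifnot(is.data.frame(responses), id_col %in% names(responses),
            all(qcols %in% names(responses)))
  score <- if (nrow(responses) == 0L) integer(0) else {
    vapply(seq_len(nrow(responses)), function(i) {
      score_responses(as.numeric(responses[i, qcols]))
    }, 0L)
  }
  data.frame(participant = responses[[id_col]], score = score,
             stringsAsFactors = FALSE)
}
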