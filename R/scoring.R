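# Pure scoring core: per-question points, total score, ordinal category.
# Scores are integers only; incomplete answer vectors are an error here —
# defaulting unanswered questions to "unknown" is a caller-level choice and
# never happens silently.

#' Construct an answer vector
#'
#' Normalizes a set of responses into the canonical form used by the scoring
#' functions: a character vector of values from [response_options()], named
#' by question index (`"1"`..`"10"`). Input values are trimmed and
#' case-folded, so `"Yes"` and `" NO "` are accepted; names may carry a
#' leading `"q"` (`"q3"` is question 3). An unnamed vector of length 10 is
#' taken to answer questions 1..10 in order.
#'
#' The constructor does not require completeness — a partial vector is legal
#' data — but [total_score()] and [assess()] reject vectors that do not cover
#' all of the scale's questions.
#'
#' @param x Character vector (or list) of responses.
#' @return A named character vector of canonical options, class
#'   `answer_vector`.
#' @export
#' @examples
#' answer_vector(rep("unknown", 10))
#' answer_vector(c(q1 = "Yes", q2 = "no"))
answer_vector <- function(x) {
  if (inherits(x, "answer_vector")) return(x)
  nm <- names(x)
  x <- vapply(x, as.character, character(1))
  if (is.null(nm)) {
    if (length(x) != 10L)
      stop(sprintf("an unnamed answer vector must have length 10, got %d",
                   length(x)))
    nm <- as.character(1:10)
  } else {
    nm <- sub("^[qQ]", "", trimws(nm))
    if (any(!grepl("^[0-9]+$", nm)))
      stop("answer names must be question indices like '3' or 'q3'")
    if (anyDuplicated(nm))
      stop(sprintf("duplicate answer for question %s", nm[duplicated(nm)][1L]))
  }
  vals <- tolower(trimws(x))
  bad <- !vals %in% response_options()
  if (any(bad))
    stop(sprintf("invalid response '%s' for question %s; expected one of %s",
                 x[bad][1L], nm[bad][1L],
                 paste(response_options(), collapse = ", ")))
  structure(stats::setNames(vals, nm), class = "answer_vector")
}

check_complete <- function(scale, answers) {
  idx <- as.character(vapply(scale$questions, `[[`, integer(1), "index"))
  missing <- setdiff(idx, names(answers))
  if (length(missing))
    stop(sprintf("answer vector is incomplete: missing question(s) %s",
                 paste(missing, collapse = ", ")))
  extra <- setdiff(names(answers), idx)
  if (length(extra))
    stop(sprintf("answer vector has answers for unknown question(s) %s",
                 paste(extra, collapse = ", ")))
  invisible(answers)
}

#' Points for one question/answer pair
#'
#' Looks up the weight the instrument assigns to answering question `index`
#' with `answer`.
#'
#' @param scale A `naranjo_scale`.
#' @param index Question index, 1..10.
#' @param answer One of [response_options()] (case-insensitive).
#' @return Integer points.
#' @export
#' @examples
#' score_answer(naranjo_scale(), 4, "no")   # -1: no recurrence on rechallenge
score_answer <- function(scale, index, answer) {
  index <- as.integer(index)
  pos <- match(index, vapply(scale$questions, `[[`, integer(1), "index"))
  if (is.na(pos))
    stop(sprintf("no question with index %d in scale '%s'", index, scale$name))
  answer <- tolower(trimws(as.character(answer)))
  if (!answer %in% response_options())
    stop(sprintf("invalid response '%s'; expected one of %s", answer,
                 paste(response_options(), collapse = ", ")))
  scale$questions[[pos]]$weights[[answer]]
}

#' Total Naranjo score of a complete answer vector
#'
#' Sums the per-question points over all of the scale's questions. The sum is
#' independent of the order in which answers are supplied.
#'
#' @param scale A `naranjo_scale`.
#' @param answers Anything accepted by [answer_vector()]; must cover every
#'   question of the scale (an incomplete vector is an error listing the
#'   missing indices).
#' @return Integer total score.
#' @export
#' @examples
#' total_score(naranjo_scale(), rep("yes", 10))   # 8
total_score <- function(scale, answers) {
  answers <- answer_vector(answers)
  check_complete(scale, answers)
  total <- 0L
  for (q in scale$questions)
    total <- total + q$weights[[answers[[as.character(q$index)]]]]
  total
}

#' Map a total score to its causality category
#'
#' Applies the ordinal thresholds: Definite for `score >= definite_min` (9 on
#' the published scale), Probable down to `probable_min` (5), Possible down
#' to `possible_min` (1), Doubtful below that. The three closed lower bounds
#' partition the integers exhaustively and disjointly into the four bins.
#'
#' @param score Integer score(s); vectorized.
#' @param thresholds A `naranjo_scale`, or a named integer vector with
#'   elements `definite_min`, `probable_min`, `possible_min`. Defaults to the
#'   published thresholds.
#' @return Ordered factor with levels [adr_categories()].
#' @export
#' @examples
#' categorize(c(-4, 0, 1, 4, 5, 8, 9, 13))
categorize <- function(score, thresholds = naranjo_scale()) {
  if (inherits(thresholds, "naranjo_scale")) thresholds <- thresholds$thresholds
  labels <- adr_categories()
  out <- ifelse(score >= thresholds[["definite_min"]], labels[4L],
         ifelse(score >= thresholds[["probable_min"]], labels[3L],
         ifelse(score >= thresholds[["possible_min"]], labels[2L],
                labels[1L])))
  factor(out, levels = labels, ordered = TRUE)
}

#' Assess one case
#'
#' The orchestrating scorer: computes each question's point contribution, the
#' total score and the causality category for a complete answer vector.
#'
#' @param scale A `naranjo_scale`.
#' @param answers Anything accepted by [answer_vector()]; must be complete.
#' @param case_id Identifier attached to the result.
#' @return An object of class `naranjo_assessment`: a list with `case_id`,
#'   `answers`, `contributions` (integer points named by question index),
#'   `total`, `category` (ordered factor) and the scale's `scale_name` /
#'   `scale_version`.
#' @export
#' @examples
#' a <- assess(naranjo_scale(), rep("unknown", 10), case_id = "c1")
#' a$total      # 0
#' a$category   # Doubtful
assess <- function(scale, answers, case_id = "case") {
  answers <- answer_vector(answers)
  check_complete(scale, answers)
  idx <- vapply(scale$questions, `[[`, integer(1), "index")
  contributions <- vapply(scale$questions, function(q)
    q$weights[[answers[[as.character(q$index)]]]], integer(1))
  names(contributions) <- as.character(idx)
  total <- sum(contributions)
  structure(
    list(case_id = as.character(case_id),
         answers = answers[as.character(idx)],
         contributions = contributions,
         total = total,
         category = categorize(total, scale),
         scale_name = scale$name,
         scale_version = scale$version),
    class = "naranjo_assessment")
}

#' @export
print.naranjo_assessment <- function(x, ...) {
  cat(sprintf("<naranjo_assessment> case '%s' (scale %s/%s)\n",
              x$case_id, x$scale_name, x$scale_version))
  for (i in names(x$contributions))
    cat(sprintf("  Q%-2s %-8s %+d\n", i, x$answers[[i]], x$contributions[[i]]))
  cat(sprintf("  Total score: %d\n", x$total))
  cat(sprintf("  Category: %s ADR\n", as.character(x$category)))
  invisible(x)
}
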