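# The instrument is modelled as data, not code: a naranjo_scale object holds
# the ordered questions, their three-way integer weights and the category
# thresholds, and everything downstream (scoring, session, batch) reads from
# it. The published scale is a built-in constant; a document loader exists so
# degenerate scales can be constructed for testing without touching it.

#' Response options of the instrument
#'
#' Every question admits exactly three answers: `"yes"`, `"no"` and
#' `"unknown"` ("don't know / not done"). These canonical strings are the
#' only values accepted by the scoring functions; console/file tokens such as
#' `"Y"` or `"X"` are mapped onto them by [parse_token()].
#'
#' @return Character vector of the three canonical option names, in the
#'   column order of the published table.
#' @export
#' @examples
#' response_options()
response_options <- function() c("yes", "no", "unknown")

#' ADR causality categories
#'
#' The four ordinal categories of drug-reaction causality, from least to most
#' likely. [categorize()] returns them as an ordered factor with these
#' levels.
#'
#' @return Character vector `c("Doubtful", "Possible", "Probable",
#'   "Definite")`, in increasing order of causal likelihood.
#' @export
adr_categories <- function() c("Doubtful", "Possible", "Probable", "Definite")

new_question <- function(index, text, yes, no, unknown) {
  list(index = as.integer(index), text = text,
       weights = c(yes = as.integer(yes), no = as.integer(no),
                   unknown = as.integer(unknown)))
}

#' The Naranjo adverse drug reaction probability scale
#'
#' Constructs the canonical 10-question Naranjo instrument: the question
#' texts, the integer points awarded for each Yes/No/Unknown answer, and the
#' thresholds that partition total scores into the four causality categories
#' (Definite for scores >= 9, Probable for 5--8, Possible for 1--4, Doubtful
#' for <= 0).
#'
#' The constructor is deterministic and side-effect free; the returned object
#' is plain data and can be serialized with [write_scale()].
#'
#' @return An object of class `naranjo_scale`: a list with elements `name`,
#'   `version`, `questions` (a list of 10 questions, each with `index`,
#'   `text` and an integer `weights` vector named by [response_options()])
#'   and `thresholds` (integer vector with elements `definite_min`,
#'   `probable_min`, `possible_min`).
#' @export
#' @examples
#' scale <- naranjo_scale()
#' scale$questions[[2]]$weights
#' scale$thresholds
naranjo_scale <- function() {
  questions <- list(
    new_question(1L, "Are there previous conclusive reports on this reaction?",
                 1, 0, 0),
    new_question(2L, "Did the adverse reaction appear after the suspected drug was administered?",
                 2, -1, 0),
    new_question(3L, "Did the adverse reaction improve when the drug was discontinued or a specific antagonists was administered?",
                 1, 0, 0),
    new_question(4L, "Did the adverse reaction reappear when the drug was readministered?",
                 2, -1, 0),
    new_question(5L, "Are there alternative causes that could on their own have caused the reaction?",
                 -1, 2, 0),
    new_question(6L, "Did the reaction reappear when a placebo was given?",
                 -1, 1, 0),
    new_question(7L, "Was the drug detected in the blood (or other fluids) in concentrations known to be toxic?",
                 1, 0, 0),
    new_question(8L, "Was the reaction more severe when the dose was increased or less severe when the dose was decreased?",
                 1, 0, 0),
    new_question(9L, "Did the patient have a similar reaction to the same or similar drug in any previous exposure?",
                 1, 0, 0),
    new_question(10L, "Was the adverse event confirmed by any objective evidence?",
                 1, 0, 0)
  )
  out <- structure(
    list(name = "naranjo", version = "1981",
         questions = questions,
         thresholds = c(definite_min = 9L, probable_min = 5L,
                        possible_min = 1L)),
    class = "naranjo_scale")
  validate_scale(out)
}

#' Validate a scale object
#'
#' Checks the structural invariants of a `naranjo_scale`: exactly 10
#' questions with unique ascending indices 1..10, a total integer weight map
#' over the three response options for every question, integer weights within
#' the published range \[-1, 2\], and strictly ordered category thresholds
#' (`possible_min < probable_min < definite_min`). Errors name the offending
#' field.
#'
#' @param scale An object to validate.
#' @return The validated scale, invisibly usable in pipelines.
#' @export
validate_scale <- function(scale) {
  if (!is.list(scale) || is.null(scale$questions) || is.null(scale$thresholds))
    stop("scale must be a list with 'questions' and 'thresholds'")
  if (!is.character(scale$name) || length(scale$name) != 1L)
    stop("scale field 'name' must be a single string")
  if (!is.character(scale$version) || length(scale$version) != 1L)
    stop("scale field 'version' must be a single string")

  qs <- scale$questions
  if (length(qs) != 10L)
    stop(sprintf("scale field 'questions' must contain exactly 10 questions, got %d",
                 length(qs)))
  idx <- vapply(qs, function(q) as.integer(q$index), integer(1))
  if (anyDuplicated(idx))
    stop(sprintf("scale field 'questions' has duplicate index %d",
                 idx[duplicated(idx)][1L]))
  if (!identical(idx, 1:10))
    stop("scale field 'questions' must carry indices 1..10 in ascending order")
  opts <- response_options()
  for (q in qs) {
    w <- q$weights
    missing_opt <- setdiff(opts, names(w))
    if (length(missing_opt))
      stop(sprintf("question %d field 'weights' is missing option '%s'",
                   q$index, missing_opt[1L]))
    w <- w[opts]
    if (any(is.na(w)) || any(w != as.integer(w)))
      stop(sprintf("question %d field 'weights' must be integer-valued", q$index))
    if (any(w < -1L | w > 2L))
      stop(sprintf("question %d field 'weights' must lie in [-1, 2]", q$index))
    if (!is.character(q$text) || length(q$text) != 1L || !nzchar(q$text))
      stop(sprintf("question %d field 'text' must be a non-empty string", q$index))
  }

  th <- scale$thresholds
  need <- c("definite_min", "probable_min", "possible_min")
  if (!all(need %in% names(th)))
    stop(sprintf("scale field 'thresholds' is missing '%s'",
                 setdiff(need, names(th))[1L]))
  th <- th[need]
  if (any(is.na(th)) || any(th != as.integer(th)))
    stop("scale field 'thresholds' must be integer-valued")
  if (!(th[["possible_min"]] < th[["probable_min"]] &&
        th[["probable_min"]] < th[["definite_min"]]))
    stop("scale field 'thresholds' must satisfy possible_min < probable_min < definite_min (strict ordering)")
  invisible(scale)
}

# plain-list document form used by the JSON/YAML serializers
as_scale_document <- function(scale) {
  list(
    name = scale$name,
    version = scale$version,
    questions = lapply(scale$questions, function(q)
      list(index = q$index, text = q$text,
           weights = as.list(q$weights))),
    thresholds = as.list(scale$thresholds)
  )
}

scale_from_document <- function(doc) {
  if (!is.list(doc)) stop("scale document must be a mapping/object")
  for (field in c("name", "version", "questions", "thresholds"))
    if (is.null(doc[[field]]))
      stop(sprintf("scale document is missing field '%s'", field))
  questions <- lapply(doc$questions, function(q) {
    if (is.null(q$index) || is.null(q$text) || is.null(q$weights))
      stop("each question needs fields 'index', 'text' and 'weights'")
    w <- q$weights
    list(index = as.integer(q$index), text = as.character(q$text),
         weights = c(yes = as_weight(w$yes, q$index, "yes"),
                     no = as_weight(w$no, q$index, "no"),
                     unknown = as_weight(w$unknown, q$index, "unknown")))
  })
  th <- doc$thresholds
  out <- structure(
    list(name = as.character(doc$name), version = as.character(doc$version),
         questions = questions,
         thresholds = c(definite_min = as_threshold(th$definite_min, "definite_min"),
                        probable_min = as_threshold(th$probable_min, "probable_min"),
                        possible_min = as_threshold(th$possible_min, "possible_min"))),
    class = "naranjo_scale")
  validate_scale(out)
  out
}

as_weight <- function(x, index, option) {
  if (is.null(x))
    stop(sprintf("question %s field 'weights' is missing option '%s'",
                 index, option))
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x))
    stop(sprintf("question %s weight for '%s' must be a single integer",
                 index, option))
  as.integer(x)
}

as_threshold <- function(x, field) {
  if (is.null(x))
    stop(sprintf("scale document field 'thresholds' is missing '%s'", field))
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x))
    stop(sprintf("threshold '%s' must be a single integer", field))
  as.integer(x)
}

#' Read a scale definition from a JSON or YAML document
#'
#' Loads and validates a scale document with keys `name`, `version`,
#' `questions` (list of `{index, text, weights: {yes, no, unknown}}`) and
#' `thresholds` (`{definite_min, probable_min, possible_min}`). Round-trips
#' with [write_scale()]. Schema violations (missing option weight, duplicate
#' index, non-integer weight, non-monotone thresholds, wrong question count)
#' raise descriptive errors naming the offending field.
#'
#' @param path Path to a UTF-8 `.json`, `.yaml` or `.yml` file.
#' @param format `"auto"` (default; inferred from the extension), `"json"` or
#'   `"yaml"`.
#' @return A validated `naranjo_scale`.
#' @seealso [naranjo_scale()] for the built-in instrument.
#' @export
read_scale <- function(path, format = c("auto", "json", "yaml")) {
  format <- resolve_format(match.arg(format), path, c(json = "json",
                                                     yaml = "yaml", yml = "yaml"))
  doc <- switch(format,
                json = jsonlite::fromJSON(path, simplifyVector = FALSE),
                yaml = yaml::read_yaml(path))
  scale_from_document(doc)
}

#' Write a scale definition to a JSON or YAML document
#'
#' @param scale A `naranjo_scale`.
#' @param path Output path.
#' @param format `"auto"` (from extension), `"json"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
write_scale <- function(scale, path, format = c("auto", "json", "yaml")) {
  validate_scale(scale)
  format <- resolve_format(match.arg(format), path, c(json = "json",
                                                     yaml = "yaml", yml = "yaml"))
  doc <- as_scale_document(scale)
  switch(format,
         json = jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE),
         yaml = yaml::write_yaml(doc, path))
  invisible(path)
}

resolve_format <- function(format, path, by_ext) {
  if (format != "auto") return(format)
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (!ext %in% names(by_ext))
    stop(sprintf("cannot infer format from extension '.%s'; pass format= explicitly", ext))
  unname(by_ext[[ext]])
}

#' @export
print.naranjo_scale <- function(x, ...) {
  cat(sprintf("<naranjo_scale> %s (version %s)\n", x$name, x$version))
  cat(sprintf("  %d questions; points per answer [yes/no/unknown]:\n",
              length(x$questions)))
  for (q in x$questions)
    cat(sprintf("  %2d. [%+d/%+d/%+d] %s\n", q$index,
                q$weights[["yes"]], q$weights[["no"]], q$weights[["unknown"]],
                q$text))
  th <- x$thresholds
  cat(sprintf("  categories: Definite >= %d; Probable %d..%d; Possible %d..%d; Doubtful <= %d\n",
              th[["definite_min"]], th[["probable_min"]], th[["definite_min"]] - 1L,
              th[["possible_min"]], th[["probable_min"]] - 1L,
              th[["possible_min"]] - 1L))
  invisible(x)
}
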