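# Batch scoring: read many cases from CSV/JSON, assess each, tally
# categories, write per-case results plus a summary. Lenient by default —
# a malformed row becomes a per-row error entry rather than killing the
# batch — with strict = TRUE escalating any row error to a failure.
# Conservation holds throughout: every input case ends up exactly once,
# in the assessments or in the errors.

new_batch <- function(cases, errors = NULL, source = "memory") {
  if (is.null(errors))
    errors <- data.frame(case_id = character(0), row = integer(0),
                         message = character(0), stringsAsFactors = FALSE)
  ids <- vapply(cases, `[[`, character(1), "case_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate case_id '%s' in batch", ids[duplicated(ids)][1L]))
  structure(list(cases = cases, errors = errors, source = source),
            class = "naranjo_batch")
}

#' Assemble a case batch in memory
#'
#' @param answers A list of answer vectors (anything [answer_vector()]
#'   accepts), optionally named by case id; unnamed entries get sequential
#'   ids `case_1`, `case_2`, ...
#' @param source Provenance string recorded on the batch.
#' @return An object of class `naranjo_batch` with unique case ids.
#' @export
#' @examples
#' b <- case_batch(list(c1 = rep("unknown", 10), c2 = rep("yes", 10)))
case_batch <- function(answers, source = "memory") {
  ids <- names(answers)
  if (is.null(ids)) ids <- paste0("case_", seq_along(answers))
  ids[!nzchar(ids)] <- paste0("case_", which(!nzchar(ids)))
  cases <- Map(function(id, a) list(case_id = id, answers = answer_vector(a)),
               ids, answers)
  new_batch(unname(cases), source = source)
}

#' Read cases from a CSV or JSON file
#'
#' CSV files carry a header `case_id,q1,...,q10` and one case per row, with
#' cells holding dialect tokens (`Y`/`N`/`X` or the full words). JSON files
#' hold a list of objects `{"case_id": ..., "answers": {"1": ..., ...,
#' "10": ...}}`. Rows with unrecognized tokens or missing cells are recorded
#' as per-row errors on the batch rather than failing the read; `strict =
#' TRUE` escalates the first such row to an error. Structural problems —
#' missing or duplicate header columns, duplicate case ids — always fail.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (from extension), `"csv"` or `"json"`.
#' @param dialect [token_dialect()] used to interpret cell tokens.
#' @param strict If `TRUE`, any malformed row aborts the read.
#' @return A `naranjo_batch` whose `errors` data frame records skipped rows.
#' @export
read_cases <- function(path, format = c("auto", "csv", "json"),
                       dialect = token_dialect(), strict = FALSE) {
  format <- resolve_format(match.arg(format), path,
                           c(csv = "csv", json = "json"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  switch(format,
         csv = read_cases_csv(path, dialect, strict),
         json = read_cases_json(path, dialect, strict))
}

expected_header <- function() c("case_id", paste0("q", 1:10))

row_error <- function(case_id, row, message)
  data.frame(case_id = case_id, row = as.integer(row), message = message,
             stringsAsFactors = FALSE)

# parse the 10 answer cells of one record; returns an answer_vector or a
# bare character scalar describing the first bad cell (distinguish with
# inherits(), since an answer_vector is itself a character vector)
parse_record <- function(tokens, dialect) {
  answers <- character(10)
  for (i in 1:10) {
    tok <- tokens[[i]]
    if (is.null(tok) || length(tok) == 0L || is.na(tok) || !nzchar(trimws(tok)))
      return(sprintf("missing value for q%d", i))
    parsed <- parse_token(tok, dialect)
    if (parsed$outcome != "accepted")
      return(sprintf("invalid token '%s' for q%d", tok, i))
    answers[[i]] <- parsed$option
  }
  answer_vector(stats::setNames(answers, as.character(1:10)))
}

read_cases_csv <- function(path, dialect, strict) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  want <- expected_header()
  if (anyDuplicated(header))
    stop(sprintf("duplicate header column '%s' in %s",
                 header[duplicated(header)][1L], path))
  if (length(miss <- setdiff(want, header)))
    stop(sprintf("missing header column(s) %s in %s",
                 paste(miss, collapse = ", "), path))
  if (length(extra <- setdiff(header, want)))
    stop(sprintf("unexpected header column(s) %s in %s",
                 paste(extra, collapse = ", "), path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  cases <- list()
  errors <- list()
  for (r in seq_len(nrow(df))) {
    id <- trimws(df[["case_id"]][r])
    if (!nzchar(id)) {
      msg <- "missing case_id"
      if (strict) stop(sprintf("row %d: %s", r, msg))
      errors[[length(errors) + 1L]] <- row_error(sprintf("row_%d", r), r, msg)
      next
    }
    parsed <- parse_record(as.list(df[r, paste0("q", 1:10)]), dialect)
    if (!inherits(parsed, "answer_vector")) {
      if (strict) stop(sprintf("row %d (case '%s'): %s", r, id, parsed))
      errors[[length(errors) + 1L]] <- row_error(id, r, parsed)
      next
    }
    cases[[length(cases) + 1L]] <- list(case_id = id, answers = parsed)
  }
  new_batch(cases, errors = do.call(rbind, c(errors, list(row_error(character(0), integer(0), character(0))))),
            source = path)
}

read_cases_json <- function(path, dialect, strict) {
  records <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(records)) stop(sprintf("%s must hold a JSON array of cases", path))
  cases <- list()
  errors <- list()
  for (r in seq_along(records)) {
    rec <- records[[r]]
    id <- rec$case_id
    if (is.null(id) || !nzchar(trimws(as.character(id)))) {
      msg <- "missing case_id"
      if (strict) stop(sprintf("record %d: %s", r, msg))
      errors[[length(errors) + 1L]] <- row_error(sprintf("record_%d", r), r, msg)
      next
    }
    id <- trimws(as.character(id))
    ans <- rec$answers
    tokens <- lapply(as.character(1:10), function(k) ans[[k]])
    parsed <- parse_record(tokens, dialect)
    if (!inherits(parsed, "answer_vector")) {
      if (strict) stop(sprintf("record %d (case '%s'): %s", r, id, parsed))
      errors[[length(errors) + 1L]] <- row_error(id, r, parsed)
      next
    }
    cases[[length(cases) + 1L]] <- list(case_id = id, answers = parsed)
  }
  new_batch(cases, errors = do.call(rbind, c(errors, list(row_error(character(0), integer(0), character(0))))),
            source = path)
}

#' Write a case batch to CSV or JSON
#'
#' Inverse of [read_cases()]: CSV rows use the compact `Y`/`N`/`X` tokens;
#' JSON records carry the full canonical option words. Reading the written
#' file back yields a batch with identical case ids and answers.
#'
#' @param batch A `naranjo_batch`.
#' @param path Output path.
#' @param format `"auto"` (from extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cases <- function(batch, path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path,
                           c(csv = "csv", json = "json"))
  if (format == "csv") {
    token <- c(yes = "Y", no = "N", unknown = "X")
    rows <- vapply(batch$cases, function(cs)
      paste(c(cs$case_id, unname(token[cs$answers[as.character(1:10)]])),
            collapse = ","), character(1))
    writeLines(c(paste(expected_header(), collapse = ","), rows), path)
  } else {
    recs <- lapply(batch$cases, function(cs)
      list(case_id = cs$case_id,
           answers = as.list(unclass(cs$answers[as.character(1:10)]))))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Score every case in a batch
#'
#' Assesses each case with [assess()] in input order and tallies the
#' category distribution. Per-case failures (and rows already rejected at
#' read time) are carried as error entries, never as a batch-level failure,
#' so `length(batch$cases)` read errors included always equals
#' `length(assessments) + nrow(errors)`.
#'
#' @param scale A `naranjo_scale`.
#' @param batch A `naranjo_batch`.
#' @return An object of class `naranjo_report`: list with `assessments`,
#'   `counts` (named integer vector over [adr_categories()]) and `errors`.
#' @export
#' @examples
#' b <- case_batch(list(c1 = rep("unknown", 10), c2 = rep("yes", 10)))
#' score_batch(naranjo_scale(), b)
score_batch <- function(scale, batch) {
  validate_scale(scale)
  assessments <- list()
  errors <- list(batch$errors)
  for (cs in batch$cases) {
    a <- tryCatch(assess(scale, cs$answers, case_id = cs$case_id),
                  error = function(e) conditionMessage(e))
    if (is.character(a))
      errors[[length(errors) + 1L]] <- row_error(cs$case_id, NA_integer_, a)
    else
      assessments[[length(assessments) + 1L]] <- a
  }
  cats <- vapply(assessments, function(a) as.character(a$category), character(1))
  counts <- table(factor(cats, levels = adr_categories()))
  counts <- stats::setNames(as.integer(counts), adr_categories())
  structure(list(assessments = assessments, counts = counts,
                 errors = do.call(rbind, errors), source = batch$source),
            class = "naranjo_report")
}

report_rows <- function(report) {
  cols <- c("case_id", "total_score", "category", paste0("q", 1:10, "_points"))
  if (length(report$assessments) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  rows <- lapply(report$assessments, function(a)
    data.frame(case_id = a$case_id, total_score = a$total,
               category = as.character(a$category),
               t(stats::setNames(as.integer(a$contributions),
                                 paste0("q", 1:10, "_points"))),
               stringsAsFactors = FALSE, check.names = FALSE))
  do.call(rbind, rows)
}

#' Write a batch report
#'
#' CSV output has columns `case_id,total_score,category,q1_points,...,
#' q10_points`, one assessment per row (categories as the capitalized words
#' `Doubtful`/`Possible`/`Probable`/`Definite`); the category-count summary
#' and the error list go to the optional `summary` CSV. JSON output bundles
#' assessments, summary counts and errors in one document. Output is
#' byte-stable: identical reports serialize to identical bytes.
#'
#' @param report A `naranjo_report`.
#' @param path Output path.
#' @param format `"auto"` (from extension), `"csv"` or `"json"`.
#' @param summary For CSV only: optional path for the category-count /
#'   error summary file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("auto", "csv", "json"),
                         summary = NULL) {
  format <- resolve_format(match.arg(format), path,
                           c(csv = "csv", json = "json"))
  if (format == "csv") {
    utils::write.csv(report_rows(report), path, row.names = FALSE,
                     quote = FALSE)
    if (!is.null(summary)) {
      lines <- c("category,count",
                 sprintf("%s,%d", adr_categories(),
                         report$counts[adr_categories()]),
                 sprintf("errors,%d", nrow(report$errors)))
      writeLines(lines, summary)
    }
  } else {
    doc <- list(
      assessments = lapply(report$assessments, function(a)
        list(case_id = a$case_id,
             answers = as.list(unclass(a$answers)),
             contributions = as.list(a$contributions),
             total = a$total,
             category = as.character(a$category))),
      summary = list(counts = as.list(report$counts)),
      errors = report$errors)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(path)
}

#' Read a batch report back from disk
#'
#' Reconstructs a `naranjo_report` from a file written by [write_report()].
#' The CSV form carries the assessments only (errors live in the separate
#' summary file); the JSON form restores counts and errors as well.
#'
#' @param path Path to a report file.
#' @param format `"auto"` (from extension), `"csv"` or `"json"`.
#' @return A `naranjo_report`.
#' @export
read_report <- function(path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path,
                           c(csv = "csv", json = "json"))
  empty_errors <- row_error(character(0), integer(0), character(0))
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    assessments <- lapply(seq_len(nrow(df)), function(r) {
      contributions <- stats::setNames(
        as.integer(df[r, paste0("q", 1:10, "_points")]), as.character(1:10))
      structure(list(case_id = as.character(df$case_id[r]),
                     answers = NULL,
                     contributions = contributions,
                     total = as.integer(df$total_score[r]),
                     category = factor(df$category[r],
                                       levels = adr_categories(),
                                       ordered = TRUE),
                     scale_name = NA_character_,
                     scale_version = NA_character_),
                class = "naranjo_assessment")
    })
    cats <- vapply(assessments, function(a) as.character(a$category), character(1))
    counts <- stats::setNames(
      as.integer(table(factor(cats, levels = adr_categories()))),
      adr_categories())
    errors <- empty_errors
  } else {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    assessments <- lapply(doc$assessments, function(a)
      structure(list(case_id = a$case_id,
                     answers = answer_vector(unlist(a$answers)),
                     contributions = stats::setNames(
                       vapply(a$contributions, as.integer, integer(1)),
                       names(a$contributions)),
                     total = as.integer(a$total),
                     category = factor(a$category, levels = adr_categories(),
                                       ordered = TRUE),
                     scale_name = NA_character_,
                     scale_version = NA_character_),
                class = "naranjo_assessment"))
    counts <- stats::setNames(
      vapply(doc$summary$counts[adr_categories()], as.integer, integer(1)),
      adr_categories())
    errors <- if (length(doc$errors))
      do.call(rbind, lapply(doc$errors, function(e)
        row_error(e$case_id, if (is.null(e$row)) NA_integer_ else e$row,
                  e$message)))
    else empty_errors
  }
  structure(list(assessments = assessments, counts = counts, errors = errors,
                 source = path),
            class = "naranjo_report")
}

#' @export
print.naranjo_batch <- function(x, ...) {
  cat(sprintf("<naranjo_batch> %d case(s), %d read error(s) (source: %s)\n",
              length(x$cases), nrow(x$errors), x$source))
  invisible(x)
}

#' @export
print.naranjo_report <- function(x, ...) {
  cat(sprintf("<naranjo_report> %d assessment(s), %d error(s)\n",
              length(x$assessments), nrow(x$errors)))
  for (cat_name in adr_categories())
    cat(sprintf("  %-9s %d\n", cat_name, x$counts[[cat_name]]))
  invisible(x)
}
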