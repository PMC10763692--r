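# Console workflow: ask the 10 questions in order, validate each token,
# re-prompt on invalid input (unbounded retries), then display the final
# score and category. The session never re-implements scoring — a completed
# run's result is exactly assess() on the accepted answers. Every consumed
# input line leaves an event in the transcript, so scripted runs replay
# byte-identically.

#' Token dialect for console and file input
#'
#' Defines which input strings map to each response option. Matching is
#' case-insensitive after trimming surrounding whitespace; the four token
#' sets must be pairwise disjoint after that canonicalization. The default
#' dialect accepts the single letters `Y`/`N`/`X` alongside the full words,
#' plus `quit` to abort an interactive session.
#'
#' @param yes,no,unknown Character vectors of accepted tokens per option.
#' @param abort Tokens that end an interactive session without a result.
#' @return A list of canonicalized token sets, class `token_dialect`.
#' @export
#' @examples
#' token_dialect()
#' token_dialect(unknown = c("x", "dk", "unknown"))
token_dialect <- function(yes = c("y", "yes"), no = c("n", "no"),
                          unknown = c("x", "unknown"), abort = "quit") {
  canon <- function(x) unique(tolower(trimws(as.character(x))))
  d <- list(yes = canon(yes), no = canon(no), unknown = canon(unknown),
            abort = canon(abort))
  all_tokens <- unlist(d, use.names = FALSE)
  if (anyDuplicated(all_tokens))
    stop(sprintf("token '%s' appears in more than one set",
                 all_tokens[duplicated(all_tokens)][1L]))
  structure(d, class = "token_dialect")
}

dialect_help <- function(dialect) {
  sprintf("Invalid input. Please enter %s (yes), %s (no) or %s (don't know).",
          paste(toupper(dialect$yes), collapse = "/"),
          paste(toupper(dialect$no), collapse = "/"),
          paste(toupper(dialect$unknown), collapse = "/"))
}

#' Classify one raw input token
#'
#' Trims and case-folds `raw`, then classifies it under the dialect.
#' Rejection is a value, not an error: unrecognized tokens yield outcome
#' `"rejected"` together with a help message listing the accepted tokens.
#'
#' @param raw A single input string.
#' @param dialect A [token_dialect()].
#' @return A list with `outcome` (`"accepted"`, `"abort"` or `"rejected"`),
#'   `option` (the canonical response option, or `NA` unless accepted) and,
#'   on rejection, `message`.
#' @export
#' @examples
#' parse_token("Y")$option        # "yes"
#' parse_token("  n  ")$option    # "no"
#' parse_token("maybe")$outcome   # "rejected"
parse_token <- function(raw, dialect = token_dialect()) {
  tok <- tolower(trimws(as.character(raw)))
  for (opt in response_options())
    if (tok %in% dialect[[opt]])
      return(list(outcome = "accepted", option = opt))
  if (tok %in% dialect$abort)
    return(list(outcome = "abort", option = NA_character_))
  list(outcome = "rejected", option = NA_character_,
       message = dialect_help(dialect))
}

# one-line-at-a-time reader over a character vector or a connection;
# returns NULL at end of input
line_reader <- function(input) {
  if (is.character(input)) {
    i <- 0L
    function() {
      i <<- i + 1L
      if (i > length(input)) NULL else input[[i]]
    }
  } else if (inherits(input, "connection")) {
    # open once and hold; readLines() on an unopened connection would
    # open/close per call and drop the rest of a piped stream
    if (!isOpen(input)) open(input, "r")
    function() {
      line <- readLines(input, n = 1L)
      if (length(line) == 0L) NULL else line
    }
  } else stop("input must be a character vector of lines or a connection")
}

#' Run an interactive assessment session
#'
#' Walks through the scale's questions in index order. Each question is
#' prompted until a valid token is read; invalid tokens are logged as
#' rejection events and followed by a help line and a re-prompt, with no
#' retry cap. An abort token or end of input terminates the session without
#' a result. When all questions have been answered, the final score and
#' category are appended to the output and the assessment is attached to the
#' transcript.
#'
#' `input` may be a character vector of pre-scripted lines (useful for tests
#' and replays) or a connection such as [stdin()]. Output lines are always
#' collected in the transcript; pass a connection via `output` to also print
#' them as the session runs.
#'
#' @param scale A `naranjo_scale`.
#' @param input Character vector of input lines, or a readable connection.
#' @param output Optional writable connection for live display.
#' @param dialect A [token_dialect()].
#' @param case_id Identifier for the resulting assessment.
#' @return An object of class `naranjo_transcript`: a list with `events`
#'   (data frame of `question`, `input`, `outcome`), `result` (a
#'   `naranjo_assessment`, or `NULL` if aborted), `completed`, `case_id` and
#'   `output` (every line the session displayed).
#' @export
#' @examples
#' tr <- run_session(naranjo_scale(), input = rep("X", 10))
#' tr$result$total   # 0
run_session <- function(scale = naranjo_scale(), input, output = NULL,
                        dialect = token_dialect(), case_id = "interactive") {
  validate_scale(scale)
  read_line <- line_reader(input)
  out_lines <- character(0)
  emit <- function(x) out_lines <<- c(out_lines, x)
  events <- list()
  log_event <- function(question, raw, outcome)
    events[[length(events) + 1L]] <<- data.frame(
      question = question, input = raw, outcome = outcome,
      stringsAsFactors = FALSE)
  answers <- character(0)

  emit(sprintf("ADR causality assessment (%s scale, version %s)",
               scale$name, scale$version))
  aborted <- FALSE
  for (q in scale$questions) {
    repeat {
      emit(sprintf("Q%d. %s [Y/N/X]:", q$index, q$text))
      raw <- read_line()
      if (is.null(raw)) {
        log_event(q$index, NA_character_, "aborted")
        emit("Input ended before all questions were answered; no score computed.")
        aborted <- TRUE
        break
      }
      parsed <- parse_token(raw, dialect)
      if (parsed$outcome == "accepted") {
        log_event(q$index, raw, "accepted")
        answers[[as.character(q$index)]] <- parsed$option
        break
      } else if (parsed$outcome == "abort") {
        log_event(q$index, raw, "aborted")
        emit("Session aborted; no score computed.")
        aborted <- TRUE
        break
      } else {
        log_event(q$index, raw, "rejected")
        emit(parsed$message)
      }
    }
    if (aborted) break
  }

  result <- NULL
  if (!aborted) {
    result <- assess(scale, answer_vector(answers), case_id = case_id)
    emit("----------------------------------------")
    emit(sprintf("Naranjo score: %d", result$total))
    emit(sprintf("ADR category: %s", as.character(result$category)))
  }
  if (!is.null(output)) writeLines(out_lines, output)
  structure(
    list(events = do.call(rbind, events),
         result = result,
         completed = !aborted,
         case_id = as.character(case_id),
         output = out_lines),
    class = "naranjo_transcript")
}

#' Write a session transcript to JSON
#'
#' Serializes the ordered event log (question index, raw input, outcome) and,
#' for completed sessions, the assessment (contributions, total, category).
#'
#' @param transcript A `naranjo_transcript`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path) {
  doc <- list(case_id = transcript$case_id,
              completed = transcript$completed,
              events = transcript$events)
  if (!is.null(transcript$result)) {
    r <- transcript$result
    doc$assessment <- list(case_id = r$case_id,
                           answers = as.list(unclass(r$answers)),
                           contributions = as.list(r$contributions),
                           total = r$total,
                           category = as.character(r$category),
                           scale_name = r$scale_name,
                           scale_version = r$scale_version)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.naranjo_transcript <- function(x, ...) {
  n_events <- if (is.null(x$events)) 0L else nrow(x$events)
  cat(sprintf("<naranjo_transcript> case '%s': %d event(s), %s\n",
              x$case_id, n_events,
              if (x$completed) "completed" else "aborted"))
  if (!is.null(x$result))
    cat(sprintf("  score %d, category %s\n", x$result$total,
                as.character(x$result$category)))
  invisible(x)
}
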