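write_lines_tmp <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("CSV cases parse dialect tokens and capture bad rows as errors", {
  path <- write_lines_tmp(c(
    "case_id,q1,q2,q3,q4,q5,q6,q7,q8,q9,q10",
    "c1,X,X,X,X,X,X,X,X,X,X",
    "c2,Y,Y,?,N,X,X,X,X,X,X",
    "c3,y, n ,yes,NO,X,X,X,X,X,X"), ".csv")
  batch <- read_cases(path)
  expect_length(batch$cases, 2L)
  expect_identical(vapply(batch$cases, `[[`, character(1), "case_id"),
                   c("c1", "c3"))
  expect_identical(unclass(batch$cases[[1]]$answers),
                   stats::setNames(rep("unknown", 10), as.character(1:10)))
  expect_identical(unname(batch$cases[[2]]$answers[1:4]),
                   c("yes", "no", "yes", "no"))
  expect_identical(nrow(batch$errors), 1L)
  expect_identical(batch$errors$case_id, "c2")
  expect_match(batch$errors$message, "invalid token '\\?' for q3")
})

test_that("structural CSV problems always fail the read", {
  dup_col <- write_lines_tmp(c("case_id,q1,q1,q3,q4,q5,q6,q7,q8,q9,q10",
                               "c1,X,X,X,X,X,X,X,X,X,X"), ".csv")
  expect_error(read_cases(dup_col), "duplicate header column 'q1'")

  missing_col <- write_lines_tmp(c("case_id,q1,q2,q3,q4,q5,q6,q7,q8,q9",
                                   "c1,X,X,X,X,X,X,X,X,X"), ".csv")
  expect_error(read_cases(missing_col), "missing header column\\(s\\) q10")

  dup_id <- write_lines_tmp(c("case_id,q1,q2,q3,q4,q5,q6,q7,q8,q9,q10",
                              "c1,X,X,X,X,X,X,X,X,X,X",
                              "c1,Y,X,X,X,X,X,X,X,X,X"), ".csv")
  expect_error(read_cases(dup_id), "duplicate case_id 'c1'")
})

test_that("strict mode escalates a malformed row to a failure", {
  path <- write_lines_tmp(c("case_id,q1,q2,q3,q4,q5,q6,q7,q8,q9,q10",
                            "c1,X,X,X,X,X,X,X,X,X,X",
                            "c2,Y,Y,?,N,X,X,X,X,X,X"), ".csv")
  expect_error(read_cases(path, strict = TRUE), "row 2 \\(case 'c2'\\)")
  expect_length(read_cases(path, strict = FALSE)$cases, 1L)
})

test_that("JSON cases round-trip through write_cases", {
  batch <- case_batch(list(a1 = all_of("unknown"),
                           a2 = answers_with(yes = c(1:4, 7:10), no = c(5, 6))))
  for (ext in c(".json", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_cases(batch, path)
    back <- read_cases(path)
    expect_identical(lapply(back$cases, `[[`, "case_id"),
                     lapply(batch$cases, `[[`, "case_id"))
    expect_identical(lapply(back$cases, `[[`, "answers"),
                     lapply(batch$cases, `[[`, "answers"))
    expect_identical(nrow(back$errors), 0L)
  }
})

test_that("malformed JSON records become per-record errors", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(case_id = "j1",
         answers = stats::setNames(as.list(rep("yes", 10)), as.character(1:10))),
    list(case_id = "j2",
         answers = stats::setNames(as.list(rep("yes", 9)), as.character(1:9))),
    list(answers = stats::setNames(as.list(rep("no", 10)), as.character(1:10)))),
    path, auto_unbox = TRUE)
  batch <- read_cases(path)
  expect_length(batch$cases, 1L)
  expect_identical(nrow(batch$errors), 2L)
  expect_match(batch$errors$message[1], "missing value for q10")
  expect_match(batch$errors$message[2], "missing case_id")
})

test_that("score_batch tallies categories and preserves conservation", {
  scale <- naranjo_scale()
  batch <- case_batch(list(c1 = all_of("unknown"),
                           c2 = answers_with(yes = c(1:4, 7:10), no = c(5, 6)),
                           c3 = answers_with(no = c(2, 4), yes = c(5, 6))))
  report <- score_batch(scale, batch)
  expect_identical(report$counts,
                   c(Doubtful = 2L, Possible = 0L, Probable = 0L, Definite = 1L))
  expect_identical(sum(report$counts), length(report$assessments))
  expect_identical(length(batch$cases),
                   length(report$assessments) + nrow(report$errors))
  expect_identical(vapply(report$assessments, `[[`, character(1), "case_id"),
                   c("c1", "c2", "c3"))
})

test_that("an empty batch yields an empty report with zero counts", {
  report <- score_batch(naranjo_scale(), case_batch(list()))
  expect_length(report$assessments, 0L)
  expect_identical(unname(report$counts), rep(0L, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(report, path)
  expect_identical(readLines(path),
                   paste(c("case_id", "total_score", "category",
                           paste0("q", 1:10, "_points")), collapse = ","))
})

test_that("read errors carry into the report so every case appears exactly once", {
  path <- write_lines_tmp(c("case_id,q1,q2,q3,q4,q5,q6,q7,q8,q9,q10",
                            "good,Y,N,X,Y,N,X,Y,N,X,Y",
                            "bad,Y,N,!,Y,N,X,Y,N,X,Y"), ".csv")
  batch <- read_cases(path)
  report <- score_batch(naranjo_scale(), batch)
  expect_length(report$assessments, 1L)
  expect_identical(nrow(report$errors), 1L)
  n_input <- 2L
  expect_identical(n_input, length(report$assessments) + nrow(report$errors))
})

test_that("reports serialize per published category words and round-trip", {
  scale <- naranjo_scale()
  batch <- case_batch(list(c1 = all_of("unknown")))
  report <- score_batch(scale, batch)
  csv <- withr::local_tempfile(fileext = ".csv")
  summ <- withr::local_tempfile(fileext = ".csv")
  write_report(report, csv, summary = summ)
  expect_identical(readLines(csv)[2], "c1,0,Doubtful,0,0,0,0,0,0,0,0,0,0")
  expect_identical(readLines(summ)[1:2], c("category,count", "Doubtful,1"))

  # write -> read -> write reproduces identical bytes, both formats
  for (ext in c(".csv", ".json")) {
    p1 <- withr::local_tempfile(fileext = ext)
    p2 <- withr::local_tempfile(fileext = ext)
    write_report(report, p1)
    write_report(read_report(p1), p2)
    expect_identical(readLines(p2), readLines(p1))
  }
})

test_that("scoring N copies of one case yields N identical assessments", {
  scale <- naranjo_scale()
  a <- answers_with(yes = 1:3)
  batch <- case_batch(stats::setNames(replicate(5, a, simplify = FALSE),
                                      paste0("r", 1:5)))
  report <- score_batch(scale, batch)
  totals <- vapply(report$assessments, `[[`, integer(1), "total")
  expect_identical(totals, rep(totals[1], 5))
  cats <- vapply(report$assessments, function(x) as.character(x$category),
                 character(1))
  expect_identical(cats, rep(cats[1], 5))
})
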