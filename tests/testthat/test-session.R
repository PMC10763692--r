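test_that("parse_token canonicalizes whitespace and case before classifying", {
  d <- token_dialect()
  expect_identical(parse_token("Y", d)$option, "yes")
  expect_identical(parse_token("x", d)$option, "unknown")
  expect_identical(parse_token("  n  ", d)$option, "no")
  expect_identical(parse_token("YES", d)$option, "yes")
  expect_identical(parse_token("quit", d)$outcome, "abort")
  rej <- parse_token("maybe", d)
  expect_identical(rej$outcome, "rejected")
  expect_match(rej$message, "Y/YES")
})

test_that("dialect token sets must be disjoint after canonicalization", {
  expect_error(token_dialect(yes = c("y", "N")), "token 'n'")
  d <- token_dialect(unknown = c("x", "dk"))
  expect_identical(parse_token("DK", d)$option, "unknown")
})

test_that("an all-unknown scripted session completes with score 0, Doubtful", {
  tr <- run_session(naranjo_scale(), input = rep("X", 10), case_id = "s1")
  expect_true(tr$completed)
  expect_identical(nrow(tr$events), 10L)
  expect_identical(unique(tr$events$outcome), "accepted")
  expect_identical(tr$result$total, 0L)
  expect_identical(as.character(tr$result$category), "Doubtful")
  expect_match(tr$output, "Naranjo score: 0", all = FALSE)
  expect_match(tr$output, "ADR category: Doubtful", all = FALSE)
})

test_that("an invalid token triggers exactly one rejection and a re-prompt of the same question", {
  lines <- c("Z", "Y", rep("N", 9))
  tr <- run_session(naranjo_scale(), input = lines, case_id = "s2")
  expect_true(tr$completed)
  expect_identical(sum(tr$events$outcome == "rejected"), 1L)
  expect_identical(tr$events$question[1:2], c(1L, 1L))
  expect_identical(tr$events$outcome[1:2], c("rejected", "accepted"))
  # prompt for question 1 appears twice in the display
  expect_identical(sum(grepl("^Q1\\.", tr$output)), 2L)
  # accepted answers: yes on 1, no on 2..10 -> published column sums give 1+0=1? no:
  # q1 yes = +1, q2..q10 no = 0 -1 +2 +1 +0 +0 +0 +0 = hand sum below
  expect_identical(tr$result$total,
                   total_score(naranjo_scale(), answers_with(yes = 1, no = 2:10)))
})

test_that("retries are unbounded until a valid token arrives", {
  lines <- c(rep("??", 25), "Y", rep("X", 9))
  tr <- run_session(naranjo_scale(), input = lines)
  expect_true(tr$completed)
  expect_identical(sum(tr$events$outcome == "rejected"), 25L)
  expect_identical(nrow(tr$events), 35L)
})

test_that("end of input and the abort token both yield aborted transcripts", {
  tr <- run_session(naranjo_scale(), input = c("Y", "N", "X"))
  expect_false(tr$completed)
  expect_null(tr$result)
  expect_identical(sum(tr$events$outcome == "accepted"), 3L)
  expect_identical(tr$events$outcome[4L], "aborted")
  expect_true(is.na(tr$events$input[4L]))

  tr2 <- run_session(naranjo_scale(), input = c("Y", "quit"))
  expect_false(tr2$completed)
  expect_identical(tr2$events$input[2L], "quit")
  expect_identical(tr2$events$outcome[2L], "aborted")
})

test_that("a completed session's result equals assess() on the accepted answers", {
  scale <- naranjo_scale()
  set.seed(5)
  token_for <- c(yes = "Y", no = "n", unknown = " x ")
  for (rep in 1:10) {
    opts <- sample(response_options(), 10, replace = TRUE)
    tr <- run_session(scale, input = unname(token_for[opts]), case_id = "p")
    expect_identical(tr$result,
                     assess(scale, stats::setNames(opts, as.character(1:10)), "p"))
  }
})

test_that("replaying the same scripted input yields byte-identical output", {
  lines <- c("Z", "y", "N", "x", rep("Y", 7))
  tr1 <- run_session(naranjo_scale(), input = lines)
  tr2 <- run_session(naranjo_scale(), input = lines)
  expect_identical(tr1$output, tr2$output)
  # and the connection-backed display path writes those same lines
  con <- textConnection("captured", "w", local = TRUE)
  run_session(naranjo_scale(), input = lines, output = con)
  close(con)
  expect_identical(captured, tr1$output)
})

test_that("every consumed input line leaves a transcript event", {
  lines <- c("bogus", "Y", "quit")
  tr <- run_session(naranjo_scale(), input = lines)
  expect_identical(nrow(tr$events), length(lines))
  expect_identical(tr$events$input, lines)
})

test_that("transcripts serialize to JSON with events and assessment", {
  path <- withr::local_tempfile(fileext = ".json")
  tr <- run_session(naranjo_scale(), input = c("Z", rep("Y", 10)), case_id = "t1")
  write_transcript(tr, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_identical(doc$case_id, "t1")
  expect_true(doc$completed)
  expect_length(doc$events, 11L)
  expect_identical(doc$events[[1]]$outcome, "rejected")
  expect_equal(doc$assessment$total, 8)
  expect_identical(doc$assessment$category, "Probable")
})
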