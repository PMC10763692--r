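# Synthetic cases and the exhaustive-enumeration oracle. The oracle carries
# its OWN transcription of the published weight table and its OWN threshold
# rule (interval breaks via cut(), not the >= comparisons in categorize());
# sharing the naranjo_scale() constants would make every cross-check against
# the scoring module vacuous.

# Independent copy of the published 10 x 3 point table (rows = questions,
# columns = yes/no/don't-know), transcribed separately from naranjo_scale().
oracle_weights <- function() {
  matrix(c(
     1,  0, 0,   # previous conclusive reports
     2, -1, 0,   # event after drug administration
     1,  0, 0,   # improved on dechallenge/antagonist
     2, -1, 0,   # reappeared on rechallenge
    -1,  2, 0,   # alternative causes
    -1,  1, 0,   # reaction on placebo
     1,  0, 0,   # toxic drug concentration measured
     1,  0, 0,   # dose-response relationship
     1,  0, 0,   # similar reaction on past exposure
     1,  0, 0),  # objective confirmation
    nrow = 10, byrow = TRUE,
    dimnames = list(NULL, c("yes", "no", "unknown")))
}

# independent threshold rule: half-open integer bins <=0 / 1-4 / 5-8 / >=9
oracle_categorize <- function(total) {
  as.character(cut(total, breaks = c(-Inf, 0, 4, 8, Inf),
                   labels = adr_categories()))
}

#' Enumerate every possible answer vector
#'
#' Generates all 3^10 = 59,049 complete answer vectors and scores each one
#' with an independently transcribed copy of the published weight table and
#' an independently coded threshold rule. This is the audit oracle that the
#' package's property tests cross-check the scoring module against; the two
#' implementations share no lookup code.
#'
#' @param scale A `naranjo_scale`; used only to confirm the expected shape
#'   (10 questions, three options each). The oracle's weights are its own.
#' @return A data frame with 59,049 rows: columns `q1`..`q10` (canonical
#'   option words), `total` (integer) and `category` (character).
#' @export
#' @examples
#' \donttest{
#' e <- enumerate_vectors()
#' range(e$total)   # -4 .. 13
#' }
enumerate_vectors <- function(scale = naranjo_scale()) {
  validate_scale(scale)
  if (length(scale$questions) != 10L)
    stop("enumeration oracle requires a 10-question scale")
  opts <- response_options()
  grid <- expand.grid(rep(list(opts), 10), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  names(grid) <- paste0("q", 1:10)
  w <- oracle_weights()
  total <- integer(nrow(grid))
  for (i in 1:10)
    total <- total + as.integer(w[i, ][grid[[i]]])
  grid$total <- total
  grid$category <- oracle_categorize(total)
  grid
}

#' Generate random answer vectors
#'
#' Draws `n` cases with independent answers per question under the given
#' option probabilities. The default is uniform (1/3 each); there is no
#' published empirical answer distribution to emulate. Identical seeds give
#' identical batches; the caller's RNG state is left untouched.
#'
#' @param n Number of cases.
#' @param seed Integer seed.
#' @param probs Named probabilities over [response_options()]; must be
#'   non-negative and sum to 1 (within 1e-9).
#' @param source Provenance string for the batch.
#' @return A `naranjo_batch` of `n` cases with ids `case_0001`, ...
#' @export
#' @examples
#' b <- random_cases(5, seed = 7)
#' length(b$cases)
random_cases <- function(n, seed = 1L,
                         probs = c(yes = 1/3, no = 1/3, unknown = 1/3),
                         source = "random") {
  if (!is.numeric(n) || length(n) != 1L || n < 1L || n != as.integer(n))
    stop("n must be a positive integer")
  opts <- response_options()
  if (length(miss <- setdiff(opts, names(probs))))
    stop(sprintf("probs is missing option '%s'", miss[1L]))
  probs <- probs[opts]
  if (any(probs < 0))
    stop("probs must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9)
    stop(sprintf("probs must sum to 1 (got %.12f)", sum(probs)))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  draws <- matrix(sample(opts, n * 10L, replace = TRUE, prob = probs),
                  nrow = n, ncol = 10L)
  cases <- lapply(seq_len(n), function(i)
    list(case_id = sprintf("case_%04d", i),
         answers = answer_vector(stats::setNames(draws[i, ],
                                                 as.character(1:10)))))
  new_batch(cases, source = sprintf("%s(seed=%d)", source, as.integer(seed)))
}

#' Boundary witness cases
#'
#' One answer vector for each attainable total score (-4 through 13 on the
#' published scale), found by exhaustive enumeration. The witnesses straddle
#' every category boundary (0/1, 4/5, 8/9) and re-score to their labelled
#' totals under [assess()], which makes them convenient fixtures for
#' threshold tests.
#'
#' @param scale A `naranjo_scale`.
#' @return A `naranjo_batch` with one case per attainable total, ids of the
#'   form `total_-4` ... `total_13`, in increasing score order.
#' @export
boundary_cases <- function(scale = naranjo_scale()) {
  enum <- enumerate_vectors(scale)
  totals <- sort(unique(enum$total))
  cases <- lapply(totals, function(t) {
    row <- enum[which(enum$total == t)[1L], paste0("q", 1:10)]
    list(case_id = sprintf("total_%d", t),
         answers = answer_vector(stats::setNames(unlist(row),
                                                 as.character(1:10))))
  })
  new_batch(cases, source = "boundary_enumeration")
}
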