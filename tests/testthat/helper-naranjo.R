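# Expected point table frozen from the published instrument, transcribed in
# the tests independently of both R/scale.R and the enumeration oracle.
expected_weights <- function() {
  m <- matrix(c(
     1,  0, 0,
     2, -1, 0,
     1,  0, 0,
     2, -1, 0,
    -1,  2, 0,
    -1,  1, 0,
     1,  0, 0,
     1,  0, 0,
     1,  0, 0,
     1,  0, 0),
    nrow = 10, byrow = TRUE,
    dimnames = list(NULL, c("yes", "no", "unknown")))
  storage.mode(m) <- "integer"
  m
}

# uniform answer vector helpers
all_of <- function(option) rep(option, 10)

# named answer vector from per-question assignments, rest defaulting to a
# filler option (explicit, never silent in the scoring core itself)
answers_with <- function(yes = integer(0), no = integer(0), fill = "unknown") {
  a <- rep(fill, 10)
  a[yes] <- "yes"
  a[no] <- "no"
  stats::setNames(a, as.character(1:10))
}

# scoring-module totals for the rows of an enumeration data frame, computed
# case by case through the public API
module_totals <- function(scale, enum) {
  m <- as.matrix(enum[paste0("q", 1:10)])
  vapply(seq_len(nrow(m)), function(i) total_score(scale, m[i, ]), integer(1))
}
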