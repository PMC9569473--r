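## internal helpers shared across modules

# run code under a fixed RNG seed without disturbing the caller's stream;
# seed = NULL means "use the current stream"
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# squared Euclidean distances between the rows of a (n x 3) and b (m x 3)
cross_sqdist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0   # guard rounding noise before sqrt
  d2
}

check_number <- function(x, what, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", what), class = "xlinkr_input_error")
  }
  if (x < min) {
    abort(sprintf("`%s` must be >= %s (got %s).", what, format(min), format(x)),
          class = "xlinkr_input_error")
  }
  invisible(x)
}

# inclusive 1-based ranges are used everywhere; validate a start/end pair set
check_ranges <- function(start, end) {
  if (any(end < start)) {
    bad <- which(end < start)[1]
    abort(sprintf("Invalid range: end (%d) < start (%d).", end[bad], start[bad]),
          class = "xlinkr_range_error")
  }
  invisible(NULL)
}
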