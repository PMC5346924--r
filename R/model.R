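#' Specify a fragmentation pattern-space model
#'
#' A pattern-space model describes exhaustive, unbiased fragmentation of a
#' single transcript: fragments with lengths drawn from a fixed set are placed
#' on non-overlapping positions until no remaining gap (leading, internal or
#' trailing) can hold another fragment, i.e. every gap is strictly shorter than
#' the smallest allowed fragment length.  Each maximal placement is a
#' *fragmentation pattern*, and the *pattern space* is the set of all distinct
#' patterns.  All pattern counting, coverage-profile and simulation functions
#' in this package consume this object.
#'
#' @param transcript_length positive integer, transcript length `T` in bp.
#' @param lengths integer vector of allowed fragment lengths in bp
#'   (each >= 1, no duplicates); stored in increasing order.
#' @param weights optional named numeric vector of nonnegative, dimensionless
#'   per-length weights `W(F_j)` (names are fragment lengths; every model
#'   length must have a weight).  Typically the ratio of observed to expected
#'   relative length frequency, see [compute_weights()].
#' @param read_length optional positive integer read length `R` in bp; required
#'   only for read coverage profiles.
#' @param weight_mode how weights act on the pattern space.
#'   `"contribution"` (default) keeps all patterns equiprobable and scales each
#'   fragment's coverage contribution by `W(F_j)`; `"pattern"` reweights each
#'   whole pattern by the product of its fragments' weights (the mode used by
#'   the simulator for consistent sampling).
#'
#' @return an object of class `pattern_space_model`.
#' @examples
#' m <- pattern_space_model(10, 4)
#' count_patterns(m)
#' pattern_space_model(1000, c(100, 151, 200), read_length = 100)
#' @export
pattern_space_model <- function(transcript_length, lengths, weights = NULL,
                                read_length = NULL,
                                weight_mode = c("contribution", "pattern")) {
  weight_mode <- match.arg(weight_mode)
  if (length(transcript_length) != 1L || !is.finite(transcript_length) ||
      transcript_length < 1 || transcript_length != floor(transcript_length)) {
    stop("`transcript_length` must be a single positive integer")
  }
  if (length(lengths) < 1L || anyNA(lengths) ||
      any(lengths < 1 | lengths != floor(lengths))) {
    stop("`lengths` must be a non-empty vector of positive integers")
  }
  if (anyDuplicated(lengths)) stop("duplicate fragment lengths are not allowed")
  lengths <- sort(as.numeric(lengths))
  if (!is.null(weights)) {
    if (is.null(names(weights))) {
      if (length(weights) != length(lengths)) {
        stop("unnamed `weights` must have one entry per fragment length")
      }
      names(weights) <- as.character(lengths)
    }
    missing <- setdiff(as.character(lengths), names(weights))
    if (length(missing)) {
      stop("missing weights for fragment lengths: ", paste(missing, collapse = ", "))
    }
    weights <- weights[as.character(lengths)]
    if (anyNA(weights) || any(weights < 0)) {
      stop("weights must be nonnegative and non-missing")
    }
    weights <- as.numeric(weights)
    names(weights) <- as.character(lengths)
  }
  if (!is.null(read_length)) {
    if (length(read_length) != 1L || !is.finite(read_length) ||
        read_length < 1 || read_length != floor(read_length)) {
      stop("`read_length` must be a single positive integer")
    }
    read_length <- as.numeric(read_length)
  }
  structure(
    list(
      transcript_length = as.numeric(transcript_length),
      lengths = lengths,
      weights = weights,
      read_length = read_length,
      weight_mode = weight_mode
    ),
    class = "pattern_space_model"
  )
}

#' @export
print.pattern_space_model <- function(x, ...) {
  cat("Fragmentation pattern-space model\n")
  cat("  transcript length T:", x$transcript_length, "bp\n")
  if (length(x$lengths) <= 8) {
    cat("  fragment lengths:", paste(x$lengths, collapse = ", "), "bp\n")
  } else {
    cat("  fragment lengths:", length(x$lengths), "values in [",
        min(x$lengths), ",", max(x$lengths), "] bp\n")
  }
  if (!is.null(x$read_length)) cat("  read length R:", x$read_length, "bp\n")
  if (!is.null(x$weights)) {
    cat("  weighted (mode:", x$weight_mode, ")\n")
  }
  invisible(x)
}

.assert_model <- function(model) {
  if (!inherits(model, "pattern_space_model")) {
    stop("expected a `pattern_space_model` object")
  }
  model
}

# Per-fragment coverage vector C of length F for one coverage kind.
# read kind: ones over the first and last min(R, F) positions, summed, so
# overlapping mates (F < 2R) give values of 2 and F <= R gives a constant 2.
.coverage_vector <- function(F, kind, read_length = NULL) {
  switch(kind,
    start_point = c(1, numeric(F - 1)),
    fragment = rep(1, F),
    read = {
      if (is.null(read_length)) stop("read coverage requires `read_length`")
      r <- min(read_length, F)
      v <- numeric(F)
      v[seq_len(r)] <- v[seq_len(r)] + 1
      v[seq.int(F - r + 1, F)] <- v[seq.int(F - r + 1, F)] + 1
      v
    },
    stop("unknown coverage kind: ", kind)
  )
}

.COVERAGE_KINDS <- c("start_point", "fragment", "read")
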