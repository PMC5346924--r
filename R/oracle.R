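# Brute-force enumeration of the pattern space.
#
# The enumeration is the ground truth for the dynamic program and for the
# simulator's distributional checks.  It is exponential in T and guarded by a
# safety bound; the DP in R/dp.R is the performance path.

#' Enumerate every fragmentation pattern explicitly
#'
#' Depth-first enumeration of all exhaustive fragment placements for small
#' transcripts.  Every returned pattern is maximal: each gap (leading,
#' internal, trailing) is strictly shorter than the smallest fragment length,
#' so no further fragment fits anywhere.  A transcript shorter than the
#' smallest fragment yields the single empty pattern.
#'
#' Enumeration order is deterministic: at each suffix the leading gap is
#' increased first, then the fragment length.
#'
#' @param model a [pattern_space_model()]; weights are ignored here.
#' @param max_transcript_length refusal bound on `T` (enumeration grows
#'   exponentially); raise explicitly for larger toy cases.
#' @return an object of class `pattern_space`: a list of patterns, each a
#'   two-column matrix (`start` 0-based, `length`), with the model attached
#'   as an attribute.
#' @examples
#' enumerate_patterns(pattern_space_model(4, 2)) # {(0,2),(2,2)} and {(1,2)}
#' @export
enumerate_patterns <- function(model, max_transcript_length = 25) {
  model <- .assert_model(model)
  T <- model$transcript_length
  if (T > max_transcript_length) {
    stop("transcript length ", T, " exceeds the enumeration bound (",
         max_transcript_length, "); the pattern space grows exponentially. ",
         "Raise `max_transcript_length` explicitly for larger toy cases.")
  }
  lengths <- model$lengths
  F1 <- lengths[1L]
  out <- list()
  frag_starts <- numeric(0)
  frag_lens <- numeric(0)
  recurse <- function(pos) {
    l <- T - pos
    if (l < F1) {
      out[[length(out) + 1L]] <<- cbind(start = frag_starts, length = frag_lens)
      return(invisible())
    }
    for (g in 0:(F1 - 1)) {
      for (Fj in lengths) {
        if (g + Fj > l) next
        frag_starts <<- c(frag_starts, pos + g)
        frag_lens <<- c(frag_lens, Fj)
        recurse(pos + g + Fj)
        frag_starts <<- frag_starts[-length(frag_starts)]
        frag_lens <<- frag_lens[-length(frag_lens)]
      }
    }
  }
  recurse(0)
  structure(out, class = "pattern_space", model = model)
}

#' @export
print.pattern_space <- function(x, ...) {
  m <- attr(x, "model")
  cat(sprintf("<pattern_space> %d patterns (T=%d, lengths: %s)\n",
              length(x), as.integer(m$transcript_length),
              paste(m$lengths, collapse = ",")))
  invisible(x)
}

#' Coverage profile by direct summation over enumerated patterns
#'
#' Sums each fragment's coverage vector over all enumerated patterns: the
#' brute-force counterpart of [expected_profile()], exact by construction
#' (integer-valued when unweighted).  In contribution mode each fragment's
#' vector is scaled by its length's weight; in pattern mode each whole
#' pattern is scaled by the product of its fragments' weights.
#'
#' @param patterns a `pattern_space` from [enumerate_patterns()].
#' @param kind coverage kind (`"start_point"`, `"fragment"`, `"read"`).
#' @param read_length read length for `kind = "read"`; defaults to the
#'   model's.
#' @param weights optional named weight vector overriding the model's.
#' @param weight_mode `"contribution"` or `"pattern"`; defaults to the
#'   model's mode.
#' @return a `coverage_profile`.
#' @export
profile_from_patterns <- function(patterns,
                                  kind = c("start_point", "fragment", "read"),
                                  read_length = NULL, weights = NULL,
                                  weight_mode = NULL) {
  stopifnot(inherits(patterns, "pattern_space"))
  kind <- match.arg(kind)
  model <- attr(patterns, "model")
  T <- model$transcript_length
  if (is.null(read_length)) read_length <- model$read_length
  if (is.null(weights)) weights <- model$weights
  if (is.null(weight_mode)) {
    weight_mode <- if (is.null(model$weights)) "contribution" else model$weight_mode
  }
  if (kind == "read" && is.null(read_length)) {
    stop("`kind = \"read\"` requires a read length")
  }
  wt <- function(F) if (is.null(weights)) 1 else unname(weights[as.character(F)])
  vals <- numeric(T)
  for (pat in patterns) {
    if (nrow(pat) == 0L) next
    pat_w <- if (weight_mode == "pattern") prod(vapply(pat[, "length"], wt, numeric(1))) else 1
    for (i in seq_len(nrow(pat))) {
      F <- pat[i, "length"]
      p <- pat[i, "start"]
      C <- .coverage_vector(F, kind, read_length)
      scale <- if (weight_mode == "pattern") pat_w else wt(F)
      vals[(p + 1):(p + F)] <- vals[(p + 1):(p + F)] + scale * C
    }
  }
  pmodel <- model
  pmodel$weights <- weights
  pmodel$weight_mode <- weight_mode
  pmodel$read_length <- read_length
  .new_profile(vals, kind, pmodel)
}

#' Dump an enumerated pattern space as TSV
#'
#' One row per placed fragment: `pattern` (1-based pattern id), `start`
#' (0-based) and `length`.  Patterns with no fragments (transcript shorter
#' than every fragment) emit a single row with empty start/length fields.
#' A teaching/debugging companion to [enumerate_patterns()].
#'
#' @param patterns a `pattern_space`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(patterns, path) {
  stopifnot(inherits(patterns, "pattern_space"))
  rows <- lapply(seq_along(patterns), function(i) {
    p <- patterns[[i]]
    if (nrow(p) == 0L) {
      data.frame(pattern = i, start = NA_real_, length = NA_real_)
    } else {
      data.frame(pattern = i, start = p[, "start"], length = p[, "length"])
    }
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
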