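# Expected coverage profiles.
#
# A coverage profile N is the position-wise sum, over every pattern in the
# (weighted) pattern space, of a per-fragment coverage vector C:
#   start_point: C = (1, 0, ..., 0)            -> SPP, sums to 1 per fragment
#   fragment:    C = (1, ..., 1)               -> FCP, sums to F_j
#   read:        ones over the first and last min(R, F_j) bases, summed
#                -> RCP, sums to 2 * min(R, F_j); overlapping mates give 2s.
# Profiles are assembled from the start matrix by interval accumulation
# (difference vector + cumsum), which is exact for integer-valued counts.

.new_profile <- function(values, kind, model, normalized = FALSE, log_scale = 0) {
  structure(
    list(
      values = values,
      kind = kind,
      normalized = normalized,
      transcript_length = model$transcript_length,
      lengths = model$lengths,
      weighted = !is.null(model$weights),
      weight_mode = if (is.null(model$weights)) NA_character_ else model$weight_mode,
      read_length = model$read_length,
      log_scale = log_scale
    ),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf(
    "<coverage_profile> kind=%s T=%d %s%s\n",
    x$kind, as.integer(x$transcript_length),
    if (x$normalized) "normalized" else "raw counts",
    if (x$weighted) sprintf(" weighted(%s)", x$weight_mode) else ""
  ))
  v <- x$values
  n <- min(10L, length(v))
  cat("  values[1..", n, "]: ", paste(signif(v[seq_len(n)], 6), collapse = " "),
      if (length(v) > n) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.double.coverage_profile <- function(x, ...) x$values

#' @export
length.coverage_profile <- function(x) length(x$values)

# accumulate weights over half-open intervals [starts, ends) on 1..T grid;
# starts/ends are 0-based, may repeat
.interval_accumulate <- function(d, starts, ends, wts) {
  add <- rowsum(c(wts, -wts), c(starts, ends))
  idx <- as.numeric(rownames(add)) + 1L
  d[idx] <- d[idx] + add[, 1L]
  d
}

#' Expected coverage profile of the pattern space
#'
#' Computes the expected starting-point (`"start_point"`), fragment
#' (`"fragment"`) or read (`"read"`) coverage profile of the model: for each
#' transcript position, the total coverage contributed by all fragments over
#' all patterns of the (weighted) pattern space.  If the model carries
#' weights they are applied according to its `weight_mode`; an unweighted
#' model gives the plain expected profile.
#'
#' @param model a [pattern_space_model()]; `read_length` is required for
#'   `kind = "read"`.
#' @param kind coverage kind, one of `"start_point"`, `"fragment"`, `"read"`.
#' @param normalized if `TRUE`, the profile is sum-normalized to 1.
#' @param exact use the exact big-integer path end to end (unweighted or
#'   contribution-mode models; intended for validation at modest `T`).
#' @return a `coverage_profile` object holding a length-`T` nonnegative
#'   vector.  If the transcript is shorter than the smallest fragment length
#'   the profile is all zero (the pattern space holds only the empty
#'   placement) and a warning is raised.
#' @examples
#' m <- pattern_space_model(10, 4)
#' as.numeric(expected_profile(m, "start_point"))
#' as.numeric(expected_profile(m, "fragment", normalized = TRUE))
#' @export
expected_profile <- function(model, kind = c("start_point", "fragment", "read"),
                             normalized = FALSE, exact = FALSE) {
  model <- .assert_model(model)
  kind <- match.arg(kind)
  T <- model$transcript_length
  lengths <- model$lengths
  if (kind == "read" && is.null(model$read_length)) {
    stop("`kind = \"read\"` requires a model with `read_length`")
  }
  if (T < lengths[1L]) {
    warning("transcript shorter than the smallest fragment length: ",
            "the pattern space holds only the empty placement (zero profile)")
    return(.new_profile(numeric(T), kind, model))
  }
  if (exact) {
    prof <- .profile_exact(model, kind)
  } else {
    sm <- .start_matrix_num(model)
    vals <- .profile_from_matrix(sm$M, lengths, T, kind, model$read_length)
    if (sm$log_scale == 0 && !all(is.finite(vals))) {
      # raw sums overflowed even though the matrix did not; redo in log space
      sm <- .start_matrix_log_forced(model)
      vals <- .profile_from_matrix(sm$M, lengths, T, kind, model$read_length)
    }
    prof <- .new_profile(vals, kind, model, log_scale = sm$log_scale)
  }
  if (normalized) prof <- normalize_profile(prof) else prof
}

.start_matrix_log_forced <- function(model) {
  T <- model$transcript_length
  lengths <- model$lengths
  k <- length(lengths)
  W <- if (is.null(model$weights)) rep(1, k) else unname(model$weights)
  weighted_mass <- !is.null(model$weights) && model$weight_mode == "pattern"
  lB <- .suffix_counts_log(T, lengths, if (weighted_mass) log(W) else NULL)
  logM <- matrix(-Inf, k, T)
  for (j in seq_len(k)) {
    Fj <- lengths[j]
    if (Fj > T) next
    p <- 0:(T - Fj)
    logM[j, p + 1L] <- log(W[j]) + lB[p + 1L] + lB[T - p - Fj + 1L]
  }
  off <- suppressWarnings(max(logM[is.finite(logM)]))
  if (!is.finite(off)) off <- 0
  list(M = exp(logM - off), log_scale = off)
}

.profile_from_matrix <- function(M, lengths, T, kind, read_length) {
  if (kind == "start_point") return(colSums(M))
  d <- numeric(T + 1L)
  for (j in seq_along(lengths)) {
    Fj <- lengths[j]
    if (Fj > T) next
    p <- 0:(T - Fj)
    m <- M[j, p + 1L]
    if (kind == "fragment") {
      d[p + 1L] <- d[p + 1L] + m
      d[p + Fj + 1L] <- d[p + Fj + 1L] - m
    } else { # read
      r <- min(read_length, Fj)
      d[p + 1L] <- d[p + 1L] + m
      d[p + r + 1L] <- d[p + r + 1L] - m
      d[p + Fj - r + 1L] <- d[p + Fj - r + 1L] + m
      d[p + Fj + 1L] <- d[p + Fj + 1L] - m
    }
  }
  cumsum(d)[seq_len(T)]
}

# exact big-integer profile (unweighted counts; contribution weights applied
# as a final per-length scaling)
.profile_exact <- function(model, kind) {
  T <- model$transcript_length
  lengths <- model$lengths
  if (!is.null(model$weights) && model$weight_mode == "pattern") {
    stop("exact mode supports unweighted models or contribution weighting only")
  }
  unweighted <- is.null(model$weights)
  W <- if (unweighted) rep(1, length(lengths)) else unname(model$weights)
  rows <- .start_matrix_exact_bi(T, lengths)
  zero <- bi(0)
  # unweighted: one big-integer accumulator end to end (fully exact);
  # contribution weights: exact per-length counts, double scaling at the end
  acc_bi <- rep(list(zero), T)
  total <- numeric(T)
  for (j in seq_along(lengths)) {
    Fj <- lengths[j]
    if (Fj > T || W[j] == 0) next
    acc <- if (unweighted) acc_bi else rep(list(zero), T)
    C <- .coverage_vector(Fj, kind, model$read_length)
    for (p in 0:(T - Fj)) {
      mjp <- rows[[j]][[p + 1L]]
      if (bi_is_zero(mjp)) next
      for (o in which(C > 0)) {
        pos <- p + o
        acc[[pos]] <- bi_add(acc[[pos]], if (C[o] == 2) bi_add(mjp, mjp) else mjp)
      }
    }
    if (unweighted) {
      acc_bi <- acc
    } else {
      total <- total + W[j] * vapply(acc, bi_to_num, numeric(1))
    }
  }
  if (unweighted) total <- vapply(acc_bi, bi_to_num, numeric(1))
  .new_profile(total, kind, model)
}

#' Sum-normalize a coverage profile
#'
#' Divides the profile by its sum so the entries add to 1.  An all-zero
#' profile is returned unchanged (with `normalized = FALSE`) and a warning.
#' Normalizing an already normalized profile is a no-op.
#'
#' @param profile a `coverage_profile`.
#' @return a `coverage_profile` with `normalized = TRUE` (unless degenerate).
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "coverage_profile"))
  s <- sum(profile$values)
  if (s == 0) {
    warning("all-zero profile cannot be normalized")
    return(profile)
  }
  profile$values <- profile$values / s
  profile$normalized <- TRUE
  profile$log_scale <- 0
  profile
}

#' Expected coverage profile of a weighted pattern space
#'
#' Convenience wrapper around [expected_profile()] that insists the model
#' carries an empirical fragment-length weighting.  With all weights equal to
#' 1 the result is identical to the unweighted expected profile.
#'
#' @inheritParams expected_profile
#' @return a `coverage_profile`.
#' @export
weighted_profile <- function(model, kind = c("start_point", "fragment", "read"),
                             normalized = FALSE, exact = FALSE) {
  model <- .assert_model(model)
  if (is.null(model$weights)) stop("`model` has no weights; see `compute_weights()`")
  expected_profile(model, kind, normalized = normalized, exact = exact)
}
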