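# Dynamic-programming core of the pattern-space model.
#
# Everything rests on the suffix pattern counts B(l) = FP(l, F_{1..k}): the
# number (or weighted mass) of exhaustive fragmentation patterns on a
# transcript of length l.  Recursion over the leading gap i (0 <= i < F1) and
# the first fragment length F_j:
#
#   FP(l) = sum_{i=0}^{F1-1} sum_{j=1}^{k} FP(l - F_j - i),   l >= F1
#   FP(l) = 1 for 0 <= l < F1 (the empty placement),  FP(l) = 0 for l < 0.
#
# Because prefix fillings with every gap (including the one abutting a fixed
# fragment start) shorter than F1 are mirror images of suffix patterns, the
# number of patterns containing a fragment of length F_j starting at position
# p factorizes as B(p) * B(T - p - F_j).  This gives all coverage profiles in
# O(T * (k + F1)) instead of the exponential enumeration.
#
# Three numeric regimes share that recursion:
#   * plain doubles (exact integers below 2^53, the common case),
#   * log-space (logsumexp) when doubles would overflow,
#   * exact big integers (R/bigint.R) for the exact counting path.

# ---- suffix counts -------------------------------------------------------

# doubles; optional per-length weights give the weighted pattern mass
.suffix_counts <- function(T, lengths, w = NULL) {
  F1 <- lengths[1L]
  if (is.null(w)) w <- rep(1, length(lengths))
  v <- numeric(T + 1)
  v[seq_len(min(F1, T + 1))] <- 1
  cs <- cumsum(v)
  if (T >= F1) {
    for (l in F1:T) {
      hi <- l - lengths
      ok <- hi >= 0
      s <- 0
      if (any(ok)) {
        lo <- pmax(0, hi[ok] - F1 + 1)
        lov <- numeric(sum(ok))
        pos <- lo > 0
        lov[pos] <- cs[lo[pos]]
        s <- sum(w[ok] * (cs[hi[ok] + 1L] - lov))
      }
      v[l + 1L] <- s
      cs[l + 1L] <- cs[l] + s
    }
  }
  v
}

# log-space variant, used when the double path overflows
.suffix_counts_log <- function(T, lengths, logw = NULL) {
  F1 <- lengths[1L]
  k <- length(lengths)
  if (is.null(logw)) logw <- numeric(k)
  lv <- rep(-Inf, T + 1)
  lv[seq_len(min(F1, T + 1))] <- 0
  if (T >= F1) {
    offs <- rep(lengths, times = F1) + rep(0:(F1 - 1), each = k) # F_j + i
    lw <- rep(logw, times = F1)
    for (l in F1:T) {
      idx <- l - offs
      keep <- idx >= 0
      if (!any(keep)) next
      vals <- lv[idx[keep] + 1L] + lw[keep]
      m <- max(vals)
      if (is.finite(m)) lv[l + 1L] <- m + log(sum(exp(vals - m)))
    }
  }
  lv
}

# exact big-integer variant (unweighted); uses the sliding window
# S(l) = S(l-1) + G(l) - G(l - F1) with G(m) = sum_j FP(m - F_j)
.suffix_counts_exact <- function(T, lengths) {
  F1 <- lengths[1L]
  zero <- bi(0)
  one <- bi(1)
  FPs <- rep(list(one), min(F1, T + 1))
  if (T >= F1) {
    length(FPs) <- T + 1
    G <- vector("list", T + 1)
    gsum <- function(l) {
      g <- zero
      for (Fj in lengths) {
        d <- l - Fj
        if (d >= 0) g <- bi_add(g, FPs[[d + 1L]])
      }
      g
    }
    for (m in 0:F1) G[[m + 1L]] <- gsum(m)
    S <- zero
    for (m in 1:F1) S <- bi_add(S, G[[m + 1L]])
    FPs[[F1 + 1L]] <- S
    if (T > F1) {
      for (l in (F1 + 1):T) {
        G[[l + 1L]] <- gsum(l)
        S <- bi_sub(bi_add(S, G[[l + 1L]]), G[[l - F1 + 1L]])
        FPs[[l + 1L]] <- S
      }
    }
  }
  FPs
}

# ---- pattern counting ----------------------------------------------------

#' Count fragmentation patterns exactly
#'
#' Computes the exact number of distinct exhaustive fragmentation patterns
#' `FP(T, F_1..k)` for the model, as an unbounded integer.  Weights, if any,
#' are ignored: counting is a purely combinatorial quantity.
#'
#' @param model a [pattern_space_model()].
#' @return an object of class `pattern_count`; use `as.character()` for the
#'   exact decimal value and `as.numeric()` for a double approximation.
#' @examples
#' as.numeric(count_patterns(pattern_space_model(10, 4))) # 7
#' count_patterns(pattern_space_model(5, c(3, 4)))        # 5
#' @export
count_patterns <- function(model) {
  model <- .assert_model(model)
  FPs <- .suffix_counts_exact(model$transcript_length, model$lengths)
  structure(list(bigint = FPs[[model$transcript_length + 1L]]),
            class = "pattern_count")
}

#' @export
format.pattern_count <- function(x, ...) {
  s <- bi_to_str(x$bigint)
  if (nchar(s) > 15) {
    sprintf("%s (~%.6e)", s, bi_to_num(x$bigint))
  } else {
    s
  }
}

#' @export
print.pattern_count <- function(x, ...) {
  cat("fragmentation patterns:", format(x), "\n")
  invisible(x)
}

#' @export
as.character.pattern_count <- function(x, ...) bi_to_str(x$bigint)

#' @export
as.double.pattern_count <- function(x, ...) bi_to_num(x$bigint)

#' Total weighted mass of the pattern space
#'
#' Generalizes the pattern count to weighted models: each pattern contributes
#' the product of its fragments' weights.  With all weights equal to 1 this
#' equals [count_patterns()]; for a transcript equal to a single fragment
#' length `F` it equals `W(F)`.
#'
#' @param model a weighted [pattern_space_model()].
#' @return a single nonnegative number.
#' @export
weighted_pattern_mass <- function(model) {
  model <- .assert_model(model)
  if (is.null(model$weights)) stop("`model` has no weights")
  T <- model$transcript_length
  v <- .suffix_counts(T, model$lengths, unname(model$weights))
  out <- v[T + 1L]
  if (!is.finite(out)) {
    lv <- .suffix_counts_log(T, model$lengths, log(unname(model$weights)))
    out <- exp(lv[T + 1L])
  }
  out
}

# ---- per-length start matrix --------------------------------------------

# Relative start matrix: list(M = k x T numeric matrix, log_scale = s) with
# true counts equal to M * exp(s).  s is 0 whenever doubles suffice.
.start_matrix_num <- function(model) {
  T <- model$transcript_length
  lengths <- model$lengths
  k <- length(lengths)
  W <- if (is.null(model$weights)) rep(1, k) else unname(model$weights)
  weighted_mass <- !is.null(model$weights) && model$weight_mode == "pattern"
  B <- if (weighted_mass) .suffix_counts(T, lengths, W) else .suffix_counts(T, lengths)
  if (all(is.finite(B)) && max(B) < 1e290) {
    M <- matrix(0, k, T)
    for (j in seq_len(k)) {
      Fj <- lengths[j]
      if (Fj > T) next
      p <- 0:(T - Fj)
      M[j, p + 1L] <- W[j] * B[p + 1L] * B[T - p - Fj + 1L]
    }
    list(M = M, log_scale = 0)
  } else {
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
}

# exact start matrix as a list of per-length rows of bigints (unweighted)
.start_matrix_exact_bi <- function(T, lengths) {
  FPs <- .suffix_counts_exact(T, lengths)
  zero <- bi(0)
  lapply(lengths, function(Fj) {
    row <- rep(list(zero), T)
    if (Fj <= T) {
      for (p in 0:(T - Fj)) {
        row[[p + 1L]] <- bi_mul(FPs[[p + 1L]], FPs[[T - p - Fj + 1L]])
      }
    }
    row
  })
}

#' Per-length, per-position fragment start counts
#'
#' The factorized intermediate behind every coverage profile: entry `(j, p)`
#' is the total (weight-scaled) count, over all patterns, of fragments of
#' length `F_j` starting at position `p` (0-based).  In contribution mode the
#' unweighted count is scaled by `W(F_j)`; in pattern mode the count carries
#' the weighted pattern mass.  Summing rows yields the raw starting-point
#' profile.
#'
#' @param model a [pattern_space_model()].
#' @param exact use the exact big-integer path (unweighted or contribution
#'   mode only); entries are converted to doubles on return.
#' @return a `k x T` numeric matrix with fragment lengths as row names.
#'   The attribute `log_scale` is a log-scale offset `s` such that true counts
#'   equal `matrix * exp(s)`; it is 0 unless counts exceed double range.
#' @export
start_matrix <- function(model, exact = FALSE) {
  model <- .assert_model(model)
  T <- model$transcript_length
  lengths <- model$lengths
  if (exact) {
    if (!is.null(model$weights) && model$weight_mode == "pattern") {
      stop("exact mode supports unweighted models or contribution weighting only")
    }
    W <- if (is.null(model$weights)) rep(1, length(lengths)) else unname(model$weights)
    rows <- .start_matrix_exact_bi(T, lengths)
    M <- matrix(0, length(lengths), T)
    for (j in seq_along(lengths)) {
      M[j, ] <- W[j] * vapply(rows[[j]], bi_to_num, numeric(1))
    }
    res <- list(M = M, log_scale = 0)
  } else {
    res <- .start_matrix_num(model)
  }
  dimnames(res$M) <- list(as.character(lengths), NULL)
  structure(res$M, log_scale = res$log_scale)
}

#' Expected number of fragments of each length
#'
#' Sums the unweighted start matrix over positions: `count_j` is the total
#' number of length-`F_j` fragments across all patterns of the space, the
#' quantity whose normalization gives the expected fragment-length frequency.
#'
#' @param model a [pattern_space_model()]; weights are ignored.
#' @return named numeric vector of per-length totals (names are lengths).
#' @examples
#' per_length_fragment_counts(pattern_space_model(5, c(3, 4))) # 3 and 2
#' @export
per_length_fragment_counts <- function(model) {
  model <- .assert_model(model)
  unweighted <- model
  unweighted$weights <- NULL
  res <- .start_matrix_num(unweighted)
  out <- rowSums(res$M) * exp(res$log_scale)
  names(out) <- as.character(model$lengths)
  out
}
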