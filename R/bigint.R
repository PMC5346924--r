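# Minimal nonnegative arbitrary-precision integers.
#
# Pattern counts grow exponentially in the transcript length, so the exact
# counting path cannot rely on doubles.  Numbers are stored as numeric vectors
# of base-2^15 limbs, least significant first.  Only the operations the exact
# dynamic program needs are provided: add, subtract (a >= b), multiply,
# comparison and decimal rendering.  Limb products are at most 2^30 and
# convolution sums stay far below 2^53, so all limb arithmetic is exact.

.BI_BASE <- 32768

#' Create an exact big integer
#'
#' @param x a single nonnegative integer-valued number no larger than 2^53.
#' @return an object of class `bigint`.
#' @keywords internal
#' @noRd
bi <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x), x >= 0, x == floor(x))
  if (x == 0) return(structure(0, class = "bigint"))
  v <- numeric(0)
  while (x > 0) {
    v <- c(v, x %% .BI_BASE)
    x <- x %/% .BI_BASE
  }
  structure(v, class = "bigint")
}

.bi_trim <- function(v) {
  n <- length(v)
  while (n > 1L && v[n] == 0) n <- n - 1L
  structure(v[seq_len(n)], class = "bigint")
}

# carry-propagate a numeric limb vector (entries may exceed the base)
.bi_carry <- function(v) {
  repeat {
    carry <- v %/% .BI_BASE
    if (all(carry == 0)) break
    v <- v %% .BI_BASE
    carry <- c(0, carry)
    if (length(carry) > length(v)) v <- c(v, 0)
    v <- v + carry
  }
  .bi_trim(v)
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  av <- c(unclass(a), numeric(n - length(a)))
  bv <- c(unclass(b), numeric(n - length(b)))
  .bi_carry(av + bv)
}

# a - b, requires a >= b
bi_sub <- function(a, b) {
  if (bi_cmp(a, b) < 0) stop("bigint subtraction would be negative")
  n <- max(length(a), length(b))
  d <- c(unclass(a), numeric(n - length(a))) - c(unclass(b), numeric(n - length(b)))
  i <- 1L
  while (i <= length(d)) {
    if (d[i] < 0) {
      d[i] <- d[i] + .BI_BASE
      d[i + 1L] <- d[i + 1L] - 1
    }
    i <- i + 1L
  }
  .bi_trim(d)
}

bi_mul <- function(a, b) {
  av <- unclass(a); bv <- unclass(b)
  if ((length(av) == 1L && av == 0) || (length(bv) == 1L && bv == 0)) return(bi(0))
  # polynomial product; FFT rounding is well below 0.5 for limbs < 2^15
  prod <- round(stats::convolve(av, rev(bv), type = "open"))
  prod[prod < 0] <- 0
  .bi_carry(prod)
}

# -1, 0, 1 for a < b, a == b, a > b
bi_cmp <- function(a, b) {
  av <- unclass(.bi_trim(unclass(a))); bv <- unclass(.bi_trim(unclass(b)))
  if (length(av) != length(bv)) return(if (length(av) < length(bv)) -1L else 1L)
  for (i in rev(seq_along(av))) {
    if (av[i] != bv[i]) return(if (av[i] < bv[i]) -1L else 1L)
  }
  0L
}

bi_is_zero <- function(a) length(unclass(a)) == 1L && unclass(a)[1L] == 0

# conversion to double; Inf when out of range
bi_to_num <- function(a) {
  v <- unclass(a)
  sum(v * .BI_BASE^(seq_along(v) - 1))
}

# exact decimal string, via base 2^15 -> base 1e7 Horner evaluation
bi_to_str <- function(a) {
  v <- unclass(a)
  dec <- 0 # base-1e7 digit vector, little-endian
  for (limb in rev(v)) {
    dec <- dec * .BI_BASE
    dec[1L] <- dec[1L] + limb
    repeat {
      carry <- dec %/% 1e7
      if (all(carry == 0)) break
      dec <- dec %% 1e7
      carry <- c(0, carry)
      if (length(carry) > length(dec)) dec <- c(dec, 0)
      dec <- dec + carry
    }
  }
  n <- length(dec)
  while (n > 1L && dec[n] == 0) n <- n - 1L
  dec <- dec[seq_len(n)]
  paste0(
    format(dec[n], scientific = FALSE),
    paste(rev(sprintf("%07d", dec[-n])), collapse = "")
  )
}

#' @export
format.bigint <- function(x, ...) bi_to_str(x)

#' @export
print.bigint <- function(x, ...) {
  cat(bi_to_str(x), "\n")
  invisible(x)
}

#' @export
as.character.bigint <- function(x, ...) bi_to_str(x)

#' @export
as.double.bigint <- function(x, ...) bi_to_num(x)
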