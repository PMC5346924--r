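# Estimation of the original number of transcript molecules from a
# starting-point profile, by distance between empirical cumulative
# distribution functions (ECDFs) of sum-normalized per-position SP counts.
#
# A reference set holds, for each candidate molecule number M on a grid, one
# ECDF pooled over n_rep simulated repetitions.  A test profile is assigned
# the grid value whose pooled ECDF lies closest under the distance
#
#   d(E_m, E_d) = sum_{i=1}^{n-1} (E_m(x_i) - E_d(x_i))^2 (x_{i+1} - x_i)
#
# over the sorted unique union x of both ECDFs' values (the largest value
# contributes no interval, exactly as the summation limit states).

.new_ecdf <- function(x, p) {
  structure(list(x = x, p = p), class = "sp_ecdf")
}

#' @export
print.sp_ecdf <- function(x, ...) {
  cat(sprintf("<sp_ecdf> %d support points in [%.3g, %.3g]\n",
              length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

.ecdf_from_values <- function(values) {
  x <- sort(unique(values))
  p <- cumsum(tabulate(match(values, x), nbins = length(x))) / length(values)
  .new_ecdf(x, p)
}

#' ECDF of a starting-point profile
#'
#' Sum-normalizes the per-position SP counts and forms the empirical
#' cumulative distribution function over all `T` position values (positions
#' with zero counts included).
#'
#' @param profile a start-point `coverage_profile`.
#' @return an `sp_ecdf` (sorted unique values `x`, cumulative probabilities
#'   `p`).
#' @export
profile_ecdf <- function(profile) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (profile$kind != "start_point") {
    stop("ECDFs are defined over starting-point profiles")
  }
  s <- sum(profile$values)
  if (s == 0) stop("all-zero profile has no ECDF")
  .ecdf_from_values(profile$values / s)
}

#' Pooled ECDF over repeated profiles
#'
#' Sum-normalizes each profile and pools all `n_rep * T` position values
#' into a single ECDF: the reference representation of a repetition set.
#'
#' @param profiles a list of start-point `coverage_profile`s with a common
#'   transcript length.
#' @return an `sp_ecdf`.
#' @export
pooled_ecdf <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  Ts <- vapply(profiles, function(p) p$transcript_length, numeric(1))
  if (length(unique(Ts)) != 1L) stop("profiles have mixed transcript lengths")
  values <- unlist(lapply(profiles, function(p) {
    stopifnot(inherits(p, "coverage_profile"))
    if (p$kind != "start_point") stop("ECDFs are defined over starting-point profiles")
    s <- sum(p$values)
    if (s == 0) stop("all-zero profile has no ECDF")
    p$values / s
  }), use.names = FALSE)
  .ecdf_from_values(values)
}

# right-continuous step evaluation of an ECDF at points x
.ecdf_eval <- function(e, x) {
  c(0, e$p)[findInterval(x, e$x) + 1L]
}

#' Distance between two starting-point ECDFs
#'
#' Squared vertical difference integrated over the merged support: the sum of
#' `(E_m(x_i) - E_d(x_i))^2 * (x_{i+1} - x_i)` over the sorted unique union
#' of both value lists, with right-continuous step evaluation.  Symmetric and
#' nonnegative.
#'
#' @param e_m,e_d `sp_ecdf` objects.
#' @return a single nonnegative number.
#' @export
ecdf_distance <- function(e_m, e_d) {
  stopifnot(inherits(e_m, "sp_ecdf"), inherits(e_d, "sp_ecdf"))
  x <- sort(unique(c(e_m$x, e_d$x)))
  if (length(x) < 2L) return(0)
  i <- seq_len(length(x) - 1L)
  dm <- .ecdf_eval(e_m, x[i]) - .ecdf_eval(e_d, x[i])
  sum(dm^2 * diff(x))
}

#' Log-spaced molecule-number grid
#'
#' Candidate molecule numbers, logarithmically spaced between the endpoints
#' (inclusive) and rounded to integers; the default emulates a 43-point grid
#' between 50 and 50,000 molecules.
#'
#' @param from,to grid endpoints (molecules).
#' @param n number of grid points.
#' @return increasing integer vector.
#' @export
molecule_grid <- function(from = 50, to = 50000, n = 43) {
  unique(round(exp(seq(log(from), log(to), length.out = n))))
}

#' Build a simulated reference set over a molecule grid
#'
#' For each candidate molecule number, runs `n_rep` seeded end-to-end
#' simulations (fragmentation, amplification, sequencing, SPP) and pools the
#' repetitions' ECDFs.  Deterministic given the master seed.
#'
#' @param config a [simulation_config()] used as a template; its `molecules`
#'   entry is replaced by each grid value in turn.
#' @param grid increasing vector of candidate molecule numbers.
#' @param n_rep repetitions per grid value.
#' @param seed master seed for the whole construction.
#' @return a `reference_set`.
#' @export
build_reference <- function(config, grid = molecule_grid(), n_rep = 100,
                            seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.unsorted(grid, strictly = TRUE)) stop("`grid` must be strictly increasing")
  .maybe_seed(seed)
  ecdfs <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    cfg <- config
    cfg$molecules <- grid[g]
    cfg$seed <- NULL # draws come from the already-seeded stream
    profs <- lapply(seq_len(n_rep), function(i) simulate_experiment(cfg))
    ecdfs[[g]] <- pooled_ecdf(profs)
  }
  structure(
    list(grid = grid, ecdfs = ecdfs, n_rep = n_rep, config = config,
         seed = seed),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "<reference_set> %d molecule values in [%g, %g], %d repetitions each\n",
    length(x$grid), min(x$grid), max(x$grid), x$n_rep))
  invisible(x)
}

#' Estimate the original number of molecules behind an observed SPP
#'
#' Computes the ECDF distance from the test profile to every reference pool
#' and predicts the grid value with the smallest distance.  Ties are broken
#' toward the smaller molecule number and flagged.
#'
#' @param profile a start-point `coverage_profile` with the reference's
#'   transcript length (or an `sp_ecdf` directly).
#' @param reference a `reference_set` from [build_reference()].
#' @return a `molecule_estimate`: list with `predicted`, named `distances`
#'   and `tie`.
#' @export
estimate_molecules <- function(profile, reference) {
  stopifnot(inherits(reference, "reference_set"))
  if (length(reference$grid) == 0L) stop("empty reference set")
  e <- if (inherits(profile, "sp_ecdf")) profile else profile_ecdf(profile)
  d <- vapply(reference$ecdfs, function(er) ecdf_distance(e, er), numeric(1))
  names(d) <- as.character(reference$grid)
  best <- which.min(d) # first minimum = smallest molecule number
  structure(
    list(predicted = reference$grid[best], distances = d,
         tie = sum(d == d[best]) > 1L),
    class = "molecule_estimate"
  )
}

#' @export
print.molecule_estimate <- function(x, ...) {
  cat(sprintf("<molecule_estimate> predicted M = %g%s\n", x$predicted,
              if (x$tie) " (tie, smaller value reported)" else ""))
  cat("  distances:\n")
  print(signif(x$distances, 4))
  invisible(x)
}
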