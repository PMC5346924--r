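# Seeded simulation of an unbiased RNA-seq experiment on one transcript:
# exhaustive fragmentation of a defined number of molecules (each molecule is
# one pattern drawn from the pattern space), perfectly uniform PCR
# amplification by 2^cycles, sequencing as sampling of fragments without
# replacement, and observed coverage profiles.
#
# Pattern sampling is sequential left-to-right: at remaining suffix length
# l >= F1 the pair (gap g, length F_j) is drawn with probability
# W(F_j) * mass(l - g - F_j) / mass(l), where mass() is the (weighted) suffix
# pattern mass.  The telescoping product makes every unweighted pattern
# exactly uniform (probability 1/FP) and every weighted pattern proportional
# to the product of its fragments' weights.  All randomness comes from R's
# global RNG; use `seed` arguments (or set.seed) for reproducibility.

#' Configuration of a simulated fragmentation experiment
#'
#' @param model a [pattern_space_model()].
#' @param molecules number of transcript molecules fragmented (`M`).
#' @param pcr_cycles PCR cycles; every fragment is amplified exactly
#'   `2^pcr_cycles`-fold (perfectly efficient, uniform PCR). Default 15
#'   (32,768-fold).
#' @param n_fragments number of fragments sequenced (`S`), drawn without
#'   replacement from the amplified pool.  Default 100,000.
#' @param seed optional integer seed recorded with the run.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(model, molecules, pcr_cycles = 15,
                              n_fragments = 1e5, seed = NULL) {
  model <- .assert_model(model)
  stopifnot(molecules >= 1, pcr_cycles >= 0, n_fragments >= 1)
  structure(
    list(model = model, molecules = as.numeric(molecules),
         pcr_cycles = as.numeric(pcr_cycles),
         n_fragments = as.numeric(n_fragments), seed = seed),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> M=%g molecules, %g PCR cycles (x%g), S=%g sequenced%s\n",
    x$molecules, x$pcr_cycles, 2^x$pcr_cycles, x$n_fragments,
    if (is.null(x$seed)) "" else sprintf(", seed=%d", x$seed)))
  print(x$model)
  invisible(x)
}

.maybe_seed <- function(seed) if (!is.null(seed)) set.seed(seed)

# cumulative probability table over (gap, length) options for every suffix
# length; row l+1 covers remaining length l, column c = g*k + j.
.sampling_table <- function(model) {
  T <- model$transcript_length
  lengths <- model$lengths
  k <- length(lengths)
  F1 <- lengths[1L]
  W <- if (is.null(model$weights)) rep(1, k) else unname(model$weights)
  if (F1 * k * (T + 1) > 5e7) {
    stop("sampling table too large (", F1 * k, " options x ", T + 1, " suffix ",
         "lengths); reduce the fragment-length set or transcript length")
  }
  B <- .suffix_counts(T, lengths, if (is.null(model$weights)) NULL else W)
  use_log <- !all(is.finite(B))
  lB <- if (use_log) {
    .suffix_counts_log(T, lengths, if (is.null(model$weights)) NULL else log(W))
  }
  gaps <- rep(0:(F1 - 1), each = k)     # column-major: gap varies slowest
  lens <- rep(lengths, times = F1)
  wcol <- rep(W, times = F1)
  ncol <- F1 * k
  CP <- matrix(0, T + 1, ncol)
  for (l in F1:T) {
    rem <- l - gaps - lens
    pr <- numeric(ncol)
    ok <- rem >= 0
    if (use_log) {
      logpr <- log(wcol[ok]) + lB[rem[ok] + 1L] - lB[l + 1L]
      pr[ok] <- exp(logpr)
    } else {
      pr[ok] <- wcol[ok] * B[rem[ok] + 1L] / B[l + 1L]
    }
    CP[l + 1L, ] <- cumsum(pr)
  }
  list(CP = CP, gaps = gaps, lens = lens, F1 = F1)
}

# draw n patterns; returns data.frame(molecule, start, length) of all placed
# fragments (molecules with no fragment contribute no rows)
.sample_fragments <- function(model, n) {
  T <- model$transcript_length
  tab <- .sampling_table(model)
  l_cur <- rep.int(T, n)
  mol_out <- list(); start_out <- list(); len_out <- list()
  step <- 0L
  active <- which(l_cur >= tab$F1)
  while (length(active)) {
    step <- step + 1L
    rows <- l_cur[active] + 1L
    cp <- tab$CP[rows, , drop = FALSE]
    u <- stats::runif(length(active)) * cp[, ncol(cp)]
    col <- rowSums(cp < u) + 1L
    col <- pmin(col, ncol(cp))
    g <- tab$gaps[col]
    Fj <- tab$lens[col]
    mol_out[[step]] <- active
    start_out[[step]] <- T - l_cur[active] + g
    len_out[[step]] <- Fj
    l_cur[active] <- l_cur[active] - g - Fj
    active <- active[l_cur[active] >= tab$F1]
  }
  data.frame(molecule = unlist(mol_out, use.names = FALSE),
             start = unlist(start_out, use.names = FALSE),
             length = unlist(len_out, use.names = FALSE))
}

#' Draw fragmentation patterns from the (weighted) pattern space
#'
#' Exact sequential sampling: unweighted models return every pattern with
#' probability exactly `1/FP`; weighted models return each pattern with
#' probability proportional to the product of its fragments' weights
#' (pattern-mass semantics, the distribution the simulator uses).
#'
#' @param model a [pattern_space_model()].
#' @param n number of patterns to draw.
#' @param seed optional seed.
#' @return a list of `n` patterns, each a two-column matrix
#'   (`start` 0-based, `length`), in the same format as
#'   [enumerate_patterns()].
#' @export
sample_patterns <- function(model, n = 1, seed = NULL) {
  model <- .assert_model(model)
  .maybe_seed(seed)
  frags <- .sample_fragments(model, n)
  empty <- cbind(start = numeric(0), length = numeric(0))
  out <- rep(list(empty), n)
  if (nrow(frags)) {
    frags <- frags[order(frags$molecule, frags$start), ]
    by_mol <- split(seq_len(nrow(frags)), frags$molecule)
    for (id in names(by_mol)) {
      i <- by_mol[[id]]
      out[[as.integer(id)]] <- cbind(start = frags$start[i],
                                     length = frags$length[i])
    }
  }
  out
}

.new_library <- function(df, stage, model, pcr_cycles = 0) {
  rownames(df) <- NULL
  structure(df, class = c("simulated_library", "data.frame"),
            stage = stage, model = model, pcr_cycles = pcr_cycles)
}

#' @export
print.simulated_library <- function(x, ...) {
  cat(sprintf("<simulated_library> stage=%s, %d fragment species, %s fragments\n",
              attr(x, "stage"), nrow(x),
              format(sum(x$multiplicity), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Fragment a defined number of molecules
#'
#' Draws one fragmentation pattern per molecule and pools all fragments into
#' a multiset of `(start, length)` species.
#'
#' @param config a [simulation_config()]; its `seed` (if any) seeds the RNG.
#' @return a `simulated_library` (data frame with columns `start`, `length`,
#'   `multiplicity`; attribute `stage = "fragmented"`).
#' @export
fragment_molecules <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .maybe_seed(config$seed)
  frags <- .sample_fragments(config$model, config$molecules)
  if (!nrow(frags)) {
    return(.new_library(data.frame(start = numeric(0), length = numeric(0),
                                   multiplicity = numeric(0)),
                        "fragmented", config$model))
  }
  key <- frags$start * (max(config$model$lengths) + 1) + frags$length
  agg <- rowsum(rep(1, nrow(frags)), key)
  keys <- as.numeric(rownames(agg))
  base <- max(config$model$lengths) + 1
  .new_library(
    data.frame(start = keys %/% base, length = keys %% base,
               multiplicity = as.numeric(agg[, 1L])),
    "fragmented", config$model
  )
}

#' Uniform PCR amplification
#'
#' Multiplies every fragment's multiplicity by exactly `2^pcr_cycles`,
#' modelling perfectly efficient, unbiased PCR (15 cycles give a
#' 32,768-fold amplification).
#'
#' @param library a fragmented `simulated_library`.
#' @param pcr_cycles nonnegative number of cycles.
#' @return the amplified `simulated_library` (`stage = "amplified"`).
#' @export
amplify <- function(library, pcr_cycles) {
  stopifnot(inherits(library, "simulated_library"), pcr_cycles >= 0)
  if (attr(library, "stage") != "fragmented") {
    stop("amplify() expects a library at stage 'fragmented'")
  }
  library$multiplicity <- library$multiplicity * 2^pcr_cycles
  attr(library, "stage") <- "amplified"
  attr(library, "pcr_cycles") <- pcr_cycles
  library
}

#' Simulated sequencing: sample fragments from the amplified pool
#'
#' Draws `n_fragments` fragments without replacement from the amplified pool
#' (a multivariate hypergeometric draw over fragment species, realized by
#' uniform sampling of distinct pool indices, which stays exact for pools
#' beyond integer range).
#'
#' @param library an amplified `simulated_library`.
#' @param n_fragments number of fragments to sequence; must not exceed the
#'   pool size.
#' @return a `simulated_library` with total multiplicity `n_fragments`
#'   (`stage = "sequenced"`).
#' @export
sample_sequenced <- function(library, n_fragments) {
  stopifnot(inherits(library, "simulated_library"))
  if (attr(library, "stage") != "amplified") {
    stop("sample_sequenced() expects a library at stage 'amplified'")
  }
  total <- sum(library$multiplicity)
  if (n_fragments > total) {
    stop("cannot sequence ", n_fragments, " fragments from a pool of ", total)
  }
  if (n_fragments == total) {
    counts <- library$multiplicity
  } else {
    draws <- sample.int(total, n_fragments) # distinct pool indices
    species <- findInterval(draws, cumsum(library$multiplicity),
                            left.open = TRUE) + 1L
    counts <- tabulate(species, nbins = nrow(library))
  }
  out <- library[counts > 0, c("start", "length")]
  out$multiplicity <- counts[counts > 0]
  .new_library(out, "sequenced", attr(library, "model"),
               attr(library, "pcr_cycles"))
}

#' Observed coverage profile of a simulated library
#'
#' Position-wise sum of the coverage vectors of the fragments present in the
#' library (counting multiplicity): the simulated counterpart of
#' [expected_profile()].
#'
#' @param library a `simulated_library` (any stage; typically sequenced).
#' @param kind coverage kind (`"start_point"`, `"fragment"` or `"read"`).
#' @param read_length read length for `kind = "read"`; defaults to the
#'   model's.
#' @return a raw-count `coverage_profile`.
#' @export
observed_profile <- function(library,
                             kind = c("start_point", "fragment", "read"),
                             read_length = NULL) {
  stopifnot(inherits(library, "simulated_library"))
  kind <- match.arg(kind)
  model <- attr(library, "model")
  T <- model$transcript_length
  if (is.null(read_length)) read_length <- model$read_length
  if (kind == "read" && is.null(read_length)) {
    stop("`kind = \"read\"` requires a read length")
  }
  vals <- numeric(T)
  if (nrow(library)) {
    if (kind == "start_point") {
      agg <- rowsum(library$multiplicity, library$start)
      vals[as.numeric(rownames(agg)) + 1L] <- agg[, 1L]
    } else {
      d <- numeric(T + 1L)
      if (kind == "fragment") {
        d <- .interval_accumulate(d, library$start,
                                  library$start + library$length,
                                  library$multiplicity)
      } else {
        r <- pmin(read_length, library$length)
        d <- .interval_accumulate(d, library$start, library$start + r,
                                  library$multiplicity)
        d <- .interval_accumulate(d, library$start + library$length - r,
                                  library$start + library$length,
                                  library$multiplicity)
      }
      vals <- cumsum(d)[seq_len(T)]
    }
  }
  .new_profile(vals, kind, model)
}

#' Run one simulated experiment end to end
#'
#' Fragmentation, amplification and sequencing in order, returning the
#' observed starting-point profile (raw counts).
#'
#' @param config a [simulation_config()].
#' @param kind coverage kind of the returned profile.
#' @return a `coverage_profile`.
#' @export
simulate_experiment <- function(config, kind = "start_point") {
  stopifnot(inherits(config, "simulation_config"))
  lib <- fragment_molecules(config)
  lib <- amplify(lib, config$pcr_cycles)
  lib <- sample_sequenced(lib, min(config$n_fragments, sum(lib$multiplicity)))
  observed_profile(lib, kind)
}
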