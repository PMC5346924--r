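# Empirical fragment-length distributions and pattern-space weights.
#
# The weight of a fragment length is the ratio of its observed relative
# frequency (from paired-end insert sizes, linearly interpolated over
# unobserved lengths inside the observed range) to its expected relative
# frequency in the unweighted pattern space.  Imposing these weights on the
# pattern space transforms its L-shaped length distribution into the
# bell-shaped empirical one.

.new_histogram <- function(counts, provenance = NA_character_, skipped = 0) {
  lens <- as.numeric(names(counts))
  o <- order(lens)
  counts <- as.numeric(counts)[o]
  names(counts) <- as.character(lens[o])
  if (any(lens < 1)) stop("fragment lengths must be positive")
  if (sum(counts) <= 0) stop("histogram has no observed fragments")
  structure(counts, class = "fragment_length_histogram",
            provenance = provenance, skipped = skipped)
}

#' @export
print.fragment_length_histogram <- function(x, ...) {
  lens <- as.numeric(names(x))
  cat(sprintf(
    "<fragment_length_histogram> %d lengths in [%d, %d], %s fragments\n",
    length(x), min(lens), max(lens),
    format(sum(x), big.mark = ",", scientific = FALSE)))
  if (!is.na(attr(x, "provenance"))) cat("  source:", attr(x, "provenance"), "\n")
  sk <- attr(x, "skipped")
  if (!is.null(sk) && sk > 0) cat("  skipped records:", sk, "\n")
  invisible(x)
}

#' Read a fragment-length histogram from a two-column TSV
#'
#' The file holds one row per observed length: `length<TAB>count`.  A header
#' line is allowed and detected automatically.
#'
#' @param path path to the TSV file.
#' @return a `fragment_length_histogram` (named numeric: counts by length).
#' @export
read_length_histogram <- function(path) {
  if (!file.exists(path)) stop("cannot read histogram file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1L]][1L])))
  tab <- utils::read.delim(path, header = has_header, sep = "\t",
                           col.names = c("length", "count"))
  if (anyNA(tab$length) || anyNA(tab$count)) stop("malformed histogram file: ", path)
  counts <- tapply(tab$count, tab$length, sum)
  .new_histogram(counts, provenance = path)
}

#' Fragment lengths from paired-end alignments or a histogram file
#'
#' Builds the insert-length histogram the empirical weighting uses.  For
#' SAM/BAM input the insert length of a pair is the absolute template length
#' (`TLEN`, the distance between the two extreme ends of the mapped mates),
#' taken once per pair from the leftmost mate (positive `TLEN`), restricted
#' to primary alignments on the named reference.  Records with zero or
#' undefined template length are skipped and counted in the `skipped`
#' attribute.  A `.tsv`/`.txt` path is read as a precomputed
#' `length<TAB>count` table instead.
#'
#' @param source path to a SAM, BAM or two-column TSV file.
#' @param reference reference sequence name to restrict to (required for
#'   SAM/BAM); an unknown name raises an error listing available references.
#' @return a `fragment_length_histogram`.
#' @export
lengths_from_alignments <- function(source, reference = NULL) {
  if (!file.exists(source)) stop("cannot read alignment source: ", source)
  ext <- tolower(tools::file_ext(source))
  if (ext %in% c("tsv", "txt")) {
    return(read_length_histogram(source))
  }
  if (!ext %in% c("sam", "bam")) {
    stop("unsupported alignment source (expect .sam, .bam or .tsv): ", source)
  }
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM/BAM requires the Rsamtools package")
  }
  bam <- source
  if (ext == "sam") {
    bam <- Rsamtools::asBam(source, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  header <- Rsamtools::scanBamHeader(bam)[[1L]]
  refs <- names(header$targets)
  if (is.null(reference)) {
    if (length(refs) == 1L) reference <- refs else
      stop("`reference` must be given; available references: ",
           paste(refs, collapse = ", "))
  }
  if (!reference %in% refs) {
    stop("reference '", reference, "' not found; available references: ",
         paste(refs, collapse = ", "))
  }
  flags <- Rsamtools::scanBamFlag(isPaired = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(what = c("rname", "isize"), flag = flags)
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  on_ref <- !is.na(rec$rname) & as.character(rec$rname) == reference
  isize <- rec$isize[on_ref]
  usable <- !is.na(isize) & isize > 0  # leftmost mate of each pair
  skipped <- sum(is.na(isize) | isize == 0)
  if (!any(usable)) {
    stop("empty insert-length histogram: no usable paired records on ",
         "reference '", reference, "'")
  }
  counts <- table(isize[usable])
  .new_histogram(counts, provenance = paste0(source, " [", reference, "]"),
                 skipped = skipped)
}

#' Interpolated empirical fragment-length distribution
#'
#' Linearly interpolates counts for unobserved integer lengths strictly
#' inside the observed range (endpoints are never extrapolated), then
#' normalizes to relative frequencies.  Interpolation acts on counts, before
#' normalization.
#'
#' @param hist a `fragment_length_histogram`.
#' @return an `empirical_length_distribution`: a data frame with columns
#'   `length`, `frequency` (sums to 1) and `interpolated` (flagging exactly
#'   the unobserved interior lengths).
#' @export
interpolate_distribution <- function(hist) {
  stopifnot(inherits(hist, "fragment_length_histogram"))
  lens <- as.numeric(names(hist))
  grid <- seq.int(min(lens), max(lens))
  counts <- rep(NA_real_, length(grid))
  counts[match(lens, grid)] <- as.numeric(hist)
  interpolated <- is.na(counts)
  if (any(interpolated)) counts <- zoo::na.approx(counts, x = grid)
  freq <- counts / sum(counts)
  structure(
    data.frame(length = grid, frequency = freq, interpolated = interpolated),
    class = c("empirical_length_distribution", "data.frame"),
    provenance = attr(hist, "provenance")
  )
}

#' Expected relative fragment-length frequencies of a pattern space
#'
#' The share of each model length among all fragments of the unweighted
#' pattern space: `count_j / sum_j count_j` with counts from
#' [per_length_fragment_counts()].
#'
#' @param model a [pattern_space_model()] (treated as unweighted).
#' @return named numeric vector of frequencies summing to 1.
#' @examples
#' expected_length_frequencies(pattern_space_model(5, c(3, 4))) # 0.6, 0.4
#' @export
expected_length_frequencies <- function(model) {
  counts <- per_length_fragment_counts(model)
  counts / sum(counts)
}

#' Weights imposing an empirical length distribution on a pattern space
#'
#' For each model fragment length, the weight is the ratio of the observed
#' relative frequency to the expected relative frequency in the pattern
#' space: `W(F_j) = observed(F_j) / expected(F_j)`.  A length with positive
#' observed but zero expected frequency is an error; zero observed with zero
#' expected yields `W = 0` with a warning.
#'
#' @param observed an `empirical_length_distribution` (or a named numeric
#'   vector of frequencies by length).
#' @param expected named numeric vector from
#'   [expected_length_frequencies()].
#' @param lengths fragment lengths to compute weights for; defaults to the
#'   lengths of `expected`.  All must lie in both supports.
#' @return named numeric weight vector (a `WeightTable`), usable as the
#'   `weights` argument of [pattern_space_model()].
#' @export
compute_weights <- function(observed, expected, lengths = NULL) {
  if (inherits(observed, "empirical_length_distribution")) {
    obs <- stats::setNames(observed$frequency, as.character(observed$length))
  } else {
    obs <- observed
    if (is.null(names(obs))) stop("`observed` must be named by fragment length")
  }
  if (is.null(names(expected))) stop("`expected` must be named by fragment length")
  if (is.null(lengths)) lengths <- as.numeric(names(expected))
  key <- as.character(lengths)
  missing_obs <- key[!key %in% names(obs)]
  missing_exp <- key[!key %in% names(expected)]
  if (length(missing_obs) || length(missing_exp)) {
    stop("lengths outside the observed/expected support: ",
         paste(unique(c(missing_obs, missing_exp)), collapse = ", "))
  }
  o <- unname(obs[key])
  e <- unname(expected[key])
  bad <- e == 0 & o > 0
  if (any(bad)) {
    stop("observed frequency positive but expected frequency zero for lengths: ",
         paste(lengths[bad], collapse = ", "))
  }
  w <- numeric(length(key))
  nz <- e > 0
  w[nz] <- o[nz] / e[nz]
  if (any(!nz)) warning("weight set to 0 for lengths absent from the pattern space: ",
                        paste(lengths[!nz], collapse = ", "))
  stats::setNames(w, key)
}

#' Synthetic bell-shaped insert-length histogram
#'
#' Deterministic discretized, truncated normal counts over an integer length
#' range: the stand-in for an empirical insert-size distribution when no
#' alignment data are at hand.  Defaults emulate a typical RNA-seq library
#' (mode near 151 bp with a wide right tail up to 960 bp).
#'
#' @param mean,sd mean and standard deviation of the underlying normal (bp).
#' @param range integer length range (inclusive) to truncate to.
#' @param total approximate total number of fragments to distribute.
#' @return a `fragment_length_histogram`; lengths whose rounded count is zero
#'   are dropped (they become interpolated lengths downstream).
#' @export
synthetic_length_histogram <- function(mean = 151, sd = 80,
                                       range = c(100, 960), total = 1e6) {
  grid <- seq.int(range[1L], range[2L])
  dens <- stats::dnorm(grid, mean = mean, sd = sd)
  counts <- round(total * dens / sum(dens))
  keep <- counts > 0
  .new_histogram(stats::setNames(counts[keep], grid[keep]),
                 provenance = sprintf("synthetic truncated normal (mean=%g, sd=%g)",
                                      mean, sd))
}

#' Empirical weights for a model, end to end
#'
#' Convenience pipeline: interpolate the histogram, restrict the model's
#' length set to the observed range (weights are undefined outside it),
#' compute expected frequencies and weights, and return the weighted model.
#'
#' @param model a [pattern_space_model()] whose lengths at least partly
#'   overlap the observed range.
#' @param hist a `fragment_length_histogram`.
#' @return a weighted `pattern_space_model` (same `weight_mode`); lengths
#'   outside the observed range are dropped with a message.
#' @export
apply_length_distribution <- function(model, hist) {
  model <- .assert_model(model)
  dist <- interpolate_distribution(hist)
  inside <- model$lengths >= min(dist$length) & model$lengths <= max(dist$length)
  if (!any(inside)) stop("no model length lies inside the observed length range [",
                         min(dist$length), ", ", max(dist$length), "]")
  if (!all(inside)) {
    message("dropping ", sum(!inside),
            " model length(s) outside the observed range [",
            min(dist$length), ", ", max(dist$length), "]")
  }
  trimmed <- pattern_space_model(model$transcript_length, model$lengths[inside],
                                 read_length = model$read_length,
                                 weight_mode = model$weight_mode)
  expected <- expected_length_frequencies(trimmed)
  w <- compute_weights(dist, expected, trimmed$lengths)
  pattern_space_model(trimmed$transcript_length, trimmed$lengths, weights = w,
                      read_length = trimmed$read_length,
                      weight_mode = trimmed$weight_mode)
}
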