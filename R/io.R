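# File formats: TSV is canonical throughout (profiles, histograms, weight
# tables, libraries, reference sets); bedGraph export is offered for genome
# browsers.  Profile TSVs carry their metadata in '# key: value' comment
# lines so a written profile reads back losslessly.

#' Write a coverage profile to disk
#'
#' TSV format: comment header with metadata, then `position` (1-based) and
#' `value` columns at full double precision.  bedGraph format uses 0-based
#' half-open intervals and a caller-supplied sequence name.
#'
#' @param profile a `coverage_profile`.
#' @param path output file path.
#' @param format `"tsv"` (default, round-trips via [read_profile()]) or
#'   `"bedgraph"`.
#' @param seqname sequence name for bedGraph output.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, format = c("tsv", "bedgraph"),
                          seqname = "transcript") {
  stopifnot(inherits(profile, "coverage_profile"))
  format <- match.arg(format)
  v <- profile$values
  if (format == "tsv") {
    meta <- c(
      sprintf("# kind: %s", profile$kind),
      sprintf("# normalized: %s", profile$normalized),
      sprintf("# transcript_length: %d", as.integer(profile$transcript_length)),
      sprintf("# lengths: %s", paste(profile$lengths, collapse = ",")),
      if (!is.null(profile$read_length))
        sprintf("# read_length: %d", as.integer(profile$read_length)),
      if (profile$weighted) sprintf("# weight_mode: %s", profile$weight_mode),
      if (profile$log_scale != 0) sprintf("# log_scale: %.17g", profile$log_scale)
    )
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(meta, con)
    writeLines("position\tvalue", con)
    writeLines(sprintf("%d\t%.17g", seq_along(v), v), con)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%.17g", seqname, seq_along(v) - 1L,
                     seq_along(v), v)
    writeLines(c(sprintf("track type=bedGraph name=%s_%s", seqname,
                         profile$kind), lines), path)
  }
  invisible(path)
}

#' Read a coverage profile written by [write_profile()]
#'
#' @param path a profile TSV path.
#' @return a `coverage_profile`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^# ([^:]+): (.*)$", "\\1\t\\2", ml)
    kv <- strsplit(kv, "\t")[[1L]]
    meta[[kv[1L]]] <- kv[2L]
  }
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")], sep = "\t")
  values <- tab$value[order(tab$position)]
  lengths <- as.numeric(strsplit(meta$lengths, ",")[[1L]])
  model <- pattern_space_model(
    as.numeric(meta$transcript_length), lengths,
    read_length = if (!is.null(meta$read_length)) as.numeric(meta$read_length)
  )
  prof <- .new_profile(values, meta$kind, model,
                       normalized = identical(meta$normalized, "TRUE"),
                       log_scale = if (!is.null(meta$log_scale))
                         as.numeric(meta$log_scale) else 0)
  if (!is.null(meta$weight_mode)) {
    prof$weighted <- TRUE
    prof$weight_mode <- meta$weight_mode
  }
  prof
}

#' Write a weight table or length distribution as TSV
#'
#' @param x a named weight vector (from [compute_weights()]) or an
#'   `empirical_length_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_length_table <- function(x, path) {
  if (inherits(x, "empirical_length_distribution")) {
    utils::write.table(
      data.frame(length = x$length, value = sprintf("%.17g", x$frequency),
                 interpolated = as.integer(x$interpolated)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(
      data.frame(length = names(x), value = sprintf("%.17g", unname(x))),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a simulated library as TSV
#'
#' Columns: `start` (0-based), `length`, `multiplicity`, `stage`.
#'
#' @param library a `simulated_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "simulated_library"))
  df <- as.data.frame(library)
  df$stage <- attr(library, "stage")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat model configuration file
#'
#' YAML with flat keys: `transcript_length` (or `T`), `lengths` (list) or
#' `length_range` (two values, expanded to the full integer range),
#' `read_length`, `weight_mode`, and optionally `weights_file` (two-column
#' TSV `length<TAB>weight`).
#'
#' @param path YAML config path.
#' @return a [pattern_space_model()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  T <- cfg$transcript_length
  if (is.null(T)) T <- cfg$T
  if (is.null(T)) stop("config must set `transcript_length`")
  lengths <- cfg$lengths
  if (is.null(lengths) && !is.null(cfg$length_range)) {
    lengths <- seq.int(cfg$length_range[[1L]], cfg$length_range[[2L]])
  }
  if (is.null(lengths)) stop("config must set `lengths` or `length_range`")
  weights <- NULL
  if (!is.null(cfg$weights_file)) {
    wt <- utils::read.delim(cfg$weights_file, sep = "\t")
    weights <- stats::setNames(wt[[2L]], as.character(wt[[1L]]))
  }
  pattern_space_model(
    T, unlist(lengths), weights = weights,
    read_length = cfg$read_length,
    weight_mode = if (is.null(cfg$weight_mode)) "contribution" else cfg$weight_mode
  )
}

#' Serialize a reference set to a directory
#'
#' Writes one `ecdf_M<value>.tsv` (columns `value`,
#' `cumulative_probability`) per grid point plus a `manifest.yaml` with the
#' grid, repetition count, seed and simulation configuration — enough to
#' re-run the construction bit-identically.
#'
#' @param reference a `reference_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(reference, dir) {
  stopifnot(inherits(reference, "reference_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- reference$config
  manifest <- list(
    grid = as.numeric(reference$grid),
    n_rep = reference$n_rep,
    seed = reference$seed,
    transcript_length = cfg$model$transcript_length,
    lengths = as.numeric(cfg$model$lengths),
    weights = if (!is.null(cfg$model$weights)) as.list(cfg$model$weights),
    weight_mode = cfg$model$weight_mode,
    read_length = cfg$model$read_length,
    pcr_cycles = cfg$pcr_cycles,
    n_fragments = cfg$n_fragments
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  for (g in seq_along(reference$grid)) {
    e <- reference$ecdfs[[g]]
    utils::write.table(
      data.frame(value = sprintf("%.17g", e$x),
                 cumulative_probability = sprintf("%.17g", e$p)),
      file.path(dir, sprintf("ecdf_M%g.tsv", reference$grid[g])),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a reference set written by [write_reference()]
#'
#' @param dir the reference directory.
#' @return a `reference_set`.
#' @export
read_reference <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  weights <- if (!is.null(manifest$weights)) unlist(manifest$weights)
  model <- pattern_space_model(
    manifest$transcript_length, unlist(manifest$lengths), weights = weights,
    read_length = manifest$read_length,
    weight_mode = if (is.null(manifest$weight_mode)) "contribution"
                  else manifest$weight_mode
  )
  config <- simulation_config(model, molecules = 1,
                              pcr_cycles = manifest$pcr_cycles,
                              n_fragments = manifest$n_fragments)
  grid <- unlist(manifest$grid)
  ecdfs <- lapply(grid, function(M) {
    tab <- utils::read.delim(file.path(dir, sprintf("ecdf_M%g.tsv", M)),
                             sep = "\t")
    .new_ecdf(as.numeric(tab$value), as.numeric(tab$cumulative_probability))
  })
  structure(
    list(grid = grid, ecdfs = ecdfs, n_rep = manifest$n_rep, config = config,
         seed = manifest$seed),
    class = "reference_set"
  )
}
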