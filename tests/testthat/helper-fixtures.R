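# Shared fixtures, all built in code at test time.

# all singleton and pair length sets drawn from a small pool
small_length_sets <- function(pool = c(2, 3, 4, 5)) {
  sets <- as.list(pool)
  for (i in seq_along(pool)) {
    for (j in seq_along(pool)) {
      if (i < j) sets[[length(sets) + 1L]] <- c(pool[i], pool[j])
    }
  }
  sets
}

# minimal SAM file with two proper pairs (insert lengths 100 and 150) plus one
# unpaired record, on a 1000 bp synthetic reference
write_fixture_sam <- function(path = tempfile(fileext = ".sam")) {
  seq10 <- strrep("ACGTACGTAC", 1)
  qual10 <- strrep("I", 10)
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:SYN-1\tLN:1000",
    "@SQ\tSN:SYN-2\tLN:500",
    paste("pair1", 99, "SYN-1", 1, 60, "10M", "=", 91, 100, seq10, qual10, sep = "\t"),
    paste("pair1", 147, "SYN-1", 91, 60, "10M", "=", 1, -100, seq10, qual10, sep = "\t"),
    paste("pair2", 99, "SYN-1", 11, 60, "10M", "=", 151, 150, seq10, qual10, sep = "\t"),
    paste("pair2", 147, "SYN-1", 151, 60, "10M", "=", 11, -150, seq10, qual10, sep = "\t"),
    paste("single", 0, "SYN-1", 5, 60, "10M", "*", 0, 0, seq10, qual10, sep = "\t")
  )
  writeLines(lines, path)
  path
}

# sum-normalized values of a profile
norm_values <- function(profile) profile$values / sum(profile$values)
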