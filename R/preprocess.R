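#' In-silico size selection
#'
#' Removes reads shorter than `min_length` bases. Short overlap-length PCR
#' by-products (52--91 bp) consist almost entirely of primer-derived
#' sequence; a cutoff of 95 bp removes them all while keeping every designed
#' amplicon (144--237 bp). The cutoff is inclusive: a read of exactly
#' `min_length` bases is retained. Paired-end mates are filtered
#' independently; record order is preserved and records are not modified.
#'
#' @param reads a data.frame with columns `id`, `sequence` and optionally
#'   `quality` (as returned by [read_fastq()] or [simulate_reads()]), or a
#'   character vector of sequences.
#' @param min_length minimum retained read length in bases (default 95).
#' @return A list of class `size_select` with `reads` (the retained
#'   records), `retained`, `removed` and `retained_fraction`.
#' @examples
#' r <- data.frame(id = paste0("r", 1:4),
#'                 sequence = strrep("A", c(52, 94, 95, 150)))
#' size_select(r)$retained  # 2
#' @export
size_select <- function(reads, min_length = 95L) {
  stopifnot(min_length >= 1L)
  if (is.character(reads)) reads <- data.frame(id = seq_along(reads), sequence = reads)
  keep <- nchar(reads$sequence) >= min_length
  structure(list(reads = reads[keep, , drop = FALSE],
                 retained = sum(keep), removed = sum(!keep),
                 retained_fraction = if (nrow(reads)) mean(keep) else 0),
            class = "size_select")
}

#' @export
print.size_select <- function(x, ...) {
  cat(sprintf("<size_select> retained %d / removed %d (%.1f%% retained)\n",
              x$retained, x$removed, 100 * x$retained_fraction))
  invisible(x)
}

#' Exact read-length histogram
#'
#' In single-reaction multiplex data the profile is bimodal: short
#' overlap-length products (52--91 bp) against designed amplicons
#' (144--237 bp); examining it guides the size-selection cutoff.
#'
#' @param reads as for [size_select()].
#' @return A named integer vector: counts per observed read length, names
#'   are lengths in bases. Counts sum to the number of reads.
#' @export
length_profile <- function(reads) {
  seqs <- if (is.character(reads)) reads else reads$sequence
  tab <- table(nchar(seqs))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
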