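#' Length of the rCRS mitochondrial genome in bases
#'
#' The revised Cambridge Reference Sequence (NC_012920.1) is a 16,569-bp
#' circular molecule; all default coordinates in this package use its
#' 1-based numbering.
#' @export
RCRS_LENGTH <- 16569L

#' Reference genome container
#'
#' A minimal container for a single (optionally circular) contig. The mtDNA
#' reference is circular: positions wrap through the origin, so intervals
#' like 16,024--576 are valid and their arithmetic must be wrap-aware.
#'
#' @param sequence DNA sequence as a single character string (A/C/G/T/N).
#' @param name contig name, used for BAM/VCF contig matching.
#' @param circular logical; whether coordinates wrap through the origin.
#' @return An object of class `ref_genome` with fields `name`, `length`,
#'   `sequence` and `circular`.
#' @examples
#' g <- ref_genome("ACGTACGT", name = "toy")
#' g$length
#' @export
ref_genome <- function(sequence, name = "chrM", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("reference sequence contains characters outside A/C/G/T/N")
  structure(
    list(name = name, length = nchar(sequence), sequence = sequence,
         circular = isTRUE(circular)),
    class = "ref_genome"
  )
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %s: %d bp, %s\n", x$name, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a single-contig reference from FASTA
#'
#' The FASTA header may be anything; when `expect_length` is given the
#' genome is accepted only if its length matches (the rCRS is recognised by
#' its 16,569-bp length), unless `force = TRUE`.
#'
#' @param path path to a FASTA file containing exactly one sequence.
#' @param name contig name to assign (default: first word of the header).
#' @param circular logical, passed to [ref_genome()].
#' @param expect_length expected sequence length, or `NULL` to skip the check.
#' @param force skip the length check.
#' @return A [ref_genome()] object.
#' @export
read_reference_fasta <- function(path, name = NULL, circular = TRUE,
                                 expect_length = RCRS_LENGTH, force = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected exactly one sequence in ", path, ", found ", length(ss))
  w <- Biostrings::width(ss)[1L]
  if (!force && !is.null(expect_length) && w != expect_length)
    stop(sprintf("reference length %d does not match expected %d (use force = TRUE to override)",
                 w, expect_length))
  if (is.null(name)) name <- strsplit(names(ss)[1L], "\\s+")[[1L]][1L]
  ref_genome(unname(as.character(ss))[1L], name = name, circular = circular)
}

#' Deterministic synthetic stand-in for the rCRS
#'
#' Generates a fixed pseudo-random 16,569-bp circular genome named "chrM".
#' This is a synthetic sequence, not the real rCRS: it shares only the
#' length and circular topology, which is all the coordinate arithmetic,
#' probe-design and simulation machinery require. Supply the real
#' NC_012920.1 FASTA via [read_reference_fasta()] for analyses of real data.
#'
#' @param length genome length (default the rCRS length).
#' @return A [ref_genome()] object.
#' @export
synthetic_rcrs <- function(length = RCRS_LENGTH) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(16569L)
  ref_genome(paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                   collapse = ""),
             name = "chrM", circular = TRUE)
}

#' Wrap-aware interval on a circular genome
#'
#' Coordinates are 1-based and inclusive at both ends. When `start > end`
#' the region wraps through the origin (e.g. the control region 16,024--576).
#'
#' @param start,end 1-based inclusive positions.
#' @return An object of class `circular_region`.
#' @examples
#' control <- circular_region(16024, 576)
#' region_length(control, 16569)  # 1122
#' @export
circular_region <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L,
            !is.na(start), !is.na(end), start >= 1L, end >= 1L)
  structure(list(start = start, end = end), class = "circular_region")
}

#' @export
print.circular_region <- function(x, ...) {
  cat(sprintf("<circular_region> %d..%d%s\n", x$start, x$end,
              if (x$start > x$end) " (wraps origin)" else ""))
  invisible(x)
}

check_position <- function(pos, genome_length, what = "position") {
  if (any(pos < 1L | pos > genome_length))
    stop(sprintf("%s out of range [1, %d]", what, genome_length))
  invisible(pos)
}

#' Inclusive length of a wrap-aware region
#'
#' For `start <= end` the length is `end - start + 1`; for a wrapping region
#' it is `(genome_length - start + 1) + end`. The 1122-bp control region
#' (16,024--576) and the 1200-position amplified span (15,989--619) are both
#' wrapping intervals on the 16,569-bp rCRS.
#'
#' @param region a [circular_region()].
#' @param genome_length genome length in bases.
#' @return Integer length (>= 1).
#' @examples
#' region_length(circular_region(16024, 576), 16569)  # 1122
#' region_length(circular_region(15989, 619), 16569)  # 1200
#' @export
region_length <- function(region, genome_length) {
  stopifnot(inherits(region, "circular_region"))
  genome_length <- as.integer(genome_length)
  check_position(c(region$start, region$end), genome_length)
  if (region$start <= region$end) region$end - region$start + 1L
  else (genome_length - region$start + 1L) + region$end
}

#' Test wrap-aware membership of a position in a region
#'
#' @param region a [circular_region()].
#' @param position 1-based position(s).
#' @param genome_length genome length in bases.
#' @return Logical vector, `TRUE` where the position lies in the region.
#' @export
region_contains <- function(region, position, genome_length) {
  stopifnot(inherits(region, "circular_region"))
  position <- as.integer(position)
  check_position(position, as.integer(genome_length))
  if (region$start <= region$end) position >= region$start & position <= region$end
  else position >= region$start | position <= region$end
}

#' Extract the sequence of a region, wrapping through the origin if needed
#'
#' @param genome a [ref_genome()].
#' @param region a [circular_region()].
#' @return A character string of length `region_length(region, genome$length)`.
#' @export
extract_sequence <- function(genome, region) {
  stopifnot(inherits(genome, "ref_genome"), inherits(region, "circular_region"))
  check_position(c(region$start, region$end), genome$length)
  if (region$start <= region$end)
    return(substr(genome$sequence, region$start, region$end))
  if (!genome$circular)
    stop("wrapping region on a non-circular genome")
  paste0(substr(genome$sequence, region$start, genome$length),
         substr(genome$sequence, 1L, region$end))
}

#' The mtDNA control region (rCRS 16,024--576)
#' @return A [circular_region()] of 1122 positions on the rCRS.
#' @export
control_region <- function() circular_region(16024L, 576L)

#' The amplified span of the 10-amplicon control-region design (15,989--619)
#' @return A [circular_region()] of 1200 positions on the rCRS.
#' @export
amplified_span <- function() circular_region(15989L, 619L)

## Internal unwrapped-coordinate helpers. "Unwrapping" maps circular
## positions to a monotone linear axis anchored at `origin`, so interval
## arithmetic that crosses the origin becomes ordinary integer arithmetic.
## Unwrapped coordinates never leak across the API boundary.
unwrap_pos <- function(pos, origin, genome_length) {
  origin + ((pos - origin) %% genome_length)
}

rewrap_pos <- function(pos, genome_length) {
  ((pos - 1L) %% genome_length) + 1L
}

## Unwrap `pos` into the frame closest to `anchor` (used for short spans
## such as probes, where positions are within a genome-half of each other).
unwrap_near <- function(pos, anchor, genome_length) {
  d <- ((pos - anchor) %% genome_length)
  ifelse(d > genome_length / 2, anchor + d - genome_length, anchor + d)
}

## Sequence access on the unwrapped axis: start..end inclusive, unwrapped.
## May span more than one full circle of a circular genome (tiles copies).
extract_unwrapped <- function(genome, start, end) {
  glen <- genome$length
  len <- end - start + 1L
  s0 <- rewrap_pos(start, glen)
  if (!genome$circular) {
    if (start < 1L || end > glen) stop("window outside a non-circular genome")
    return(substr(genome$sequence, start, end))
  }
  big <- strrep(genome$sequence, ceiling((s0 + len - 1L) / glen))
  substr(big, s0, s0 + len - 1L)
}

## Reverse complement for plain character vectors (delegates to Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
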