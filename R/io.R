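#' Read a FASTQ file into a data.frame
#'
#' Plain or gzipped 4-line FASTQ; CRLF line endings are normalised before
#' parsing. Round-trips losslessly with [write_fastq()].
#'
#' @param path path to the FASTQ(.gz) file.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- sub("\r$", "", readLines(path))   # decompresses .gz transparently
  ## structural validation so a truncated/malformed record is reported by
  ## index before handing the file to the Biostrings parser
  if (length(lines) %% 4L != 0L)
    stop(sprintf("FASTQ parse error in %s: truncated record %d (got %d lines)",
                 path, length(lines) %/% 4L + 1L, length(lines)))
  if (length(lines)) {
    ids <- lines[seq(1L, length(lines), by = 4L)]
    plus <- lines[seq(3L, length(lines), by = 4L)]
    seqs <- lines[seq(2L, length(lines), by = 4L)]
    quals <- lines[seq(4L, length(lines), by = 4L)]
    bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+") |
                   nchar(seqs) != nchar(quals))
    if (length(bad))
      stop(sprintf("FASTQ parse error in %s: malformed record %d (line %d)",
                   path, bad[1L], (bad[1L] - 1L) * 4L + 1L))
  }
  tmp <- tempfile(fileext = ".fastq")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  ss <- tryCatch(
    Biostrings::readDNAStringSet(tmp, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("FASTQ parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  data.frame(id = names(ss),
             sequence = as.character(ss),
             quality = as.character(S4Vectors::mcols(ss)$qualities),
             row.names = NULL)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `id`, `sequence` and optionally `quality`
#'   (constant high quality is written when absent).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$id
  qual <- if (!is.null(reads$quality)) reads$quality else strrep("I", nchar(reads$sequence))
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

## Resolve a SAM/BAM path to a sorted, indexed BAM (converting SAM text and
## unsorted BAM via Rsamtools as needed).
resolve_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE)  # sorts + indexes
  } else if (!file.exists(paste0(path, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", path))) {
    sorted <- Rsamtools::sortBam(path, tempfile())
    Rsamtools::indexBam(sorted)
    path <- sorted
  }
  path
}

check_contig <- function(bam, contig) {
  sq <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (is.null(contig)) {
    if (length(sq) != 1L)
      stop("BAM has ", length(sq), " contigs; specify `contig`")
    contig <- names(sq)[1L]
  } else if (!contig %in% names(sq)) {
    stop(sprintf("contig '%s' not in BAM header (found: %s)", contig,
                 paste(names(sq), collapse = ", ")))
  }
  contig
}

#' Per-base pileup counts at positions of a BAM/SAM alignment
#'
#' Counts aligned bases per nucleotide at each 1-based position, for the
#' naive counting path and depth tracks of aligned data. SAM text input is
#' converted (sorted and indexed) on the fly.
#'
#' @param path BAM or SAM file aligned against the mtDNA reference.
#' @param positions 1-based positions to query.
#' @param contig reference contig name; may be omitted for single-contig
#'   alignments.
#' @return data.frame with columns `position`, `nucleotide`, `count`
#'   (positions with no coverage yield no rows).
#' @export
read_pileup_counts <- function(path, positions, contig = NULL) {
  bam <- resolve_bam(path)
  contig <- check_contig(bam, contig)
  which <- GenomicRanges::GRanges(contig, IRanges::IRanges(positions, positions))
  p <- Rsamtools::pileup(bam,
    scanBamParam = Rsamtools::ScanBamParam(which = which),
    pileupParam = Rsamtools::PileupParam(max_depth = 10^6L,
                                         min_base_quality = 0L, min_mapq = 0L,
                                         distinguish_strands = FALSE,
                                         include_deletions = FALSE))
  data.frame(position = p$pos, nucleotide = as.character(p$nucleotide),
             count = p$count)
}

#' Depth track over a (possibly wrapping) region from a BAM/SAM file
#'
#' @param path BAM or SAM file.
#' @param span a [circular_region()].
#' @param genome_length genome length in bases.
#' @param contig reference contig name (optional for single-contig files).
#' @return Numeric per-position depth vector in span order.
#' @export
depth_track_bam <- function(path, span, genome_length, contig = NULL) {
  bam <- resolve_bam(path)
  contig <- check_contig(bam, contig)
  pieces <- if (span$start <= span$end) list(c(span$start, span$end))
            else list(c(span$start, genome_length), c(1L, span$end))
  depth <- unlist(lapply(pieces, function(pc) {
    which <- GenomicRanges::GRanges(contig, IRanges::IRanges(pc[1L], pc[2L]))
    p <- Rsamtools::pileup(bam,
      scanBamParam = Rsamtools::ScanBamParam(which = which),
      pileupParam = Rsamtools::PileupParam(max_depth = 10^6L,
                                           min_base_quality = 0L, min_mapq = 0L,
                                           distinguish_strands = FALSE,
                                           distinguish_nucleotides = FALSE))
    out <- numeric(pc[2L] - pc[1L] + 1L)
    if (nrow(p)) out[p$pos - pc[1L] + 1L] <- p$count
    out
  }))
  unname(depth)
}

#' Write / read a probe table
#'
#' TSV with columns `position`, `ref`, `alt`, `boundary`, `side`,
#' `ref_probe`, `alt_probe`; round-trips a list of probe pairs.
#'
#' @param probes list of `probe_pair` objects.
#' @param path output TSV path.
#' @return `path` invisibly (writer); list of `probe_pair` objects (reader).
#' @export
write_probe_table <- function(probes, path) {
  if (inherits(probes, "probe_pair")) probes <- list(probes)
  d <- do.call(rbind, lapply(probes, function(p) data.frame(
    position = p$site$position, ref = p$site$ref, alt = p$site$alt,
    boundary = p$boundary, side = p$side,
    ref_probe = p$ref_probe, alt_probe = p$alt_probe)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_table
#' @param path TSV path.
#' @export
read_probe_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  lapply(seq_len(nrow(d)), function(i) {
    structure(list(site = variant_site(d$position[i], d$ref[i], d$alt[i]),
                   ref_probe = toupper(d$ref_probe[i]),
                   alt_probe = toupper(d$alt_probe[i]),
                   span = NULL, boundary = as.integer(d$boundary[i]),
                   side = d$side[i], length = nchar(d$ref_probe[i])),
              class = "probe_pair")
  })
}

#' Write site calls as a minimal VCF
#'
#' One record per queried site: CHROM is the contig name, POS/REF/ALT the
#' queried site, and INFO carries `DP` (informative reads), `AF`
#' (alternative fraction, 0--1), `STATUS` and `MODE`. Sites without an
#' informative fraction get `AF` omitted and FILTER set to the status.
#'
#' @param calls an `oreo_calls` object.
#' @param path output path.
#' @param contig contig name (default "chrM").
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, contig = "chrM") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, RCRS_LENGTH),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Informative read depth (ref+alt)\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternative allele fraction\">",
           "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"Site classification\">",
           "##INFO=<ID=MODE,Number=1,Type=String,Description=\"Kit mode used\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  mode <- attr(calls, "mode")
  rows <- vapply(seq_len(nrow(calls)), function(i) {
    dp <- calls$ref_count[i] + calls$alt_count[i]
    info <- sprintf("DP=%d%s;STATUS=%s;MODE=%s", dp,
                    if (is.na(calls$alt_fraction[i])) ""
                    else sprintf(";AF=%.6g", calls$alt_fraction[i] / 100),
                    calls$status[i], mode)
    filter <- if (calls$status[i] %in% c("homoplasmic_alt", "heteroplasmic",
                                         "homoplasmic_ref")) "PASS" else calls$status[i]
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s", contig, calls$position[i],
            calls$ref[i], calls$alt[i], filter, info)
  }, character(1L))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write site calls as TSV
#'
#' @param calls an `oreo_calls` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a variant-site query list
#'
#' TSV with columns `position`, `ref`, `alt`.
#'
#' @param path TSV path.
#' @return list of [variant_site()] objects.
#' @export
read_site_table <- function(path) {
  ## read alleles as character: a lone "T" must not become logical TRUE
  d <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("position", "ref", "alt") %in% names(d)))
    stop("site table must have columns position, ref, alt")
  lapply(seq_len(nrow(d)), function(i)
    variant_site(d$position[i], d$ref[i], d$alt[i]))
}
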