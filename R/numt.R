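#' Read a numt diagnostic-site table
#'
#' TSV with columns `position` (1-based reference coordinate), `mt_allele`
#' (the cognate mtDNA base) and `numt_allele` (the base diagnostic of the
#' nuclear insertion copy). Diagnostic alleles are sample- and
#' insertion-specific and must be supplied by the user for real analyses.
#'
#' @param path path to the TSV file.
#' @return A data.frame with columns `position`, `mt_allele`, `numt_allele`.
#' @export
read_diagnostic_table <- function(path) {
  ## alleles read as character: a lone "T" must not become logical TRUE
  d <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("position", "mt_allele", "numt_allele")
  if (!all(need %in% names(d)))
    stop("diagnostic table must have columns position, mt_allele, numt_allele")
  d$position <- as.integer(d$position)
  if (any(toupper(d$mt_allele) == toupper(d$numt_allele)))
    stop("mt and numt alleles must differ at every diagnostic site")
  d$mt_allele <- toupper(d$mt_allele); d$numt_allele <- toupper(d$numt_allele)
  d[need]
}

## Per-site mt/numt counts via the anchored naive counter.
numt_site_counts <- function(seqs, genome, diagnostics, flank = 10L) {
  lapply(seq_len(nrow(diagnostics)), function(i) {
    site <- variant_site(diagnostics$position[i], diagnostics$mt_allele[i],
                        diagnostics$numt_allele[i])
    naive_site_counts(seqs, genome, site, flank = flank)
  })
}

#' Estimate the numt-derived read fraction from diagnostic sites
#'
#' At each diagnostic site, reads carrying the numt allele are counted
#' against reads carrying the cognate mt allele (other bases are excluded);
#' the pooled fraction is 100 * sum(numt reads) / sum(informative reads)
#' over all sites. A presence flag is raised when the pooled fraction
#' reaches `detection_floor` percent and at least `min_sites` sites
#' individually show numt-supporting reads. Detection of low-level numts is
#' inherently inconsistent (it depends on relative amplification of the
#' nuclear template), so absence of the flag never asserts absence of the
#' insertion.
#'
#' @param reads read sequences (as for [oreo_filter()]).
#' @param genome a [ref_genome()].
#' @param diagnostics diagnostic-site data.frame
#'   (see [read_diagnostic_table()]).
#' @param detection_floor pooled percent needed for the presence flag.
#' @param min_sites minimum individually supported sites for the flag.
#' @param flank anchor flank for site counting.
#' @return An object of class `numt_estimate`: `per_site` data.frame
#'   (`position`, `numt_reads`, `informative_reads`, `fraction`),
#'   `pooled_fraction` (percent), `sites_used`, `present`.
#' @export
numt_fraction <- function(reads, genome, diagnostics, detection_floor = 0.1,
                          min_sites = 3L, flank = 10L) {
  stopifnot(nrow(diagnostics) >= 1L)
  seqs <- read_sequences(reads)
  counts <- numt_site_counts(seqs, genome, diagnostics, flank = flank)
  per_site <- data.frame(
    position = diagnostics$position,
    numt_reads = vapply(counts, function(x) x$alt_count, integer(1L)),
    informative_reads = vapply(counts, function(x) x$total_considered, integer(1L))
  )
  per_site$fraction <- ifelse(per_site$informative_reads > 0,
                              100 * per_site$numt_reads / per_site$informative_reads,
                              NA_real_)
  tot <- sum(per_site$informative_reads)
  if (tot == 0L)
    stop("no informative reads at any diagnostic site: numt fraction undefined")
  pooled <- 100 * sum(per_site$numt_reads) / tot
  structure(list(per_site = per_site, pooled_fraction = pooled,
                 sites_used = sum(per_site$informative_reads > 0),
                 present = pooled >= detection_floor &&
                   sum(per_site$numt_reads > 0) >= min_sites),
            class = "numt_estimate")
}

#' @export
print.numt_estimate <- function(x, ...) {
  cat(sprintf("<numt_estimate> pooled fraction %.2f%% over %d informative sites; numt reads %s\n",
              x$pooled_fraction, x$sites_used,
              if (x$present) "detected" else "not detected (absence not asserted)"))
  invisible(x)
}

#' Select reads carrying a numt allele at any diagnostic site
#'
#' A read is selected if it carries the numt allele at one or more
#' diagnostic positions, located by exact anchor matching around the site
#' (the same machinery as the naive counter). The selected set and its
#' complement partition the input.
#'
#' @inheritParams numt_fraction
#' @return Logical vector over the input reads (`TRUE` = numt-supporting);
#'   subset with `reads[select_numt_reads(...)]`.
#' @export
select_numt_reads <- function(reads, genome, diagnostics, flank = 10L) {
  stopifnot(nrow(diagnostics) >= 1L)
  seqs <- read_sequences(reads)
  glen <- genome$length
  hit <- logical(length(seqs))
  for (i in seq_len(nrow(diagnostics))) {
    pos <- as.integer(diagnostics$position[i])
    win_from <- pos - flank
    window <- extract_unwrapped(genome, win_from, pos + flank)
    left <- substr(window, 1L, flank)
    right <- substr(window, flank + 2L, 2L * flank + 1L)
    base <- diagnostics$numt_allele[i]
    hit <- hit | match_either_strand(seqs, paste0(left, base)) |
      match_either_strand(seqs, paste0(base, right))
  }
  hit
}
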