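#' A queried variant site
#'
#' @param position 1-based reference coordinate of the first reference base
#'   of the site.
#' @param ref reference allele (one or more bases; more than one for a
#'   deletion described VCF-style, e.g. ref "CT" / alt "C").
#' @param alt alternative allele (e.g. "T", or "CT" for the insertion
#'   written 44.1C in forensic nomenclature, anchored at position 44).
#' @return An object of class `variant_site`.
#' @export
variant_site <- function(position, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(nchar(ref) >= 1L, nchar(alt) >= 1L)
  if (identical(ref, alt)) stop("ref and alt alleles must differ")
  if (grepl("[^ACGT]", paste0(ref, alt))) stop("alleles must be A/C/G/T strings")
  structure(list(position = as.integer(position), ref = ref, alt = alt),
            class = "variant_site")
}

## Apply substitution variants (data.frame position/ref/alt) to the sequence
## of a region starting at region_start; used for consensus-backbone probes.
apply_variants <- function(seq, region_start, genome_length, variants) {
  if (is.null(variants) || nrow(variants) == 0L) return(seq)
  for (i in seq_len(nrow(variants))) {
    if (nchar(variants$ref[i]) != nchar(variants$alt[i]))
      stop("backbone variants must be length-preserving substitutions")
    off <- ((as.integer(variants$position[i]) - region_start) %% genome_length) + 1L
    ## the window may tile several copies of a small circular genome
    while (off + nchar(variants$ref[i]) - 1L <= nchar(seq)) {
      end <- off + nchar(variants$ref[i]) - 1L
      if (substr(seq, off, end) != variants$ref[i])
        stop(sprintf("backbone variant at %d: reference disagrees", variants$position[i]))
      substr(seq, off, end) <- variants$alt[i]
      off <- off + genome_length
    }
  }
  seq
}

## Occurrences of `pattern` on either strand of `subject` (a plain string),
## counting overlapping matches; `circular` appends the head so matches
## spanning the origin are seen once.
count_occurrences <- function(subject, pattern, circular = FALSE) {
  if (circular && nchar(pattern) > 1L)
    subject <- paste0(subject, substr(subject, 1L, nchar(pattern) - 1L))
  subj <- Biostrings::DNAString(subject)
  Biostrings::countPattern(pattern, subj) +
    Biostrings::countPattern(revcomp(pattern), subj)
}

#' Design an equal-length allele-specific probe pair spanning an amplicon end
#'
#' Probes are short sequences (10--30 nt) that cover the queried site and
#' extend at least `margin` bases beyond the amplicon-end `boundary`, so a
#' read matching a probe in full cannot end in primer-derived sequence at
#' the queried position. The pair shares one length and differs only at the
#' queried allele, making the loss of error-carrying reads symmetric between
#' alleles. The shortest specific pair is returned; ties are broken by
#' maximal symmetric extension around the site, then by leftmost start.
#'
#' Specificity means the probe, carrying its own allele, occurs exactly once
#' on either strand within `specificity_region` (default: the amplified span
#' for an rCRS-length genome, otherwise the whole genome) - genome-wide
#' uniqueness is unnecessary when only control-region amplicons are
#' sequenced.
#'
#' @param genome a [ref_genome()].
#' @param site a [variant_site()]; its ref allele must match the reference
#'   (after applying `backbone_variants`).
#' @param boundary the amplicon-end position the probe must cross.
#' @param side `"right"` when `boundary` is an amplicon end position (the
#'   amplicon lies to the left), `"left"` when it is an amplicon start;
#'   `"auto"` infers this from the site/boundary geometry (`"both"` is used
#'   when the site sits exactly on the boundary).
#' @param min_len,max_len probe length search range in bases.
#' @param margin minimum bases the probe extends beyond the boundary.
#' @param specificity_region [circular_region()] within which each probe
#'   must be unique, or `NULL` for the default.
#' @param backbone_variants optional data.frame (`position`, `ref`, `alt`)
#'   of known sample substitutions applied to the probe backbone, so probes
#'   at sites flanked by other variants still match sample reads.
#' @return An object of class `probe_pair` with fields `site`, `ref_probe`,
#'   `alt_probe`, `span`, `boundary`, `side`, `length`.
#' @export
design_probe_pair <- function(genome, site, boundary,
                              side = c("auto", "right", "left", "both"),
                              min_len = 10L, max_len = 30L, margin = 1L,
                              specificity_region = NULL,
                              backbone_variants = NULL) {
  side <- match.arg(side)
  stopifnot(inherits(genome, "ref_genome"), inherits(site, "variant_site"))
  glen <- genome$length
  pos <- site$position
  rl <- nchar(site$ref)
  pos_end <- pos + rl - 1L
  ub <- round(unwrap_near(boundary, pos, glen))
  if (side == "auto")
    side <- if (ub > pos_end) "right" else if (ub < pos) "left" else "both"

  if (is.null(specificity_region))
    specificity_region <- if (glen == RCRS_LENGTH) amplified_span()
                          else circular_region(1L, glen)
  spec_start <- specificity_region$start
  spec_ref <- apply_variants(extract_sequence(genome, specificity_region),
                             spec_start, glen, backbone_variants)
  spec_circ <- region_length(specificity_region, glen) == glen

  ## reference-allele check against the (backbone-applied) sequence
  site_off <- ((pos - spec_start) %% glen) + 1L
  if (site_off + rl - 1L <= nchar(spec_ref)) {
    have <- substr(spec_ref, site_off, site_off + rl - 1L)
    if (have != site$ref)
      stop(sprintf("reference at position %d is %s, not %s", pos, have, site$ref))
  }
  spec_alt <- spec_ref
  substr_replace <- function(s, from, to, value) {
    paste0(substr(s, 1L, from - 1L), value, substr(s, to + 1L, nchar(s)))
  }
  spec_alt <- substr_replace(spec_alt, site_off, site_off + rl - 1L, site$alt)

  ## local (backbone-applied) window around the site, unwrapped coordinates
  win_from <- pos - (max_len + 5L)
  win_to <- pos_end + (max_len + 5L)
  if (!genome$circular) {
    win_from <- max(1L, win_from)
    win_to <- min(glen, win_to)
  }
  window <- apply_variants(extract_unwrapped(genome, win_from, win_to),
                           rewrap_pos(win_from, glen), glen, backbone_variants)
  wsub <- function(a, b) substr(window, a - win_from + 1L, b - win_from + 1L)

  delta <- nchar(site$alt) - rl
  best <- NULL
  for (L in seq.int(min_len, max_len)) {
    a_lo <- pos_end - L + 1L
    a_hi <- pos
    if (side %in% c("right", "both")) a_lo <- max(a_lo, ub + margin - L + 1L)
    if (side %in% c("left", "both")) a_hi <- min(a_hi, ub - margin)
    if (a_lo > a_hi) next
    cands <- data.frame(a = a_lo:a_hi)
    cands$b <- cands$a + L - 1L
    ## tie-break ordering: symmetric extension around the site, then leftmost
    cands <- cands[order(abs((pos - cands$a) - (cands$b - pos_end)), cands$a), ]
    for (k in seq_len(nrow(cands))) {
      a <- cands$a[k]; b <- cands$b[k]
      if (!genome$circular && (a < 1L || b > glen)) next
      ref_probe <- wsub(a, b)
      if (grepl("N", ref_probe, fixed = TRUE)) next
      ## alt probe: same total length; for indels the flank on the side away
      ## from the boundary absorbs the length difference
      if (delta == 0L) {
        alt_probe <- substr_replace(ref_probe, pos - a + 1L, pos_end - a + 1L, site$alt)
      } else if (side == "left") {
        b2 <- b - delta
        if (b2 < pos_end) next
        alt_probe <- paste0(wsub(a, pos - 1L), site$alt,
                            if (b2 > pos_end) wsub(pos_end + 1L, b2) else "")
      } else {
        a2 <- a + delta
        if (a2 > pos) next
        alt_probe <- paste0(if (a2 < pos) wsub(a2, pos - 1L) else "", site$alt,
                            wsub(pos_end + 1L, b))
      }
      if (nchar(alt_probe) != L) next
      if (count_occurrences(spec_ref, ref_probe, spec_circ) != 1L) next
      if (count_occurrences(spec_ref, alt_probe, spec_circ) != 0L) next
      if (count_occurrences(spec_alt, alt_probe, spec_circ) != 1L) next
      best <- list(a = a, b = b, ref_probe = ref_probe, alt_probe = alt_probe, L = L)
      break
    }
    if (!is.null(best)) break
  }
  if (is.null(best))
    stop(sprintf("no specific probe pair of length %d-%d exists for site %d%s>%s",
                 min_len, max_len, pos, site$ref, site$alt))
  structure(
    list(site = site, ref_probe = best$ref_probe, alt_probe = best$alt_probe,
         span = circular_region(rewrap_pos(best$a, glen), rewrap_pos(best$b, glen)),
         boundary = as.integer(boundary), side = side, length = best$L),
    class = "probe_pair"
  )
}

#' @export
print.probe_pair <- function(x, ...) {
  cat(sprintf("<probe_pair> site %d %s>%s, length %d, span %d..%d crossing boundary %d (%s)\n",
              x$site$position, x$site$ref, x$site$alt, x$length,
              x$span$start, x$span$end, x$boundary, x$side))
  cat(sprintf("  ref: %s\n  alt: %s\n", x$ref_probe, x$alt_probe))
  invisible(x)
}

#' Per-site allele counts
#'
#' @param ref_count,alt_count reads supporting the reference / alternative
#'   allele.
#' @param other_count reads that overlapped the queried site but matched
#'   neither allele (excluded from `total_considered`).
#' @return An object of class `allele_counts`; `total_considered` is
#'   `ref_count + alt_count`.
#' @export
allele_counts <- function(ref_count, alt_count, other_count = 0L) {
  stopifnot(ref_count >= 0, alt_count >= 0)
  structure(list(ref_count = as.integer(ref_count),
                 alt_count = as.integer(alt_count),
                 other_count = as.integer(other_count),
                 total_considered = as.integer(ref_count) + as.integer(alt_count)),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts> ref %d, alt %d (other %d); alt fraction %.4g%%\n",
              x$ref_count, x$alt_count, x$other_count,
              if (x$total_considered > 0) 100 * x$alt_count / x$total_considered else NA_real_))
  invisible(x)
}

## extract a character vector of read sequences from the accepted inputs
read_sequences <- function(reads) {
  if (is.character(reads)) return(toupper(reads))
  if (is.data.frame(reads) && !is.null(reads$sequence)) return(toupper(reads$sequence))
  if (inherits(reads, "oreo_sim")) return(toupper(reads$reads$sequence))
  stop("reads must be a character vector, a data.frame with a 'sequence' column, or an oreo_sim object")
}

## does each read contain `pattern` as an exact substring on either strand?
match_either_strand <- function(seqs, pattern) {
  grepl(pattern, seqs, fixed = TRUE) | grepl(revcomp(pattern), seqs, fixed = TRUE)
}

#' Enrich overarching reads by exact full-length probe matching (OREO)
#'
#' A read supports the reference allele iff it contains the reference probe
#' as an exact contiguous substring on either strand, and likewise for the
#' alternative probe. All other reads are excluded - in particular reads
#' that end in primer-derived sequence at the queried site (they cannot
#' contain a probe that extends past the amplicon end) and reads with a
#' sequencing error anywhere under the probe. Ambiguity bases (N) never
#' match. Mates of a pair are counted independently; no deduplication is
#' performed.
#'
#' @param reads read sequences (character vector, data.frame with a
#'   `sequence` column, or an `oreo_sim` object).
#' @param probes a [probe_pair()][design_probe_pair()].
#' @return An [allele_counts()] object; `other_count` holds reads matching a
#'   third base in the same probe context (SNP sites only, else 0).
#' @export
oreo_filter <- function(reads, probes) {
  stopifnot(inherits(probes, "probe_pair"))
  seqs <- read_sequences(reads)
  ref_hit <- match_either_strand(seqs, probes$ref_probe)
  alt_hit <- match_either_strand(seqs, probes$alt_probe)
  if (any(ref_hit & alt_hit))
    stop("a read matched both probes; the probe pair is not allele-discriminating")
  other <- 0L
  site <- probes$site
  if (nchar(site$ref) == 1L && nchar(site$alt) == 1L) {
    ## locate the queried offset exactly: the pair differs only at the site
    diffat <- which(strsplit(probes$ref_probe, "")[[1L]] != strsplit(probes$alt_probe, "")[[1L]])
    for (base in setdiff(c("A", "C", "G", "T"), c(site$ref, site$alt))) {
      p <- probes$ref_probe
      substr(p, diffat, diffat) <- base
      other <- other + sum(match_either_strand(seqs, p) & !ref_hit & !alt_hit)
    }
  }
  if (sum(ref_hit) + sum(alt_hit) == 0L &&
      length(seqs) > 0L && probes$length > max(nchar(seqs)))
    warning("probe is longer than every read; zero counts")
  allele_counts(sum(ref_hit), sum(alt_hit), other)
}

#' Alternative-allele fraction of an allele count
#'
#' @param counts an [allele_counts()] object.
#' @param digits digits for rounding, or `NULL` for full precision
#'   (summaries round to integer percent; internal computations do not).
#' @return Percentage `100 * alt / (ref + alt)`, or `NA` (with a warning)
#'   when there are no informative reads.
#' @examples
#' allele_fraction(allele_counts(7824 - 2966, 2966))  # 37.9..., prints as 38%
#' @export
allele_fraction <- function(counts, digits = NULL) {
  stopifnot(inherits(counts, "allele_counts"))
  if (counts$total_considered < 1L) {
    warning("no informative reads: allele fraction undefined (no-call)")
    return(NA_real_)
  }
  f <- 100 * counts$alt_count / counts$total_considered
  if (!is.null(digits)) round(f, digits) else f
}

#' Alignment-free pileup-like allele counts at a site
#'
#' The "naive" counting path: a read supports allele `a` at the site if it
#' contains `flank` reference bases immediately left of the site followed by
#' `a`, or `a` followed by `flank` reference bases immediately right of it,
#' on either strand. One-sided anchors make reads that terminate at an
#' amplicon or short-product end still contribute their (primer-derived)
#' base, as an alignment pileup would. Unlike [oreo_filter()] no
#' boundary-crossing is required, so this path retains the reference bias at
#' primer-shadowed sites - it is the comparator OREO is judged against, and
#' the counting path for sites in non-overlap segments where no bias exists.
#'
#' @param reads read sequences (as for [oreo_filter()]).
#' @param genome a [ref_genome()].
#' @param site a [variant_site()] (substitutions only).
#' @param flank anchor flank length in bases.
#' @param backbone_variants optional substitutions applied to anchor flanks.
#' @return An [allele_counts()] object (third/fourth bases in `other_count`;
#'   reads matching both alleles at different offsets are excluded).
#' @export
naive_site_counts <- function(reads, genome, site, flank = 10L,
                              backbone_variants = NULL) {
  stopifnot(inherits(genome, "ref_genome"), inherits(site, "variant_site"))
  if (nchar(site$ref) != 1L || nchar(site$alt) != 1L)
    stop("naive counting supports substitution sites only")
  seqs <- read_sequences(reads)
  glen <- genome$length
  pos <- site$position
  win_from <- pos - flank; win_to <- pos + flank
  window <- apply_variants(extract_unwrapped(genome, win_from, win_to),
                           rewrap_pos(win_from, glen), glen, backbone_variants)
  left <- substr(window, 1L, flank)
  right <- substr(window, flank + 2L, 2L * flank + 1L)
  if (substr(window, flank + 1L, flank + 1L) != site$ref)
    stop(sprintf("reference at position %d is %s, not %s", pos,
                 substr(window, flank + 1L, flank + 1L), site$ref))
  hit_base <- function(base) {
    match_either_strand(seqs, paste0(left, base)) |
      match_either_strand(seqs, paste0(base, right))
  }
  ref_hit <- hit_base(site$ref)
  alt_hit <- hit_base(site$alt)
  amb <- ref_hit & alt_hit
  other <- 0L
  for (base in setdiff(c("A", "C", "G", "T"), c(site$ref, site$alt)))
    other <- other + sum(hit_base(base) & !ref_hit & !alt_hit)
  allele_counts(sum(ref_hit & !amb), sum(alt_hit & !amb), other)
}
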