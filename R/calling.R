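#' Tiered calling thresholds
#'
#' The threshold tiers are: an analytical depth below which no call is
#' attempted (20x, also required of the minor component of a heteroplasmy);
#' a detection fraction (5%) above which an alternative allele is noted; a
#' calling window within which a site is reported heteroplasmic rather than
#' homoplasmic. The prototype single-reaction chemistry supports a
#' conservative 10--90% window; the nested chemistry, after in-silico size
#' selection and overarching-read enrichment, supports 5--95%.
#'
#' @param mode `"prototype"` or `"nested"`; sets the heteroplasmy window
#'   (10--90 or 5--95) unless `het_window` is given.
#' @param analytical_depth minimum informative reads for any call.
#' @param minor_depth minimum reads for the minor component of a
#'   heteroplasmic call.
#' @param detection_fraction percent at which an alternative allele is
#'   considered detected.
#' @param calling_fraction percent at which the prototype chemistry calls
#'   heteroplasmy.
#' @param het_window optional length-2 numeric, percent bounds (inclusive)
#'   of the heteroplasmy window.
#' @param primer_mask_width bases from each amplicon end treated as probable
#'   primer sequence (27, the observed extent of biased SNPs).
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(mode = c("prototype", "nested"),
                          analytical_depth = 20L, minor_depth = 20L,
                          detection_fraction = 5, calling_fraction = 10,
                          het_window = NULL, primer_mask_width = 27L) {
  mode <- match.arg(mode)
  if (is.null(het_window))
    het_window <- if (mode == "prototype") c(10, 90) else c(5, 95)
  stopifnot(analytical_depth >= 1L, detection_fraction > 0,
            detection_fraction <= calling_fraction, calling_fraction < 50,
            length(het_window) == 2L, het_window[1L] < het_window[2L])
  structure(list(mode = mode, analytical_depth = as.integer(analytical_depth),
                 minor_depth = as.integer(minor_depth),
                 detection_fraction = detection_fraction,
                 calling_fraction = calling_fraction,
                 het_window = het_window,
                 primer_mask_width = as.integer(primer_mask_width)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> %s mode: analytical %dx, minor %dx, detect %g%%, het window [%g, %g]%%, mask %d bp\n",
              x$mode, x$analytical_depth, x$minor_depth, x$detection_fraction,
              x$het_window[1L], x$het_window[2L], x$primer_mask_width))
  invisible(x)
}

SITE_STATUSES <- c("homoplasmic_ref", "homoplasmic_alt", "heteroplasmic",
                   "uncallable_low_coverage", "uncallable_primer_region",
                   "no_call")

#' Classify a site from its allele counts
#'
#' Classification is total: every input maps to exactly one status.
#' Fewer informative reads than the analytical depth gives
#' `uncallable_low_coverage`. An alternative fraction above the window upper
#' bound is `homoplasmic_alt` ("SNP"), below the lower bound
#' `homoplasmic_ref`. Within the window (bounds inclusive) the site is
#' `heteroplasmic`, provided the minor component also meets the minor-depth
#' criterion - otherwise it is demoted to `uncallable_low_coverage` rather
#' than silently asserted homoplasmic. In prototype mode an apparently
#' heteroplasmic site lying in a probable primer region is
#' `uncallable_primer_region`, because internalised primer sequence (overlap
#' extension) can mimic heteroplasmy there; nested chemistry blocks overlap
#' extension, so no masking applies.
#'
#' Status decisions use exact fractions; percentages are rounded only for
#' display.
#'
#' @param counts an [allele_counts()] object.
#' @param thresholds a [threshold_set()].
#' @param in_primer_region logical; is the site within the primer mask?
#' @param mode kit mode; defaults to the mode of `thresholds`.
#' @return An object of class `site_call` with fields `counts`,
#'   `alt_fraction` (percent, full precision), `status`, `mode`,
#'   `in_primer_region`.
#' @export
classify_site <- function(counts, thresholds, in_primer_region = FALSE,
                          mode = thresholds$mode) {
  stopifnot(inherits(counts, "allele_counts"), inherits(thresholds, "threshold_set"))
  total <- counts$total_considered
  lo <- thresholds$het_window[1L]; hi <- thresholds$het_window[2L]
  if (total < thresholds$analytical_depth) {
    status <- "uncallable_low_coverage"
    frac <- if (total > 0L) 100 * counts$alt_count / total else NA_real_
  } else {
    frac <- 100 * counts$alt_count / total
    apparent_het <- frac >= lo & frac <= hi
    if (mode == "prototype" && in_primer_region && apparent_het) {
      status <- "uncallable_primer_region"
    } else if (frac > hi) {
      status <- "homoplasmic_alt"
    } else if (frac < lo) {
      status <- "homoplasmic_ref"
    } else if (min(counts$ref_count, counts$alt_count) >= thresholds$minor_depth) {
      status <- "heteroplasmic"
    } else {
      status <- "uncallable_low_coverage"
    }
  }
  structure(list(counts = counts, alt_fraction = frac, status = status,
                 mode = mode, in_primer_region = in_primer_region),
            class = "site_call")
}

#' @export
print.site_call <- function(x, ...) {
  cat(sprintf("<site_call> %s (%s mode): alt %d / %d informative reads (%s%%)%s\n",
              x$status, x$mode, x$counts$alt_count, x$counts$total_considered,
              if (is.na(x$alt_fraction)) "NA" else sprintf("%.0f", x$alt_fraction),
              if (x$in_primer_region) " [primer region]" else ""))
  invisible(x)
}

#' Estimate consensus substitutions for probe backbones
#'
#' Sites whose naive alternative fraction reaches `min_fraction` percent are
#' returned as backbone substitutions. When biased SNPs cluster inside one
#' primer footprint, a probe for one site must carry the sample's alleles at
#' the neighbouring sites or no read will match either probe; because both
#' probes of a pair carry the same backbone, the extra loss at sites where
#' the backbone allele is itself polymorphic remains symmetric and fractions
#' stay unbiased.
#'
#' @param reads read sequences.
#' @param genome a [ref_genome()].
#' @param sites list of [variant_site()] objects (substitutions only).
#' @param min_fraction percent naive alternative fraction for inclusion.
#' @param flank anchor flank for [naive_site_counts()].
#' @return data.frame (`position`, `ref`, `alt`) suitable as
#'   `backbone_variants`.
#' @export
consensus_variants <- function(reads, genome, sites, min_fraction = 5,
                               flank = 10L) {
  keep <- list()
  for (s in sites) {
    if (nchar(s$ref) != 1L || nchar(s$alt) != 1L) next
    ct <- naive_site_counts(reads, genome, s, flank = flank)
    if (ct$total_considered >= 1L &&
        100 * ct$alt_count / ct$total_considered >= min_fraction)
      keep[[length(keep) + 1L]] <- data.frame(position = s$position,
                                              ref = s$ref, alt = s$alt)
  }
  if (!length(keep)) return(data.frame(position = integer(0),
                                       ref = character(0), alt = character(0)))
  do.call(rbind, keep)
}

#' Call a list of queried sites over a read set
#'
#' Routes each site by its segment: sites in overlap segments are counted
#' with OREO probes crossing the nearer amplicon end (the end whose primer
#' shadows the site), sites in non-overlap segments with the naive counter
#' (they are unaffected by primer bias). Probe-design failures propagate as
#' `no_call` with the reason recorded.
#'
#' @param reads read sequences (character vector, data.frame with a
#'   `sequence` column, or an `oreo_sim` object).
#' @param genome a [ref_genome()].
#' @param amplicons amplicon data.frame (see [default_amplicons()]).
#' @param sites list of [variant_site()] objects.
#' @param thresholds a [threshold_set()].
#' @param mode kit mode; defaults to the mode of `thresholds`.
#' @param consensus_backbone when `TRUE`, probe/anchor backbones carry the
#'   alternative alleles of other queried sites detected above the detection
#'   threshold by a first naive pass (see [consensus_variants()]); the
#'   default keeps a pure reference backbone.
#' @param naive_flank anchor flank for the naive counting path.
#' @param margin bases a probe must extend past the amplicon end.
#' @param min_len,max_len probe length range.
#' @return An object of class `oreo_calls`: a data.frame with one row per
#'   site (`position`, `ref`, `alt`, `method`, `in_primer`, `ref_count`,
#'   `alt_count`, `other_count`, `alt_fraction`, `status`, `note`), plus
#'   attributes `mode` and `thresholds`.
#' @export
call_region <- function(reads, genome, amplicons, sites, thresholds,
                        mode = thresholds$mode, consensus_backbone = FALSE,
                        naive_flank = 10L, margin = 1L,
                        min_len = 10L, max_len = 30L) {
  stopifnot(inherits(genome, "ref_genome"), inherits(thresholds, "threshold_set"))
  glen <- genome$length
  segments <- build_segments(amplicons, glen)
  seqs <- read_sequences(reads)

  backbone <- NULL
  if (isTRUE(consensus_backbone))
    backbone <- consensus_variants(seqs, genome, sites,
                                   min_fraction = thresholds$detection_fraction,
                                   flank = naive_flank)

  rows <- vector("list", length(sites))
  for (k in seq_along(sites)) {
    s <- sites[[k]]
    seg_i <- segment_for_position(s$position, segments, glen)
    primer <- in_primer_region(s$position, amplicons,
                               thresholds$primer_mask_width, glen)
    note <- ""
    bb <- if (!is.null(backbone)) backbone[backbone$position != s$position, , drop = FALSE]
    counts <- NULL
    method <- NA_character_
    if (is.na(seg_i)) {
      note <- "outside amplified span"
      status <- "no_call"; frac <- NA_real_
      counts <- allele_counts(0L, 0L)
    } else if (segments$overlap[seg_i]) {
      method <- "oreo"
      amp_ids <- as.integer(strsplit(segments$amplicon_ids[seg_i], ",")[[1L]])
      left_amp <- amplicons[match(amp_ids[1L], amplicons$id), ]
      right_amp <- amplicons[match(amp_ids[2L], amplicons$id), ]
      ## nearer amplicon end: the left amplicon's end or the right one's start
      d_end <- (left_amp$end - s$position) %% glen
      d_start <- (s$position - right_amp$start) %% glen
      if (d_end <= d_start) {
        boundary <- left_amp$end; side <- "right"
      } else {
        boundary <- right_amp$start; side <- "left"
      }
      counts <- tryCatch({
        pp <- design_probe_pair(genome, s, boundary, side = side,
                                min_len = min_len, max_len = max_len,
                                margin = margin, backbone_variants = bb)
        oreo_filter(seqs, pp)
      }, error = function(e) e)
      if (inherits(counts, "error")) {
        note <- conditionMessage(counts)
        counts <- NULL
      }
    } else {
      method <- "naive"
      counts <- tryCatch(naive_site_counts(seqs, genome, s, flank = naive_flank,
                                           backbone_variants = bb),
                         error = function(e) e)
      if (inherits(counts, "error")) {
        note <- conditionMessage(counts)
        counts <- NULL
      }
    }
    if (is.null(counts)) {
      status <- "no_call"; frac <- NA_real_
      counts <- allele_counts(0L, 0L)
    } else if (note == "") {
      call <- classify_site(counts, thresholds, in_primer_region = primer,
                            mode = mode)
      status <- call$status; frac <- call$alt_fraction
    }
    rows[[k]] <- data.frame(position = s$position, ref = s$ref, alt = s$alt,
                            method = method, in_primer = primer,
                            ref_count = counts$ref_count,
                            alt_count = counts$alt_count,
                            other_count = counts$other_count,
                            alt_fraction = frac, status = status, note = note)
  }
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  attr(out, "thresholds") <- thresholds
  class(out) <- c("oreo_calls", "data.frame")
  out
}

#' @export
print.oreo_calls <- function(x, ...) {
  cat(sprintf("Site calls (%s mode), %d sites:\n", attr(x, "mode"), nrow(x)))
  show <- as.data.frame(x)
  show$alt_fraction <- ifelse(is.na(show$alt_fraction), NA,
                              round(show$alt_fraction))
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.oreo_calls <- function(object, ...) {
  tab <- table(factor(object$status, levels = SITE_STATUSES))
  cat(sprintf("Site calls (%s mode): %d queried sites\n",
              attr(object, "mode"), nrow(object)))
  cat(sprintf("  SNPs (homoplasmic alternative): %d\n", tab[["homoplasmic_alt"]]))
  cat(sprintf("  heteroplasmic: %d\n", tab[["heteroplasmic"]]))
  cat(sprintf("  homoplasmic reference: %d\n", tab[["homoplasmic_ref"]]))
  cat(sprintf("  uncallable (low coverage / primer region): %d / %d\n",
              tab[["uncallable_low_coverage"]], tab[["uncallable_primer_region"]]))
  cat(sprintf("  no call: %d\n", tab[["no_call"]]))
  invisible(tab)
}

#' Summarise agreement with an independent call set
#'
#' Treats calls present in `calls` but absent from the comparison set as
#' potential false positives, in the conservative sense of the validation
#' arithmetic: rate = 100 * discrepant / compared.
#'
#' @param discrepant number of discrepant (potentially false-positive)
#'   sites.
#' @param compared total number of compared calls.
#' @return A list with `discrepant`, `compared` and `false_positive_rate`
#'   (percent).
#' @examples
#' validation_rate(6, 480)$false_positive_rate  # 1.25
#' @export
validation_rate <- function(discrepant, compared) {
  stopifnot(compared >= 1L, discrepant >= 0L, discrepant <= compared)
  list(discrepant = as.integer(discrepant), compared = as.integer(compared),
       false_positive_rate = 100 * discrepant / compared)
}

#' Compare two call sets site-by-site
#'
#' @param calls an `oreo_calls` object (or data.frame with `position`,
#'   `alt`, `status`).
#' @param reference_calls data.frame with `position` and `alt` columns
#'   listing the comparison data's accepted alternative alleles.
#' @return A list: `compared` (sites with a reported variant in either set),
#'   `discrepant` (variants in `calls` absent from the reference),
#'   `missed` (reference variants not called), and `false_positive_rate`.
#' @export
compare_callsets <- function(calls, reference_calls) {
  ours <- calls[calls$status %in% c("homoplasmic_alt", "heteroplasmic"),
                c("position", "alt")]
  key <- function(d) paste(d$position, d$alt)
  discrepant <- sum(!(key(ours) %in% key(reference_calls)))
  missed <- sum(!(key(reference_calls) %in% key(ours)))
  compared <- nrow(calls)
  c(validation_rate(discrepant, max(compared, 1L)), list(missed = missed))
}
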