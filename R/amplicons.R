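#' The bundled approximate 10-amplicon control-region design
#'
#' The exact primer coordinates of commercial control-region multiplexes are
#' proprietary. This table is an approximate reconstruction that satisfies
#' every published constraint of the design: ten amplicons of 144--237 bp
#' chained across the amplified span 15,989--619 (1200 positions, wrapping
#' the rCRS origin), with consecutive overlaps of 52--91 bp and no
#' non-consecutive overlap. It is suitable for simulation and method
#' validation; analyses of real data should supply the true amplicon table
#' via [read_amplicon_table()].
#'
#' @param primer_len primer footprint length in bases applied to both ends
#'   of every amplicon (default 22; published trimming attempts place primer
#'   footprints at 20--26 nt).
#' @return A data.frame with columns `id`, `start`, `end`, `primer_len`,
#'   `yield` (relative amplification yield, default 1 for all amplicons).
#' @examples
#' amp <- default_amplicons()
#' nrow(build_segments(amp, 16569))  # 19 segments
#' @export
default_amplicons <- function(primer_len = 22L) {
  amp <- data.frame(
    id    = 1:10,
    start = c(15989L, 16109L, 16214L, 16352L, 16452L, 16564L, 148L, 238L, 371L, 463L),
    end   = c(16188L, 16288L, 16433L, 16521L,    72L,   231L, 307L, 447L, 514L, 619L)
  )
  amp$primer_len <- as.integer(primer_len)
  amp$yield <- 1
  amp
}

#' Read an amplicon definition table
#'
#' TSV with columns `id`, `start`, `end` (1-based inclusive, reference
#' numbering, wrapping through the origin allowed) and optionally
#' `primer_len` and `yield`.
#'
#' @param path path to the TSV file.
#' @param primer_len default primer footprint when the column is absent.
#' @return A data.frame as for [default_amplicons()].
#' @export
read_amplicon_table <- function(path, primer_len = 22L) {
  amp <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "start", "end")
  if (!all(need %in% names(amp)))
    stop("amplicon table must have columns id, start, end")
  if (is.null(amp$primer_len)) amp$primer_len <- as.integer(primer_len)
  if (is.null(amp$yield)) amp$yield <- 1
  amp[c("id", "start", "end", "primer_len", "yield")]
}

## Unwrap an amplicon chain onto a linear axis anchored at the first
## amplicon's start; validates the chain structure on the way.
unwrap_amplicons <- function(amplicons, genome_length) {
  n <- nrow(amplicons)
  origin <- as.integer(amplicons$start[1L])
  s <- unwrap_pos(as.integer(amplicons$start), origin, genome_length)
  e <- s + vapply(seq_len(n), function(i)
    region_length(circular_region(amplicons$start[i], amplicons$end[i]), genome_length),
    integer(1L)) - 1L
  if (n > 1L) {
    if (any(diff(s) <= 0L) || any(diff(e) <= 0L))
      stop("amplicons must be given in chain order with strictly increasing starts and ends")
    bad <- which(s[-1L] > e[-n])
    if (length(bad)) {
      i <- bad[1L]
      msg <- if (s[i + 1L] > e[i] + 1L) "gap between" else "no overlap between"
      stop(sprintf("%s consecutive amplicons %s and %s", msg,
                   amplicons$id[i], amplicons$id[i + 1L]))
    }
  }
  if (n > 2L) {
    bad <- which(s[-(1:2)] <= e[seq_len(n - 2L)])
    if (length(bad))
      stop(sprintf("non-consecutive amplicons %s and %s overlap",
                   amplicons$id[bad[1L]], amplicons$id[bad[1L] + 2L]))
  }
  list(start = s, end = e, origin = origin)
}

#' Derive overlapping/non-overlapping segments from an amplicon chain
#'
#' A valid chain of n amplicons (consecutive amplicons overlap,
#' non-consecutive do not) partitions the amplified span into 2n-1
#' alternating segments: non-overlap segments covered by a single amplicon
#' and overlap segments covered by exactly two.
#'
#' @param amplicons amplicon data.frame (see [default_amplicons()]),
#'   in chain order.
#' @param genome_length genome length in bases.
#' @return A data.frame with columns `segment_id`, `start`, `end`
#'   (1-based inclusive, rewrapped), `overlap` (logical) and
#'   `amplicon_ids` (comma-separated contributing amplicon ids).
#' @export
build_segments <- function(amplicons, genome_length) {
  n <- nrow(amplicons)
  u <- unwrap_amplicons(amplicons, genome_length)
  s <- u$start; e <- u$end
  if (n == 1L) {
    seg <- data.frame(segment_id = 1L, start = s, end = e, overlap = FALSE,
                      amplicon_ids = as.character(amplicons$id[1L]))
  } else {
    starts <- integer(0); ends <- integer(0); over <- logical(0); ids <- character(0)
    for (i in seq_len(n)) {
      ns <- if (i == 1L) s[1L] else e[i - 1L] + 1L
      ne <- if (i == n) e[n] else s[i + 1L] - 1L
      if (ns > ne)
        stop(sprintf("amplicon %s has no non-overlap segment (fully covered by its neighbours)",
                     amplicons$id[i]))
      starts <- c(starts, ns); ends <- c(ends, ne)
      over <- c(over, FALSE); ids <- c(ids, as.character(amplicons$id[i]))
      if (i < n) {
        starts <- c(starts, s[i + 1L]); ends <- c(ends, e[i])
        over <- c(over, TRUE)
        ids <- c(ids, paste(amplicons$id[i], amplicons$id[i + 1L], sep = ","))
      }
    }
    seg <- data.frame(segment_id = seq_along(starts), start = starts, end = ends,
                      overlap = over, amplicon_ids = ids)
  }
  seg$start <- rewrap_pos(seg$start, genome_length)
  seg$end <- rewrap_pos(seg$end, genome_length)
  seg
}

## Index of a position within a span's depth track (1-based offset).
span_offset <- function(position, span, genome_length) {
  off <- ((as.integer(position) - span$start) %% genome_length) + 1L
  n <- region_length(span, genome_length)
  if (any(off > n)) stop("position outside the span")
  off
}

#' Per-segment coverage statistics
#'
#' Segment means are arithmetic over positions; normalisation is to the mean
#' depth over all positions of the span (the per-sample overall mean), so in
#' a balanced library overlap segments sit above 1 and non-overlap segments
#' below.
#'
#' @param depth_track numeric vector of per-position depth over `span`, in
#'   span order (position `span$start` first, wrapping through the origin).
#' @param segments data.frame from [build_segments()].
#' @param span the [circular_region()] the depth track covers.
#' @param genome_length genome length in bases.
#' @return A data.frame with `segment_id`, `overlap`, `amplicon_ids`,
#'   `mean_depth`, `normalized_depth`.
#' @export
segment_coverage <- function(depth_track, segments, span, genome_length) {
  n <- region_length(span, genome_length)
  if (length(depth_track) != n)
    stop(sprintf("depth track has %d positions but the span has %d",
                 length(depth_track), n))
  if (any(depth_track < 0)) stop("depth values must be >= 0")
  overall <- mean(depth_track)
  means <- vapply(seq_len(nrow(segments)), function(i) {
    i0 <- span_offset(segments$start[i], span, genome_length)
    i1 <- i0 + region_length(circular_region(segments$start[i], segments$end[i]),
                             genome_length) - 1L
    mean(depth_track[i0:i1])
  }, numeric(1L))
  data.frame(segment_id = segments$segment_id, overlap = segments$overlap,
             amplicon_ids = segments$amplicon_ids, mean_depth = means,
             normalized_depth = if (overall > 0) means / overall else NA_real_)
}

#' Detect amplicon-end boundaries from sharp drops in a depth track
#'
#' Amplicon ends show as sharp single-step changes in coverage. The change
#' score between adjacent positions is the scale-free relative change
#' `|d(p+1) - d(p)| / max(d(p), 1)`; the `expected_count` largest scores are
#' taken greedily, each at least `window` positions from previously accepted
#' boundaries. A drop is reported as the last high-coverage position before
#' it, a rise as the first position after it. The track is padded with zero
#' depth at both ends so the outermost amplicon ends are detectable.
#'
#' @param depth_track numeric per-position depth vector (span order).
#' @param expected_count number of boundaries sought (2 per amplicon).
#' @param window minimum spacing between reported boundaries, in bases.
#' @param min_change minimum relative change for a step to count as sharp.
#' @param span optional [circular_region()]; when given, boundaries are
#'   reported in genome coordinates instead of track offsets.
#' @param genome_length genome length (required with `span`).
#' @param pad_ends treat the track ends as falling to zero coverage, so the
#'   outermost amplicon start/end count as boundaries (default); disable
#'   when the track is a window inside covered sequence.
#' @return Integer vector of boundary positions (possibly shorter than
#'   `expected_count`, with a warning).
#' @export
detect_boundaries <- function(depth_track, expected_count, window = 10L,
                              min_change = 0.25, span = NULL,
                              genome_length = NULL, pad_ends = TRUE) {
  stopifnot(expected_count >= 1L)
  d <- if (pad_ends) c(0, depth_track, 0)
       else c(depth_track[1L], depth_track, depth_track[length(depth_track)])
  step <- diff(d)                       # step[i]: change between track pos i-1 and i
  score <- abs(step) / pmax(d[-length(d)], 1)
  ord <- order(score, decreasing = TRUE)
  picked <- integer(0)                  # index into `step`
  for (i in ord) {
    if (score[i] < min_change) break
    if (length(picked) && any(abs(picked - i) < window)) next
    picked <- c(picked, i)
    if (length(picked) == expected_count) break
  }
  if (length(picked) < expected_count)
    warning(sprintf("found %d sharp changes, expected %d", length(picked), expected_count))
  ## step i sits between padded positions i and i+1 = track positions i-1, i.
  pos <- ifelse(step[picked] < 0, picked - 1L, picked)  # drop: last high; rise: first after
  pos <- sort(as.integer(pos))
  pos <- pos[pos >= 1L & pos <= length(depth_track)]
  if (!is.null(span)) {
    stopifnot(!is.null(genome_length))
    pos <- rewrap_pos(span$start + pos - 1L, genome_length)
  }
  pos
}

#' Flag non-overlap segments with unusually low coverage
#'
#' A non-overlap segment whose mean depth falls below (mean depth of all
#' other segments) / `fold_threshold` signals a possible primer-site variant
#' suppressing that amplicon (and potential numt visibility). A published
#' example showed one amplicon's non-overlap segment at 159x against 2046x
#' for the other segments of the same sample, a ~13-fold suppression; the
#' default threshold of 5 is conservative.
#'
#' @param coverages data.frame from [segment_coverage()].
#' @param fold_threshold fold suppression required to flag (> 1).
#' @return Integer vector of flagged `segment_id`s (possibly empty).
#' @export
flag_low_coverage_amplicons <- function(coverages, fold_threshold = 5) {
  stopifnot(fold_threshold > 1)
  flagged <- integer(0)
  for (i in seq_len(nrow(coverages))) {
    if (coverages$overlap[i]) next
    others <- mean(coverages$mean_depth[-i])
    if (coverages$mean_depth[i] < others / fold_threshold)
      flagged <- c(flagged, coverages$segment_id[i])
  }
  flagged
}

#' Is a position within the primer-footprint mask of any amplicon end?
#'
#' Positions within `mask_width` bases of either end of any amplicon
#' (wrap-aware, measured inward from the end) are treated as probable
#' primer-binding sequence. The default width of 27 bases reflects the
#' observed extent of reference-biased SNPs from amplicon ends.
#'
#' @param position 1-based position(s).
#' @param amplicons amplicon data.frame.
#' @param mask_width mask width in bases from each amplicon end.
#' @param genome_length genome length in bases.
#' @return Logical vector.
#' @export
in_primer_region <- function(position, amplicons, mask_width = 27L,
                             genome_length = RCRS_LENGTH) {
  position <- as.integer(position)
  check_position(position, genome_length)
  out <- logical(length(position))
  for (i in seq_len(nrow(amplicons))) {
    alen <- region_length(circular_region(amplicons$start[i], amplicons$end[i]),
                          genome_length)
    w <- min(as.integer(mask_width), alen)
    from_start <- ((position - amplicons$start[i]) %% genome_length) + 1L
    from_end <- ((amplicons$end[i] - position) %% genome_length) + 1L
    out <- out | (from_start <= w & from_start <= alen) |
      (from_end <= w & from_end <= alen)
  }
  out
}

## Segment (row index) containing each position; NA when outside the span.
segment_for_position <- function(position, segments, genome_length) {
  vapply(position, function(p) {
    hit <- which(vapply(seq_len(nrow(segments)), function(i)
      region_contains(circular_region(segments$start[i], segments$end[i]), p,
                      genome_length), logical(1L)))
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1L))
}
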