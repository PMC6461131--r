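#' Describe an in-silico amplicon sequencing run
#'
#' The generative model mirrors the mechanics of single-multiplex
#' overlapping-amplicon sequencing. Reads are emitted as full-length
#' single-end amplicon sequences (600-cycle paired-end chemistry fully spans
#' 144--237-bp amplicons after merging). Three template classes exist:
#' designed amplicons, short overlap-length by-products (the region shared
#' by two consecutive amplicons, emitted as pure reference since their
#' content is essentially all primer-derived), and - when configured - numt
#' templates carrying numt alleles at diagnostic sites. Within a designed
#' amplicon, positions inside a primer footprint (default 22 bases at each
#' end, within the published 20--26 range) emit the reference allele
#' regardless of the template drawn: this is the reference-bias mechanism.
#' In prototype mode a configurable fraction of molecules additionally carry
#' internalised primer blocks (overlap extension): the footprints of the
#' neighbouring amplicons' ends lying inside the read body also emit
#' reference. Nested chemistry blocks overlap extension, so the rate must
#' be 0 there. Per-base substitution errors are applied last.
#'
#' @param genome a [ref_genome()].
#' @param amplicons amplicon data.frame with `id`, `start`, `end`,
#'   `primer_len`, `yield` (see [default_amplicons()]).
#' @param mode `"prototype"` or `"nested"`.
#' @param n_reads number of reads to emit.
#' @param sample_haplotype data.frame (`position`, `ref`, `alt`, `fraction`)
#'   of substitution sites; `fraction` is the per-molecule probability of
#'   the alternative allele (1 = homoplasmic alternative).
#' @param short_product_rate fraction of reads from short overlap-length
#'   by-products.
#' @param overlap_extension_rate fraction of designed-amplicon molecules
#'   with internalised primer blocks (prototype only).
#' @param numt optional list with `diagnostics` (data.frame `position`,
#'   `mt_allele`, `numt_allele`) and `fraction`: numt templates are emitted
#'   at that fraction of the yield of each amplicon containing a diagnostic
#'   site.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed; identical seeds give identical output.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(genome, amplicons = default_amplicons(),
                              mode = c("prototype", "nested"),
                              n_reads = 10000L, sample_haplotype = NULL,
                              short_product_rate = 0.3,
                              overlap_extension_rate = 0,
                              numt = NULL, error_rate = 0.002, seed = NULL) {
  mode <- match.arg(mode)
  rates <- c(short_product_rate, overlap_extension_rate, error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (mode == "nested" && overlap_extension_rate > 0)
    stop("overlap extension is blocked by the nested chemistry; set overlap_extension_rate = 0")
  if (!is.null(sample_haplotype)) {
    stopifnot(all(c("position", "ref", "alt", "fraction") %in% names(sample_haplotype)))
    if (any(nchar(sample_haplotype$ref) != 1L | nchar(sample_haplotype$alt) != 1L))
      stop("the simulator emits substitution heteroplasmies only")
    if (any(sample_haplotype$fraction < 0 | sample_haplotype$fraction > 1))
      stop("haplotype fractions must lie in [0, 1]")
  }
  if (!is.null(numt))
    stopifnot(is.list(numt), !is.null(numt$diagnostics), !is.null(numt$fraction),
              numt$fraction >= 0, numt$fraction <= 1)
  structure(list(genome = genome, amplicons = amplicons, mode = mode,
                 n_reads = as.integer(n_reads),
                 sample_haplotype = sample_haplotype,
                 short_product_rate = short_product_rate,
                 overlap_extension_rate = overlap_extension_rate,
                 numt = numt, error_rate = error_rate, seed = seed),
            class = "sim_config")
}

#' Simulate a sequencing run with per-read ground truth
#'
#' See [simulation_config()] for the generative model. With identical
#' `seed`, output is identical (single integer-seeded RNG stream).
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to `config$seed`; required in one of
#'   the two places).
#' @return An object of class `oreo_sim`: a list with
#'   `reads` (data.frame `id`, `sequence`, `quality`),
#'   `truth` (data.frame `id`, `origin` in amplicon/short/numt,
#'   `amplicon_id` - the amplicon, or the left amplicon of the junction for
#'   short products -, `start`, `end` genome coordinates of the template,
#'   `strand`, `extended`), `site_truth` (data.frame `id`, `position`,
#'   `template_allele`, `primer_forced` - whether the emitted base at the
#'   site was overwritten by primer-derived reference), and `config`.
#' @export
simulate_reads <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) stop("a seed is required for reproducible simulation")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  genome <- config$genome
  glen <- genome$length
  amp <- config$amplicons
  n_amp <- nrow(amp)
  u <- unwrap_amplicons(amp, glen)
  s <- u$start; e <- u$end
  plen <- as.integer(amp$primer_len)
  amp_seq <- vapply(seq_len(n_amp), function(i) extract_unwrapped(genome, s[i], e[i]),
                    character(1L))
  origin <- u$origin

  uw <- function(pos) origin + ((as.integer(pos) - origin) %% glen)
  hap <- config$sample_haplotype
  if (!is.null(hap)) hap$upos <- uw(hap$position)
  diag <- if (!is.null(config$numt)) config$numt$diagnostics else NULL
  if (!is.null(diag)) diag$upos <- uw(diag$position)

  ## internal primer blocks per amplicon (unwrapped ranges), from neighbours
  internal_blocks <- lapply(seq_len(n_amp), function(i) {
    blocks <- list()
    if (i > 1L) blocks <- c(blocks, list(c(e[i - 1L] - plen[i - 1L] + 1L, e[i - 1L])))
    if (i < n_amp) blocks <- c(blocks, list(c(s[i + 1L], s[i + 1L] + plen[i + 1L] - 1L)))
    blocks
  })
  in_blocks <- function(upos, blocks)
    any(vapply(blocks, function(b) upos >= b[1L] && upos <= b[2L], logical(1L)))

  n <- config$n_reads
  is_short <- stats::runif(n) < config$short_product_rate
  amp_id <- integer(n)
  amp_id[!is_short] <- sample.int(n_amp, sum(!is_short), replace = TRUE,
                                  prob = amp$yield)
  junction <- integer(n)  # short product between amplicon j and j+1
  if (n_amp < 2L && any(is_short)) stop("short products need at least two amplicons")
  junction[is_short] <- sample.int(n_amp - 1L, sum(is_short), replace = TRUE)

  numt_amp <- if (!is.null(diag))
    which(vapply(seq_len(n_amp), function(i)
      any(diag$upos >= s[i] & diag$upos <= e[i]), logical(1L)))
  else integer(0)
  is_numt <- logical(n)
  if (length(numt_amp) && !is.null(config$numt)) {
    cand <- !is_short & amp_id %in% numt_amp
    is_numt[cand] <- stats::runif(sum(cand)) < config$numt$fraction
  }
  extended <- logical(n)
  if (config$mode == "prototype" && config$overlap_extension_rate > 0)
    extended[!is_short] <- stats::runif(sum(!is_short)) < config$overlap_extension_rate

  seqs <- character(n)
  ustart <- integer(n); uend <- integer(n)
  ustart[is_short] <- s[junction[is_short] + 1L]
  uend[is_short] <- e[junction[is_short]]
  ustart[!is_short] <- s[amp_id[!is_short]]
  uend[!is_short] <- e[amp_id[!is_short]]
  for (j in seq_len(n_amp - 1L)) {
    idx <- which(is_short & junction == j)
    if (length(idx)) seqs[idx] <- extract_unwrapped(genome, s[j + 1L], e[j])
  }

  site_truth <- list()
  for (i in seq_len(n_amp)) {
    idx <- which(!is_short & amp_id == i)
    if (!length(idx)) next
    seqs[idx] <- amp_seq[i]
    own_footprint <- function(upos)
      upos <= s[i] + plen[i] - 1L || upos >= e[i] - plen[i] + 1L
    ## sample haplotype alleles (numt templates carry reference backbone)
    if (!is.null(hap)) {
      in_amp <- which(hap$upos >= s[i] & hap$upos <= e[i])
      for (k in in_amp) {
        off <- hap$upos[k] - s[i] + 1L
        tmpl_alt <- stats::runif(length(idx)) < hap$fraction[k]
        tmpl_alt[is_numt[idx]] <- FALSE
        forced <- rep(own_footprint(hap$upos[k]), length(idx)) |
          (extended[idx] & in_blocks(hap$upos[k], internal_blocks[[i]]))
        emit <- tmpl_alt & !forced
        if (any(emit))
          substr(seqs[idx[emit]], off, off) <- hap$alt[k]
        site_truth[[length(site_truth) + 1L]] <- data.frame(
          id = idx, position = hap$position[k],
          template_allele = ifelse(tmpl_alt, hap$alt[k], hap$ref[k]),
          primer_forced = forced)
      }
    }
    ## numt alleles at diagnostic sites
    if (!is.null(diag) && any(is_numt[idx])) {
      nidx <- idx[is_numt[idx]]
      in_amp <- which(diag$upos >= s[i] & diag$upos <= e[i])
      for (k in in_amp) {
        off <- diag$upos[k] - s[i] + 1L
        forced <- own_footprint(diag$upos[k]) |
          (extended[nidx] & in_blocks(diag$upos[k], internal_blocks[[i]]))
        emit <- !forced
        if (any(emit))
          substr(seqs[nidx[emit]], off, off) <- diag$numt_allele[k]
      }
    }
  }

  ## per-base substitution errors, applied last
  if (config$error_rate > 0) {
    lens <- nchar(seqs)
    nerr <- stats::rbinom(n, lens, config$error_rate)
    for (i in which(nerr > 0L)) {
      at <- sample.int(lens[i], nerr[i])
      for (p in at) {
        cur <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
  }

  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  rev <- strand == "-"
  if (any(rev)) seqs[rev] <- revcomp(seqs[rev])

  ids <- sprintf("read%07d", seq_len(n))
  reads <- data.frame(id = ids, sequence = seqs,
                      quality = strrep("I", nchar(seqs)))
  truth <- data.frame(
    id = ids,
    origin = ifelse(is_short, "short", ifelse(is_numt, "numt", "amplicon")),
    amplicon_id = ifelse(is_short, amp$id[pmax(junction, 1L)], amp$id[pmax(amp_id, 1L)]),
    start = rewrap_pos(ustart, glen), end = rewrap_pos(uend, glen),
    strand = strand, extended = extended)
  st <- if (length(site_truth)) {
    st <- do.call(rbind, site_truth)
    st$id <- ids[st$id]
    st[order(st$id, st$position), ]
  } else {
    data.frame(id = character(0), position = integer(0),
               template_allele = character(0), primer_forced = logical(0))
  }
  structure(list(reads = reads, truth = truth, site_truth = st, config = config),
            class = "oreo_sim")
}

#' @export
print.oreo_sim <- function(x, ...) {
  tab <- table(x$truth$origin)
  cat(sprintf("<oreo_sim> %d reads (%s mode): %s\n", nrow(x$reads), x$config$mode,
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Per-position depth track of a simulated run
#'
#' Computed from the simulation truth (template regions), i.e. the depth an
#' aligner would report for error-free mapping.
#'
#' @param sim an `oreo_sim` object.
#' @param span [circular_region()] over which to compute depth (default:
#'   the amplified span for an rCRS-length genome, else the whole genome).
#' @return Numeric vector of per-position depth, in span order.
#' @export
depth_track <- function(sim, span = NULL) {
  stopifnot(inherits(sim, "oreo_sim"))
  glen <- sim$config$genome$length
  if (is.null(span))
    span <- if (glen == RCRS_LENGTH) amplified_span() else circular_region(1L, glen)
  n <- region_length(span, glen)
  o1 <- ((sim$truth$start - span$start) %% glen) + 1L
  lens <- ((sim$truth$end - sim$truth$start) %% glen) + 1L
  o2 <- o1 + lens - 1L
  if (any(o2 > n)) stop("a simulated read extends outside the span")
  delta <- tabulate(o1, n + 1L) - tabulate(o2 + 1L, n + 1L)
  cumsum(delta)[seq_len(n)]
}

#' Compare calls against simulation ground truth
#'
#' @param sim an `oreo_sim` object.
#' @param calls an `oreo_calls` object from [call_region()].
#' @return A list of class `truth_comparison`: `per_site` data.frame
#'   (`position`, `true_fraction`, `estimated_fraction`, `true_status`,
#'   `called_status`, `matched` - whether the queried site exists in the
#'   simulated haplotype; unmatched sites are listed with true fraction 0),
#'   `confusion` (true x called status table) and `bias` (mean estimated -
#'   true fraction over sites with an estimate, percentage points).
#' @export
truth_compare <- function(sim, calls) {
  stopifnot(inherits(sim, "oreo_sim"), inherits(calls, "oreo_calls"))
  hap <- sim$config$sample_haplotype
  true_frac <- rep(0, nrow(calls))
  matched <- rep(FALSE, nrow(calls))
  if (!is.null(hap)) {
    m <- match(calls$position, hap$position)
    matched <- !is.na(m)
    true_frac[matched] <- 100 * hap$fraction[m[matched]]
  }
  true_status <- ifelse(true_frac == 0, "homoplasmic_ref",
                        ifelse(true_frac == 100, "homoplasmic_alt", "heteroplasmic"))
  per_site <- data.frame(position = calls$position, true_fraction = true_frac,
                         estimated_fraction = calls$alt_fraction,
                         true_status = true_status,
                         called_status = calls$status, matched = matched)
  ok <- !is.na(per_site$estimated_fraction)
  structure(list(
    per_site = per_site,
    confusion = table(true = factor(true_status, levels = SITE_STATUSES),
                      called = factor(calls$status, levels = SITE_STATUSES)),
    bias = if (any(ok)) mean(per_site$estimated_fraction[ok] - true_frac[ok]) else NA_real_),
    class = "truth_comparison")
}

#' @export
print.truth_comparison <- function(x, ...) {
  cat(sprintf("<truth_comparison> %d sites, mean bias %.2f percentage points\n",
              nrow(x$per_site), x$bias))
  keep <- rowSums(x$confusion) > 0 | colSums(x$confusion) > 0
  print(x$confusion[keep, keep, drop = FALSE])
  invisible(x)
}
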