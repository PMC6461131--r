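## Shared fixtures and independent brute-force oracles. Oracles are written
## as plain enumerations so they stay independent of the code paths they
## check.

toy_genome <- function(n, seed, circular = TRUE) {
  withr::with_seed(seed,
    ref_genome(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     collapse = ""),
               name = "toy", circular = circular))
}

other_base <- function(base) setdiff(c("A", "C", "G", "T"), base)[1L]

## Variant site taking ref from the genome, alt any other base.
site_at <- function(genome, pos) {
  r <- substr(genome$sequence, pos, pos)
  variant_site(pos, r, other_base(r))
}

## Brute-force region length: enumerate every position and test membership.
brute_region_length <- function(region, glen) {
  sum(vapply(seq_len(glen), function(p)
    region_contains(region, p, glen), logical(1L)))
}

## Brute-force read/probe matching: scan every substring of every read and
## of its reverse complement, comparing characters.
brute_match_count <- function(seqs, pattern) {
  L <- nchar(pattern)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  hits <- vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < L) return(FALSE)
    for (i in seq_len(n - L + 1L)) {
      sub <- substr(s, i, i + L - 1L)
      if (sub == pattern || sub == rc) return(TRUE)
    }
    FALSE
  }, logical(1L), USE.NAMES = FALSE)
  sum(hits)
}

## Brute-force probe design: enumerate every (start, length) placement,
## check coverage/boundary/specificity by direct string counting, and
## return the minimum feasible length (NA when none).
brute_min_probe_length <- function(genome, site, boundary, side,
                                   min_len = 10L, max_len = 30L, margin = 1L) {
  glen <- genome$length
  doubled <- paste0(genome$sequence, genome$sequence)
  getseq <- function(a, b) {
    a2 <- ((a - 1L) %% glen) + 1L
    substr(doubled, a2, a2 + (b - a))
  }
  count_in_genome <- function(pattern, seqstr) {
    subj <- paste0(seqstr, substr(seqstr, 1L, nchar(pattern) - 1L))  # circular
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
    n <- 0L
    for (i in seq_len(nchar(subj) - nchar(pattern) + 1L)) {
      sub <- substr(subj, i, i + nchar(pattern) - 1L)
      if (sub == pattern) n <- n + 1L
      if (sub == rc) n <- n + 1L
    }
    n
  }
  pos <- site$position
  d <- ((boundary - pos) %% glen)
  ub <- if (d > glen / 2) pos + d - glen else pos + d
  alt_seq <- genome$sequence
  substr(alt_seq, pos, pos) <- site$alt
  for (L in min_len:max_len) {
    for (a in (pos - L + 1L):pos) {
      b <- a + L - 1L
      if (side == "right" && b < ub + margin) next
      if (side == "left" && a > ub - margin) next
      ref_probe <- getseq(a, b)
      alt_probe <- ref_probe
      substr(alt_probe, pos - a + 1L, pos - a + 1L) <- site$alt
      if (count_in_genome(ref_probe, genome$sequence) != 1L) next
      if (count_in_genome(alt_probe, genome$sequence) != 0L) next
      if (count_in_genome(alt_probe, alt_seq) != 1L) next
      return(L)
    }
  }
  NA_integer_
}

## A small valid random amplicon chain on a toy circular genome.
random_chain <- function(n_amp, glen, seed) {
  withr::with_seed(seed, {
    repeat {
      lens <- sample(40:60, n_amp, replace = TRUE)
      overlaps <- if (n_amp > 1L) sample(10:18, n_amp - 1L, replace = TRUE) else integer(0)
      starts <- integer(n_amp); ends <- integer(n_amp)
      starts[1L] <- sample(glen, 1L)
      ends[1L] <- starts[1L] + lens[1L] - 1L
      ok <- TRUE
      for (i in seq_len(n_amp - 1L)) {
        starts[i + 1L] <- ends[i] - overlaps[i] + 1L
        ends[i + 1L] <- starts[i + 1L] + lens[i + 1L] - 1L
        if (i >= 1L && starts[i + 1L] <= ends[i] - lens[i] + 1L) ok <- FALSE
        if (i >= 2L && starts[i + 1L] <= ends[i - 1L] + 1L) ok <- FALSE
      }
      if (ok && ends[n_amp] - starts[1L] + 1L < glen) break
    }
    data.frame(id = seq_len(n_amp),
               start = ((starts - 1L) %% glen) + 1L,
               end = ((ends - 1L) %% glen) + 1L,
               primer_len = 5L, yield = 1)
  })
}

## Positions outside every primer footprint, pairwise spaced >= `spacing`.
unmasked_positions <- function(amplicons, primer_len, spacing = 12L,
                               glen = RCRS_LENGTH, n = Inf) {
  span <- amplified_span()
  upos <- span$start + seq_len(region_length(span, glen)) - 1L
  pos <- ((upos - 1L) %% glen) + 1L
  free <- !in_primer_region(pos, amplicons, primer_len, glen)
  keep <- integer(0); last <- -Inf
  for (i in seq_along(upos)) {
    if (free[i] && upos[i] - last >= spacing) {
      keep <- c(keep, pos[i]); last <- upos[i]
      if (length(keep) >= n) break
    }
  }
  keep
}

## 3-SD binomial half-width (percentage points) for a fraction at depth n.
binom_3sd_pp <- function(frac_pct, n) 300 * sqrt(frac_pct / 100 * (1 - frac_pct / 100) / n)
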