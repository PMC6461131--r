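test_that("allele fractions reproduce the worked read-count examples", {
  expect_identical(round(allele_fraction(allele_counts(7824 - 2966, 2966))), 38)
  expect_identical(round(allele_fraction(allele_counts(2998 - 2909, 2909))), 97)
  expect_identical(allele_fraction(allele_counts(100, 0)), 0)
  expect_warning(f <- allele_fraction(allele_counts(0, 0)), "no informative")
  expect_true(is.na(f))
})

test_that("probe pairs are minimal, equal length, boundary-crossing and allele-specific", {
  g <- toy_genome(60, seed = 101)
  site <- site_at(g, 30)
  pp <- design_probe_pair(g, site, boundary = 28, side = "left")
  expect_identical(pp$length, 10L)
  expect_identical(nchar(pp$ref_probe), nchar(pp$alt_probe))
  ## differs only at the queried site
  d <- which(strsplit(pp$ref_probe, "")[[1L]] != strsplit(pp$alt_probe, "")[[1L]])
  expect_length(d, 1L)
  ## spans the site and >= 1 base beyond the boundary (left side: below 28)
  expect_true(region_contains(pp$span, 30, 60))
  expect_true(region_contains(pp$span, 27, 60))
  ## the probe is reference sequence apart from the allele
  expect_identical(pp$ref_probe, extract_sequence(g, pp$span))
})

test_that("site exactly at a boundary forces extension on both sides", {
  g <- toy_genome(80, seed = 7)
  site <- site_at(g, 40)
  pp <- design_probe_pair(g, site, boundary = 40)
  expect_identical(pp$side, "both")
  expect_true(region_contains(pp$span, 39, 80))
  expect_true(region_contains(pp$span, 41, 80))
})

test_that("probe length grows to escape a duplicated context and matches the exhaustive oracle", {
  ## duplicate a 21-base block around the site elsewhere in the genome, so
  ## every short placement covering the site is ambiguous
  g0 <- toy_genome(200, seed = 13)
  s <- g0$sequence
  substr(s, 120, 140) <- substr(s, 38, 58)
  g <- ref_genome(s, name = "dup")
  site <- site_at(g, 50)
  pp <- design_probe_pair(g, site, boundary = 48, side = "left")
  expect_gt(pp$length, 10L)
  oracle <- brute_min_probe_length(g, site, boundary = 48, side = "left")
  expect_identical(pp$length, oracle)
})

test_that("designed probe length equals the brute-force minimum on random toy genomes", {
  for (seed in c(2, 5, 8, 12)) {
    g <- toy_genome(150, seed = seed)
    pos <- withr::with_seed(seed * 7, sample(40:110, 1L))
    site <- site_at(g, pos)
    for (conf in list(list(b = pos - 3L, side = "left"),
                      list(b = pos + 4L, side = "right"))) {
      oracle <- brute_min_probe_length(g, site, conf$b, conf$side)
      if (is.na(oracle)) {
        expect_error(design_probe_pair(g, site, conf$b, side = conf$side),
                     "no specific probe")
      } else {
        pp <- design_probe_pair(g, site, conf$b, side = conf$side)
        expect_identical(pp$length, oracle)
      }
    }
  }
})

test_that("sites with no specific probe fail with a named error", {
  ## a genome that is one repeated 10-mer: nothing short is unique
  unit <- "ACGTACGGTC"
  g <- ref_genome(strrep(unit, 12), name = "rep")
  site <- site_at(g, 55)
  expect_error(design_probe_pair(g, site, boundary = 53, side = "left"),
               "no specific probe.*55")
})

test_that("exact matching counts reads per allele and respects strand and N rules", {
  g <- toy_genome(120, seed = 31)
  site <- site_at(g, 60)
  pp <- design_probe_pair(g, site, boundary = 57, side = "left")
  ref_read <- extract_sequence(g, circular_region(40, 85))
  mut <- ref_read
  substr(mut, 60 - 40 + 1, 60 - 40 + 1) <- site$alt
  one_err <- ref_read
  substr(one_err, 55 - 40 + 1, 55 - 40 + 1) <- other_base(substr(ref_read, 16, 16))
  n_read <- ref_read
  substr(n_read, 58 - 40 + 1, 58 - 40 + 1) <- "N"
  rc_alt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mut)))
  ct <- oreo_filter(c(ref_read, mut, one_err, n_read, rc_alt), pp)
  expect_identical(ct$ref_count, 1L)
  expect_identical(ct$alt_count, 2L)  # forward alt + reverse-complement alt
  expect_identical(ct$total_considered, 3L)
  ## a probe longer than every read yields zero counts with a warning
  expect_warning(z <- oreo_filter(substr(ref_read, 1, 8), pp), "longer than every read")
  expect_identical(z$total_considered, 0L)
})

test_that("filter counts equal a brute-force substring scan over a simulated read set", {
  g <- synthetic_rcrs()
  amp <- default_amplicons()
  pos <- 16180  # inside amplicon 1's right footprint, overlap with amplicon 2
  site <- site_at(g, pos)
  hap <- data.frame(position = pos, ref = site$ref, alt = site$alt, fraction = 0.4)
  cfg <- simulation_config(g, amp, mode = "prototype", n_reads = 1000,
                           sample_haplotype = hap, short_product_rate = 0.4,
                           error_rate = 0.005, seed = 17)
  sim <- simulate_reads(cfg)
  pp <- design_probe_pair(g, site, boundary = 16188, side = "right")
  ct <- oreo_filter(sim, pp)
  expect_identical(ct$ref_count, brute_match_count(sim$reads$sequence, pp$ref_probe))
  expect_identical(ct$alt_count, brute_match_count(sim$reads$sequence, pp$alt_probe))
})

test_that("enrichment recovers a primer-shadowed fraction the naive pileup underestimates", {
  g <- synthetic_rcrs()
  amp <- default_amplicons()
  pos <- 16175
  site <- site_at(g, pos)
  hap <- data.frame(position = pos, ref = site$ref, alt = site$alt, fraction = 0.30)
  cfg <- simulation_config(g, amp, mode = "prototype", n_reads = 20000,
                           sample_haplotype = hap, short_product_rate = 0.5,
                           error_rate = 0.002, seed = 42)
  sim <- simulate_reads(cfg)
  pp <- design_probe_pair(g, site, boundary = 16188, side = "right")
  f_oreo <- allele_fraction(oreo_filter(sim, pp))
  f_naive <- allele_fraction(naive_site_counts(sim, g, site))
  expect_lt(f_naive, 30 - 10)   # materially below truth
  n <- oreo_filter(sim, pp)$total_considered
  expect_lt(abs(f_oreo - 30), binom_3sd_pp(30, n))
})

test_that("equal-length pairs keep the estimate unbiased across error rates", {
  g <- synthetic_rcrs()
  amp <- default_amplicons()
  pos <- 16175
  site <- site_at(g, pos)
  pp <- design_probe_pair(g, site, boundary = 16188, side = "right")
  hap <- data.frame(position = pos, ref = site$ref, alt = site$alt, fraction = 0.30)
  for (e in c(0, 0.005, 0.01)) {
    cfg <- simulation_config(g, amp, mode = "prototype", n_reads = 30000,
                             sample_haplotype = hap, short_product_rate = 0.4,
                             error_rate = e, seed = 100 + round(1000 * e))
    sim <- simulate_reads(cfg)
    ct <- oreo_filter(sim, pp)
    expect_lt(abs(allele_fraction(ct) - 30),
              binom_3sd_pp(30, ct$total_considered) + 0.5)
  }
})

test_that("insertion probes share length with their reference partner and match alt reads", {
  g <- toy_genome(100, seed = 55)
  pos <- 50
  refb <- substr(g$sequence, pos, pos)
  ins <- variant_site(pos, refb, paste0(refb, "A"))  # single-base insertion
  pp <- design_probe_pair(g, ins, boundary = 47, side = "left")
  expect_identical(nchar(pp$ref_probe), nchar(pp$alt_probe))
  ## a read from the insertion haplotype contains the alt probe
  hapseq <- paste0(substr(g$sequence, 20, pos), "A", substr(g$sequence, pos + 1, 80))
  ct <- oreo_filter(c(hapseq, extract_sequence(g, circular_region(20, 80))), pp)
  expect_identical(ct$alt_count, 1L)
  expect_identical(ct$ref_count, 1L)
})

test_that("naive anchored counts agree with per-position truth on clean reads", {
  g <- synthetic_rcrs()
  amp <- default_amplicons()
  pos <- 16320  # centre of a non-overlap segment, no primer shadow
  site <- site_at(g, pos)
  hap <- data.frame(position = pos, ref = site$ref, alt = site$alt, fraction = 0.25)
  cfg <- simulation_config(g, amp, mode = "prototype", n_reads = 20000,
                           sample_haplotype = hap, short_product_rate = 0.3,
                           error_rate = 0, seed = 77)
  sim <- simulate_reads(cfg)
  ct <- naive_site_counts(sim, g, site)
  ## compare against simulator truth restricted to emitted (non-forced) alleles
  st <- sim$site_truth[sim$site_truth$position == pos & !sim$site_truth$primer_forced, ]
  expect_identical(ct$alt_count, sum(st$template_allele == site$alt))
  expect_lt(abs(allele_fraction(ct) - 25), binom_3sd_pp(25, ct$total_considered))
})
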