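test_that("threshold tiers classify the worked examples correctly", {
  proto <- threshold_set("prototype")
  nested <- threshold_set("nested")
  ## 97% of 2998 reads: above the 90% window bound -> a SNP
  expect_identical(classify_site(allele_counts(2998 - 2909, 2909), proto)$status,
                   "homoplasmic_alt")
  ## 22% at a primer-site position is callable with the nested chemistry
  expect_identical(classify_site(allele_counts(780, 220), nested,
                                 in_primer_region = TRUE)$status,
                   "heteroplasmic")
  ## ... but masked with the prototype chemistry
  expect_identical(classify_site(allele_counts(780, 220), proto,
                                 in_primer_region = TRUE)$status,
                   "uncallable_primer_region")
  ## below the 20x analytical threshold
  expect_identical(classify_site(allele_counts(10, 9), proto)$status,
                   "uncallable_low_coverage")
  ## 3.75% under the nested 5% detection bound -> reference
  expect_identical(classify_site(allele_counts(385, 15), nested)$status,
                   "homoplasmic_ref")
  ## apparent heteroplasmy whose minor component misses 20x is demoted
  expect_identical(classify_site(allele_counts(90, 12), proto)$status,
                   "uncallable_low_coverage")
  ## window bounds are inclusive for heteroplasmy
  expect_identical(classify_site(allele_counts(900, 100), proto)$status,
                   "heteroplasmic")
  expect_identical(classify_site(allele_counts(100, 900), proto)$status,
                   "heteroplasmic")
})

test_that("classification is total and monotone in the window bounds", {
  proto <- threshold_set("prototype")
  wide <- threshold_set("prototype", het_window = c(5, 95))
  withr::with_seed(99, {
    for (k in 1:300) {
      ct <- allele_counts(sample(0:500, 1L), sample(0:500, 1L))
      primer <- sample(c(TRUE, FALSE), 1L)
      st_narrow <- classify_site(ct, proto, primer)$status
      st_wide <- classify_site(ct, wide, primer)$status
      expect_true(st_narrow %in% c("homoplasmic_ref", "homoplasmic_alt",
                                   "heteroplasmic", "uncallable_low_coverage",
                                   "uncallable_primer_region", "no_call"))
      ## raising thresholds (wide -> narrow window) never turns a homoplasmic
      ## call heteroplasmic
      if (st_wide %in% c("homoplasmic_ref", "homoplasmic_alt"))
        expect_false(st_narrow == "heteroplasmic")
    }
  })
})

test_that("validation arithmetic reports the conservative false-positive rate", {
  v <- validation_rate(6, 480)
  expect_equal(v$false_positive_rate, 1.25)
  calls <- data.frame(position = c(100, 200, 300), alt = c("T", "G", "A"),
                      status = c("homoplasmic_alt", "homoplasmic_alt", "homoplasmic_ref"))
  refset <- data.frame(position = c(100, 400), alt = c("T", "C"))
  cmp <- compare_callsets(calls, refset)
  expect_identical(cmp$discrepant, 1L)   # 200G not in the reference set
  expect_identical(cmp$missed, 1L)       # 400C not called
})

test_that("clean simulated SNPs are called homoplasmic alternative everywhere", {
  g <- synthetic_rcrs()
  amp <- default_amplicons()
  positions <- c(16320, 16175, 330)  # non-overlap centre, primer shadow, non-overlap
  sites <- lapply(positions, function(p) site_at(g, p))
  hap <- data.frame(position = positions,
                    ref = sapply(sites, `[[`, "ref"),
                    alt = sapply(sites, `[[`, "alt"), fraction = 1)
  cfg <- simulation_config(g, amp, mode = "prototype", n_reads = 15000,
                           sample_haplotype = hap, short_product_rate = 0.3,
                           error_rate = 0.002, seed = 31)
  sim <- simulate_reads(cfg)
  calls <- call_region(sim, g, amp, sites, threshold_set("prototype"))
  expect_identical(calls$status, rep("homoplasmic_alt", 3))
  expect_identical(sum(calls$status == "heteroplasmic"), 0L)
  ## the shadowed site was routed through enrichment, the others naively
  expect_identical(calls$method[match(16175, calls$position)], "oreo")
  expect_identical(calls$method[match(16320, calls$position)], "naive")
  s <- summary(calls)
  expect_identical(as.integer(s[["homoplasmic_alt"]]), 3L)
})

test_that("internalised primers mimic heteroplasmy and are masked in prototype mode", {
  g <- synthetic_rcrs()
  amp <- default_amplicons()
  pos <- 16175
  site <- site_at(g, pos)
  hap <- data.frame(position = pos, ref = site$ref, alt = site$alt, fraction = 1)
  cfg <- simulation_config(g, amp, mode = "prototype", n_reads = 20000,
                           sample_haplotype = hap, short_product_rate = 0.3,
                           overlap_extension_rate = 0.4, error_rate = 0.002,
                           seed = 8)
  sim <- simulate_reads(cfg)
  calls <- call_region(sim, g, amp, list(site), threshold_set("prototype"))
  ## enrichment alone cannot remove internalised blocks: apparent heteroplasmy
  expect_true(calls$alt_fraction < 90)
  expect_identical(calls$status, "uncallable_primer_region")
})

test_that("nested chemistry calls a 22% heteroplasmy lying under a primer site", {
  g <- synthetic_rcrs()
  amp <- default_amplicons()
  pos <- 16175
  site <- site_at(g, pos)
  hap <- data.frame(position = pos, ref = site$ref, alt = site$alt, fraction = 0.22)
  cfg <- simulation_config(g, amp, mode = "nested", n_reads = 20000,
                           sample_haplotype = hap, short_product_rate = 0.3,
                           error_rate = 0.002, seed = 12)
  sim <- simulate_reads(cfg)
  kept <- size_select(sim$reads, 95)$reads
  calls <- call_region(kept, g, amp, list(site), threshold_set("nested"))
  expect_identical(calls$status, "heteroplasmic")
  expect_lt(abs(calls$alt_fraction - 22), 3)
})

test_that("fraction recovery is within binomial error across the heteroplasmy range", {
  g <- synthetic_rcrs()
  amp <- default_amplicons()
  ## five shadowed sites in five different overlaps, one per queried fraction
  positions <- c(16175, 16420, 16510, 220, 440)
  boundaries <- c(16188, 16433, 16521, 231, 447)  # right ends of amplicons 1,3,4,6,8
  fracs <- c(0.05, 0.10, 0.20, 0.38, 0.50)
  sites <- lapply(positions, function(p) site_at(g, p))
  hap <- data.frame(position = positions,
                    ref = sapply(sites, `[[`, "ref"),
                    alt = sapply(sites, `[[`, "alt"), fraction = fracs)
  cfg <- simulation_config(g, amp, mode = "nested", n_reads = 90000,
                           sample_haplotype = hap, short_product_rate = 0.3,
                           error_rate = 0.002, seed = 61)
  sim <- simulate_reads(cfg)
  for (i in seq_along(positions)) {
    pp <- design_probe_pair(g, sites[[i]], boundaries[i], side = "right")
    ct <- oreo_filter(sim, pp)
    expect_gt(ct$total_considered, 1000)
    expect_lt(abs(allele_fraction(ct) - 100 * fracs[i]),
              binom_3sd_pp(100 * fracs[i], ct$total_considered))
  }
})

test_that("heteroplasmic status is recovered in repeated runs for fractions >= 10%", {
  g <- synthetic_rcrs()
  amp <- default_amplicons()
  pos <- 16300  # non-overlap segment of amplicon 3: naive counting path
  site <- site_at(g, pos)
  nested <- threshold_set("nested")
  for (frac in c(0.10, 0.20, 0.50)) {
    hap <- data.frame(position = pos, ref = site$ref, alt = site$alt, fraction = frac)
    status <- vapply(1:5, function(rep) {
      cfg <- simulation_config(g, amp, mode = "nested", n_reads = 15000,
                               sample_haplotype = hap, short_product_rate = 0.3,
                               error_rate = 0.002, seed = 500 + rep)
      sim <- simulate_reads(cfg)
      calls <- call_region(sim, g, amp, list(site), nested)
      calls$status
    }, character(1L))
    expect_true(all(status == "heteroplasmic"))
  }
})

test_that("probe design failure propagates as a reasoned no-call", {
  g <- synthetic_rcrs()
  amp <- default_amplicons()
  site <- site_at(g, 16175)
  expect_error(variant_site(16175, "A", "A"))
  wrong_ref <- variant_site(16175, other_base(site$ref), site$ref)
  cfg <- simulation_config(g, amp, mode = "prototype", n_reads = 500,
                           short_product_rate = 0.3, error_rate = 0, seed = 3)
  sim <- simulate_reads(cfg)
  calls <- call_region(sim, g, amp, list(wrong_ref), threshold_set("prototype"))
  expect_identical(calls$status, "no_call")
  expect_match(calls$note, "reference at position")
})
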