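---
title: "Removing primer-derived reference bias from overlapping-amplicon mtDNA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing primer-derived reference bias from overlapping-amplicon mtDNA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oreo)
```

## The problem

Single-multiplex sequencing of the mtDNA control region amplifies ten
overlapping 144–237-bp amplicons spanning rCRS positions 15,989–619 (1200
positions across the circular origin; the control region proper is
16,024–576, 1122 bp). Three mechanisms put *reference* alleles into reads
irrespective of the template:

1. **Read ends.** Each read begins and ends in primer sequence, synthesised
   from the reference design, over a footprint of roughly 20–26 bases.
2. **Short overlap products.** Primer pairs from neighbouring amplicons
   generate by-products the length of the overlap itself (52–91 bp). These
   amplify preferentially and are almost entirely primer-derived.
3. **Overlap extension** (single-reaction "prototype" chemistry only).
   Overlapping single-stranded products anneal and prime synthesis from an
   already incorporated primer end, internalising reference-allele blocks
   *inside* read bodies. Nested chemistry blocks this by flanking amplicons
   with adapters in the same PCR step.

At a site under a primer footprint the pileup allele fraction mixes genuine
template reads with primer-derived reference reads: homoplasmic variants
drop into the heteroplasmy window and look like mixtures, and real
heteroplasmy fractions are underestimated. Because commercial primer
sequences are proprietary, exact trimming is impossible, and blind
fixed-length trimming either leaves bias (too short) or opens coverage gaps
(too long).

## Overarching read enrichment

For a queried site near an amplicon end, `design_probe_pair()` builds two
probes of one shared length \(L \in [10, 30]\) that

- cover the site, differing only at the queried allele;
- extend at least `margin` (default 1) bases beyond the amplicon-end
  `boundary`; and
- occur, each carrying its own allele, exactly once on either strand
  within the amplified span (15,989–619). Span-level rather than
  genome-wide uniqueness suffices because only control-region amplicons
  are sequenced.

`oreo_filter()` counts a read for an allele only if the read contains that
probe as an exact, contiguous substring (forward or reverse-complement; `N`
never matches). A read whose sequence at the site is primer-derived ends at
the amplicon boundary and cannot contain a probe that crosses it, so only
overarching reads from the neighbouring amplicon are counted. The returned
fraction is `100 * alt / (ref + alt)`.

Exactness is deliberate: a read with any error under the probe is lost, but
because the pair shares length and differs at one base, the expected loss
is identical for both alleles and the fraction stays unbiased (verified in
the test suite across error rates 0–1%). The search returns the *shortest*
specific pair — minimising symmetric loss — breaking ties by the most
symmetric extension around the site, then the leftmost start. Indel queries
build the alternative probe with the inserted/deleted bases and rebalance
the flank away from the boundary so both probes keep the same length.

**Probe backbones.** By default probes are reference sequence apart from
the queried allele. When several biased SNPs cluster inside one footprint,
a probe for one site inevitably spans its neighbours, and a
reference-backbone pair would match no sample read at all. The
`consensus_backbone` option of `call_region()` therefore runs a first naive
pass and carries the alternative alleles of other queried sites detected
above the detection threshold into the probe backbone. Both probes of a
pair share the backbone, so any extra loss at sites where a backbone allele
is itself polymorphic remains symmetric; it costs depth, not accuracy
(alleles at distinct sites are treated as independent — linkage between
heteroplasmic sites on one molecule is not modelled).

## The naive comparator and aligned input

Sites in non-overlapping segments need no correction and are counted by
`naive_site_counts()`: a read supports allele *a* if it contains `flank`
(default 10) reference bases immediately left of the site followed by *a*,
or *a* followed by the right flank, on either strand. One-sided anchors
matter: a read that terminates at an amplicon or short-product end still
contributes its primer-derived base, exactly as an alignment pileup would —
this is what preserves the bias the enrichment is judged against. Flank 10
makes an 11-mer anchor, short enough to sit inside any product yet specific
within the 1200-bp span; queried sites should be at least 12 bases apart.
For aligned data, `read_pileup_counts()` and `depth_track_bam()` take
BAM/SAM input instead.

## Classification

`threshold_set()` fixes the tiers: 20× analytical depth (no call below it),
20× minor-component depth for a heteroplasmic call, 5% detection, and an
inclusive heteroplasmy window — 10–90% for prototype data, 5–95% for nested
data after size selection and enrichment. Decisions use exact fractions;
rounding is display-only. Two policy choices deserve note:

- An apparent heteroplasmy whose minor component misses 20× is demoted to
  `uncallable_low_coverage`, not called homoplasmic: absence of the minor
  allele is not asserted from thin evidence.
- In prototype mode, an apparently heteroplasmic site within 27 bases of
  any amplicon end (`in_primer_region()`; 27 bp is the observed extent of
  biased SNPs from amplicon ends) is `uncallable_primer_region`, because
  overlap extension can leave internalised reference blocks that even
  overarching reads carry. Nested chemistry prevents overlap extension, so
  no masking applies there and sub-primer heteroplasmies are callable.

Window bounds are treated as inclusive for heteroplasmy; the choice is
recorded here because the convention at exactly 10% or 90% is otherwise
ambiguous.

## Size selection and numt screening

`size_select()` retains reads of at least 95 bases (inclusive), removing
the 52–91-bp short products while no designed amplicon (≥144 bp) can be
lost; any cutoff in 92–95 would separate the modes, and 95 matches the
convention used with standard read-trimming tools. `length_profile()`
exposes the bimodal length histogram that motivates the cutoff.

`numt_fraction()` quantifies co-amplified nuclear mtDNA copies from a
user-supplied table of diagnostic sites (position, mt allele, numt allele),
pooling numt-supporting over informative reads across sites. The presence
flag requires a pooled fraction of at least 0.1% *and* three individually
supported sites; because numt visibility depends on the relative
amplification of the nuclear template, the absence of the flag never
asserts absence of the insertion. Diagnostic alleles are not bundled: the
published diagnostic positions for the known chromosome-11 insertion are
not reproduced in machine-readable form, and hard-coding guesses would be
worse than requiring a table.

## The simulator

`simulate_reads()` emits full-length single-end amplicon reads (600-cycle
paired-end chemistry fully spans these amplicons after merging, so a
merged-read model avoids simulating a merging stage). Per read: a template
class is drawn (short product with probability `short_product_rate`,
default 0.3, chosen so the overlap-coverage excess is clearly visible —
the true proportion in real libraries is not published; otherwise a
designed amplicon by relative yield); template alleles at haplotype sites
are drawn per-molecule from the configured fractions; positions within
primer footprints (default 22 bases per end, inside the published 20–26
range) emit reference regardless of template; in prototype mode a fraction
`overlap_extension_rate` of molecules also emit reference across the
internalised footprints of neighbouring amplicon ends. numt templates carry
numt alleles at diagnostic sites at a configured fraction of the yield of
each amplicon containing such a site. Uniform per-base substitution errors
(default 0.002) are applied last; strands are drawn 50/50; qualities are
constant because the method never consults them.

`overlap_extension_rate` defaults to 0: no rate is published, and the
recovery properties the package promises (estimates within binomial error
of truth) are properties of end-derived bias, which enrichment removes
completely. Extension is switched on explicitly to study the residual-bias
regime that motivates prototype-mode masking; with it enabled, enrichment
is knowingly biased low by about the extension rate — that is the
phenomenon, not an estimator defect. The simulator does not model PCR
kinetics, chimeras beyond overlap extension, instrument error profiles,
indel errors, or length heteroplasmy in homopolymer tracts; conclusions
from passing tests extend to real data only in so far as the bias really is
primer-placement-driven.

Determinism: one integer seed drives a single RNG stream; identical seeds
give byte-identical FASTQ. The global RNG state is saved and restored.

## Numerical and scale choices

- Boundary detection scores the relative change `|d(p+1)−d(p)|/max(d(p),1)`
  (scale-free across multiplexing depths), takes the expected number of
  largest scores greedily with a minimum spacing (`window`, default 10 bp),
  ignores changes below `min_change = 0.25`, and reports drops as the last
  high position, rises as the first high position. Track ends are padded
  with zero depth so the outermost amplicon ends are detectable.
- Low-coverage flagging compares each non-overlap segment with the mean of
  all other segments at a fold threshold of 5 — conservative against the
  ~13-fold suppression seen when primer-site variants inhibit one amplicon.
- Coverage means are arithmetic per position; segment means are normalised
  to the per-sample span mean (normalisation after segment averaging; the
  alternative order is noted in output metadata by this choice being
  stated here).
- Test and acceptance simulations use 20,000–160,000 reads: large enough
  that three-binomial-SD tolerances sit at or below two percentage points
  at the depths being checked, small enough to run interactively.
- The bundled reference is a deterministic synthetic 16,569-bp circular
  genome; every documented behaviour depends only on length and topology.
  The bundled amplicon table is an approximate reconstruction satisfying
  all published design constraints (span 15,989–619, lengths 144–237,
  overlaps 52–91, valid chain) and is labelled approximate.

## Known limitations

Multi-allelic sites are handled pairwise (third alleles land in
`other_count`); homopolymer tracts and the AC repeat are outside
substitution calling and their length heteroplasmy is not quantified;
probes are not designed against multi-contig references; no
mixture/two-contributor deconvolution; no fuzzy probe matching. The
simulator's independence of alleles across sites means haplotype-phased
heteroplasmy is not represented.
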