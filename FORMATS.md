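# File formats

All tabular files are tab-separated with a header row. Positions are 1-based
inclusive rCRS coordinates; intervals may wrap through the origin
(start > end). Allele columns are read as character, so a lone `T` is never
coerced to a logical.

## Amplicon table (`read_amplicon_table`)

| column | meaning |
|---|---|
| `id` | amplicon identifier, chain order |
| `start` | outer 5' position (includes the primer footprint) |
| `end` | outer 3' position |
| `primer_len` | optional; primer footprint length per end (default 22) |
| `yield` | optional; relative amplification yield (default 1) |

## Variant-site query list (`read_site_table`)

`position`, `ref`, `alt`. Indels are VCF-style: insertion `ref=C`,
`alt=CT` (the forensic "44.1C" anchored at 44); deletion `ref=CT`, `alt=C`.

## Probe table (`write_probe_table` / `read_probe_table`)

`position`, `ref`, `alt`, `boundary`, `side`, `ref_probe`, `alt_probe`.

## numt diagnostic table (`read_diagnostic_table`)

`position`, `mt_allele`, `numt_allele`.

## Sample haplotype (simulator config `haplotype`)

`position`, `ref`, `alt`, `fraction` (per-molecule alternative-allele
probability; 1 = homoplasmic alternative).

## Calls TSV (`write_calls_tsv`)

`position`, `ref`, `alt`, `method` (`oreo`/`naive`), `in_primer`,
`ref_count`, `alt_count`, `other_count`, `alt_fraction` (percent, full
precision), `status`, `note`.

## Calls VCF (`write_calls_vcf`)

Minimal VCFv4.2; CHROM is the contig name (default `chrM`), INFO carries
`DP` (ref+alt informative reads), `AF` (alternative fraction, 0-1),
`STATUS`, `MODE`. FILTER repeats the status for uncallable/no-call sites.

## Run configuration (`oreo simulate --config`)

`key = value` lines, `#` comments. Keys: `genome` (FASTA path or
`synthetic`), `amplicons`, `mode` (`prototype`/`nested`), `n_reads`,
`short_product_rate`, `overlap_extension_rate`, `error_rate`, `haplotype`,
`numt_diagnostics`, `numt_fraction`, `seed`.

## Run report / size-selection summary

Two columns `key`, `value`; stage counts reconcile
(`reads_in = retained + removed`).
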