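# hotspotter

Identification of significantly mutated genomic regions ("mutational
hotspots") across cohorts of tumor/normal sample pairs, starting from raw
per-sample variant calls.

Cohort cancer studies need more than a variant caller: raw calls are a mix
of true somatic events, germline variants the caller failed to subtract,
known polymorphisms and sequencing/mapping artifacts, and "significance" of
a region only means something relative to the cohort's background mutation
rate. `hotspotter` implements the full chain as five phases:

1. **Extraction** — import per-sample VCFs and tumor/normal metadata into a
   variant store; keep only *cancer-exclusive* variants: present in ≥ 1
   cohort tumor, absent from every normal in the store (matched or not —
   the panel of normals) and from every named known-polymorphism set
   (DBSNP-like VCFs). Variants are collapsed across carrier samples;
   tumor variants seen in normals go to a separate germline-candidate list.
2. **Annotation** — interval-indexed annotation store (BED sets plus gene
   models from GTF, with derived exons/introns/UTRs); each variant gets its
   overlapping records and a coding-effect label
   (synonymous / non-synonymous / non-coding) from codon translation,
   strand-aware.
3. **Clustering** — level one groups variants by genomic proximity
   (single-linkage chaining, gap threshold `gap_bp`); level two merges
   proximity clusters that share an annotated region into hotspots, with
   unannotated clusters kept as *novel* regions.
4. **Validation** — every (variant, carrier) pair is re-examined jointly in
   tumor and matched-normal pileups and triaged **somatic / germline /
   artifact** by an ordered threshold rule on quality-filtered
   alt-supporting reads; per-region side-by-side alignment-profile HTML
   pages are written for QC.
5. **Scoring & reporting** — each region with `k` somatic variant–sample
   observations in `n = length x samples` trials is tested against the
   background per-base rate `mu` with the binomial upper tail
   `P(X >= k), X ~ Binomial(n, mu)`; q-values by Benjamini–Hochberg;
   per-cohort enrichment by one-sided Fisher (hypergeometric) tests. The
   output is a ranked, hyperlinked HTML report plus three UCSC custom
   tracks (all SNVs, target regions, verified variants).

A first-class **simulator** (`sim_config()`, `simulate_all()`) generates a
complete hermetic study — reference, gene models, cohort VCFs, polymorphism
set, coordinate-sorted SAM alignments and a machine-readable truth table —
so every phase is testable without external data.

## Worked example

Simulate a four-pair lymphoma cohort with one implanted hotspot at 60x the
background rate, then run the whole pipeline:

```r
library(hotspotter)

cfg <- sim_config(seed = 42, genome_length = 40000L,
                  cohorts = c(lymphoma = 4L), background_rate = 1.5e-4,
                  n_genes = 4L, polymorphism_set_size = 40L, poly_overlap_n = 8L,
                  hotspots = list(list(start = 6001L, end = 6500L,
                                       fold = 60, min_carriers = 3L)))
sim <- simulate_all(cfg, "fixtures")

rc <- run_config(
  metadata = sim$cohort$metadata_path, vcfs = sim$cohort$vcfs,
  reference = sim$fasta, gtf = sim$gtf,
  polymorphisms = c(dbsnp = sim$cohort$polymorphism_path),
  cohort = "lymphoma", out_dir = "out",
  tumor_alignments  = sim$alignments[grep("^T", names(sim$alignments))],
  normal_alignments = sim$alignments[grep("^N", names(sim$alignments))])
bundle <- run_pipeline(rc)
```

The run log prints one line per phase:

```
phase one: 8 samples, 62 variants in store, 29 cancer-exclusive, 4 germline-candidate
phase two: 22 annotation records, 4 gene models; 0/29 variants annotated
phase three: 9 proximity clusters -> 9 hotspots (8 novel)
phase four: 33 pairs validated (33 somatic, 0 germline, 0 artifact, 0 unknown)
phase five: background 0.000206 /bp/sample; 9 hotspots scored, 8 at q < 0.05
```

and `tidy(bundle$results)` gives the ranked table (broom-style `tidy()` and
`glance()` methods, and an `autoplot()` Manhattan view, are provided):

```
   rank region_name   region_category     k    p_raw  q_value
1     1 novel_1_5263  novel              22 3.38e-22 3.05e-21
2     2 novel_1_7894  novel               1 8.25e- 4 1.24e- 3
...
```

Rank 1 is the implanted region: 22 somatic observations against a
background of `2.06e-4` per base per sample — 29 cancer-exclusive variants
survived the normal/polymorphism filters (the 62 imported calls included
planted germline and polymorphism sites), and all 33 (variant, carrier)
pairs validated somatic from the synthetic pileups. The singleton regions
below it illustrate a real caveat of scoring data-defined novel regions at
footprint length (their single variant is their own evidence); see the
methods vignette (`vignettes/hotspot-methods.Rmd`) for why, and prefer
annotated categories when it matters. `out/report/report.html` links each
rank to its per-region QC page and the three UCSC tracks sit in
`out/report/tracks/`.

A thin CLI (`inst/scripts/hotspotter.R`) wraps the same two entry points:
`hotspotter.R simulate --seed 1 --out fixtures/` and
`hotspotter.R run --config run.yaml` (see `?read_run_config`).

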