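---
title: "Detecting mutational hotspots in tumor/normal cohorts: methods and design"
author: "hotspotter authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mutational hotspots in tumor/normal cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotter)
```

## The problem

Cohort studies of cancer genomes ask a deceptively simple question: *which
genomic regions are mutated more often across tumors than chance allows?*
Answering it from raw variant-caller output requires a chain of steps, each
of which can silently corrupt the answer: germline variation and known
polymorphisms masquerade as somatic events, sequencing and mapping artifacts
inflate counts, and a region's significance depends on a background mutation
rate that must itself be estimated from the data. `hotspotter` implements
this chain as five phases over a cohort of tumor/normal pairs:

1. **Extraction** — collect per-sample variant calls in a store, subtract
   everything seen in any normal sample (matched or not — the panel of
   normals) and in named known-polymorphism sets, and collapse the survivors
   across carriers ("cancer-exclusive" variants).
2. **Annotation** — label each variant with the annotated regions it
   overlaps (genes, exons, introns, UTRs, promoters, enhancers, TFBS, ...)
   and a coding-effect class: synonymous, non-synonymous or non-coding.
3. **Clustering** — group variants first by genomic proximity
   (single-linkage chaining under a gap threshold), then attach proximity
   clusters to shared annotated regions; clusters touching nothing become
   *novel* candidate regions.
4. **Validation** — re-examine every (variant, carrier) pair jointly in
   the tumor and matched-normal read pileups, and triage it as somatic,
   germline or artifact.
5. **Scoring and reporting** — test each region's somatic load against the
   background rate with a binomial model, correct with Benjamini–Hochberg,
   test per-cohort enrichment with one-sided Fisher tests, and emit a
   ranked HTML report with UCSC custom tracks and per-region QC pages.

## The statistical model

Let $\mu$ be the per-base per-sample somatic mutation probability,
estimated genome-wide as

$$\hat\mu = \frac{\text{somatic variant–sample observations}}
{\text{callable length} \times \text{number of samples}}.$$

Hotspot regions are deliberately *not* excluded from the numerator: the
resulting rate is slightly inflated by true hotspots, which makes the test
conservative. For a region of length $L$ observed in $S$ samples with $k$
somatic variant–sample observations, the raw p-value is the binomial upper
tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(L \cdot S,\ \hat\mu),$$

computed through the regularized incomplete beta function so that it is
stable for $L \cdot S$ up to $10^9$ and exact at $k = 0$ ($p = 1$). A site
mutated in three samples contributes $k = 3$: the binomial trials are
(base, sample) pairs. A configuration flag switches to counting distinct
sites instead. Raw p-values are adjusted across all scored regions with the
Benjamini–Hochberg step-up rule; ranking is by q-value with ties broken by
raw p, then by descending $k$, so re-scoring identical input reproduces
identical ranks.

Per-cohort enrichment uses the one-sided hypergeometric tail on the
2×2 table (mutated / unmutated) × (in cohort / out of cohort) over tumor
samples — enrichment direction only, since the question is which cancer
types concentrate mutations in the region.

## The verdict rule

Validation drops pileup entries below the mapping-quality and base-quality
floors and then applies, in order: (1) fewer than `min_alt_tumor`
alt-supporting tumor reads → **artifact**; (2) at least `min_alt_normal`
alt-supporting normal reads → **germline**; (3) otherwise → **somatic**.
The artifact check deliberately precedes the germline check: a call whose
support evaporates under quality filtering tells us nothing about the
patient's germline. Germline verdicts are diverted to a separate report
rather than deleted — predisposing variants can matter in their own right.
A passing normal depth below `min_normal_depth` flags the verdict
low-confidence without changing it. Indel support is allele-exact: a read
counts only if its alignment contains the exact inserted sequence (or a
deletion of the exact length) immediately after the anchor base.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `gap_bp` | 1000 | bp | level-one single-linkage gap; larger values merge nearby clusters |
| `target_categories` | gene, promoter, utr | — | annotation categories eligible for level-two grouping |
| `min_mapq` | 20 | phred | reads below this never support a call |
| `min_baseq` | 10 | phred | bases below this never support a call |
| `min_alt_tumor` | 2 | reads | artifact threshold |
| `min_alt_normal` | 2 | reads | germline threshold |
| `min_normal_depth` | 8 | reads | low-confidence flag only |
| `callable_length` | reference length | bp | background denominator; supply the callable size for real data |

All validation thresholds are manual by design — they are study-specific
judgements, so the package exposes them rather than hiding them.

## Coordinate and identity conventions

Internally every interval is 0-based half-open; VCF (1-based) and GTF
(1-based closed) are converted at the boundary and BED passes through
unchanged, which eliminates off-by-one drift between the three formats.
Chromosome dialects (`chr1` vs `1`) are normalized at import (default:
strip `chr`). Variant identity everywhere is allele-exact
(chrom, pos, ref, alt) *after* canonical left-alignment: shared trailing
bases are truncated (extending left over the reference when an allele
empties) and shared leading bases trimmed, so a homopolymer insertion
called at different offsets by different callers filters correctly against
the panel of normals and polymorphism sets. The simulator emits planted
alleles already left-normalized so truth tables, VCFs and synthesized
reads agree on one representation.

Effect classification uses the standard genetic code only (human tumors),
takes whatever transcript set the user supplies as GTF — labels are only
as good as that choice — and resolves multi-transcript conflicts by
severity (non-synonymous > synonymous > non-coding). Stop gain/loss counts
as non-synonymous. Indels inside a CDS are labelled non-synonymous as a
blanket rule; frameshift vs in-frame and splice-site proximity are not
modelled, since the pipeline only distinguishes the three classes above.

## What the simulator emulates — and what it does not

`sim_config()` + `simulate_all()` generate a complete, hermetic study: a
uniform-random reference; non-overlapping multi-exon genes on both strands
with valid CDS written into the reference; tumor/normal pairs whose tumors
draw background somatic variants at a per-base rate (default
$2\times10^{-4}$ per base per sample on a 200 kb toy genome — chosen so a
ten-pair cohort yields a few hundred somatic sites, the scale of a small
targeted study); hotspot intervals at a fold-elevated rate with guaranteed
recurrent carriers; germline sites written to carrier tumors and their
matched normals (a `germline_vcf_miss_rate` knob reproduces the
caller-missed-the-normal leak-through that validation must catch);
artifact sites whose alt reads carry low mapping or base qualities;
a DBSNP-like polymorphism VCF with a planted subset present in tumors; and
coordinate-sorted SAM alignments at Poisson depth (default 40×) with
somatic VAF 0.4 and germline VAF 0.5 — conventional heterozygous-like
values. Every file is byte-identical under a fixed seed; each stage derives
its own sub-seed so stages are decoupled.

The simulator does *not* model sequencing error beyond the planted
qualities, fragment-size or GC bias, mapping ambiguity, subclonal VAF
distributions, or copy number. Passing tests on it therefore demonstrate
the pipeline's bookkeeping and statistics — filters remove exactly what
they claim, verdicts follow the rule, scores match the model — not
robustness to the full noise spectrum of real sequencing.

## Numerical and degenerate-input choices

* `P(X \ge 0)` returns exactly 1; q-values are capped at 1.
* Region length has a floor of 1 bp; a singleton novel hotspot spans its
  own footprint. Such regions are trivially "enriched" when their single
  variant is their own evidence — a known selection effect of scoring
  data-defined regions; treat singleton novel hits with suspicion and rely
  on the annotated categories or a larger `gap_bp` when it matters.
* A proximity cluster overlapping several annotation records joins *every*
  such hotspot (multi-assignment) rather than being split, preserving
  level-one integrity; the same variants may therefore appear under a gene
  and its promoter.
* Ties in clustering input order are resolved by (chrom, pos, ref, alt)
  sorting; all outputs are deterministically ordered and reports contain
  no timestamps, so identical inputs give byte-identical bundles.
* Missing DP/AD depths in VCFs import as 0 and are never used to filter at
  extraction time; depth judgements belong to validation, where they are
  recomputed from alignments.
* Pairs whose alignment files are missing are retained with status
  `unknown` rather than dropped, so verdict counts always partition the
  examined pairs.

## Design choices on genuinely open points

* **Binomial + BH is the primary significance path**; the per-cohort
  Fisher test answers the separate enrichment question. Where a single
  combined statistic could have been invented, we preferred the two
  explicit tests.
* **"Cancer-exclusive" means exclusive with respect to normals and
  polymorphism sets**, not to tumors of other cohorts: recurrence across
  cancer types is signal, not contamination.
* **The panel of normals spans all cohorts** in the store — any normal
  anywhere disqualifies a site.
* **The store is an in-memory tabular object with a plain-TSV directory
  serialization** (`write_store()`/`read_store()`): every intermediate of
  a desk-scale run stays inspectable and diff-able, and each phase writes
  its TSV so later phases can be re-run from files.

## Problem sizes used by the test and acceptance runs

The bundled verification runs use a 200 kb single-chromosome genome with
ten tumor/normal pairs for filter-soundness checks (about 460 planted
sites per seed, twenty seeds), an 80 kb genome at depth 40 for verdict
recovery (planted 80/10/10 somatic/germline/artifact), and a counts-level
scoring study of one 50×-background region among 500 null kilobase regions
across 20 samples and 100 seeds. These sizes were chosen to make sampling
error negligible relative to the asserted margins while keeping a full
verification run comfortably on a laptop.

## Known limitations

* The threshold triage is not a probabilistic somatic genotyper: no joint
  tumor/normal likelihood, no VAF model, no strand-bias test.
* Background is uniform genome-wide — no trinucleotide context,
  replication timing or expression covariates — so regions with benignly
  elevated local rates can shadow true hotspots in real data.
* Effect labels ignore splice sites and protein-level consequence
  nomenclature.
* Structural variants, CNVs and LOH are out of scope; the store holds SNVs
  and short indels only.
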