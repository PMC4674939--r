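---
title: "Sub-genome resolved methylation analysis: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-genome resolved methylation analysis: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis model

Allohexaploid wheat carries three homoeologous sub-genomes (A, B, D).
Bisulfite reads mapped to a single shared reference lose their sub-genome
identity; `polymethyl` recovers it through homoeologous SNPs. The chain of
inference is:

1. **Catalogue**: positions where each sub-genome has one unambiguous
   allele and at least one differs. Because bisulfite conversion renders
   C/T (and, on the opposite strand, G/A) indistinguishable, every SNP
   whose distinct alleles contain a {C,T} or {G,A} pair is removed. A
   consequence worth noting: *any* three distinct bases contain one of
   those pairs, so all usable SNPs are biallelic — one genome against the
   other two (A vs BD, B vs AD, D vs AB).
2. **Assignment**: a read overlapping catalogue SNPs is matched to the
   allele(s) its bases are compatible with, under *conversion
   compatibility*: on a C→T-converted strand product a read `T` also
   matches allele `C`; on a G→A product a read `A` also matches `G`.
   Without this rule, converted reads over C-containing alleles would be
   systematically lost. Matches at multiple SNPs (and across the two mates
   of a fragment, which share a name) are intersected: `A` ∩ `AB` = `A`,
   while `A` ∩ `BD` is empty and the read is discarded as contradictory
   rather than majority-voted. Reads with mapping quality ≤ 20 are never
   assigned.
3. **Tallies**: per cytosine site, methylated/total read counts per label.
   A site is *tri-resolved* when the three single-genome labels each reach
   5×; otherwise it is *biallelic* under its dominant partition, gated at
   5× for the single genome and 10× for the pair. Pair counts absorb
   single-labelled reads of the member genomes; pairs are never split
   arithmetically into their members.
4. **States and patterns**: context-specific thresholds (below) call each
   genome or pair Methylated / Unmethylated / Intermediate; Fisher's exact
   test with Benjamini–Hochberg q-values decides whether apparent
   differences are real; the site is then uni-, bi-, tri-genome
   methylated, intermediate, or unmethylated (`none`).

## Thresholds

All defaults sit in `meth_thresholds()`:

| parameter | default | meaning |
|---|---|---|
| `cpg_meth` / `cpg_unmeth` | 75 / 25 % | CpG state bands (inclusive, exactly as printed) |
| `non_cpg_meth` | 10 % | CHG/CHH methylated strictly above this |
| `within_sample_diff` | 50 % | minimum difference, sub-genome comparisons |
| `between_sample_diff`, `dmr_diff` | 25 % | after replicate pooling / per region |
| `diploid_compare_diff` | 50 % | diploid-progenitor comparisons (lower coverage) |
| `q_cutoff` | 0.01 | BH q-value cutoff for every Fisher family |
| `single_depth` / `pair_depth` | 5× / 10× | coverage gates |
| `mapq_min` | 20 | assignment quality gate |
| `promoter_bp` | 2000 bp | promoter extent upstream of the TSS |
| `expr_conserved_window` | 5 % | co-expression window |
| PPLR cutoffs | 0.4/0.6, 0.10/0.90 | differential / highly differential expression |

The asymmetric CpG versus non-CpG bands exist because most analysable
sites are seen through a biallelic SNP and are therefore an *average of
two genomes*: such a site can only be called when both genomes are likely
methylated or both likely unmethylated. High-level CpG methylation makes
75/25 workable; CHG/CHH methylation is low-level, so "methylated" means
exceeding 10 % and "unmethylated" means no signal at all. Whatever falls
between is *intermediate* — structurally unclassifiable under the
pair-averaging logic, not merely noisy.

## Conversion background correction

"0 % methylation" is unobservable in raw counts: with a conversion rate of
98.9 %, a truly unmethylated genome at 50× shows at least one spurious
methylated call about 40 % of the time, which would push most genuinely
uni-/bi-genome sites into the intermediate class. State calling therefore
corrects levels for the measured non-conversion background *b* (estimated
from the unmethylated control and passed as
`conversion_background = 1 - rate/100`):

* counts consistent with background alone — one-sided binomial test at
  `background_alpha` — are treated as exactly 0 %;
* counts above background use the rescaled level `(ℓ − b) / (1 − b)`.

`background_alpha = 0.05` balances the two error directions at typical
resolved depths (30–60× per genome): false "above background" flags on
unmethylated genomes (≈ 1–2 % per genome, which send a site to
intermediate) against zeroing of genuinely low-level (5–10 %) non-CpG
methylation (which would send an intermediate site to `none`). This
correction is this package's design choice; it follows the long-standing
practice of testing methylation calls against the non-conversion rate
rather than against zero.

## Statistical machinery

* Fisher's exact p is the standard two-sided sum of hypergeometric masses
  not exceeding the observed table's mass, computed vectorised
  (`fisher_exact_2x2()`); the test suite checks it against both
  `stats::fisher.test` and an explicit `choose()`-based enumeration of all
  tables with margins ≤ 30.
* q-values are Benjamini–Hochberg per comparison family (one family = one
  genome pairing across all sites of a call). Some methylation toolkits
  use a different q-value estimator (SLIM); BH is the standard,
  reproducible step-up procedure, and results can differ slightly near the
  cutoff.
* For bi-genome calls the 50 %-difference test is applied pair-versus-third
  (both pair members against the unmethylated genome in tri-resolved mode);
  the alternative reading (testing within the pair) is not used.
* Between-sample comparisons are within-genome (A–A, B–B, D–D) at 25 %
  after replicate pooling; replicate-discordant sites (50 %/q < 0.01
  between any replicate pair) are excluded first.
* The expression t test is the pooled-variance two-sample t (the reported
  integer degrees of freedom, n₁+n₂−2, identify the pooled form rather
  than Welch). Kurtosis is reported as *excess* kurtosis (normal = 0,
  unbiased sample estimator); other conventions differ by a constant, so
  kurtosis values are comparable only in sign and ordering across tools.
* Expression histograms use twenty right-open bins `[k, k+5)` with the
  final bin `[95, 100]` closed.

# What the generator emulates

`sim_config()` defaults are the study conditions:

* **Pattern mix** over methylation-assigned cytosines: 45 % tri-genome,
  20 % differential (12 % uni split evenly over A/B/D, 8 % bi split evenly
  over the pairs), 35 % intermediate, 0 % unmethylated — the proportions
  observed among methylated wheat cytosines in targeted methyl-seq.
* **Conversion rate** 0.9892, the control-derived estimate; sequencing
  error 0.001/bp; non-directional library over the four strand products;
  paired-end 2 × 100 bp fragments with 300 ± 30 bp inserts.
* **Methylation levels**: binary-extreme by design — a "methylated" genome
  draws near the context mean (CpG 0.90, CHG 0.80, CHH 0.75; ± 0.05
  jitter), an "unmethylated" genome is exactly 0 — because the thresholds
  assume "both genomes likely methylated" versus "both likely
  unmethylated". Intermediate truth draws inside the observable
  intermediate band of each context: CpG U(0.35, 0.65), CHG/CHH
  U(0.05, 0.10).
* **SNP density** 0.04/bp with heavily biallelic alleles (10 % triallelic,
  all of which are necessarily bisulfite-ambiguous and get filtered). This
  emulates the SNP-dense regime of a capture design whose baits were
  selected for homoeologous SNP presence. It matters: at genome-wide
  average densities most sites are only pair-resolved, and a biallelic
  site cannot distinguish e.g. uni-B from bi-BD seen through an A|BD SNP —
  the uni/bi truth mix is simply not identifiable there. Tri-resolution
  comes from fragments spanning SNPs of complementary partitions, which is
  why paired-end fragments (spanning ~300 bp) are the default.
* **Coordinates**: reads are born aligned to the shared ancestral
  reference (alignment is out of scope); mapping quality is still
  populated so the MAPQ gate is exercised. Cytosines within ±2 bp of a
  divergent position differ in presence or context between genomes, carry
  no truth record, and are simulated unmethylated; the extraction step
  independently drops observations whose call-string symbol contradicts
  the reference context, which is exactly where such sites surface.
* **Expression**: per-gene baselines are gamma(shape 4) draws (relative
  SD 0.5); a genome whose promoter truth is dominated by its own
  uni-genome methylation (> 25 % of the promoter's methylation-assigned
  sites) is suppressed multiplicatively (`promoter_suppression`, default
  0.8). Under equal baseline means the suppressed genome's expected
  normalized share is ≈ 100·s/(s+2).

What it does **not** emulate: mapping ambiguity and mapping bias, PCR
duplicates, M-bias along reads, base-quality variation, tissue-specific
intermediate methylation, CHH/CHG hyper-methylated transposon context, and
regionally correlated methylation (site patterns are drawn independently,
so regional DMR signal exists only where a test injects it). Passing the
recovery tests therefore demonstrates the pipeline's correctness under the
stated noise model, not robustness to alignment artefacts.

## Study sizes used by the checks

The end-to-end recovery checks run 5 contigs × 6000 bp (within the real
extended-contig size range) at 100× per sub-genome — ≈ 10,000–11,000
methylation-assigned sites and ≈ 85,000 reads — with conversion 0.99 and no
sequencing error; the conversion-rate check simulates ≥ 10⁵ control
cytosine observations at conversion 0.9892. The complete test suite runs
in about a minute on one CPU.

# Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; SAM and TSV
  positions are converted exactly once on ingest/writing, BED passes
  through unchanged. This removes the usual off-by-one error class.
* Context is classified from the reference, never the read. Sites with
  undeterminable context (edges, ambiguous bases, `U/u` symbols) are
  excluded from all classification.
* Thresholds are inclusive exactly as printed: ≥ 75, ≤ 25, strictly > 10.
* Catalogue merge conflicts keep the progenitor-derived alleles
  (`prefer_primary`), treating the second source as gap-filling; a `drop`
  policy is available. The conservation statistic is reported as NA when
  the sources share no positions.
* Consensus for pileup/assigned-read allele calling is ≥ 90 % agreement —
  a concrete reading of "unambiguous".
* Region summaries weight by reads (summed methylated over summed total),
  not by sites; a region is the annotation unit supplied in the BED (the
  capture design's extended bait probes) — no sliding windows.
* Pair-label calls mean "both genomes share the state" only for
  Methylated/Unmethylated; an Intermediate pair call blocks uni/bi/tri
  classification of the site. A methylated-looking configuration whose
  differential test fails is likewise classified intermediate rather than
  forced into a pattern.
* Ties when choosing the dominant biallelic partition resolve in A|BD,
  B|AD, D|AB order; in practice coverage differences make ties rare.
* One global seed drives every stochastic stage; stages derive
  independent sub-seeds deterministically, so identical configs reproduce
  byte-identical outputs.

# Known limitations

* Biallelic-only resolution regions cannot distinguish uni-genome
  methylation of a pair member from bi-genome methylation of the pair;
  such sites are reported as the pair-average classification
  (tri/uni-single/bi-pair/intermediate/none) and nothing more.
* The background correction assumes a uniform conversion failure rate
  estimated from the control; locus-specific conversion resistance would
  surface as intermediate or spuriously methylated calls.
* BH q-values differ from SLIM-based ones near q = 0.01.
* The kurtosis convention affects reported magnitudes (not signs or
  orderings) of distribution-shape comparisons.
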