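---
title: "Dual-context DMR calling and endosperm regulatory genomics with dmrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-context DMR calling and endosperm regulatory genomics with dmrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrkit)
```

## The analysis problem

Maize endosperm inherits two maternal genome copies and one paternal copy,
and a DNA glycosylase pathway actively demethylates thousands of small
regions of its genome. `dmrkit` implements the computational machinery for
studying this system from enzymatic methyl-seq (EM-seq) or bisulfite-style
per-cytosine calls and its companion data types: small-RNA libraries,
allele-specific expression counts, and bulked-segregant variant tables.
Everything is exercised end to end on synthetic data with planted ground
truth, so every stage of the pipeline has a recoverable right answer.

The pipeline has five analysis stages and one generator:

1. **Methylome I/O** — read, merge and intersect CGmap-format per-cytosine
   call files.
2. **Region calling** — eligibility, hypo/hyperDMRs, mCHH regions, CHG
   unmethylated regions (the euchromatin proxy), methylated control
   regions, all on a fixed 200-bp grid.
3. **Region characterization** — overlap enrichment against annotations,
   end-anchored and flanking profiles, distances to euchromatin, GC
   content, degenerate-consensus motif matching.
4. **siRNA analysis** — classification, subsampling, length distributions,
   siRNA-region calls.
5. **Imprinting and mapping** — maternal-ratio classification, expression
   categories, and bulked-segregant allele-frequency scans.

## The dual-context DMR model

Differential methylation is called on non-overlapping 200-bp bins laid on
a grid anchored at coordinate 0 of each chromosome. For a pair of samples
$(1, 2)$ and one context $c \in \{\mathrm{CG}, \mathrm{CHG}\}$, the bin
level is count-weighted,
$v_i = \sum \text{meth}_i / \sum \text{total}_i$, never the mean of
per-site fractions — low-coverage sites should not carry the same weight
as well-covered ones.

A bin is **eligible** when, in *both* samples, it has at least 5
informative CGs with mean read depth at least 3, and likewise at least 5
CHGs at depth 3. Eligible bins are the control denominator for every
enrichment statistic: in a large, repetitive genome most bins are simply
unmappable or uninformative, and comparing DMRs against anything other
than bins that *could* have been called produces severe ascertainment
artifacts.

A bin is a **hyperDMR** when, in CG and CHG independently,

$$v_2 > 2\,v_1 \quad\text{and}\quad v_2 - v_1 > 0.20,$$

and a **hypoDMR** under the mirrored conditions. The inequalities are
strict, following "greater than"; the eligibility and mCHH/UMR thresholds
are inclusive, following "at least". When a denominator level is 0 the
fold condition is taken to hold iff the numerator level is positive —
the limit of the ratio condition; the absolute-difference guard still
applies. Requiring both contexts to move concordantly is deliberately
conservative: it trades completeness for a high-confidence set, which is
the right trade for downstream enrichment statistics.

Single-sample callers follow the same binning: mCHH regions are bins with
≥5 CHH sites, mean depth ≥2 and level ≥0.2 (an RdDM signature);
CHG-unmethylated regions (≥5 sites, depth ≥2, level ≤0.2) in embryo serve
as the euchromatin proxy, because euchromatin is stably depleted of mCHG
across maize development. Methylated control regions are eligible bins
with both mCG and mCHG ≥0.2 in at least one sample — the subset of
controls that could, in principle, be demethylated.

Sample order matters and is a convention, not a setting: sample 1 is the
methylated reference (mutant endosperm, or embryo) and sample 2 the
demethylated endosperm, so glycosylase targets appear as hypoDMRs.
Finalized DMRs are restricted to real chromosomes (`chr1`–`chr10` by
default); unplaced scaffolds are discarded after context combination, but
the eligible control set keeps them, since controls are defined
genome-wide.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `bin_size` | 200 | bp | analysis grid; bins never overlap |
| `min_sites` | 5 | cytosines | informative sites per context per sample |
| `min_cov` | 3 (2 for MR/UMR) | reads/site | mean depth over informative sites |
| `min_abs_dif` | 0.20 | level | absolute difference, strict |
| `fold` | 2 | — | relative change, strict |
| `chromosomes` | chr1..chr10 | — | scaffold exclusion at finalization |

"Mean coverage" is depth summed over a bin's informative sites of one
context divided by the site count — not a per-site minimum, and not
averaged over uncovered positions.

## Characterization statistics

Overlap selection keeps a query region when at least a fraction `min_frac`
(default 0.5, i.e. 100 bp of a 200-bp bin) of its own length is covered by
the union of annotation elements; multiple small overlaps accumulate.
Element enrichment is then the ratio of the DMR proportion to the control
proportion passing that rule. End-anchored profiles count regions per
100-bp offset bin around strand-annotated anchors (TSS, polyA, transposon
ends — solo-LTR elements should be excluded from end analyses by the
caller since they have no intact body), normalized by the same count for
controls; minus-strand anchors are mirrored so offsets read in transcript
orientation. Flanking methylation profiles average count-weighted levels
per 100-bp offset over each region's ±3 kb window, using sites with
coverage ≥1; offset bins with no covered sites are reported as missing,
never imputed as zero. Motif matching expands IUPAC degenerate codes and
reports exact consensus matches on both strands; for the short
W-containing motifs this package targets, score-based matching with a
p-value model adds nothing over the exact expansion.

## siRNA regions

Small RNAs of 20–25 nt that do not overlap ≥90% of their length with
structural-RNA loci (tRNA, 5S, NOR, miRNA) are classified as siRNAs.
Libraries are subsampled to a common depth before comparisons (the scale
is a parameter; the desk-scale default is 10^5 reads per replicate).
A region is an "siRNA region" when at least 50 bp of it are spanned by the
union of siRNA footprints — a union, not a sum, so duplicated reads and
PCR stacks do not inflate calls. Multi-mapped reads are counted where
placed; `unique_only` (MAPQ ≥ 20) reproduces the uniquely-mapping
analysis. Both modes are first-class because the biological conclusion
should not depend on the multi-mapping policy.

## Imprinting and expression categories

The maternal ratio is maternal/(maternal+paternal) informative reads; the
2:1 endosperm dosage makes 2/3 the biallelic expectation, MEGs are ratios
above 0.9 and PEGs below 0.1. Counts are summed over reciprocal cross
directions before the ratio is taken (per-direction ratios are kept as
diagnostics); a feature with fewer than `min_informative` (default 10)
reads is uncallable — the threshold is configurable because upstream
studies differ in their coverage criteria. Features are binned by DMR
proximity as overlap (≥100 bp), within 2 kb, or beyond 2 kb. Expression
categories from an RPM atlas follow a fixed precedence: constitutive off
(RPM > 1 in fewer than 3 of all libraries), then endosperm on (RPM > 1 in
≥18 of 21 endosperm libraries) or endosperm off (RPM < 0.5 in ≥20 of 21).

## Bulked-segregant mapping

The cross design — heterozygous mother × homozygous mutant father,
selection of mutant homozygotes — fixes the expected pooled alternative
allele frequency at markers unlinked to the causal locus at 0.75, rising
to $1 - r/2$ at recombination fraction $r$ (Haldane map function), hence
~1 at tight linkage. Two per-record filters are provided: the
likelihood-based filter (wild-type bulk frequency 0, depth 2–15; mutant
depth 5–50; PL(hom-ref) ≥ 400 and PL(hom-alt) = 0) and the
genotype-quality filter (GQ ≥ 20 in both, depths 5–14 and 6–49, mutant
frequency strictly above 0.75). Depth bounds are inclusive ("between
5–14"), the frequency bound strict ("above 0.75"). Window scans default
to 1 Mb windows advanced by 200 kb — the source analysis reports only the
emergent ~20 Mb candidate region, not its windowing, so the window is a
parameter with a deliberately unexciting default; variant means are
unweighted across variants, with a depth-weighted option. The candidate
region is the longest run of ≥3 consecutive windows exceeding background
+0.15, ties broken by higher pooled frequency then leftmost position.

## What the synthetic data emulates — and what it does not

The generator produces every input with planted truth at desk scale:

* **Genome**: 2 chromosomes × 5 Mb plus a 0.5 Mb unplaced scaffold
  (~1/200 of a maize genome). Annotations: 300 genes, a 400-copy
  Helitron family (half carrying planted binding motifs), Gypsy-like
  retrotransposons with solo-LTR flags, tandem arrays, and the
  structural-RNA exclusion loci.
* **Methylomes**: three replicates per tissue at 10× Poisson coverage
  (30× merged), binomial read sampling, conversion error 0.005.
  Compartment baselines: heterochromatin mCG 0.85 / mCHG 0.70 / mCHH
  0.05; euchromatin (gene bodies ± 1 kb) 0.05 / 0.02 / 0.02. 300 planted
  hypoDMR bins (plus 10 on the scaffold, which the finalization step must
  discard) with mCG = mCHG = 0.80 in the methylated tissues and 0.05 in
  wild-type endosperm — an effect far above the 0.20 threshold, because
  the recovery tests probe the caller's bookkeeping (eligibility,
  grid, direction, context concordance), not its power at the decision
  boundary.
* **BSA**: a marker-level genome of 10 × 20 Mb, one stock-specific marker
  per 50 kb, causal locus at chr4:17.5 Mb, 5 cM/Mb, 500 selected progeny,
  30× pooled mutant depth, 8× wild-type depth. Maternal gametes are drawn
  binomially at $1-r$ per marker, which is exactly the selected-progeny
  model; genotype likelihoods are synthesized from a binomial error model
  so they are internally consistent with the depths (the filters treat
  them as opaque thresholds). The recombination density is chosen so the
  linked block is a ~10 Mb share of a 200 Mb genome — the scaled
  analogue of a ~20 Mb region in a 2.1 Gb genome — keeping the
  genome-wide mean frequency near 0.75.
* **Imprinting**: 1,000 genes at ~200 informative reads, 5% MEGs
  (maternal probability 0.97), 2% PEGs (0.03), biallelic at 2/3.

Deliberately not emulated: realistic maize sequence composition,
linkage disequilibrium and ancestry blocks, mappability structure,
read-level error profiles, TE sequence evolution, and chromatin-state
autocorrelation along chromosomes. Passing recovery tests therefore
demonstrates correctness of the algorithms under the stated statistical
model, not calibration against real maize data; the headline genome-wide
counts of the original study depend on the deposited sequencing data and
are outside what a synthetic desk-scale run can or should reproduce.

## Numerical and design choices

* Coordinates are 0-based half-open (BED) for all interval tables and
  1-based for per-cytosine positions (CGmap); conversion happens only at
  I/O boundaries (`regions_to_granges`).
* The CGmap level column is never trusted; levels are recomputed from
  counts. Context is taken from the file, not re-derived from a
  reference.
* Replicate merging sums counts over the union of sites: an absent site
  is zero coverage, so no replicate-presence requirement is imposed.
* The bin grid anchors at coordinate 0; CG∩CHG combination is
  same-grid-bin identity (equivalent to any-overlap intersection on a
  shared grid).
* Fisher's two-sided p sums hypergeometric probabilities ≤ the observed
  table's (the dominant convention; two-sided definitions vary), the
  binomial test uses the same rule, the chi-square uses the Yates
  continuity correction clamped at zero, and the t test pools variances
  (with a Welch option). All four are written from first principles and
  cross-checked against enumeration oracles and the standard R
  implementations in the test suite.
* Ties in candidate-region detection resolve to the longer run, then the
  higher pooled frequency, then the leftmost coordinate — fully
  deterministic.
* Degenerate inputs are flagged, not silently imputed: empty profile bins
  are `NA`, zero control proportions make enrichment undefined,
  degenerate 2×2 margins return p = 1 with a warning.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 1)
ann <- make_genome_annotation(cfg)
sim <- simulate_methylomes(cfg, ann,
                           tissues = c("mdr1_endosperm", "wt_endosperm"))

mut <- merge_replicates(sim$replicates$mdr1_endosperm)
wt  <- merge_replicates(sim$replicates$wt_endosperm)
res <- call_dmrs(intersect_samples(mut, wt, "CG"),
                 intersect_samples(mut, wt, "CHG"),
                 dmr_params(chromosomes = cfg$chromosomes))

nrow(res$eligible)   # control regions
nrow(res$hypo)       # demethylated in wild-type endosperm
helitrons <- ann$transposons[ann$transposons$family == "DHH00002",
                             c("chrom", "start", "end")]
element_enrichment(res$hypo, res$eligible, helitrons)
```

The problem sizes above (5 Mb chromosomes, 30× merged coverage, 100 BSA
replicates in the acceptance script) are the package's standard desk
scale: large enough that binomial noise is exercised and recovery rates
are estimated on hundreds of regions, small enough to iterate on freely.

## Known limitations

* DMR units are single 200-bp bins; adjacent significant bins are not
  merged into larger regions, and no statistical test is attached to a
  DMR call — the method is intentionally threshold-based.
* The siRNA module consumes aligned intervals; adapter handling and
  alignment are upstream concerns.
* Genotype-likelihood synthesis in the BSA generator is a binomial toy
  model; it is adequate for exercising threshold filters but not a
  substitute for a genotyper's error model.
* `segregation_expectation` enumerates at most two linked loci, which
  covers the two-marker transmission designs it exists for.
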