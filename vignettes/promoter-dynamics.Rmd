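---
title: "Quantifying promoter activity dynamics from splice-junction reads"
author: "promdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying promoter activity dynamics from splice-junction reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Most mammalian protein-coding genes carry several promoters, and which
promoter a gene uses can change across development even when total gene
expression does not. `promdyn` infers per-promoter activity from standard
bulk RNA-seq without CAGE or ChIP data, by exploiting the fact that every
transcript isoform's *first intron* is spliced out of reads that could only
have originated from transcription initiated at that isoform's promoter.

The analysis proceeds in five steps.

**1. Promoter inference from annotation.** Transcripts of a gene whose
first exons overlap by at least one base are grouped into one promoter
(single-linkage closure over pairwise overlaps; the merge is parameter-free
and is implemented with `GenomicRanges::reduce(min.gapwidth = 0)`, which is
provably identical to the transitive closure because a reduced run is a
gap-free union of its members). The promoter TSS is the 5'-most member TSS
— the minimum first-exon start on `+`, the maximum first-exon end on `-` —
and promoters are ranked 1..K from 5' to 3'. Promoters whose first-exon
span overlaps a *non-first* exon of the same gene are flagged *internal*:
junction reads over their first introns are indistinguishable from
ordinary splicing of longer isoforms, so they are excluded from
quantification. The internal test deliberately ignores other genes —
isoform confusion is a within-gene phenomenon, and cross-gene overlap
would penalize dense loci.

**2. Junction counting.** Per sample, the unique-mapping read counts of a
promoter's first-intron junctions are summed (STAR `SJ.out.tab` input;
multi-mapping reads are never used). A junction contained in more than one
promoter identifies neither, so shared junctions are excluded from all of
their promoters rather than split by an allocation model the data cannot
support. A promoter is *quantifiable* when it is not internal and has at
least one promoter-unique junction; non-quantifiable promoters propagate
as missing values, never as zeros, so they can be distinguished from
silent promoters downstream. Junctions reported without a strand (STAR
code 0) are resolved when their coordinates match the catalog on exactly
one strand and dropped with a warning otherwise.

**3. Activity and classification.** Counts are depth-normalized with
DESeq2 median-of-ratios size factors computed on the promoter count matrix
itself, mirroring normalization of the objects actually quantified.
Absolute activity is `log2(normalized count + 1)`; the pseudocount of 1 is
the smallest value defined at zero and standard for count data. Gene
expression is `log2(1 + sum of linear normalized counts)` over the gene's
quantifiable promoters — summing *log-scale* activities would not be a
meaningful expression total, so the linear-sum convention is adopted (the
alternative reading is noted below under limitations). Relative activity
is the promoter's fraction of the gene's linear total, undefined when the
gene is silent in a sample. Averaging absolute activity over **all**
samples, the promoter with a gene's highest mean is the *major* promoter
provided that mean reaches 0.25 (ties go to the 5'-most promoter, a
deterministic and biologically conventional choice); promoters below 0.25
are *inactive*, the remainder *minor/alternative*. The 0.25 cutoff and the
10% contribution rule for multi-active genes are the analysis's standard
operating constants and sit in one configuration block
(`pipelineConfig()`), not scattered through code.

**4. Developmentally dynamic promoters (DDPs).** Within one organ, each
quantifiable promoter's absolute activity is regressed on a cubic
polynomial of developmental time by ordinary least squares. Time is the
ordinal stage index standardized to zero mean and unit variance before
polynomial expansion: the encoding is not dictated by the biology, and
standardization gives a well-conditioned design matrix while leaving
R-squared and the model F-test invariant to any affine choice (a tested
invariance). Significance is the F-test of the full cubic against the
intercept-only model, corrected across the organ's promoters by
Benjamini–Hochberg; a promoter is a DDP when `q <= 0.05` **and**
`R^2 >= 0.3`, both bounds inclusive. The reference implementation in the
field (maSigPro) additionally performs stepwise term selection; that step
selects *which* polynomial terms remain, not *whether* a promoter is
dynamic, and the acceptance rule here is the goodness-of-fit cutoff, so
the full-cubic F-test is used and both the FDR level and the R-squared
floor are exposed as configuration. Trend direction is the sign of the
fitted activity change from the earliest to the latest stage; non-DDPs are
`Flat` by definition. Promoters observed in fewer than 70% of an organ's
samples, or with fewer distinct times than the four a cubic requires, are
skipped with a recorded reason rather than fitted badly. Group
trajectories carry 95% percentile bands from 1000 bootstrap resamples of
promoters.

**5. Switching taxonomy and cross-organ comparison.** Each gene's major
promoter is paired with every non-inactive minor promoter, and the pair's
(major trend, minor trend) maps onto eight categories — `Up_Up`,
`Up_Flat`, `Flat_Up`, `Down_Down`, `Down_Flat`, `Flat_Down`, `Up_Down`,
`Down_Up` — with `(Flat, Flat)` pairs left `Unclassified`. The gene-level
trend is computed with the same fit/call machinery applied to gene
expression; when a pair's category disagrees with the gene trend it
implies, the pair is *flagged* as inconsistent, never silently reassigned.
Across organs, a gene dynamic in at least two organs is a *common* DDP
unless those organs are exactly a related-organ group (default
brain + cerebellum, two tissues so functionally close that sharing between
only them is not evidence of generality); genes dynamic in one organ are
*organ-specific*. Matching is by gene identifier. A gene dynamic in brain,
cerebellum and any third organ is common.

# The synthetic data generator

Desk-scale validation should not depend on downloading a large public
organ-development time course, so the package ships a generator that
emulates the *structure* of such data rather than its content:

- **Architecture.** 1–4 promoters per gene (default weights
  0.25/0.35/0.25/0.15), each promoter with two member transcripts (one
  skipping a cassette exon, giving two distinct first-intron junctions
  split 70/30), shared downstream exons, alternating strands. Planted
  internal promoters and overlapping gene pairs with a shared junction
  exercise the exclusion rules end to end.
- **Design.** Two organs, 16 stages (embryonic `E10.5`–`E18.5`, postnatal
  `P0`–`P63`), 2 replicates — the scale, not the content, of a mammalian
  organ-development time course.
- **Counts.** Negative-binomial unique junction reads with dispersion
  0.05 (a typical bulk RNA-seq value), mean
  `sizeFactor x baseline x 2^trajectory(t)`. Major promoters default to
  baseline 100 reads, minors to 40, planted-inactive promoters to 0.05.
  Trajectories live in log2 space: `up` rises by `effect = 2` log2 units
  over the course, `down` falls by the same, `flat` is constant. At these
  settings the planted amplitude is roughly four per-observation standard
  deviations of log2 activity, i.e. a strong but not caricatured signal.
- **Depth.** Per-sample size factors drawn log-uniformly over a 4x range
  and renormalized to geometric mean 1, since depth factors are
  identifiable only up to a global scalar.
- **Truth.** Every run emits the planted class, trajectory, pair category
  and size factor keyed to the identifiers the catalog will assign, so
  recovery is measured without bookkeeping heuristics.

What the generator does **not** emulate: annotation errors, novel
(unannotated) junctions, multi-mapper structure, GC/length biases,
batch effects, or cell-composition drift within an organ. Passing
recovery tests therefore demonstrates correctness of the inference
machinery under its own model assumptions, not robustness to every
artifact of real libraries.

# Numerical choices and degenerate inputs

- Constant activity profiles have zero total sum of squares; their
  R-squared is defined as 0 and the F-test p as 1.
- Exact fits (residual sum of squares below `1e-15` of the total) get
  p = 0 rather than a 0/0.
- Ties in mean activity at a gene's maximum break toward the 5'-most
  promoter; ties in the fitted endpoint difference (exactly zero) give a
  `Flat` direction.
- The size-factor estimator requires at least one promoter with positive
  counts in every sample; sparse matrices can opt into a
  positive-count pseudo-reference (`fallback = "poscounts"`).
- Depth estimation on strongly dynamic data absorbs some trajectory
  signal: with organ-asymmetric planted trends the median ratio at
  extreme stages can deviate noticeably from the planted factor. This is
  a property of median-of-ratios normalization on globally changing
  expression, not an implementation artifact; the dedicated recovery
  check therefore uses a flat-trajectory design where depth is the only
  between-sample signal, and recovers planted 4x factors within a few
  percent.
- All simulation and bootstrap randomness flows through explicit seeds,
  and seeded code restores the caller's RNG state.

# Problem sizes used in validation

The test suite and the acceptance script run entirely on generated data,
sized for seconds-scale runs: 40-gene fixtures for exact junction-count
oracles, 250 flat genes for size-factor recovery, 500 promoters against a
normal-equations least-squares oracle, 5 x 2000 pure-noise promoters for
type-I control of DDP calling, and 120 genes x 2 organs for
switching-category recovery (about 300 planted pairs). These sizes were
chosen so each property is measured with comfortable statistical margin.

# Known limitations

- The published description of gene expression ("sum of the absolute
  promoter activities") is ambiguous between linear- and log-scale
  summation; the linear-sum convention implemented here is the
  statistically coherent reading, but results are not numerically
  comparable to a log-sum implementation.
- Whether the original DDP analysis applied a significance filter in
  addition to the R-squared cutoff is not stated; this implementation
  applies both (BH FDR at 0.05 and R^2 >= 0.3) and exposes each.
- Single-exon transcripts have no first intron; promoters whose members
  are all mono-exonic are structurally non-quantifiable and are reported
  as such rather than imputed.
- The pipeline is annotation-driven: junctions absent from the catalog
  are ignored, so promoters missing from the annotation are invisible.
- Pattern categories depend on the DDP calls; near-threshold promoters
  can flip a pair between, say, `Up_Up` and `Up_Flat` across reruns of a
  *different* random dataset (within one dataset all calls are
  deterministic).
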