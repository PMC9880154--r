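---
title: "Methods: methylation calling from direct bisulfite Sanger traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation calling from direct bisulfite Sanger traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylotrace)
```

## The measurement model

In direct bisulfite Sanger sequencing, the PCR product of a bisulfite-treated
DNA pool is sequenced as a mixture rather than as individual clones. Sodium
bisulfite deaminates unmethylated cytosines to uracil, read as thymine after
PCR, while 5-methylcytosine is protected and remains cytosine. At a CpG
dinucleotide whose methylated fraction in the tissue is $m$, the sequencing
trace therefore shows superimposed C and T peaks, and the relative C
amplitude estimates $m$.

methylotrace estimates, for every catalogued CpG site covered by a read,

$$\hat{m} = 100 \times \frac{I_C}{I_C + I_T}$$

where $I_C$ and $I_T$ are the C- and T-channel peak amplitudes at the read
position mapped to that reference cytosine. We use the bounded ratio
$I_C/(I_C+I_T)$ rather than the raw quotient $I_C/I_T$: the bounded form maps
directly onto a percentage scale, is symmetric in its treatment of the two
channels, and is the standard estimator for pooled-molecule bisulfite
electropherograms. The raw quotient is unbounded and explodes at fully
methylated sites. Both forms are monotone transformations of each other, so
the choice does not affect rankings or the sign of any stage contrast.

Sites are mapped by aligning the primary base-call sequence against the
*in-silico converted* reference (every C replaced by T), since a bisulfite
read of an unmethylated molecule matches the converted reference exactly.
Methylated CpGs then appear as C-over-T mismatches, which the alignment
scoring tolerates easily at the CpG densities involved (about 3 per 100 bp).

### Alignment parameters

Alignment is a global fit of the read against a local stretch of the
converted reference (reads are amplicons of the promoter), computed with
`Biostrings::pairwiseAlignment`: match +2, mismatch −1, and an affine gap of
length $L$ costing $5 + L$. These values are fixed for determinism; on clean
Sanger reads the alignment is essentially parameter-insensitive because the
read and the converted reference differ only at methylated CpGs and
conversion failures. A read whose identity over aligned columns falls below
`min_identity` (default 0.8) fails loudly rather than producing a profile
from a misalignment. The test suite checks the alignment score against an
independent brute-force dynamic-programming oracle on short reads.

### Coverage flags and conversion QC

A site is reported as `insufficient` — mirroring how single CpGs drop out of
real electropherogram analyses — when it is unmapped or gapped, or when
$I_C + I_T$ falls below `min_total_intensity`, which defaults to 10% of the
read's median per-base total amplitude. The default is relative, not
absolute, so the flag is invariant to global trace rescaling, like the
estimator itself.

Because every cytosine outside a CpG context should be converted, the mean
$I_T/(I_C+I_T)$ over covered non-CpG reference cytosines estimates the
bisulfite conversion rate. `conversion_qc()` warns below 0.95 and refuses to
judge on fewer than 5 covered positions. The simulator's default conversion
rate is 0.99 — a typical kit specification; this is a modelling choice, not
a measured value.

When the region of interest is amplified in two overlapping PCR reactions,
each amplicon yields its own profile and `merge_amplicons()` combines them:
a site usable in one amplicon takes that value, a site usable in both takes
the mean, and flags keep the more favourable state only when an actual
measurement backs it.

## The synthetic study design

The generator reproduces the design of a mouse hypothalamus promoter
methylation study: three female animals at each of three postnatal stages —
PND14 (pre-pubertal), PND35 (pubertal), PND56 (post-pubertal) — assayed over
a 1080 bp promoter fragment with 239 bp downstream of the TSS, 32 CpG
dinucleotides, and a short high-CpG islet of about 120 bp at TSS-relative
−200..−80 containing 7 CpGs. Coordinates use the convention without a
position zero (−1 abuts +1).

True region-mean methylation fractions follow the reported ranges of that
design: the islet-bearing region 2 is the least methylated and carries the
stage effect (0.42 → 0.47 → 0.48 across the three stages), region 3 sits at
0.47–0.49, and regions 1, 4, 5 at 0.64–0.70. Relative target-gene expression
is 1.0 / 0.3 / 0.3, i.e. a ~70% drop at puberty that is sustained
afterwards.

Per animal and CpG, the true fraction is drawn
$\mathcal{N}(\mu_{\text{stage,region}}, \sigma_a)$ truncated to $[0,1]$,
with $\sigma_a = 0.04$ by default. That noise scale was chosen so the
simulated cohort reproduces the statistical *pattern* of the study design at
$n = 3$ per stage: individual-CpG Welch screens are typically
non-significant, while the region-grouped test detects the ~5-point islet
effect at $p \sim 10^{-3}$ and with power above 0.9. A markedly smaller
$\sigma_a$ would make every site-level test significant; a markedly larger
one would defeat the region test at $n = 3$.

### Promoter construction

`make_promoter_sequence()` builds the islet with exact composition: the CpG
count is derived from the requested GC fraction and observed/expected ratio
($n_{CpG} \approx \text{o/e} \cdot N_C N_G / L$), CpG anchors are spread
evenly, the remaining bases are shuffled, and stray CG dinucleotides are
repaired by moving their G to a position where it creates none. The
background is CpG-free low-GC sequence (35% GC) into which background CpGs
are placed at an exact rate (default 2.3 per 100 bp → 25 background + 7
islet = 32), spread evenly with jitter so the background never approaches
island composition. CpG-free 25%-GC guard zones of 50 bp flank the islet so
detected island boundaries cannot leak far into the background. The whole
draw is verified against its own contract — exactly one islet call at
minimum length 100, none at 200 — and redrawn under a derived sub-seed on
the rare miss, so the generator's postcondition holds for every seed.

### Molecule pools and traces

Bisulfite conversion is simulated per molecule: a methylated CpG cytosine
(probability $m$) stays C; an unmethylated cytosine converts with
probability `conversion_rate`, identically at CpG and non-CpG positions —
one knob, matching the single chemical step of a conversion kit. Since
molecules are independent, the per-position base counts of a pool of $n$
molecules are binomial, and the pool stores those counts directly; they are
the sufficient statistic for everything downstream, and materialising $10^4$
molecule strings would buy nothing.

Traces are rendered one Gaussian peak per called base per channel, with
amplitude proportional to the base frequency at that position (total
amplitude constant before noise), additive Gaussian noise clipped at zero,
and peaks every 10 scans. This deliberately models the *peak amplitudes* the
analysis consumes, not scan-resolution instrument physics: no mobility
shifts, no dye blobs, no heteroduplex artifacts, no strand-specific (G/A)
chemistry. Passing tests therefore validate the estimator and pipeline
logic, not robustness to every failure mode of a real capillary instrument.

qPCR plates are simulated per sample in triplicate for a target and a
reference (housekeeping) gene; the true per-sample $\Delta Ct$ equals the
calibrator $\Delta Ct$ plus $\log_2(1/\text{fold})$, with sample-level and
well-level noise both $\mathcal{N}(0, 0.15)$ cycles by default.

## CpG island and islet detection

`find_cpg_islands()` implements the classic composition criteria: a 100 bp
window passes when GC $\geq 50\%$ and observed/expected CpG
$= \frac{N_{CpG} \cdot L}{N_C \cdot N_G} \geq 0.6$. Windows slide by 1 bp; a
maximal run of passing starts spans from its first start to its last start
plus window − 1; runs whose spans overlap are merged so calls never overlap;
and spans of at least `minlen` are reported. Spans of 200 bp or more are
classed `island`, shorter ones `islet` — short regions that meet island
composition without reaching the conventional 200 bp length.

Numerical conventions: a CG dinucleotide counts for a window only when both
bases lie inside it; a window with no C or no G has observed/expected
defined as 0 (it fails the threshold anyway, and this avoids a 0/0). The
run-of-passing-windows rule is simpler than the decade-old EMBOSS
implementation's internal averaging and is fully deterministic; exact
agreement with EMBOSS output on edge cases is not guaranteed and not
claimed. Both composition statistics are tested against a direct-count
oracle on random sequences.

## TFBS scanning

`scan_sequence()` scores every window of every matrix with a MATCH-style
matrix similarity score. From a position frequency matrix (JASPAR text
format) with a total pseudocount of 0.8 split by a uniform background,
position $i$ carries information weight
$I(i) = \sum_b f(i,b)\,\ln(4 f(i,b))$, a site scores
$\sum_i I(i) f(i, s_i)$, and the score is min–max normalised so the
consensus site scores exactly 1 and the anti-consensus 0. A hit is a window
scoring at least $1 - d$ with deficit $d = 0.15$ by default (i.e. score
$\geq 0.85$). Scanning defaults to the plus strand, matching the convention
of selecting positive-strand predictions for promoter analyses; minus-strand
scoring uses the reverse complement.

Two simplifications are deliberate. MATCH's separate core-similarity filter
is omitted: it adds an unstated second parameter, and the matrix score alone
defines the deficit semantics. And multiple hits or matrix versions of one
factor collapse to one *factor* in `classify_regulators()`, because
regulator tallies count factors, not sites. The score implementation is
tested against exhaustive enumeration of all sites for short matrices.

The shipped motif set (`example_motifs.jaspar`) and regulator table
(`synthetic_regulators.tsv`) are synthetic fixtures with GC-box-like,
ETS-like and AT-rich matrices and invented activity/expression annotations;
they exercise the scanner and classifier but are not JASPAR matrices, and
factor counts obtained with them are not comparable to counts from a real
collection.

## Statistics

Site-wise screening uses two-sided Welch $t$-tests per stage pair — the
safer default at $n = 3$ when "pairwise t-tests" is all the design states —
reported unadjusted as a screen, with degenerate zero-variance cases given
$p = 1$ (equal means) or flagged with $p \to 0$ (unequal means).

The region-level test groups each region's member CpGs as repeated measures
within an animal, with stage a between-subject factor: the omnibus $F$
tests the stage mean square against the between-animal (within-stage) mean
square — `aov(percent ~ stage + Error(animal))`. Post-hoc pairwise stage
contrasts run on animal-level region means with pooled-SD $t$-tests and
Bonferroni adjustment (multiplied by the number of comparisons, capped
at 1). Where a design is described both as repeated-measures and one-way in
different places, both readings are available: `mode = "oneway"` runs a
plain one-way ANOVA on the animal-level region means. The two agree closely
here because, with balanced data, the between-subject stratum of the
repeated-measures fit is the ANOVA on animal means. Under the null the
omnibus rejects at the nominal 5% rate (checked by simulation), and a
region with fewer than two usable sites is marked not evaluable rather than
tested.

Relative expression uses the $\Delta\Delta Ct$ method: replicates averaged,
$\Delta Ct = Ct_{target} - Ct_{reference}$ per sample, $\Delta\Delta Ct$
against the calibrator-stage mean, relative quantity $2^{-\Delta\Delta Ct}$.
The calibrator stage has geometric-mean relative quantity exactly 1 by
construction, and stage summaries use the geometric mean accordingly
(arithmetic means of $2^{-x}$ would not anchor at 1). Stages are compared by
one-way ANOVA on $\Delta\Delta Ct$ (equivalently $\log_2$ relative
quantity, the scale on which qPCR noise is approximately normal) with Tukey
HSD. The whole procedure is invariant to plate-wide Ct shifts.

Methylation–expression association is the Pearson correlation between
animal-level region mean methylation and the same animal's relative
quantity. Pairing is per animal (nine pairs in the default design), not per
stage mean: a three-point correlation is essentially degenerate, and the
animal-level pairing is the only version with any resolution — this is an
interpretation choice and is flagged as such. Fewer than three complete
pairs returns `NA`.

## Problem sizes and reproducibility

All simulations are bit-reproducible given a seed; every generator takes one
explicitly, and the pipeline derives per-stage sub-seeds from the run seed.
Default problem sizes were chosen to keep a full run interactive: one
simulated cohort (9 samples × 2 amplicons of a 1080 bp promoter, $10^4$
molecules per pool) runs in a few seconds; the operating-characteristic
simulations in the test suite and acceptance script use 100 cohorts for
power and 500 for type-I error at the methylome level (the trace layer adds
sub-point noise and is exercised separately by the recovery check).

## Known limitations

* The trace model is per-base-position, not per-scan physics; quality
  scores, mobility correction and SCF input are out of scope.
* Reverse-strand (G/A) bisulfite reads and clone-based (per-molecule)
  sequencing are not modelled.
* Island detection follows the stated composition parameters with a simple
  deterministic run rule; it is not a re-implementation of EMBOSS Cpgplot.
* The TFBS scanner omits MATCH's core filter, and the shipped motif set is
  synthetic; factor counts from it characterise the scanner, not any real
  promoter.
* qPCR amplification-efficiency correction is not implemented; the
  $\Delta\Delta Ct$ method assumes efficiencies near 2.
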