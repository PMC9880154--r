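# methylotrace

Promoter DNA methylation analysis from **direct bisulfite Sanger
sequencing** — the setting where a bisulfite-converted, PCR-amplified pool
of molecules is sequenced as one chromatogram and the methylated fraction of
every CpG appears as a mixed C/T peak. The package is aimed at groups who
quantify promoter methylation of candidate genes (e.g. puberty-related,
imprinted loci) across conditions or developmental stages with Sanger
traces and qPCR, rather than with genome-wide bisulfite sequencing.

## What it computes

For each reference cytosine in CpG context covered by a read, methylation is
estimated from the trace peak amplitudes as

```
methylation % = 100 · I_C / (I_C + I_T)
```

after aligning the base calls to the in-silico converted reference (C→T).
Around that core estimator the package provides:

* **Trace IO** — AB1 (ABIF) chromatogram reading and writing, a lossless
  plain-text TSV trace dialect, and primary/secondary base calling with a
  mixed-base threshold (default 0.33 of the primary amplitude).
* **CpG island/islet detection** — 100 bp sliding windows, GC ≥ 50%,
  observed/expected CpG = (N_CpG·L)/(N_C·N_G) ≥ 0.6; spans ≥ 200 bp are
  islands, shorter passing spans (≥ 100 bp) are islets.
* **TFBS scanning** — JASPAR-format PWMs scored with a MATCH-style,
  information-weighted matrix similarity score in [0, 1]; hits at score
  ≥ 1 − deficit (default deficit 0.15), plus regulator classification by
  activity and expression.
* **Statistics** — site-wise Welch screens, region-grouped
  repeated-measures ANOVA with Bonferroni post-hoc, ΔΔCt relative
  expression (2^−ΔΔCt) with one-way ANOVA/Tukey, and animal-level
  methylation–expression Pearson correlation.
* **A synthetic-data module** — promoters with a planted CpG islet,
  cohorts, bisulfite-converted molecule pools, rendered chromatograms and
  qPCR plates with known ground truth, so the whole pipeline is testable
  end to end without instrument data.

See `vignettes/methylotrace-methods.Rmd` for the model, parameter choices
and limitations.

## Worked example

Simulate the default study design (3 stages × 3 animals, a 1080 bp promoter
with 32 CpGs and a ~120 bp islet at −200..−80, 10⁴ molecules per trace) and
run the full pipeline:

```r
library(methylotrace)
res <- run_all(run_config(overrides = list(out = "demo_run", seed = 1)))

res$islands
#>  start end length mean_gc mean_obs_exp n_cpg klass
#>    614 790    177 54.4026    0.7428605     7 islet

subset(res$regions$posthoc, region_id == 2)
#>  region_id stage_a stage_b      diff      p_raw      p_adj
#>          2   PND14   PND35 -4.828938 0.05748349 0.17245048
#>          2   PND14   PND56 -7.564659 0.01041908 0.03125724
#>          2   PND35   PND56 -2.735721 0.23237962 0.69713885

res$expression$stages
#>  stage mean_rq sd_ddct n
#>  PND14   1.000   0.225 3
#>  PND35   0.313   0.204 3
#>  PND56   0.293   0.141 3

res$correlation
#>  region_id       r n_pairs
#>          1 -0.5849       9
#>          2 -0.7003       9
#>          3 -0.6340       9
#>          4  0.0133       9
#>          5 -0.5282       9
```

Reading the output: the planted islet is recovered as the single `islet`
call (177 bp span covering the planted ~120 bp composition core, 7 CpGs);
the islet-bearing region 2 is ~5 points less methylated pre-puberty than at
puberty and ~7.6 points less than post-puberty (omnibus repeated-measures
p = 0.028 for this seed); target expression drops ~70% at puberty and stays
low; and region-2 methylation anti-correlates with expression across the
nine animals (r = −0.70). The run directory contains every intermediate:
reference FASTA, CpG catalog, per-sample traces, merged profiles,
conversion QC, island calls, TFBS hits, statistics tables and a replayable
log.

A thin command-line wrapper is included at `inst/cli/methylotrace.R`
(subcommands `run-all`, `islands`, `scan-tfbs`, `stats`).

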