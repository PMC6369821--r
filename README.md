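# neuroedit

Comparative analysis of adenosine-to-inosine (A-to-I) RNA editing across cell
populations, for transcriptomics studies that sequence several neuronal (or
other) populations with a few biological replicates each, by RNA-seq or
targeted amplicon sequencing (mmPCR-seq).

A-to-I editing is read out as an A-to-G mismatch on the transcribed strand
(T-to-C on the genomic minus strand), and the editing level at a site is
estimated from allele counts as G / (A + G). Starting from per-site base
counts (or a BAM/SAM plus a site list), the package provides:

- **Discovery**: de novo editing-site calling from full A/C/G/T counts with a
  configurable filter cascade (depth, alt reads, allele-fraction window, SNP
  exclusion), 12-way conversion tally with the A-to-G + T-to-C signature
  fraction, known/novel partition, annotation and repeat summaries, and
  100-base locus grouping.
- **Quantification**: editing levels from counts, replicate pooling by
  summed counts, an inclusion rule (≥ 20× pooled coverage in ≥ 7 of 10
  populations, replicate spread ≤ 0.2), and per-replicate overall editing.
- **Differential editing**: two-sided Fisher's exact tests on pooled allele
  counts over all population pairs, BH/Bonferroni/none multiplicity
  handling, and a joint significance gate: adjusted p < 0.05 **and** an
  absolute level difference > 20 percentage points.
- **Population specificity**: per-replicate z-scores against the grand
  mean/SD over all replicates of all populations; a site is specific to a
  population when all of its replicates have |z| > 1.65 with a common sign
  and the pooled level is ≥ 10 points from the next closest population;
  χ² category enrichment of the specific set.
- **Isoform linkage**: read-backed phasing of site clusters (within 40
  bases), observed isoform usage versus the independence expectation
  P(isoform) = ∏ pᵢ^[G] (1−pᵢ)^[A], Student's/Welch's t comparisons, and
  sequential-editing order inference.
- **Synthetic data**: a ground-truth generator (negative-binomial coverage,
  beta-binomial replicate noise, planted shifts, SNP-like artifacts, joint
  isoform tables: independent / fully linked / sequential / custom) that
  backs every statistical test in the package.

## Worked example

Simulate a 10-population × 3-replicate study with six sites planted 35
points higher in population 2, then run the full pipeline:

```r
library(neuroedit)

truth <- synthetic_truth(
  n_populations = 10, replicates = 3, n_sites = 150,
  specific = data.frame(site = 1:6, population = 2, shift = 0.35),
  mean_depth = 300, seed = 42)
sim <- gen_counts(truth)
sim$counts
#> edit_counts: 150 sites x 30 samples (with full base counts)
#>   median per-sample coverage: 288
#>   mean defined editing level: 0.224

res <- run_pipeline(sim$counts, sim$sheet, out_dir = "results_demo")
sum(res$inclusion$keep)
#> [1] 136
sig <- res$differential[res$differential$significant, ]
nrow(sig); length(unique(sig$pos))
#> [1] 54
#> [1] 6
res$specific[, c("pos", "population", "direction", "min_abs_z", "gap_to_next")]
#>    pos population direction min_abs_z gap_to_next
#> 1 1000      pop02      high  2.232515   0.3152982
#> 2 2000      pop02      high  1.913980   0.2413228
#> 3 3000      pop02      high  2.436422   0.2808593
#> 4 4000      pop02      high  2.351749   0.2959342
#> 5 5000      pop02      high  2.429704   0.3342126
#> 6 6000      pop02      high  2.453777   0.3255831
```

136 of 150 sites pass the coverage/reproducibility rule; the 54 significant
pairwise records all involve the six planted sites (each differs from
several other populations), and the specificity rule recovers exactly those
six sites as high in `pop02` — every replicate |z| above 1.65 and pooled
levels 24–33 points above the next closest population.

Isoform linkage on a two-site cluster, with reads drawn from a joint
distribution in which the fully-unedited (AA) and fully-edited (GG) isoforms
are overrepresented:

```r
joint <- joint_isoform_table(mode = "custom",
  table = c(AA = 0.67, AG = 0.035, GA = 0.035, GG = 0.26))
reads <- gen_cluster_reads(joint, 10000, seed = 1)
ic <- isoform_counts(do.call(rbind, strsplit(reads, "")),
                     sites("chr2L", c(100L, 140L)), strand_adjust = FALSE)
ic[1:4]
#>   AA   AG   GA   GG
#> 6657  362  373 2608
observed_vs_expected(list(ic))[, 1:4]
#>   isoform mean_observed mean_expected mean_diff
#> 1      AA        0.6657        0.4934     0.172
#> 2      AG        0.0362        0.2085    -0.172
#> 3      GA        0.0373        0.2096    -0.172
#> 4      GG        0.2608        0.0885     0.172
```

Both marginals are ~30% edited, so independence would predict 49% AA and 9%
GG; the observed 67%/26% — a symmetric +17-point excess of the concordant
isoforms — is the signature of sites edited together on the same
transcripts.

See `vignette("comparative-editing")` for the statistical models,
parameter defaults, and design rationale.

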