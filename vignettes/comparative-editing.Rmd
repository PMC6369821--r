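---
title: "Comparative A-to-I editing analysis: models and methods"
author: "neuroedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative A-to-I editing analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroedit)
```

## The problem

Adenosine-to-inosine (A-to-I) editing by ADAR enzymes rewrites individual
bases in neuronal transcripts, and inosine is read as guanosine by both the
ribosome and the sequencer. An editing site therefore shows up as an A-to-G
mismatch on the transcribed strand (T-to-C on the genome's minus strand), and
the *editing level* — the fraction of transcripts edited at the site — is
estimated from read counts as

$$\hat\theta = \frac{G}{A + G}.$$

When several cell populations are sequenced separately (each with a few
biological replicates, via RNA-seq or targeted mmPCR-seq amplicons), four
questions follow, and `neuroedit` implements one module for each:

1. **Discovery** — which genomic positions are editing sites at all?
2. **Differential editing** — at which sites do two populations differ?
3. **Population specificity** — which sites are uniquely regulated in exactly
   one population?
4. **Isoform linkage** — when several sites sit within one read's reach, are
   they edited on the *same* transcripts or independently?

A synthetic-data generator with known ground truth ties the modules together:
every statistical claim made by the test suite is a parameter-recovery or
property check against planted truth, never against external data.

## Site discovery

Discovery consumes full A/C/G/T base counts pooled across the replicates of a
population and calls any position where a non-reference base passes a filter
cascade: minimum depth (default 20), minimum alternative reads (3),
alternative allele fraction between 0.05 and 0.95, and absence from a
user-supplied SNP exclusion list. The upper allele-fraction bound removes
homozygous-SNP-like positions; the exclusion list handles known
polymorphisms. All twelve ref-to-alt conversion classes are tallied: in a
clean experiment the A-to-G plus T-to-C share of de novo variants is high,
and the tally is the standard specificity diagnostic. During pileup,
mismatches within 5 bases of the aligned read ends are masked
(`trim_ends = 5`), where alignment artifacts concentrate.

These thresholds vary across published editing pipelines, so each one is
explicit configuration (`discovery_config()`), with the package defaults
reflecting common practice rather than any single study. Raising any
threshold can only shrink the call set — a property the tests assert over
randomized count tables.

Identified sites are partitioned against a user-provided known-site list,
summarised by functional category and repeat overlap, and grouped into loci
by single-linkage chaining with a 100-base gap rule: adjacent sites closer
than `locus_gap` share a locus. Chaining equals the connected components of
the pairwise-proximity graph; the tests verify this against a brute-force
O(n²) oracle.

## Quantification and site inclusion

Editing levels are always computed from counts, and replicates are pooled by
*summing counts*, never by averaging levels: a replicate with more reads
carries proportionally more weight, exactly as if its reads had been
sequenced in one library. The same logic gives the per-replicate *overall
editing level*, the total G over total A+G across all sites — a
coverage-weighted aggregate.

Comparative analysis is restricted to sites that can actually be compared.
The inclusion rule (`inclusion_rule()`) keeps a site when

* its pooled coverage reaches `min_coverage` (default 20×) in at least
  `min_populations` (default 7) of the populations, and
* within every covered population, the spread (max − min) of editing levels
  among replicates that individually reach `min_coverage` is at most
  `reproducibility_max_spread` (default 0.2).

Both boundaries are inclusive. The spread criterion is our operationalisation
of "reproducible between replicates"; it is deliberately simple and fully
configurable. One consequence worth knowing: the rule is monotone in
`min_populations` and in the spread bound, but not strictly in
`min_coverage`, because lowering the coverage cutoff enlarges the set of
populations and replicates that the spread check applies to. This coupling is
inherent to any "reproducible where covered" definition; the tests therefore
assert monotonicity for the two unambiguous fields and monotone coverage
counts for the third.

Where a site is measured by both RNA-seq and targeted amplicons, counts
should be merged upstream per the user's source-priority policy (typically
the deeper source); the container is agnostic to the technology.

## Differential editing

For every site and every unordered pair of populations, the pooled A/G counts
form a 2×2 table tested with a two-sided Fisher's exact test
(`stats::fisher.test`; the suite cross-checks it against direct
hypergeometric enumeration). A pair is flagged significant only if **both**

* the multiplicity-adjusted p-value is below `alpha` (default 0.05), and
* the absolute level difference exceeds `min_delta` (default 0.20, i.e. 20
  percentage points).

The effect-size gate means a site with overwhelming counts but a 19-point
difference is *not* called — statistical and biological significance are
required jointly, and every flagged record satisfies the gate by
construction.

Multiplicity is handled across all site × pair tests jointly;
Benjamini–Hochberg is the default, with Bonferroni and `"none"` available —
the raw-p mode mirrors analyses that quote unadjusted *P* < 0.05 for pairwise
panels. Per-population summaries count, for each population, the sites edited
higher (or lower) than at least one other population, binned by how many
other populations differ.

## Population-specific sites

For each site, every replicate's level is standardised against the grand
mean and standard deviation over *all* covered replicates of *all*
populations (sample SD, n−1; a population-SD option exists). A site is
called specific to one population when

* **every** replicate of that population has |z| > 1.65 with a common sign,
  and
* the population's pooled level is at least 10 percentage points away from
  the next closest population's pooled level.

The 1.65 cutoff is the one-sided 5% point of the normal; demanding it of all
replicates simultaneously is what gives the rule its specificity, and on
fully null synthetic data the realised call rate is far below 1%. The
"10% different" gap is interpreted as an absolute editing-level difference
(percentage points), consistent with how editing differences are quoted
throughout; ties for next-closest resolve to the minimal gap, which is
conservative. A site may in principle be called in two populations only in
opposite directions; such calls are emitted as separate rows.

Whether z-scores should be computed on raw or variance-stabilised
(arcsine/logit) levels is genuinely open; raw levels are used because the
calling rule operates on level *differences* in natural units and the gap
criterion is defined on the same scale.

Enrichment of the specific set by functional category uses one 2×2 χ² per
category, comparing the category's share among specific sites with its share
among all tested sites (the background deliberately includes the specific
sites, mirroring the "X% of specific vs Y% of all tested" framing).

## Editing-isoform linkage

Sites within `cluster_window = 40` bases of another site (single-linkage,
clusters of 2–4 sites) can be phased by single reads or amplicons. For each
read covering *all* sites of a cluster, the joint A/G pattern — the *editing
isoform* — is recorded; reads with any other base at a cluster site are
discarded. Marginal edited fractions recomputed from the isoform table equal
the per-site levels from the same reads exactly, an invariant asserted in the
tests.

Under independent editing, isoform probabilities are products of marginals:
$P(\text{isoform}) = \prod_i p_i^{[G_i]}(1-p_i)^{[A_i]}$ — also the
multinomial MLE under the independence model, which the tests confirm by
direct likelihood maximisation. Crucially, the expectation is always computed
from the marginals of the *same spanning-read set*, never from rounded
external level estimates; mixing rounded marginals into the expectation
produces inconsistencies of several percentage points.

Coregulated clusters show the signature of an excess of the fully-unedited
and fully-edited isoforms, with mixed isoforms depleted — provably so under
full positive linkage, and asserted on constructed inputs. Per-isoform
observed-minus-expected differences are tested across replicates with a
one-sample Student's t; population-vs-others isoform usage uses Welch's t
with a 10-point mean-difference gate.

`ordering_inference()` addresses sequential editing: if site *i* must be
edited before site *j*, reads with G at *j* but A at *i* should be nearly
absent while the converse pattern stays common. The rule emits "*i* precedes
*j*" when the *j*-only pattern falls below `noise_floor` (default 2% of
spanning reads), the *i*-only pattern reaches the floor, and both sites are
edited above the floor; symmetric absence of both mixed patterns (full
linkage) yields no order, by design.

## The synthetic-data generator

`synthetic_truth()` fixes the study design the tests assume: 10 populations ×
3 replicates, per-site true levels drawn from Beta(1.2, 4) (editing levels
are mostly low with a long right tail), negative-binomial coverage (mean 300,
size 10 — moderately overdispersed, as bulk libraries are), and
beta-binomial replicate noise with intra-class correlation ρ = 0.01, which
reproduces the "highly reproducible replicates" regime while still being
noisier than pure binomial sampling. Planted population-specific shifts,
SNP-like artifact positions (allele fraction ~0.5 or ~1.0) and low-level
non-A-to-G conversion noise are all optional and recorded in the truth
object, so every test can compare pipeline output against generator
bookkeeping.

Cluster reads are drawn from explicit joint isoform tables: `independent`
(product), `fully_linked` (all-or-none; requires equal marginals),
`sequential` (editing at site 1 gates the rest; conditional probabilities
chosen to hit the requested marginals, which must be non-increasing from
site 1), or `custom` (any validated table). Every mode's table matches its
declared marginals to 10⁻⁹, and reads can be emitted as toy SAM records to
exercise the BAM pileup and phasing paths end to end.

What the generator does **not** emulate: position-dependent sequencing error,
amplification bias between amplicons, double-stranded RNA structure driving
ADAR preference, or expression differences between populations. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated sampling models, not robustness to every artifact of real
libraries.

## Numerical and degenerate-input choices

* Levels are `NA`, never 0, at zero coverage; an all-zero Fisher table
  returns p = 1 with a warning.
* Sites with zero level variance across replicates are skipped by the z-score
  module (z is undefined), with the flat-levels case covered in tests.
* Observed-vs-expected t tests return p = 1 when all replicate differences
  are exactly zero (no departure, no variance) and `NA` when variance is zero
  but the mean is not.
* Single-linkage chaining breaks ties deterministically by (chrom, strand,
  position) ordering; a gap exactly equal to the threshold splits.
* All randomness flows through a single integer seed per generator call;
  reruns are byte-identical, and the test suite asserts this on serialized
  output.

## Problem sizes

The test suite and the reproduction script run entirely on synthetic data at
deliberately modest scales — hundreds of sites, 10 populations × 3
replicates, coverage 200–2,000×, up to 10⁵ simulated reads — chosen so that
Monte-Carlo error is small relative to every asserted tolerance while the
whole suite completes in about a minute.

## Known limitations

* Pileup distance-to-read-end masking is computed in reference-layout
  coordinates; for reads with indels near a site the masked window can
  differ by the indel length from the query-coordinate distance.
* The differential module tests pooled counts; replicate-level mixed models
  and covariate adjustment are out of scope.
* Paired-end mates are treated as independent reads by the phasing
  extractor; mate-aware deduplication should happen upstream (duplicate
  flags are honoured).
* Known-site lists, SNP lists and annotations are inputs; the package ships
  none.
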