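---
title: "Cross-platform somatic variant interpretation with crossvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform somatic variant interpretation with crossvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossvar)
```

# The problem

Tumor genomes are routinely characterized by sequencing a tumor sample and a
matched normal from the same patient, often on more than one platform
(whole-exome capture, WES, and whole-genome sequencing, WGS) and with more
than one variant caller. Each caller/platform combination has its own error
profile, and a large fraction of raw calls are private to a single
technology. `crossvar` implements an interpretation layer on top of such
call sets: it merges them into evidence tiers, separates somatic from
germline variants, estimates tumor cellularity, characterizes the somatic
mutational spectrum and its signatures, scores genes for exonic
conservation against a population panel, flags pathway-level variant
burdens, and filters structural variants. Because the kind of patient data
this pipeline targets is generally not publicly distributable, the package
ships a synthetic-data generator that emulates every input with recorded
ground truth; all tests run against that stated world.

# Consolidation model

Every call is a `(chrom, pos, ref, alt)` key observed by one caller on one
platform for one sample role, with read support summarized as the mutant
allele fraction MAF = alt reads / depth (depth 0 means no support). Keys
are grouped per sample role and classified:

* **cross-platform**: called by at least one caller on either platform,
  with MAF strictly greater than 5% on *both* platforms. The non-calling
  platform's evidence may come from a pileup support table rather than a
  formal call, mirroring the practice of validating one technology's calls
  against the raw reads of the other.
* **single-technology**: everything else that was called.

The 5% bound is strict (a MAF of exactly 0.05 fails), following the
"larger than 5%" phrasing of the filter the package reproduces. Indels are
trimmed to minimal representation and left-aligned against the reference
before keying, so callers reporting different representations of one event
merge.

A tumor variant is **somatic** when the matched normal shows neither a
call at the key nor a pileup MAF above `normal_maf_max` (default 0.05 —
the original workflow states "present only in the tumor" without a bound,
so it is an explicit parameter here), and the tumor site is covered by at
least `min_reads = 3` reads on each platform where coverage is known.
A tumor variant with no normal evidence at all is *unclassifiable*
(`somatic = NA`), never silently somatic.

**Candidates** are somatic, novel (not in the dbSNP-like known-sites set),
protein-altering variants that are either stopgain, or predicted damaging
and located at a conserved position or in a conserved gene (see ECS). The
candidate branch operates on SNVs' functional classes; small indels flow
through tiering and somatic extraction identically but are not
candidate-eligible under this rule.

# Cellularity

For clonal heterozygous variants in a diploid tumor with purity $p$, the
expected somatic MAF is $p/2$; the estimator is therefore twice a central
statistic of the somatic MAF distribution, restricted to the window
$(0.05, 0.5]$ to exclude sub-threshold noise and homozygous/LOH tails.
The default central statistic is the mode of a Gaussian kernel density
estimate (bandwidth 0.03, a compromise between resolving the clonal peak
and smoothing binomial sampling noise at typical 40–100x depths); the
median is available as an alternative since the original description does
not state which statistic was used. Fewer than 20 usable MAFs is an error
rather than a silent estimate. Copy-number aberrations and subclonal
structure are explicitly out of scope: under CNVs the factor 2 is wrong
locally, and a large subclone biases the mode low. This is a first-pass
estimate of the kind used to sanity-check somatic call sets, not a
substitute for CNV-aware purity tools.

# Mutational spectrum and kataegis

Somatic SNVs are collapsed onto the six pyrimidine-referenced substitution
classes (C>A, C>G, C>T, T>A, T>C, T>G) with their 5'/3' flanking bases,
giving the standard 96 channels. (Some descriptions of this analysis list
the six classes as C>A, C>G, C>T, G>A, G>C, G>T; that set is not a
strand-collapsed partition, and the results discussed in terms of T>C and
T>G patterns imply the standard pyrimidine convention, which is what the
package uses.) For heatmap display the channel fractions are divided by
the strand-collapsed trinucleotide frequencies of the reference and
log10-transformed; zero cells receive a pseudo-count of 0.5 before the log
(the quantity is display-only, so the exact pseudo-count is
inconsequential; 0.5 is the conventional half-count). SNVs at contig edges
have no trinucleotide context and are excluded with a count.

Rainfall distances are the classic per-chromosome distance to the previous
somatic SNV. Cluster (kataegis) detection reports maximal merged windows
in which at least `min_snvs` SNVs fall within `window_bp` bases, using a
two-pointer sweep anchored on SNV positions; the default rules, 8 SNVs in
160 bp and 50 SNVs in 5000 bp, are the published start parameters for this
analysis. Anchoring windows on SNV positions covers every qualifying span;
the test suite verifies exact agreement with a brute-force all-windows
oracle. Merged windows may exceed `window_bp` when qualifying spans chain.

# Signatures

De novo extraction factorizes the 96 x n count matrix by NMF with
multiplicative updates under the Frobenius objective, 50 random restarts
by default, keeping the best fit; the objective is non-increasing across
updates and the winning restart index is reported for reproducibility.
Plain NMF is only identifiable up to an invertible non-negative mixing,
so profile recovery is guaranteed only when samples "anchor" the
signatures (each signature dominates some sample); the tests encode
exactly that case.

Refitting decomposes a spectrum over a known catalog by non-negative
least squares (Lawson–Hanson active set, written here because no NNLS
routine ships with the available dependencies), followed by the
conventional pruning step: exposures below `min_exposure = 0.06` are
zeroed and the fit re-run on the survivors. Exposures are fractions of
the spectrum; if the unconstrained sum exceeds 1 it is renormalized to 1,
and any remaining mass is reported as `unknown_fraction`, so exposures
plus unknown always sum to exactly 1.

# Exonic conservation score (ECS)

For a population panel of $S$ samples, with $V_g$ coding non-synonymous
variants in gene $g$ (summed over samples), exonic union length $L_g$,
total modeled exonic length $L_{tot} = \sum_g L_g$, and mean per-sample
exonic variant count $V_{avg}$:

$$\mathrm{ECS}_g = \frac{V_g \cdot L_{tot}}{L_g \cdot V_{avg} \cdot S}$$

This is the gene's per-bp panel variant rate divided by the panel-wide
average rate: a dimensionless rate ratio. Reading $L_{tot}$ as the union
length over all modeled genes and $V_{avg}$ as the per-sample mean is the
only interpretation under which the score is "the mutation rate within
the gene divided by the average mutation rate", and it yields the exact
identity $\sum_g \mathrm{ECS}_g L_g / L_{tot} = 1$ whenever every panel
variant falls in a modeled gene — asserted to 1e-9 in the tests. (The
alternative, averaging $V_{avg}$ over genes, only rescales all scores and
is available via `avg_over = "genes"`.) Genes with ECS strictly below
0.01 are called conserved; smaller means more conserved, and a gene with
no panel variants scores 0. A variant inside two overlapping genes counts
for both, so no score depends on an arbitrary tie-break. Note that a
panel VCF cannot represent samples with zero variants, so `n_samples`
should be supplied explicitly when some panel samples are empty.

# Pathway burden

Damaging variants are aggregated per GO term through a gene-to-term map
(a gene in several terms contributes to all of them). A term is enriched
when the tumor's count — of affected genes or of variants — strictly
exceeds the *maximum per-sample* count in the panel, never the pooled
count. Strictness means a tumor statistically indistinguishable from the
panel is flagged at rate at most $1/(S+1)$ per term (exchangeability);
the acceptance test verifies this rate in a high-load regime (per-term
Poisson mean 400) where discreteness ties, which can only deflate the
rate below $1/(S+1)$, are negligible. Term-hierarchy propagation is out
of scope; the map is taken as given.

# Structural variants

Split reads pass when they have >= 95 positions with base quality >= 35,
at most two alignment parts, and >= 92 mapped bases in total. A tumor SV
is somatic when no control SV of the same type matches it — reciprocal
overlap >= 0.5 for interval types, both breakpoints within 100 bp for
translocations; the matching rule of the original workflow lives in an
unavailable supplement, so both values are exposed parameters with these
defaults. Overlapping somatic SVs of one type are merged into clusters
for a "non-overlapping" count. For de novo insertions, a tumor-assembled
contig is germline — and excluded — when control-sample reads cover at
least 90% of its positions (inclusive bound: 90 of 100 covered positions
is germline). Gene annotation labels events exonic/intronic/intergenic
and flags insert positions within 100 kb of the nearest gene.

# The synthetic stated world

`sim_config()` defaults describe the design the pipeline targets at desk
scale: a 1 Mb single-chromosome reference with 50 non-overlapping genes;
tumor purity 0.30 (the study-like microsatellite-unstable case); 200
somatic SNVs drawn from a signature mixture (60/40 of a deamination-like
C>T profile and a 5'-C T>G profile, the two processes contrasted in the
tumors this pipeline was built around) with positions sampled from
matching reference trinucleotide contexts; 500 germline SNVs (30%
homozygous); per-platform depths of 100x (WES) and 40x (WGS), plausible
for the two technologies; detection probability 1 per caller by default,
with platform-private false positives injectable to emulate
single-technology artifacts; and a 1092-sample population panel with
per-gene Poisson rates of 5e-4 non-synonymous variants per exonic bp per
sample (roughly the per-bp coding variant load seen in population panels)
scaled by gamma-distributed per-gene multipliers, a tenth of the genes
planted as strongly conserved.

Somatic MAFs are Beta-distributed with mean purity/2 and concentration
100; `maf_concentration = Inf` gives the deterministic noise-free limit
(every somatic MAF exactly purity/2), which together with
`read_noise = FALSE` defines the "noise-free, full detection" world in
which somatic precision and recall are required to be exactly 1. With
finite concentration a small fraction of true MAFs can fall below the 5%
support bound, so perfect recall is only a property of the noise-free
limit — by design, since the thresholds themselves are under test
elsewhere.

What the generator does *not* emulate: read-level artifacts (mapping
error, strand bias, FFPE damage), copy-number variation and subclonal
structure, indel-rich microsatellite loci, and realistic linkage between
germline variants. A green test therefore establishes the correctness of
the decision rules and estimators on their stated model, not robustness
to artifacts these rules were not designed to see.

# Numerical choices and degenerate inputs

* MAF with depth 0 is undefined and fails every threshold.
* All thresholds follow their stated direction of strictness: MAF
  "larger than 5%" (strict), ECS `< 0.01` (strict), burden `>` panel max
  (strict), split-read bounds `>=` (inclusive), insertion coverage
  `>= 90%` (inclusive).
* `estimate_purity` errors below 20 usable MAFs; `ecs` errors on zero
  denominators; `fit_exposures` errors on an all-zero spectrum; VCFs
  without recoverable depth fields are rejected with a named error.
* Conflicting REF alleles at one position are kept as distinct variant
  keys; no reconciliation is attempted.
* All simulation is a pure function of `sim_config` (including the seed);
  per-stage seeds are derived deterministically from it.

# Limitations

The pipeline consumes caller outputs; it does not call variants, align
reads, or assemble contigs. The purity model ignores CNVs. The ECS panel
is assumed to be annotated consistently with the tumor calls. Reported
headline numbers of the study this design follows (somatic counts per
tumor, 30%/48% cellularity, specific signature exposures, SV counts)
derive from patient data that was never deposited, so the package
validates procedures against synthetic ground truth rather than
reproducing those values.
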