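---
title: "Methods: joint population genomics of an endosymbiont and mtDNA in an inbred host panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint population genomics of an endosymbiont and mtDNA in an inbred host panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytopop)
```

## The problem

Maternally inherited endosymbionts such as *Wolbachia* are co-transmitted
with the host's mitochondria in a single maternal cytoplasm. When an
infection sweeps a host population, both cytoplasmic genomes hitchhike
together: diversity collapses, genealogies flatten into stars, and any
variation in bacterial titre becomes a phenotype the host's nuclear genome
may partly control. `cytopop` implements the full analysis chain for such a
system on a panel of inbred, effectively haploid host lines sequenced with
short reads:

1. infection calling from depth and breadth of sequencing coverage;
2. relative titre (copy number) of the endosymbiont and mtDNA from
   organelle-to-nuclear depth ratios;
3. nucleotide diversity (π, Watterson's θ) and Tajima's D, tested against a
   neutral coalescent null conditioned on the observed number of
   segregating sites;
4. linkage disequilibrium between variants on the two cytoplasmic genomes
   as a co-transmission proxy;
5. distance-based genealogy summaries that quantify star-likeness;
6. per-SNP association of nuclear genotypes with the two titre phenotypes,
   singly and jointly.

Upstream read mapping and variant calling are out of scope: the pipeline
consumes VCFs, per-base depth tables (bedtools `genomecov` dialects), and
reference FASTAs.

## Data model

Genotypes live in a `variant_matrix`: an n × S haploid-coded allele matrix
(0 reference, 1 alternate, `NA` missing) with strictly increasing 1-based
positions and the contig length attached, so per-site statistics can be
normalised over monomorphic bases too. Inbred diploid calls collapse
0/0 → 0, 1/1 → 1; heterozygous calls default to missing (the expectation
for fully inbred lines), configurable to reference or alternate for the
consensus/diversity stages, where the right treatment is genuinely
ambiguous. Consensus output at missing sites emits the reference base by
default (configurable to `N`).

All coordinates are 1-based closed, matching VCF; BED input/output converts
from/to 0-based half-open on the fly. Windows tile the contig as
[1..w], [w+1..2w], …, keeping the last partial window.

## Quality control

Three site-level filters run before any statistic, in this order:

* **biallelic SNPs only** — indels and multi-allelic records removed;
* **missingness** — sites with a missing fraction strictly above 10%
  removed (a site at exactly 10% is kept); missingness is computed over the
  samples present after any subsetting, so the filter is self-consistent on
  subsets;
* **SNP-density mask** — every placement of a 2-kb sliding window
  containing more than `max_snps` variants (default 20) is masked and
  merged; clusters of tens of SNPs in 2 kb against a background of a few
  per 10 kb flag repeated elements, not polymorphism. The threshold is a
  package default, not an estimate: the mask is emitted as BED so it can be
  audited, and site counts are reported both pre- and post-mask.

A separate coverage mask flags bases whose cross-sample mean depth exceeds
3× the contig-wide mean; those bases are excluded from titre means.

## Infection calling

Depth of coverage is the mean read depth over all reference bases; breadth
is the fraction of bases covered by at least two reads (a lone read does
not make a base "covered"; the minimum is configurable). A line is scored
infected when breadth > 0.90 **and** mean depth > 1, both strict. These
thresholds presume a bimodal panel; `breadth_gap()` reports the largest gap
in the sorted breadth distribution so users can see whether the panel
actually splits in two before trusting fixed cutoffs, and the thresholds
are exposed as arguments. In a panel where every line is infected (the
regime this package targets), the rule simply confirms it.

The breadth denominator is the reference length, the natural choice when
all samples are mapped to one reference.

## Titre estimation

Relative copy number is the ratio of the target genome's mean depth
(masked bases excluded) to the mean depth of a nuclear normalisation region
from the same library, times a ploidy factor. The default factor is 1 — a
plain depth ratio — because relative titres are what the downstream
correlation and association analyses need; `ploidy_factor = 2` converts to
copies per diploid cell and is reported alongside whenever used. Each
target is normalised by a nuclear region of comparable size so sampling
noise in the normaliser is comparable between targets.

With Poisson per-base depth, the relative error of a titre estimate at 30×
nuclear coverage over 10–20 kb contigs is a fraction of a percent; the
5%-recovery test in the suite is correspondingly comfortable and mostly
guards against masking and pairing mistakes.

The mt–endosymbiont titre relationship is summarised by least-squares
slope, product-moment correlation and a two-sided t-test on n − 2 df.

## Diversity and the fixed-S coalescent null

Per-site π uses pairwise-complete calls: with m non-missing calls and j
alternate alleles, π = 2j(m−j)/(m(m−1)). Tajima's D uses the per-locus sum
of site π and the standard constants (a1, a2, b1, b2, c1, c2, e1, e2)
evaluated at the panel sample count — the common tool convention under
missing data; the 10% missingness filter bounds the distortion between the
two conventions. Windows with S = 0 report D as undefined and are excluded
from genome-wide summaries. Both an overall whole-genome D and the mean of
defined windowed D values are reported, since "overall" is ambiguous and
the two can differ.

Significance is assessed against the neutral constant-size coalescent
without recombination, conditioned on the observed S by Hudson's device:
simulate an unconstrained genealogy (inter-coalescence times
Exponential(k(k−1)/2)), then place exactly S infinite-sites mutations on
branches with probability proportional to branch length. Empirical
p-values use the add-one rule (p = (#{x ≤ obs}+1)/(R+1)), so p is never
exactly zero; confidence intervals are empirical type-7 quantiles. The
tail must be chosen explicitly; for a sweep/bottleneck alternative the
lower tail is the relevant one. All simulation functions take explicit
seeds and restore the RNG state, and the pipeline derives per-stage
substreams from its single configured seed.

Two calibration facts matter when interpreting the null:

* mean total tree length converges to 2·a1(n), and the suite checks this
  at n = 167 within Monte-Carlo error;
* fixed-S conditioning biases the mean per-locus π slightly **below**
  S/a1 — about −3.5% at n = 167 — because E[Σ wᵢLᵢ / L] ≠ E[Σ wᵢLᵢ]/E[L].
  This is a property of the conditioning itself, reproduced independently
  by msprime, not an implementation artefact. The mean of the null D is
  correspondingly a little below zero (≈ −0.1 at n = 167, S = 90), which
  is well inside the (−0.2, 0.2) band the calibration test uses.

At n = 167 and S = 90 the null D distribution has a 95% interval of
roughly (−1.6, 1.9); an observed D of −2.4 sits far in the lower tail
(empirical p ≈ 2 × 10⁻⁴ at 5000 replicates), which is what
`scripts/acceptance.R` recomputes.

## Cross-genome linkage disequilibrium

For every pair of sites drawn one from each genome, r² is the squared
product-moment correlation of the haploid 0/1 vectors over samples called
at both sites — no phasing is needed or implemented, since inbred lines
are haplotypes. Pairs that are constant after pairwise deletion are
undefined; the mean is reported both excluding them and counting them as
zero, because at the near-zero LD levels expected under a single recent
invasion the convention visibly moves the summary. For truly independent
genomes E[r²] ≈ 1/(n−1), the finite-sample null of a squared correlation —
the calibration the suite checks at n = 167.

## Genealogy summaries

Pairwise differences are counted over jointly called sites, with a
companion overlap matrix. A sample is "identical to another" when some
other sample shows zero differences over at least 80% of sites jointly
called (configurable) — the missing-data convention is ours, stated
because identity counts are meaningless without one. Neighbor joining
(via ape) provides a quick sketch; likelihood inference with bootstrap
support is deliberately out of scope.

A subtlety worth recording: even deep neutral panels are not free of
identical pairs. The most recent coalescence creates a cherry whose two
branches carry no mutation with probability c/(c + 2μ), c = n(n−1)/2, μ
the per-tree mutation intensity — so the non-unique fraction reaches ~0
only when θL ≫ n². The separation test therefore uses n = 20 with
θ_W = 0.01/site over 20 kb (S = 710) for its deep-neutral arm, against
sweep-mode panels at n = 167, S = 90 which sit above 0.4 by construction.

## Association

Nuclear SNPs inside user-supplied candidate regions (long haplotype blocks
from a prior selection scan; the package does not re-derive them) are
filtered to minor-allele count ≥ 3 (≈ 2% in 167 lines) and missingness
≤ 10%. Per SNP, complete cases only, no imputation:

* **single trait** — least-squares slope of the phenotype on allele count,
  two-sided t-test on n − 2 df;
* **two traits jointly** — the canonical correlation ρ between the
  genotype and the two mean-centred phenotypes, tested with
  F = ((n−1−k)/k)·ρ²/(1−ρ²), k = 2, on (k, n−1−k) df. With a single
  genotype vector this is algebraically the overall F of regressing
  genotype on the two phenotypes and equals Wilks' exact F for one
  predictor; the suite asserts this equivalence against the `lm`/`cancor`
  oracles to 10⁻⁸ rather than assuming it.

Hits are rows below a fixed cutoff (default 9 × 10⁻⁶) with no further
correction — the candidate regions are LD blocks whose SNPs are far from
independent tests — but Bonferroni and Benjamini–Hochberg columns are
always reported so the choice is transparent. Hits within 20 kb are
annotated as one cluster.

## The synthetic panel generator

The generator exists so every stage can run and be validated without any
external data, and its defaults are the study conditions the package
targets: 167 lines; 78 endosymbiont and 90 mtDNA segregating sites;
log-normal titres with natural-scale mean (SD) 5.56 (2.45) and
33.85 (15.5); log-scale mt–endo correlation 0.4 (a moderate positive
dependence consistent with a strongly significant correlation at n = 167);
30× nuclear Poisson coverage; one planted causal SNP at MAF 0.3 with an
effect of 1.5 log-SD per allele on both titres; a 300-bp 4× coverage
anomaly on the endosymbiont contig for the mask round-trip. Organelle
contigs default to 20 kb desk-scale stand-ins for the real genome sizes —
per-site quantities scale accordingly and the manifest records lengths.

Sweep-mode genealogies are phenomenological, not forward simulations: one
founder haplotype, each mutation carried by a geometric(mean 1.3) number
of random lines. This reproduces the operative signatures of a recent
single-origin spread — many identical sequences, an excess of rare
variants, strongly negative D — without modelling the sweep dynamics.
Neutral mode draws a fixed-S coalescent sample. Titre effects are added on
the log scale with the residual noise shrunk so the total log-variance
stays on target (floored at 10% so the phenotype never degenerates);
`noise = FALSE` gives the deterministic limit used to validate effect
plumbing. Depth is Poisson per base.

What the generator does **not** emulate: mapping artefacts, base-quality
error, indels, within-host titre variation between tissues, linkage within
the nuclear candidate regions (background SNPs are independent), and
recombination anywhere. Passing tests therefore validate the statistical
machinery under the stated model, not robustness to alignment pathology.

## Numerical choices and problem sizes

* Empirical p-values: add-one rule; CIs: type-7 quantiles; ties in NJ and
  in `which.min` follow R defaults.
* Degenerate inputs fail loudly: zero nuclear depth, fully masked targets,
  all-zero depth panels, collinear phenotypes, n < 4 for D.
* The test suite runs the coalescent calibration at 10 000 replicates and
  the headline significance test at 2 000; the acceptance script uses
  5 000. The power study uses 100 generator seeds; the oracle equivalence
  checks use 200 random matrices and 50 random association datasets. These
  sizes make the whole suite complete in a few minutes on one core while
  keeping Monte-Carlo error well below every tolerance tested.

## Known limitations

* The fixed-S π bias described above means fixed-S nulls should be read as
  conditional distributions, not as unbiased estimators of fixed-θ
  quantities.
* Tajima's D under missing data mixes per-site pairwise-complete π with
  constants at the panel n; with ≤ 10% missingness the effect is small but
  it is a convention, not an exact treatment.
* The association stage fits no kinship or structure correction; it is
  intended for panels already known to lack cryptic relatedness.
* NJ trees are sketches; bootstrap support and likelihood inference belong
  to external tools.
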