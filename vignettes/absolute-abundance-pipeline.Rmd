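---
title: "Absolute-abundance analysis of the honey bee gut microbiota: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute-abundance analysis of the honey bee gut microbiota: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`beegut` implements the quantitative analysis of a factorial cage experiment
on honey bees: two gut-colonization states (CL = inoculated with a worker gut
homogenate, MD = microbiota-depleted) crossed with five pesticide feeding
treatments (Control, Insecticide, Herbicide, Fungicide, and their ternary
Mix), four cages of 30 bees per combination. Readouts are 16S rRNA amplicon
ASV tables, qPCR quantification cycles for total 16S and host actin, enzyme
activities of five physiological markers in three body compartments, and
daily survival and feeder-mass logs. The package converts these into
absolute bacterial abundances, community statistics, per-ASV treatment
tests, physiology statistics with a control-normalized cluster heatmap, and
survival/consumption analyses — and ships a synthetic-data generator that
emulates the whole design so every stage is testable end to end.

# Absolute quantification by qPCR

Plasmid dilution series give per-gene standard curves by least squares of
Cq on $\log_{10}$(copies). The amplification efficiency is
$E = 10^{-1/\text{slope}}$ (perfect doubling chemistry: slope $-3.32$,
$E = 2$), and raw copies in 1 uL of extract are recovered by

$$n = E^{\,\text{intercept} - \text{Cq}}.$$

Per-gut quantities are raw copies times the DNA elution volume (default 50
uL). Total 16S copies are then normalized against the host actin gene —
divide by the sample's actin copies and multiply by the median actin copies
across samples — which cancels gut-size and extraction-efficiency variation
(any common rescaling of actin values leaves the result unchanged).
Finally, normalized copies are divided by 4, the approximate mean number of
16S loci per bacterial cell among bee gut symbionts, to give cells per gut.

Numerical choices: replicate Cq values (triplicates by design) are averaged
arithmetically; a replicate spread above 1 cycle warns but does not exclude.
The elution-volume multiplication happens before actin normalization; the
normalized ratio is unaffected by this order, so the choice is cosmetic but
fixed for reproducibility. The divisor 4 and the elution volume are exposed
as arguments.

# Contaminant screening against blanks

Reagent contaminants are identified from 16 blank extractions with two
complementary scores, combined by the "either" rule (flag when either score
falls strictly below the threshold, default 0.1):

* **Prevalence** — a one-sided Fisher exact test on the 2x2
  presence/absence table of blanks versus true samples, oriented toward
  over-representation in blanks.
* **Frequency** — contaminants enter every extraction at a roughly constant
  absolute level, so their *relative* abundance varies inversely with the
  total bacterial load. The score is the one-sided p value of the Spearman
  correlation between an ASV's relative abundance and log10 load, over the
  samples where the ASV occurs (at least 5 required, otherwise neutral 0.5).

A design point worth spelling out: when cohorts with systematically
different compositions *and* loads are pooled — exactly the CL/MD contrast
here, where MD bees carry three-fold lower loads and are dominated by
opportunists — a genuine community member can show a strong negative
abundance-load correlation purely through the cohort factor.
`frequency_method()` therefore accepts a `strata` argument (the pipeline
passes colonization) and combines per-stratum one-sided p values with
Stouffer's weighted-z rule. Without stratification the false-flag rate on
simulated data triples.

Because the "either" rule thresholds one-sided p values at 0.1, about 10% of
genuine taxa are expected to be flagged by chance; this is inherent to the
method, and the package reports per-ASV scores so users can audit calls.
Organellar reads are handled separately: any ASV whose lineage contains
Mitochondria or Chloroplast at any rank, or whose domain is Eukaryota
(case-insensitive), is dropped before contaminant scoring.

# The absolute-abundance table

Per-sample ASV proportions from the filtered count table are multiplied by
the sample's normalized 16S copy number, so each row of the resulting
matrix sums to the sample's load. ASV-level statistics use normalized 16S
copies; cells per gut are used for load comparisons and plots. The usual
compositional caveat applies and is asserted in tests: dropping a column
and renormalizing changes the remaining absolute estimates, so filtering
decisions precede scaling.

# Community statistics from first principles

Dissimilarities: Bray-Curtis
$\mathrm{BC}(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$; unweighted
UniFrac (branch length unique to either sample's leaf set over the branch
length of their union); weighted UniFrac
$\sum_e L_e\,|p_A(e) - p_B(e)|$ over branches with subtree relative
abundances $p$, optionally divided by the abundance-weighted maximum
attainable distance $\sum_{\text{tips}} d_{\text{tip}}(p_A + p_B)$
(default: normalized). All three are cross-checked in the test suite
against vegan and phyloseq to machine precision.

Ordination is classical PCoA: Gower double-centering of $-\tfrac12 D^2$,
eigendecomposition, coordinates from positive eigenvalues; negative
eigenvalues (non-Euclidean input) are reported, not silently dropped.

Permutational tests:

* **PERMANOVA** (one-way ADONIS) computes the pseudo-F directly from the
  distance matrix via the Gower identity
  ($SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$), with
  $R^2 = SS_B / SS_T$. The p value counts the observed arrangement among
  the permutations, $p = (1 + \#\{F^* \ge F\})/(1 + B)$.
* **ANOSIM** ranks all pairwise distances and uses
  $R = (\bar r_B - \bar r_W)/(M/2)$, $M = n(n-1)/2$.
* **PERMDISP** embeds by PCoA keeping real and imaginary axes, computes
  distances to group centroids with the negative-eigenvalue contribution
  subtracted (Anderson's correction; negative squared distances are clipped
  at 0 with a warning), and permutes the distances-to-centroid across
  samples to obtain the null of the one-way F. This permutation scheme is
  simpler than permuting least-squares residuals; on simulated data both
  give indistinguishable decisions, and the F statistic itself is identical
  to `vegan::betadisper(type = "centroid")`.

An exhaustive mode enumerates every distinct label arrangement (feasible up
to n about 8) and is verified against an independent enumeration oracle in
the tests. Pesticide effects "within colonization" are one-way tests on the
stratum subsets; the overall colonization test uses the full factor. Both
framings are reported because the study design supports either. Permutations
are unrestricted by default; the cage structure exists in the metadata, and
cage-restricted schemes were deliberately left out of scope.

# Per-ASV permutation ANOVA

For each ASV present in at least 25% of a stratum's samples (the
prevalence floor avoids all-zero treatment groups and is recorded in the
output), the observed statistics are the one-way ANOVA F across the five
treatments and the per-treatment t statistics against the Control level
from the pooled linear model. Abundance values are then randomized without
replacement (default 10,000 times; the engine is vectorized so the full
default is affordable) and the omnibus p value is the proportion of
permuted F values at or above the observed one — the study's randomization
rule, which can legitimately return 0. A plus-one variant is available via
`permutation_p()` for publication-grade reporting.

A five-level factor has no single t value, so "the t value of the tested
effect" is operationalized as: omnibus significance from permuted F,
per-level detail from permuted t against Control. Per-level p values are
two-sided on |t| by default, because planted decreases are as interesting
as increases; the one-sided variant is retained as the faithful mode.
Post hoc, all Tukey HSD pairs are computed and Bonferroni-adjusted across
the 10 pairs within an ASV; multiplicity across ASVs is reported but not
adjusted, matching how such screens are usually presented. Per-ASV seeds
are derived deterministically from the master seed and the ASV identifier,
and samples are sorted by name before testing, so results are independent
of input row order.

# Physiology statistics and the cluster heatmap

For each of the 11 valid (tissue, marker) combinations — GST, G6PDH, LDH in
head, abdomen and midgut; ALP and POx in midgut only — and within each
colonization stratum, residuals from the treatment means are routed by a
Shapiro-Wilk test at alpha = 0.05: parametric data get one-way ANOVA with
Tukey HSD, otherwise Kruskal-Wallis with Dunn's test under
Benjamini-Hochberg. The CL-versus-MD contrast per pesticide level uses the
same routing, with the two-group ANOVA (equivalent to the pooled t test) on
the parametric branch and the Wilcoxon rank sum test otherwise — one
consistent routing rule everywhere rather than a separately tuned two-group
test.

The integrative heatmap normalizes each (tissue, marker) row of treatment
means to the *rate of variation* against the colonized control:
$(\bar x_t - \bar x_{\mathrm{CL.Control}})/\bar x_{\mathrm{CL.Control}}$,
so the reference column is exactly 0, increases are positive (red) and
decreases negative (green). MD rows are normalized to CL.Control as well —
the alternative (each stratum's own control) is selectable but not the
default. Clustering is UPGMA on Euclidean distances with ultrametric node
heights (half the merge distance, so an ultrametric input is reproduced
exactly); ties are broken by lexicographic label order, which makes the
dendrogram invariant to input row order. The ratio variant $t/c$ of the
normalization is available.

# Survival and consumption

Survival uses the Kaplan-Meier product-limit estimate per cage with
administrative censoring at the 5-day horizon; deaths are recorded at
integer days (the daily 8 am census makes finer timing unavailable). The
log-rank test is the Mantel-Cox observed-versus-expected chi-square with
the full covariance matrix; pairwise post hoc log-rank tests are adjusted
by Benjamini-Hochberg. Food consumption is evaporation-corrected (mean of
the evaporation-control series per day), divided by bees alive at the start
of the day, and accumulated per bee; negative corrected values clip to 0
with a warning. The cage is the experimental unit for consumption — bees
share feeders, so bee-level values would be pseudo-replicated — and
cumulative per-bee totals are compared by Kruskal-Wallis.

# The synthetic-data generator

The generator reproduces the design exactly: 2 x 5 x 16 guts = 160 gut
samples, 16 blanks, 40 cages of 30 bees, 7 pooled physiology replicates per
treatment and tissue. Its data-generating assumptions, with defaults:

* **Loads** are lognormal with CV 0.5; the MD mean is 3e7 cells/gut and the
  CL mean three-fold higher. Only a fold difference is documented for the
  real system, so the distribution family and CV are package choices fixed
  once.
* **Compositions**: CL communities are dominated by the core phylotypes
  (Lactobacillus Firm-5/Firm-4, Gilliamella, Snodgrassella, Bifidobacterium,
  Frischella labels), MD communities by hive-environment opportunists, with
  Dirichlet concentration 100 around the stratum base weights. Reads are
  Dirichlet-multinomial at Poisson depth (mean 40,000/sample, i.e. about
  6.4M reads over 160 samples, the scale of a MiSeq run).
* **Contaminants** (6 ASVs) enter every extraction at a constant mean
  absolute level (2e5 copies, lognormal CV 0.5), independent of load — the
  signature the frequency method detects; blanks contain only contaminants.
  Two organellar ASVs exercise the taxonomy filter.
* **Planted treatment effects** multiply the expected absolute abundance of
  five low-abundance MD opportunists under one pesticide each, leaving
  other ASVs untouched. Folds (6-9 by target) are calibrated so each
  planted shift is about five within-group standard deviations — the
  compositional CV of an ASV of weight $w$ at concentration $c$ is
  $\sqrt{(1-w)/(w(1+c))}$, so rarer targets need larger folds — while MD
  mean-load inflation stays below 5%, preserving the three-fold CL/MD
  contrast.
* **qPCR**: Cq values invert the standard curve with Gaussian noise of
  0.15 cycles per replicate, in triplicate; a lognormal per-sample
  extraction efficiency multiplies 16S and actin alike (the actin
  normalization must cancel it), and the dilution series spans 1e2-1e8
  copies.
* **Physiology**: Gaussian activities (CV 0.12) around tissue/marker
  baselines; midgut GST is 1.4x higher in CL, and the fungicide raises head
  LDH in both strata (plus herbicide/mix effects in MD), mirroring the
  qualitative pattern the analysis should recover.
* **Survival/feeding**: binomial daily deaths at a null hazard of
  0.008/day for every treatment (the design anticipates no survival
  effect), per-bee consumption 45 ± 6 mg/day and evaporation 80 ± 15
  mg/day with a three-cage evaporation-control series.

What the generator does *not* emulate: chimeras and denoising errors (ASV
tables are taken as given), taxonomic correlation structure beyond the
Dirichlet, cage-level microbiota effects, batch or plate effects in qPCR,
index hopping, or heavy-tailed overdispersion beyond the
Dirichlet-multinomial. Passing recovery tests therefore demonstrates that
the statistical machinery is correct and calibrated under a faithful but
idealized model of the study — not that the pipeline is robust to every
artifact of real amplicon data.

# Numerical choices and test problem sizes

Permutation p values use fixed recorded seeds; per-ASV seeds derive from
the master seed and ASV id. Exact Wilcoxon enumeration switches to the
tie-corrected normal approximation above a combined n of 20. Exhaustive
permutation modes are limited to n <= 8. Degenerate inputs (constant
values, all-zero distances) return p = 1 with a degeneracy flag rather
than NaN. The test suite calibrates type-I error with 3,000-4,000 null
simulations at 2,000 randomizations each and verifies permutation p values
against exhaustive enumeration on all instance shapes up to n = 7; these
sizes give Monte-Carlo standard errors well inside the asserted 5% ± 1%
band while keeping the default suite fast.

# Known limitations

One-way designs only: no interaction machinery, no mixed models, no
cage-restricted permutation schemes, no compositional (CLR/ALR) alternative
to the absolute-abundance scaling, no rarefaction. The contaminant screen
is a transparent re-implementation of the prevalence/frequency logic, not a
port of any specific tool, and its 0.1 threshold trades recall for a ~10%
false-flag rate among genuine taxa.
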