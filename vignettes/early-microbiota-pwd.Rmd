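---
title: "Discriminating post-weaning diarrhoea susceptibility from early-life faecal microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating post-weaning diarrhoea susceptibility from early-life faecal microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwdmicro)
```

## The problem

Post-weaning diarrhoea (PWD) is a major enteric disorder of piglets,
typically driven by *Enterobacteriaceae* overgrowth in the weeks after the
abrupt dietary and social stress of weaning.  A recurring hypothesis is
that susceptibility is foreshadowed by the composition of the faecal
microbiota in the first week of life, long before any clinical sign.
`pwdmicro` implements, as a tested and reusable pipeline, the statistical
chain needed to probe that hypothesis in a litter-structured cohort:

1. **Fingerprint diversity** — preprocessing of capillary-electrophoresis
   community fingerprints (alignment on an internal size standard,
   baseline removal, area normalization), peak detection, and
   Simpson/Shannon/richness/Pielou summaries per animal.
2. **Community comparison** — binarized (presence/absence) profiles,
   Jaccard dissimilarities, ANOSIM permutation testing and UPGMA
   clustering.
3. **Differential abundance** — strict count and variance filters,
   median-of-ratios scaling normalization, a common-dispersion
   negative-binomial exact test per OTU, and Benjamini–Hochberg FDR.
4. **Multivariate classification** — sparse PLS-DA with a two-stage
   cross-validated stability-selection procedure, plus sparse-PLS
   relevance networks and OTU–pathway association matrices.
5. **Cohort statistics** — qPCR absolute quantification, dry-matter-based
   diarrhoea classification, normality-gated univariate comparisons,
   MUC13 allele-prevalence testing and colostral immune loads.

Because no real cohort data ship with the package, a fully seeded
synthetic-study generator (`simulate_study()`) provides every input with
known ground truth, and all validation is done against it.

## The synthetic cohort

`sim_config()` fixes the study conditions: 5 litters × 4 piglets
(2 males, 2 females per litter), an overall diarrhoea prevalence of 13/20
(drawn exactly; per-litter prevalences are configurable because the real
litter distribution is only loosely characterized), and postnatal-day
(PND) phenotype series.

**OTU counts.** Counts follow a negative binomial with variance
$\mu + \phi\mu^2$ and a dispersion $\phi$ shared across OTUs, matching
the common-dispersion exact test downstream.  Baseline relative
abundances are log-normal (a standard rank-abundance shape for gut
communities); sequencing depth is uniform on 20,000–50,000 reads.  Group
effects multiply the mean by $2^{\pm\mathrm{lfc}/2}$ (healthy side
positive), so swapping labels exactly negates the log2 fold change.  The
defaults place 10 discriminant OTUs at $|\mathrm{lfc}| = 3$, a strong but
realistic early-life signature given that a 20-animal cohort must be able
to detect it; D-enriched discriminant OTUs are assigned
*Enterobacteriaceae* taxonomy, H-enriched ones lactic-acid or fibrolytic
families.

**Fingerprints.** Each trace is a sum of fixed-width Gaussian peaks (one
injective position per rendered phylotype; co-migration can be forced for
stress tests), a smooth baseline, white noise and a per-sample affine
scan distortion.  Only the 40 most abundant OTUs are rendered — rare taxa
fall below fingerprint detection in practice.  The internal size standard
is modelled as a separate detection channel (a different fluorophore in
the real instrument), so the community trace is not contaminated by
ladder peaks; the profile carries the distorted standard positions for
alignment.

**qPCR.** Standards follow
$C_q = b - \log_{10}(\text{copies})/\log_{10}(1+E)$ with efficiency
$E = 0.95$ and 10-fold dilutions spanning $10^2$–$10^{10}$ copies; sample
$C_q$ values derive from ground-truth copy trajectories for total
bacteria, *Firmicutes*, *Bacteroidetes*, *Lactobacillus* and
*Enterobacteriaceae*.

**Phenotypes.** Faecal dry matter (DM, %) is recorded daily over PND
30–47 around a healthy baseline of 26% (sd 0.8).  In D pigs only, DM is
a decreasing linear function of log10 *Enterobacteriaceae* copies (slope
−5 %DM per log10 by default); an episode bloom of +2.2 log10, whose first
day is uniform on PND 38–42 and which lasts 2–4 days, drives DM below the
20% liquid-faeces threshold for at least two consecutive days.  MUC13
amplicon lengths (151 bp A / 83 bp B) are drawn independently of group,
mirroring the finding that genotype did not explain susceptibility in the
motivating cohort.  All stages draw from named random streams derived
from one root seed, so any stage can be regenerated independently and a
fixed seed reproduces every output byte for byte.

What the generator does **not** emulate: read-level sequencing error,
chimeras, compositional coupling between OTUs (counts are independent
negative binomials given the mean), litter-level random effects on the
microbiota, or realistic electropherogram artefacts beyond a smooth
baseline.  Green tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
failure mode of real data.

## Statistical choices and numerical details

**ANOSIM.** All pairwise dissimilarities are ranked (ties averaged) and
$R = (\bar r_B - \bar r_W) / (n(n-1)/4)$, Clarke's convention, so $R = 1$
exactly when every between-group dissimilarity exceeds every within-group
one.  The permutation p-value uses the $(1+x)/(1+N)$ estimator so it is
never zero; an exact mode enumerates all distinct two-group assignments
for small cohorts and is validated against a naive enumeration oracle.

**Diversity.** Simpson is reported as Gini–Simpson $1-\sum p_i^2$ so that
"higher = more diverse" (the inverse form is available); evenness is
Pielou $H/\ln S$, defined as 1 for a single peak.  The fingerprint
software used in the motivating study reports an unspecified
"equitability" index that can move opposite to Pielou on the same
profile; both of our indices are emitted and the discrepancy is simply
noted, not resolved.

**Exact test.** OTU counts are adjusted to a common library size by
rescaling normalized counts to the geometric-mean depth and rounding
half-up — a simpler device than quantile matching that is exactly
invertible when libraries are already equal.  Conditioning on the
two-group total, the mean parameter cancels and the split follows a
Pólya distribution (binomial in the Poisson limit); the two-sided p-value
sums all splits no more probable than the observed one (doubling the
smaller tail is available).  The common dispersion maximizes the summed
conditional likelihood; log2 fold changes add a prior count of 0.125 so
structural zeros stay finite.  The variance filter is applied to relative
abundances by default (the scale is configurable since the original
description does not fix it) and fold changes are reported in base 2,
labelled as such.

**Sparse PLS-DA.** Per component, the dominant singular pair of the
scaled cross-product $X^\top Y$ is sparsified by soft thresholding: the
`keepX` largest loadings survive, shrunk by the largest excluded
magnitude (the standard lasso surrogate in sparse PLS); ties are broken
by feature order, and a tied survivor is retained at vanishing magnitude
so exactly `keepX` loadings stay nonzero.  Signs are fixed by making the
largest loading positive.  Deflation regresses both blocks on the
X-scores (regression mode), which keeps successive score columns exactly
orthogonal.  Prediction uses nearest class centroid in score space with
deterministic ties to the first level (a maximum-indicator rule is
available).  Cross-validation is stratified 5-fold with 10 repeats by
default — with 20 animals split 13/7, stratification is essential — over
a grid of `keepX` $\in \{5, 10, \dots, 50\}$ and 1–3 components.  The
stable set keeps features selected in **every** fold × repeat (frequency
= 1); the second stage refits on that set only, re-tuning `keepX` there
because the original procedure fixes the feature list but not the refit
sparsity.  If no feature reaches frequency 1 the procedure falls back to
a high quantile of the frequency distribution, with a warning.  If the
cross-covariance is numerically exhausted (e.g. a one-feature stable
set asked for two components), trailing components are truncated rather
than fabricated.

**Relevance networks.** The similarity between an X-feature and a
Y-feature is the bilinear reconstruction
$\sum_h \mathrm{cor}(x_j, \xi_h)\,\mathrm{cor}(y_k, \xi_h)$ over
components (Y-side scores $\omega_h$ in canonical mode).  Using X-scores
on both sides in regression mode makes the full-rank, keep-all similarity
reproduce the plain Pearson cross-correlation matrix — a property we test
— which would not hold with $\omega_h$.  Edges keep $|s| > 0.5$ by
default, signed.  At $n = 20$ the covariance-maximizing projection
inflates null score correlations well above zero; the honest null
property is that similarities concentrate near zero (median $|s| <
0.35$ in our null simulations), not that score correlations vanish.

**Cohort statistics.** "Liquid faeces on 2 to 3 consecutive days" is
codified as ≥ 2 consecutive *observed* days below 20% DM, with gaps in
the observation days breaking runs.  The Shapiro–Wilk gate (α = 0.05) is
applied per group and either group failing routes the comparison to
Mann–Whitney — the strictest reading of "normal within each group";
groups below 3 observations skip the gate and force the non-parametric
branch.  The repeated-measures analysis is implemented literally as
paired t-tests between consecutive ages within each group rather than a
mixed-model ANOVA, matching the original description; age-wise p-values
are emitted unadjusted with BH adjustment available.  The MUC13
chi-squared uses no continuity correction (Pearson's test, as named), and
allele calls tolerate ±2 bp.  qPCR quantification inverts the fitted
standard curve and rescales to copies per 100 µg DNA, flagging (not
discarding) $C_q$ values beyond the standards.

## Problem sizes used in validation

The test suite and acceptance script validate on desk-scale problems
chosen to keep each property sharp: full permutation enumeration at
$n \le 8$; 200 random datasets of 20 samples for the null ANOSIM mean;
1000 null OTUs for the type-I rate; 200-OTU tables with 20 injected
$|\mathrm{lfc}| = 2$ effects at $\phi = 0.2$ for power; 50 seeded
20 × 100 matrices with five 3-SD features for stability selection; and
20 seeds of the two-stage procedure for the error-ordering property.
These sizes give Monte-Carlo error comfortably below the asserted
tolerances.

## Known limitations

* Two-class designs only; the multilevel/repeated-measures variant of
  sparse PLS-DA is out of scope.
* A single common NB dispersion; no tagwise or trended shrinkage, no GLM
  framework, no compositional (log-ratio) methods.
* Litter is recorded but not modelled as a random effect.
* No chromatogram file-format parsing; fingerprints enter as plain
  position/intensity tables.
* The pipeline consumes a pathway-abundance matrix as given; predicted
  metagenome imputation itself is out of scope.

## A short tour

```{r tour, eval = FALSE}
study <- simulate_study(sim_config(seed = 1))

# diarrhoea classification from dry matter
cls <- vapply(split(study$phenotypes$dm, study$phenotypes$dm$pig),
              function(d) classify_diarrhoea(d$dm, d$day)$group, "")

# fingerprint diversity and community comparison
peaks <- lapply(lapply(study$fingerprints$profiles, preprocess_profile),
                detect_peaks)
div <- do.call(rbind, lapply(peaks, alpha_diversity))
jac <- binarize_and_jaccard(peaks)
anosim_test(jac, cls[rownames(jac)], n_permutations = 999, seed = 1)

# differential abundance
res <- exact_test(filter_otus(study$otu_table),
                  factor(cls[colnames(study$otu_table$counts)], c("D", "H")))

# or simply run everything:
out <- run_pipeline(pipeline_config(outdir = "pwd_run", seed = 1))
```
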