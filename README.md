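# pwdmicro

Statistical pipeline for asking whether piglets that will develop
post-weaning diarrhoea (D) can be discriminated from healthy littermates
(H) using their **early-life faecal microbiota**, in a litter-structured
cohort (5 litters × 4 piglets).

The package implements the full analysis chain as reusable, tested R
functions:

* **Fingerprint diversity** — preprocessing of capillary-electrophoresis
  community fingerprints (alignment on internal size standards, rolling-
  minimum baseline removal, area normalization), peak detection, and
  Gini–Simpson (1 − Σp²), Shannon (−Σp ln p), richness and Pielou
  evenness (H/ln S) per animal.
* **Community comparison** — presence/absence binarization, Jaccard
  distance d = 1 − |A∩B|/|A∪B|, ANOSIM with
  R = (r̄_between − r̄_within)/(n(n−1)/4) ∈ [−1, 1] tested by label
  permutation, and UPGMA clustering with newick export.
* **Differential abundance** — strict count (> 3 sequences) and variance
  (> 10⁻⁸) filters, median-of-ratios scaling normalization, a
  common-dispersion negative-binomial **exact test** per OTU
  (conditioning on the two-group total; variance = μ + φμ²), and
  Benjamini–Hochberg FDR.
* **Sparse PLS-DA** — lasso-style soft-thresholded loadings (exactly
  `keepX` nonzero per component), stratified repeated cross-validation,
  and the two-stage **stability selection**: keep only features selected
  in *every* fold × repeat (frequency = 1), then refit on that stable
  set.  Plus sparse-PLS relevance networks (edges at |similarity| > 0.5)
  and OTU–pathway association matrices.
* **Cohort statistics** — qPCR absolute quantification from log-linear
  standard curves (efficiency 10^(−1/slope) − 1), diarrhoea
  classification from faecal dry matter (< 20% DM on ≥ 2 consecutive
  days), Shapiro-gated t / Mann–Whitney comparisons,
  *Enterobacteriaceae*–dry-matter correlations, MUC13 (151 bp / 83 bp)
  genotyping with Pearson chi-squared prevalence testing, and colostral
  immune loads.
* **Synthetic cohort generator** — a seeded in-silico study (cohort,
  NB OTU counts, fingerprint traces, qPCR runs, phenotypes) with known
  ground truth, so every stage is testable without external data.

## Worked example

```r
library(pwdmicro)
study <- simulate_study(sim_config(seed = 1))

# classify each pig from its dry-matter series
cls <- vapply(split(study$phenotypes$dm, study$phenotypes$dm$pig),
              function(d) classify_diarrhoea(d$dm, d$day)$group, "")
table(cls)
#> cls
#>  D  H
#> 13  7

# fingerprint community comparison
peaks <- lapply(lapply(study$fingerprints$profiles, preprocess_profile),
                detect_peaks)
jac <- binarize_and_jaccard(peaks)
anosim_test(jac, cls[rownames(jac)], n_permutations = 999, seed = 1)
#> ANOSIM: R = -0.0472, p = 0.662 (999 permutations)

# negative-binomial exact test, D vs H
res <- exact_test(filter_otus(study$otu_table),
                  factor(cls[colnames(study$otu_table$counts)], c("D", "H")))
attr(res, "phi")
#> 0.21
head(res[order(res$p_value), c("otu_id", "taxonomy", "log2fc", "fdr")], 5)
#>  otu_id                                        taxonomy log2fc     fdr
#> OTU0198 k__Bacteria; p__Firmicutes; f__Lactobacillaceae  -3.24 1.1e-22
#> OTU0084 k__Bacteria; p__Firmicutes; f__Lactobacillaceae  -3.09 8.4e-22
#> OTU0011 k__Bacteria; p__Firmicutes; f__Lactobacillaceae  -3.18 9.4e-22
#> OTU0123  k__Bacteria; p__Firmicutes; f__Ruminococcaceae  -3.26 2.6e-18
#> OTU0184  k__Bacteria; p__Firmicutes; f__Ruminococcaceae  -3.52 7.4e-17
```

Reading the output: the classifier recovers the simulated 13 D / 7 H
split exactly.  The exact test recovers the planted discriminant OTUs —
`log2fc` is D vs H, so the negative values mean these *Lactobacillaceae*
and *Ruminococcaceae* OTUs are depleted in the pigs that later develop
diarrhoea, at the simulated effect size of ~3 log2 units.  The ANOSIM R
near 0 is itself informative: binarized presence/absence fingerprints are
insensitive to pure abundance shifts among persistently detected
phylotypes, so a strong abundance signature need not produce a
membership signature.

The whole chain, including sparse PLS-DA stability selection, relevance
networks, qPCR quantification and cohort statistics, runs with:

```r
res <- run_pipeline(pipeline_config(outdir = "pwd_run", seed = 1))
res$manifest        # per-stage record counts
```

Every output table is TSV; the dendrogram is newick; networks are also
exported as GraphML.  Identical config + seed reproduces every file byte
for byte.  A thin command-line wrapper is installed at
`inst/scripts/pwd-pipeline.R`
(`Rscript pwd-pipeline.R run-all --seed 1 --outdir pwd_run`).

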