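# End-to-end orchestration: simulate (or load) the study, then run the
# fingerprint, differential-abundance, multivariate and cohort stages and
# write a consolidated set of machine-readable tables.

#' Pipeline configuration
#'
#' @param outdir output directory (created if needed).
#' @param seed root seed for every stage.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param dm_threshold liquid-faeces dry-matter threshold (% DM).
#' @param min_total,min_variance OTU filtering thresholds.
#' @param n_permutations ANOSIM permutations.
#' @param network_threshold relevance-network |similarity| threshold.
#' @param min_rel_height fingerprint peak-detection threshold.
#' @param ncomp_grid,keepX_grid,n_folds,n_repeats two-stage sPLS-DA design.
#' @param pathways optional sample x pathway abundance matrix (stands in
#'   for predicted-metagenome output); the OTU-pathway association matrix
#'   is skipped when absent.
#' @param use_truth_labels use ground-truth labels instead of dry-matter
#'   classification (power studies).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("pwdrun"), seed = 1L,
                            sim = sim_config(),
                            dm_threshold = 20, min_total = 3,
                            min_variance = 1e-8, n_permutations = 999,
                            network_threshold = 0.5, min_rel_height = 0.03,
                            ncomp_grid = 1:3, keepX_grid = seq(5, 50, by = 5),
                            n_folds = 5, n_repeats = 10,
                            pathways = NULL, use_truth_labels = FALSE) {
  sim$seed <- seed
  structure(as.list(environment()), class = "pipeline_config")
}

.write_tsv <- function(df, dir, name, rownames = FALSE) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = rownames, col.names = if (rownames) NA else TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: synthetic-study generation, diarrhoea
#' classification from dry matter, fingerprint preprocessing + diversity +
#' Jaccard/ANOSIM + clustering, OTU filtering + normalization + NB exact
#' testing + FDR, two-stage stability-selected sPLS-DA, sPLS relevance
#' network against the qPCR targets (and OTU-pathway associations when a
#' pathway matrix is supplied), and the cohort statistics (qPCR
#' quantification, Enterobacteriaceae-DM correlation, MUC13 prevalence,
#' colostral immune loads, H-vs-D diversity comparisons).  Every stage's
#' tables are written to `config$outdir` as TSV; a run manifest records
#' per-stage row counts and the seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with every stage's results plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, n) manifest[[length(manifest) + 1]] <<-
    data.frame(stage = stage, rows = n, seed = config$seed)

  ## stage 1: simulate
  study <- simulate_study(config$sim)
  write_otu_table(study$otu_table, file.path(config$outdir, "otu_table.tsv"))
  .write_tsv(study$phenotypes$dm, config$outdir, "dry_matter.tsv")
  .write_tsv(study$qpcr$samples, config$outdir, "qpcr_samples.tsv")
  .write_tsv(data.frame(pig = names(study$truth$group_labels),
                        group = unname(study$truth$group_labels)),
             config$outdir, "ground_truth_labels.tsv")
  note("simulate", nrow(study$otu_table$counts))

  ## diarrhoea classification (labels used downstream, as in the
  ## a-posteriori grouping of the study design)
  cls <- lapply(split(study$phenotypes$dm, study$phenotypes$dm$pig), function(d)
    classify_diarrhoea(d$dm, d$day, config$dm_threshold))
  labels_df <- data.frame(
    pig = names(cls),
    group = vapply(cls, `[[`, "", "group"),
    episode_start = vapply(cls, `[[`, 0, "episode_start"),
    stringsAsFactors = FALSE)
  labels_df <- labels_df[match(study$cohort$pig, labels_df$pig), ]
  .write_tsv(labels_df, config$outdir, "diarrhoea_classification.tsv")
  labels <- if (config$use_truth_labels)
    study$truth$group_labels[study$cohort$pig] else
    stats::setNames(labels_df$group, labels_df$pig)
  note("classify", nrow(labels_df))

  ## stage 2: fingerprints
  prof <- lapply(study$fingerprints$profiles, preprocess_profile)
  peaks <- lapply(prof, detect_peaks, min_rel_height = config$min_rel_height)
  div <- do.call(rbind, lapply(names(peaks), function(s)
    cbind(sample = s, group = unname(labels[s]), alpha_diversity(peaks[[s]]))))
  .write_tsv(div, config$outdir, "fingerprint_diversity.tsv")
  jac <- binarize_and_jaccard(peaks)
  write_distance_matrix(jac, file.path(config$outdir, "jaccard_distance.tsv"))
  ano <- anosim_test(jac, labels[rownames(jac)],
                     n_permutations = config$n_permutations,
                     seed = stream_seed(config$seed, "anosim"))
  .write_tsv(data.frame(R = ano$R, p = ano$p_value,
                        permutations = ano$n_permutations, seed = config$seed),
             config$outdir, "anosim.tsv")
  write_dendrogram_newick(cluster_dendrogram(jac),
                          file.path(config$outdir, "dendrogram.nwk"))
  note("fingerprint", nrow(div))

  ## stage 3: differential abundance
  filt <- filter_otus(study$otu_table, config$min_total, config$min_variance)
  dares <- exact_test(filt, factor(labels[colnames(filt$counts)], c("D", "H")))
  .write_tsv(dares, config$outdir, "differential_abundance.tsv")
  note("diffabund", nrow(dares))

  ## stage 4: two-stage sPLS-DA on log-transformed normalized counts
  lognorm <- t(log2(scaling_normalize(filt)$normalized + 1))
  rep2 <- tune_and_stability(lognorm, labels[rownames(lognorm)],
                             ncomp_grid = config$ncomp_grid,
                             keepX_grid = config$keepX_grid,
                             n_folds = config$n_folds,
                             n_repeats = config$n_repeats,
                             seed = stream_seed(config$seed, "splsda"))
  .write_tsv(data.frame(otu_id = rownames(rep2$selection_frequency),
                        rep2$selection_frequency,
                        stable = rownames(rep2$selection_frequency) %in% rep2$stable_set),
             config$outdir, "splsda_stability.tsv")
  .write_tsv(data.frame(stage = c("first", "second"),
                        cv_error = c(rep2$first_stage_error, rep2$second_stage_error),
                        ncomp = c(rep2$stage1_config$ncomp, rep2$stage2_config$ncomp),
                        keepX = c(rep2$stage1_config$keepX, rep2$stage2_config$keepX)),
             config$outdir, "splsda_errors.tsv")
  note("splsda", length(rep2$stable_set))

  ## stage 5: relevance network between discriminant OTUs and the qPCR
  ## targets (per-pig mean log10 copies across days)
  qp <- study$qpcr$samples
  curves <- lapply(split(study$qpcr$standards, study$qpcr$standards$target),
                   fit_standard_curve)
  quant <- do.call(rbind, lapply(names(curves), function(tg) {
    s <- qp[qp$target == tg, ]
    cbind(s[c("sample", "target", "day")],
          quantify_copies(curves[[tg]], s$cq, s$dna_mass_ug))
  }))
  lcp <- aggregate(log10(copies_per_100ug) ~ sample + target, quant, mean)
  names(lcp)[3] <- "log10_copies"
  qw <- reshape(lcp, idvar = "sample", timevar = "target", direction = "wide")
  rownames(qw) <- qw$sample
  qmat <- as.matrix(qw[rownames(lognorm), -1])
  colnames(qmat) <- sub("^log10_copies\\.", "", colnames(qmat))
  disc <- rep2$stable_set
  net_model <- spls_fit(lognorm[, disc, drop = FALSE], qmat,
                        ncomp = min(2, length(disc)), mode = "regression")
  net <- relevance_network(net_model, config$network_threshold)
  write_network_edges(net, file.path(config$outdir, "relevance_network.tsv"))
  write_network_graphml(net, file.path(config$outdir, "relevance_network.graphml"))
  assoc <- NULL
  if (!is.null(config$pathways)) {
    assoc <- association_matrix(lognorm[, disc, drop = FALSE],
                                config$pathways[rownames(lognorm), , drop = FALSE])
    .write_tsv(as.data.frame(assoc), config$outdir, "otu_pathway_associations.tsv",
               rownames = TRUE)
  }
  note("network", nrow(net$edges))

  ## stage 6: cohort statistics
  .write_tsv(quant, config$outdir, "qpcr_quantification.tsv")

  ent <- quant[quant$target == "Enterobacteriaceae", ]
  dmm <- study$phenotypes$dm
  key <- paste(ent$sample, ent$day)
  dm_at <- dmm$dm[match(key, paste(dmm$pig, dmm$day))]
  entcor <- correlate_entero_dm(ent$copies_per_100ug, dm_at, config$dm_threshold)
  .write_tsv(entcor, config$outdir, "entero_dm_correlation.tsv")

  cmp <- do.call(rbind, lapply(c("simpson", "shannon", "richness", "evenness"),
    function(v) cbind(variable = v,
                      group_compare(div[[v]], factor(div$group, c("D", "H"))))))
  .write_tsv(cmp, config$outdir, "diversity_group_comparison.tsv")

  muc <- muc13_genotype_and_test(
    lengths = stats::setNames(
      lapply(seq_len(nrow(study$phenotypes$muc13)), function(i)
        unique(unlist(study$phenotypes$muc13[i, c("len1", "len2")]))),
      study$phenotypes$muc13$pig),
    groups = labels[study$phenotypes$muc13$pig])
  .write_tsv(muc$genotypes, config$outdir, "muc13_genotypes.tsv")

  col <- study$phenotypes$colostrum
  loads <- do.call(rbind, lapply(seq_len(nrow(col)), function(i) {
    conc <- c(IgG = col$igg_mg_ml[i], IgA = col$iga_mg_ml[i],
              TGFb1 = col$tgfb1_ng_ml[i])
    cbind(pig = col$pig[i],
          ingested_immune_load(conc, col$intake_g[i],
                               units = c(IgG = "mg/mL", IgA = "mg/mL",
                                         TGFb1 = "ng/mL")))
  }))
  .write_tsv(loads, config$outdir, "colostrum_immune_loads.tsv")
  note("cohort", nrow(quant))

  manifest <- do.call(rbind, manifest)
  .write_tsv(manifest, config$outdir, "manifest.tsv")

  invisible(list(study = study, labels = labels, diversity = div,
                 jaccard = jac, anosim = ano, diffabund = dares,
                 splsda = rep2, network = net, associations = assoc,
                 curves = curves, quantification = quant,
                 entero_dm = entcor, muc13 = muc, colostrum_loads = loads,
                 manifest = manifest, outdir = config$outdir))
}
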