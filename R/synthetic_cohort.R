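# Synthetic study generator: cohort structure, OTU counts, fingerprint
# traces, qPCR runs and phenotypes with known ground truth.

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic cohort
#' generator.  Defaults emulate the study design: 5 litters of 4 piglets
#' (2 males, 2 females each), an overall diarrhoea prevalence of 13/20,
#' negative-binomial OTU counts with group effects concentrated in a small
#' set of discriminant taxa, fingerprint traces whose peak areas track taxon
#' abundances, a log-linear qPCR standard curve, and faecal dry-matter
#' series negatively coupled to *Enterobacteriaceae* load in D pigs only.
#'
#' @param n_litters number of litters (sows).
#' @param pigs_per_litter piglets selected per litter.
#' @param n_otus number of OTUs in the simulated count table.
#' @param n_discriminant number of OTUs carrying a group effect.
#' @param effect_size absolute log2 fold change (H vs D) given to
#'   discriminant OTUs when `logfc_effects` is not supplied.
#' @param logfc_effects optional named numeric vector, OTU id -> signed
#'   log2 fold change (H vs D); overrides `n_discriminant`/`effect_size`.
#' @param dispersion negative-binomial dispersion phi >= 0
#'   (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param library_size_range length-2 positive integer range of sequencing
#'   depths per sample.
#' @param d_prevalence either a scalar overall diarrhoea prevalence in
#'   \[0, 1\] (exact count `round(p * n)` of D pigs drawn at random) or a
#'   vector of per-litter D counts of length `n_litters`.
#' @param entero_dm_slope coupling of dry matter (% DM) to log10
#'   *Enterobacteriaceae* copies in D pigs; must be <= 0.
#' @param entero_elevation log10 increase in *Enterobacteriaceae* copies in
#'   D pigs during the diarrhoea episode.
#' @param episode_window integer range of post-natal days in which a D
#'   pig's first liquid-faeces day falls.
#' @param dm_days post-natal days on which dry matter is recorded.
#' @param dm_baseline,dm_noise_sd mean and s.d. of healthy dry-matter (%).
#' @param qpcr_efficiency amplification efficiency in (0.7, 1.1].
#' @param qpcr_intercept standard-curve Cq at 1 copy.
#' @param qpcr_noise_sd s.d. of Cq noise (cycles).
#' @param fp_n_phylotypes number of (most abundant) OTUs rendered as
#'   fingerprint peaks.
#' @param fp_sigma Gaussian peak width (size units).
#' @param fp_shift_max maximum absolute per-sample scan shift (size units).
#' @param fp_noise_sd trace noise s.d. as a fraction of the tallest peak.
#' @param fp_comigration if `TRUE`, force two phylotypes to share one peak
#'   position (stress test); default keeps the map injective.
#' @param seed root seed; all stages draw from named streams derived from it.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_litters = 5L, pigs_per_litter = 4L,
                       n_otus = 200L, n_discriminant = 10L,
                       effect_size = 3, logfc_effects = NULL,
                       dispersion = 0.2,
                       library_size_range = c(20000L, 50000L),
                       d_prevalence = 13 / 20,
                       entero_dm_slope = -5,
                       entero_elevation = 2.2,
                       episode_window = 38:42,
                       dm_days = 30:47,
                       dm_baseline = 26, dm_noise_sd = 0.8,
                       qpcr_efficiency = 0.95,
                       qpcr_intercept = 38,
                       qpcr_noise_sd = 0.15,
                       fp_n_phylotypes = 40L,
                       fp_sigma = 1.2,
                       fp_shift_max = 3,
                       fp_noise_sd = 0.002,
                       fp_comigration = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (n_litters < 1 || pigs_per_litter < 1) stopf("litter structure counts must be positive")
  if (n_otus < 1) stopf("n_otus must be positive")
  if (is.null(logfc_effects) && n_discriminant > n_otus)
    stopf("n_discriminant (%d) exceeds n_otus (%d)", n_discriminant, n_otus)
  if (dispersion < 0) stopf("dispersion phi must be >= 0")
  if (length(library_size_range) != 2 || any(library_size_range <= 0))
    stopf("library_size_range must be two positive counts")
  if (qpcr_efficiency <= 0.7 || qpcr_efficiency > 1.1)
    stopf("qpcr_efficiency must lie in (0.7, 1.1]")
  if (entero_dm_slope > 0) stopf("entero_dm_slope must be <= 0")
  if (is.numeric(d_prevalence) && length(d_prevalence) == 1) {
    if (d_prevalence < 0 || d_prevalence > 1) stopf("scalar d_prevalence must be in [0, 1]")
  } else if (length(d_prevalence) != n_litters) {
    stopf("d_prevalence must be scalar or one D count per litter")
  }
  structure(cfg, class = "sim_config")
}

# pool of pig gut taxa used for simulated taxonomy strings
.taxon_pool <- function() {
  data.frame(
    phylum = c("Bacteroidetes", "Firmicutes", "Firmicutes", "Firmicutes",
               "Fusobacteria", "Actinobacteria", "Proteobacteria",
               "Bacteroidetes", "Firmicutes", "Firmicutes", "Firmicutes",
               "Firmicutes"),
    family = c("Prevotellaceae", "Lachnospiraceae", "Ruminococcaceae",
               "Lactobacillaceae", "Fusobacteriaceae", "Corynebacteriaceae",
               "Enterobacteriaceae", "Bacteroidaceae", "Clostridiaceae",
               "Streptococcaceae", "Veillonellaceae", "Erysipelotrichaceae"),
    stringsAsFactors = FALSE
  )
}

#' Generate the cohort structure and ground truth
#'
#' Assigns piglets to litters with balanced sexes, draws the
#' healthy/diarrhoeic (H/D) labels at the configured prevalence, fixes the
#' signed log2 fold-change effects of the discriminant OTUs, and simulates
#' true 16S copy-number trajectories for the qPCR targets (total bacteria,
#' Firmicutes, Bacteroidetes, *Lactobacillus*, *Enterobacteriaceae*),
#' with an *Enterobacteriaceae* bloom during each D pig's episode.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (data.frame: pig, litter, sex, group) and
#'   `truth` (list: group_labels, true_effects, episodes, true_copies).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "cohort"))
  n <- config$n_litters * config$pigs_per_litter
  litter <- rep(seq_len(config$n_litters), each = config$pigs_per_litter)
  sex <- unlist(lapply(seq_len(config$n_litters), function(l) {
    s <- rep(c("M", "F"), length.out = config$pigs_per_litter)
    sample(s)
  }))
  pig <- sprintf("pig%02d", seq_len(n))

  prev <- config$d_prevalence
  group <- rep("H", n)
  if (length(prev) == 1) {
    n_d <- round(prev * n)
    group[sample(n, n_d)] <- "D"
  } else {
    for (l in seq_len(config$n_litters)) {
      idx <- which(litter == l)
      k <- prev[l]
      if (k > length(idx)) stopf("per-litter D count exceeds litter size")
      if (k > 0) group[sample(idx, k)] <- "D"
    }
  }
  cohort <- data.frame(pig = pig, litter = litter, sex = sex, group = group,
                       stringsAsFactors = FALSE)

  # discriminant OTU effects, H vs D, symmetric +/- by construction
  if (is.null(config$logfc_effects)) {
    otu_ids <- sprintf("OTU%04d", seq_len(config$n_otus))
    disc <- sample(otu_ids, config$n_discriminant)
    eff <- rep(c(1, -1), length.out = config$n_discriminant) * config$effect_size
    names(eff) <- disc
  } else {
    eff <- config$logfc_effects
  }

  # diarrhoea episodes for D pigs: first liquid day uniform in the window
  d_idx <- which(group == "D")
  episodes <- data.frame(pig = pig[d_idx],
                         start = sample(config$episode_window, length(d_idx), replace = TRUE),
                         duration = sample(2:4, length(d_idx), replace = TRUE),
                         stringsAsFactors = FALSE)

  # true copies per pig x day x target (log10-normal baselines)
  targets <- c("total_bacteria", "Firmicutes", "Bacteroidetes",
               "Lactobacillus", "Enterobacteriaceae")
  base_log10 <- c(total_bacteria = 9.5, Firmicutes = 9.0, Bacteroidetes = 8.5,
                  Lactobacillus = 7.5, Enterobacteriaceae = 7.0)
  days <- config$dm_days
  grid <- expand.grid(pig = pig, day = days, target = targets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lg <- base_log10[grid$target] + rnorm(nrow(grid), 0, 0.25)
  ep <- episodes[match(grid$pig, episodes$pig), ]
  in_ep <- !is.na(ep$start) & grid$day >= ep$start & grid$day < ep$start + ep$duration &
    grid$target == "Enterobacteriaceae"
  lg[in_ep] <- lg[in_ep] + config$entero_elevation
  grid$copies <- 10^lg

  truth <- list(
    group_labels = stats::setNames(group, pig),
    true_effects = eff,
    episodes = episodes,
    true_copies = grid
  )
  list(cohort = cohort, truth = truth)
}

#' Simulate an OTU count table
#'
#' Draws per-sample OTU counts from a negative binomial with
#' variance = mu + phi * mu^2; the group effect multiplies the mean by
#' `2^(+lfc/2)` in H and `2^(-lfc/2)` in D pigs (symmetric, so swapping
#' labels exactly negates the log fold change).  Baseline relative
#' abundances follow a log-normal rank-abundance profile; taxonomy strings
#' are assigned from a bundled pig-gut taxon pool, with D-enriched
#' discriminant OTUs placed in *Enterobacteriaceae* and H-enriched ones in
#' lactic-acid / fibrolytic families.
#'
#' @param cohort cohort data.frame from [generate_cohort()].
#' @param truth ground-truth list from [generate_cohort()].
#' @param config a [sim_config()].
#' @return an [otu_count_table()].
#' @export
simulate_otu_table <- function(cohort, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$dispersion < 0) stopf("dispersion phi must be >= 0")
  set.seed(stream_seed(config$seed, "counts"))
  p <- config$n_otus
  n <- nrow(cohort)
  otu_ids <- sprintf("OTU%04d", seq_len(p))

  rel <- exp(rnorm(p, 0, 1.5))
  rel <- rel / sum(rel)
  lsr <- config$library_size_range
  libsize <- if (lsr[1] == lsr[2]) rep(lsr[1], n) else
    sample(seq(lsr[1], lsr[2]), n, replace = TRUE)

  lfc <- stats::setNames(rep(0, p), otu_ids)
  lfc[names(truth$true_effects)] <- truth$true_effects
  is_h <- cohort$group == "H"

  mu <- outer(rel, libsize)                       # p x n baseline means
  mult <- 2^(outer(lfc, ifelse(is_h, 0.5, -0.5))) # symmetric group effect
  mu <- mu * mult
  counts <- matrix(0L, p, n, dimnames = list(otu_ids, cohort$pig))
  if (config$dispersion == 0) {
    counts[] <- rpois(p * n, lambda = mu)
  } else {
    counts[] <- rnbinom(p * n, size = 1 / config$dispersion, mu = mu)
  }

  pool <- .taxon_pool()
  fam_idx <- sample(nrow(pool), p, replace = TRUE)
  # bias discriminant taxonomy: D-enriched -> Enterobacteriaceae,
  # H-enriched -> Lactobacillaceae / Ruminococcaceae
  d_enriched <- names(truth$true_effects)[truth$true_effects < 0]
  h_enriched <- names(truth$true_effects)[truth$true_effects > 0]
  fam_idx[match(d_enriched, otu_ids)] <- which(pool$family == "Enterobacteriaceae")
  fam_idx[match(h_enriched, otu_ids)] <-
    sample(which(pool$family %in% c("Lactobacillaceae", "Ruminococcaceae")),
           length(h_enriched), replace = TRUE)
  taxonomy <- stats::setNames(
    sprintf("k__Bacteria; p__%s; f__%s", pool$phylum[fam_idx], pool$family[fam_idx]),
    otu_ids)

  meta <- data.frame(sample = cohort$pig, pig = cohort$pig,
                     group = cohort$group, day = 7L, stringsAsFactors = FALSE)
  otu_count_table(counts, taxonomy, meta)
}

#' Simulate CE-SSCP-style fingerprint traces
#'
#' Each sample's trace is a sum of fixed-width Gaussian peaks (one position
#' per rendered phylotype, area proportional to its relative abundance)
#' plus a smooth baseline, white noise, and a per-sample random affine
#' scan distortion (shift plus slight stretch).  The internal size standard
#' is modelled as a separate detection channel: its observed peak positions
#' (distorted like the trace) are carried alongside the trace rather than
#' summed into it.
#'
#' Only the `fp_n_phylotypes` most abundant OTUs are rendered (rare taxa
#' fall below fingerprint detection in practice); their relative abundances
#' are renormalized.  Peak positions are injective by default.
#'
#' @inheritParams simulate_otu_table
#' @param table an [otu_count_table()].
#' @return list with `profiles` (named list of `fingerprint_profile`),
#'   `peak_positions` (named vector, phylotype -> nominal size) and
#'   `standard_sizes`.
#' @export
simulate_fingerprints <- function(table, config) {
  stopifnot(inherits(table, "otu_table"), inherits(config, "sim_config"))
  if (ncol(table$counts) == 0) stopf("OTU table has no samples")
  set.seed(stream_seed(config$seed, "traces"))

  standard_sizes <- c(60, 100, 490, 530)
  k <- min(config$fp_n_phylotypes, nrow(table$counts))
  tot <- rowSums(table$counts)
  top <- order(tot, decreasing = TRUE)[seq_len(k)]
  otus <- rownames(table$counts)[top]

  # injective phylotype -> position map, min spacing 3 size units
  cand <- seq(140, 470, by = 3)
  pos <- sort(sample(cand, k))
  if (config$fp_comigration && k >= 2) pos[2] <- pos[1]
  names(pos) <- otus

  grid <- seq(40, 550, by = 0.25)
  rel <- sweep(table$counts[top, , drop = FALSE], 2,
               pmax(colSums(table$counts[top, , drop = FALSE]), 1), "/")

  profiles <- lapply(seq_len(ncol(rel)), function(j) {
    shift <- runif(1, -config$fp_shift_max, config$fp_shift_max)
    stretch <- 1 + runif(1, -0.004, 0.004)
    raw_pos <- pos * stretch + shift
    sig <- numeric(length(grid))
    for (i in seq_len(k)) {
      sig <- sig + rel[i, j] * dnorm(grid, raw_pos[i], config$fp_sigma)
    }
    base <- 0.02 * max(sig, 1e-9) * (1 + 0.5 * sin(grid / 70))
    noise <- if (config$fp_noise_sd > 0)
      rnorm(length(grid), 0, config$fp_noise_sd * max(sig, 1e-9)) else 0
    fingerprint_profile(
      sample_id = colnames(rel)[j],
      positions = grid,
      intensities = pmax(sig + base + noise, 0),
      standard_peaks = data.frame(observed = standard_sizes * stretch + shift,
                                  nominal = standard_sizes)
    )
  })
  names(profiles) <- colnames(rel)
  list(profiles = profiles, peak_positions = pos, standard_sizes = standard_sizes)
}

#' Simulate a qPCR run (standards plus cohort samples)
#'
#' Standards are 10-fold serial dilutions with
#' `Cq = intercept - log10(copies) / log10(1 + efficiency) + noise`;
#' sample Cq values are generated from the ground-truth copy numbers.
#'
#' @inheritParams simulate_otu_table
#' @param days subset of days to include (default: all days in the truth).
#' @return list of class `qpcr_run`: `standards` (target, copies, cq) and
#'   `samples` (sample, target, day, cq, dna_mass_ug).
#' @export
simulate_qpcr_run <- function(truth, config, days = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "qpcr"))
  eff <- config$qpcr_efficiency
  slope <- -1 / log10(1 + eff)
  tc <- truth$true_copies
  if (!is.null(days)) tc <- tc[tc$day %in% days, ]
  if (any(tc$copies <= 0)) stopf("true copy numbers must be positive")

  targets <- unique(tc$target)
  std <- expand.grid(target = targets, copies = 10^(2:10),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  std$cq <- config$qpcr_intercept + slope * log10(std$copies) +
    rnorm(nrow(std), 0, config$qpcr_noise_sd)

  samples <- data.frame(sample = tc$pig, target = tc$target, day = tc$day,
                        cq = config$qpcr_intercept + slope * log10(tc$copies) +
                          rnorm(nrow(tc), 0, config$qpcr_noise_sd),
                        dna_mass_ug = 100, stringsAsFactors = FALSE)
  structure(list(standards = std, samples = samples,
                 efficiency = eff, intercept = config$qpcr_intercept),
            class = "qpcr_run")
}

#' Simulate cohort phenotypes
#'
#' Produces per-pig faecal dry-matter (DM, %) series over the post-weaning
#' days, MUC13 amplicon lengths, colostrum concentrations and intakes, and
#' body weights.  In D pigs DM is a decreasing linear function of the
#' simulated log10 *Enterobacteriaceae* copies (slope `entero_dm_slope`),
#' so the *Enterobacteriaceae* bloom placed during the episode drives DM
#' below 20% for at least two consecutive days; H pigs stay above 20%.
#' MUC13 alleles (151 bp A / 83 bp B) are drawn independently of group.
#'
#' @inheritParams simulate_otu_table
#' @return list of class `cohort_phenotypes`: `pigs`, `dm` (pig, day, dm),
#'   `muc13` (pig, len1, len2), `colostrum`, `weights`.
#' @export
simulate_phenotypes <- function(cohort, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "phenotypes"))
  days <- config$dm_days
  ent <- truth$true_copies[truth$true_copies$target == "Enterobacteriaceae", ]
  base_log10 <- 7.0  # reference Enterobacteriaceae load

  dm <- do.call(rbind, lapply(cohort$pig, function(pg) {
    e <- ent[ent$pig == pg, ]
    e <- e[order(e$day), ]
    coupled <- truth$group_labels[pg] == "D" && config$entero_dm_slope < 0
    drive <- if (coupled) config$entero_dm_slope * (log10(e$copies) - base_log10) else 0
    data.frame(pig = pg, day = e$day,
               dm = config$dm_baseline + drive + rnorm(nrow(e), 0, config$dm_noise_sd),
               stringsAsFactors = FALSE)
  }))
  # healthy faeces remain solid: clamp the uncoupled background above 20% DM
  bg <- dm$dm < 20.5
  uncoupled <- truth$group_labels[dm$pig] == "H" | config$entero_dm_slope == 0
  dm$dm[bg & uncoupled] <- 20.5 + abs(dm$dm[bg & uncoupled] - 20.5)

  alleles <- matrix(sample(c(151L, 83L), 2 * nrow(cohort), replace = TRUE),
                    ncol = 2)
  muc13 <- data.frame(pig = cohort$pig, len1 = alleles[, 1], len2 = alleles[, 2],
                      stringsAsFactors = FALSE)

  sow_igg <- pmax(rnorm(config$n_litters, 60, 15), 5)    # mg/mL
  sow_iga <- pmax(rnorm(config$n_litters, 10, 3), 0.5)   # mg/mL
  sow_tgf <- pmax(rnorm(config$n_litters, 100, 30), 5)   # ng/mL
  colostrum <- data.frame(
    pig = cohort$pig, litter = cohort$litter,
    intake_g = pmax(rnorm(nrow(cohort), 300, 80), 50),
    igg_mg_ml = sow_igg[cohort$litter],
    iga_mg_ml = sow_iga[cohort$litter],
    tgfb1_ng_ml = sow_tgf[cohort$litter],
    stringsAsFactors = FALSE
  )

  wdays <- c(0, 1, 7, 14, 21, 28, 35, 42, 49)
  weights <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    bw0 <- rnorm(1, 1.5, 0.2)
    data.frame(pig = cohort$pig[i], day = wdays,
               weight_kg = bw0 + 0.28 * wdays + rnorm(length(wdays), 0, 0.15),
               stringsAsFactors = FALSE)
  }))

  structure(list(pigs = cohort, dm = dm, muc13 = muc13,
                 colostrum = colostrum, weights = weights),
            class = "cohort_phenotypes")
}

#' Simulate a complete in-silico study
#'
#' Convenience wrapper running every generator stage off one root seed:
#' cohort + ground truth, OTU counts, fingerprints, qPCR run, phenotypes.
#'
#' @param config a [sim_config()].
#' @return list: `cohort`, `truth`, `otu_table`, `fingerprints`, `qpcr`,
#'   `phenotypes`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  cg <- generate_cohort(config)
  tab <- simulate_otu_table(cg$cohort, cg$truth, config)
  fps <- simulate_fingerprints(tab, config)
  qp <- simulate_qpcr_run(cg$truth, config)
  ph <- simulate_phenotypes(cg$cohort, cg$truth, config)
  list(cohort = cg$cohort, truth = cg$truth, otu_table = tab,
       fingerprints = fps, qpcr = qp, phenotypes = ph, config = config)
}
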