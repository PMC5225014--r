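# qPCR quantification, diarrhoea classification, normality-gated group
# comparisons, Enterobacteriaceae-dry-matter correlation, MUC13 genotyping
# and colostral immune-load computation.

#' Fit a qPCR standard curve
#'
#' Least-squares line of Cq on log10(copies) over the dilution series;
#' amplification efficiency is `10^(-1/slope) - 1`.
#'
#' @param standards data.frame with columns `copies` (> 0) and `cq`.
#' @return list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `cq_range`.
#' @export
fit_standard_curve <- function(standards) {
  if (any(standards$copies <= 0)) stopf("standard copies must be positive")
  if (length(unique(standards$copies)) < 3)
    stopf("at least 3 distinct dilution points required")
  fit <- lm(cq ~ log10(copies), data = standards)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) warning("standard-curve slope is non-negative; check the dilution series")
  # summary.lm warns on noiseless dilution series; the fit itself is valid
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 cq_range = range(standards$cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: slope %.3f, intercept %.2f, r2 %.4f, efficiency %.1f%%\n",
              x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Absolute quantification from a standard curve
#'
#' `copies = 10^((Cq - intercept) / slope)`, rescaled to copies per
#' 100 ug of template DNA.  Cq values outside the standards' Cq range by
#' more than `extrapolation_margin` cycles are flagged (with a warning)
#' but still quantified.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param cq numeric Cq values.
#' @param dna_mass_ug template DNA mass per reaction (ug), recycled.
#' @param extrapolation_margin allowed Cq excursion beyond the standards.
#' @return data.frame: `cq`, `copies_per_100ug`, `flagged`.
#' @export
quantify_copies <- function(curve, cq, dna_mass_ug = 100,
                            extrapolation_margin = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  copies <- 10^((cq - curve$intercept) / curve$slope)
  flagged <- cq < curve$cq_range[1] - extrapolation_margin |
    cq > curve$cq_range[2] + extrapolation_margin
  if (any(flagged))
    warning(sprintf("%d Cq value(s) outside the standard range (margin %g)",
                    sum(flagged), extrapolation_margin))
  data.frame(cq = cq, copies_per_100ug = copies * 100 / dna_mass_ug,
             flagged = flagged)
}

#' Classify a pig as healthy or diarrhoeic from its dry-matter series
#'
#' A pig is diarrhoeic (D) if its faecal dry matter falls below
#' `dm_threshold` on at least `min_consecutive` consecutive *observed*
#' days (gaps in the observation days break runs); otherwise healthy (H).
#' The first qualifying episode window is reported.
#'
#' @param dm dry-matter percentages.
#' @param days observation days (default: consecutive).
#' @param dm_threshold liquid-faeces threshold (% DM, default 20).
#' @param min_consecutive minimum consecutive sub-threshold days.
#' @return list: `group` ("H"/"D"), `episode_start`, `episode_end`
#'   (NA for H).
#' @export
classify_diarrhoea <- function(dm, days = NULL, dm_threshold = 20,
                               min_consecutive = 2) {
  if (length(dm) < 2) stopf("at least 2 observed days required")
  days <- days %||% seq_along(dm)
  o <- order(days)
  dm <- dm[o]; days <- days[o]
  below <- dm < dm_threshold
  run_id <- cumsum(c(TRUE, diff(days) != 1 | !below[-length(below)]))
  for (r in unique(run_id[below])) {
    idx <- which(run_id == r & below)
    if (length(idx) >= min_consecutive) {
      return(list(group = "D",
                  episode_start = days[idx[1]],
                  episode_end = days[idx[length(idx)]]))
    }
  }
  list(group = "H", episode_start = NA_real_, episode_end = NA_real_)
}

#' Correlation between Enterobacteriaceae load and faecal dry matter
#'
#' Samples are split at the dry-matter threshold (liquid vs solid faeces)
#' and Pearson correlation between (log10) copies and DM is computed per
#' subgroup with a two-sided test.
#'
#' @param copies Enterobacteriaceae copy numbers.
#' @param dm matched dry-matter percentages.
#' @param dm_threshold split point (% DM, default 20).
#' @param log10_copies correlate log10(copies) (default) or raw copies.
#' @return data.frame: `subgroup` ("liquid"/"solid"), `n`, `r`, `r2`, `p`.
#' @export
correlate_entero_dm <- function(copies, dm, dm_threshold = 20,
                                log10_copies = TRUE) {
  if (length(copies) != length(dm)) stopf("copies and dm must be matched")
  x <- if (log10_copies) log10(copies) else copies
  out <- lapply(c(liquid = TRUE, solid = FALSE), function(liq) {
    sel <- if (liq) dm < dm_threshold else dm >= dm_threshold
    if (sum(sel) < 3) stopf("subgroup '%s' has fewer than 3 points",
                            if (liq) "liquid" else "solid")
    if (sd(x[sel]) == 0 || sd(dm[sel]) == 0) {
      warning("zero variance in a subgroup; correlation undefined")
      return(data.frame(n = sum(sel), r = NA_real_, r2 = NA_real_, p = NA_real_))
    }
    ct <- cor.test(x[sel], dm[sel])
    data.frame(n = sum(sel), r = unname(ct$estimate),
               r2 = unname(ct$estimate)^2, p = ct$p.value)
  })
  cbind(data.frame(subgroup = names(out), stringsAsFactors = FALSE),
        do.call(rbind, out), row.names = NULL)
}

#' Normality-gated two-group comparison
#'
#' Each group is tested for normality (Shapiro-Wilk at `alpha_normality`);
#' if both pass, a two-sample Student t-test is used, otherwise a
#' Mann-Whitney (Wilcoxon rank-sum) test.  Groups smaller than 3 skip the
#' gate and force the non-parametric branch.  With `paired_by_age` the
#' within-group age effect is tested instead, by paired t-tests between
#' consecutive ages.
#'
#' @param values numeric measurements.
#' @param groups two-level grouping.
#' @param age optional age per observation (required for `paired_by_age`).
#' @param subject optional subject id (pairs observations across ages).
#' @param paired_by_age test consecutive-age changes within each group.
#' @param alpha_normality significance level of the Shapiro-Wilk gate.
#' @return data.frame report: one row per test with `test`, `branch`,
#'   `statistic`, `p` (plus `group`, `ages` for paired comparisons).
#' @export
group_compare <- function(values, groups, age = NULL, subject = NULL,
                          paired_by_age = FALSE, alpha_normality = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stopf("exactly 2 groups required")

  if (paired_by_age) {
    if (is.null(age) || is.null(subject)) stopf("paired_by_age needs age and subject")
    out <- list()
    for (g in levels(groups)) {
      sel <- groups == g
      ags <- sort(unique(age[sel]))
      for (i in seq_len(length(ags) - 1)) {
        a1 <- ags[i]; a2 <- ags[i + 1]
        s1 <- subject[sel & age == a1]; v1 <- values[sel & age == a1]
        s2 <- subject[sel & age == a2]; v2 <- values[sel & age == a2]
        common <- intersect(s1, s2)
        if (length(common) < 3) next
        tt <- t.test(v1[match(common, s1)], v2[match(common, s2)], paired = TRUE)
        out[[length(out) + 1]] <- data.frame(
          group = g, ages = sprintf("%s-%s", a1, a2), test = "paired t",
          branch = "parametric", statistic = unname(tt$statistic),
          p = tt$p.value, stringsAsFactors = FALSE)
      }
    }
    return(do.call(rbind, out))
  }

  v1 <- values[groups == levels(groups)[1]]
  v2 <- values[groups == levels(groups)[2]]
  gate_ok <- length(v1) >= 3 && length(v2) >= 3
  normal <- gate_ok &&
    (sd(v1) == 0 || shapiro.test(v1)$p.value >= alpha_normality) &&
    (sd(v2) == 0 || shapiro.test(v2)$p.value >= alpha_normality)
  if (!gate_ok)
    message("group below 3 observations: normality gate skipped, non-parametric branch forced")

  if (normal && sd(c(v1, v2)) > 0) {
    tt <- t.test(v1, v2)
    data.frame(test = "Student t", branch = "parametric",
               statistic = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  } else if (sd(c(v1, v2)) == 0) {
    data.frame(test = "Student t", branch = "degenerate",
               statistic = 0, p = 1, stringsAsFactors = FALSE)
  } else {
    wt <- suppressWarnings(wilcox.test(v1, v2))
    data.frame(test = "Mann-Whitney", branch = "nonparametric",
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  }
}

#' MUC13 genotyping and allele-prevalence test
#'
#' Amplicon lengths are called as allele A (151 bp, resistance-associated)
#' or B (83 bp, susceptibility-associated) within `tolerance_bp`; a pig
#' with both lengths is an AB heterozygote, one length a homozygote.
#' Allele counts (2 per pig) are cross-tabulated against the H/D groups
#' and tested with Pearson's chi-squared (no continuity correction by
#' default).
#'
#' @param lengths list of detected amplicon lengths (1-2 per pig).
#' @param groups H/D label per pig.
#' @param tolerance_bp length-call tolerance (default 2 bp).
#' @param correct apply Yates continuity correction.
#' @return list: `genotypes` (data.frame pig-wise), `table` (2x2 allele x
#'   group), `chisq`, `p_value`.
#' @export
muc13_genotype_and_test <- function(lengths, groups, tolerance_bp = 2,
                                    correct = FALSE) {
  call_allele <- function(len) {
    if (abs(len - 151) <= tolerance_bp) "A"
    else if (abs(len - 83) <= tolerance_bp) "B"
    else NA_character_
  }
  pigs <- names(lengths) %||% sprintf("pig%02d", seq_along(lengths))
  geno <- do.call(rbind, lapply(seq_along(lengths), function(i) {
    ln <- lengths[[i]]
    if (length(ln) < 1 || length(ln) > 2) stopf("each pig needs 1-2 detected lengths")
    al <- vapply(ln, call_allele, character(1))
    if (any(is.na(al)))
      warning(sprintf("pig %s: unrecognized amplicon length(s) %s",
                      pigs[i], paste(ln[is.na(al)], collapse = ",")))
    if (length(al) == 1) al <- c(al, al)  # single length -> homozygote
    al <- sort(al, na.last = TRUE)
    data.frame(pig = pigs[i], allele1 = al[1], allele2 = al[2],
               genotype = if (any(is.na(al))) NA_character_ else paste0(al[1], al[2]),
               stringsAsFactors = FALSE)
  }))
  allele <- c(geno$allele1, geno$allele2)
  grp <- factor(rep(groups, 2))
  ok <- !is.na(allele)
  tab <- table(allele = allele[ok], group = grp[ok])
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(genotypes = geno, table = tab,
       chisq = unname(ct$statistic), p_value = ct$p.value)
}

#' Ingested colostral immune load
#'
#' Component-wise product of colostral concentrations and ingested
#' colostrum volume/mass, with unit propagation: each concentration unit
#' must be "per mL" (e.g. `mg/mL`); the result carries the numerator unit.
#'
#' @param concentrations named non-negative numeric vector.
#' @param intake_ml ingested colostrum (mL), non-negative.
#' @param units named character vector of concentration units (must end in
#'   "/mL"); defaults to `mg/mL` for every component.
#' @return data.frame: `component`, `quantity`, `unit`.
#' @export
ingested_immune_load <- function(concentrations, intake_ml, units = NULL) {
  if (any(concentrations < 0) || intake_ml < 0) stopf("inputs must be non-negative")
  comp <- names(concentrations) %||% sprintf("component%d", seq_along(concentrations))
  units <- units %||% stats::setNames(rep("mg/mL", length(comp)), comp)
  if (!all(grepl("/mL$", units)))
    stopf("unit mismatch: concentration units must be per mL (got %s)",
          paste(units[!grepl("/mL$", units)], collapse = ", "))
  data.frame(component = comp,
             quantity = unname(concentrations) * intake_ml,
             unit = sub("/mL$", "", unname(units[comp])),
             stringsAsFactors = FALSE)
}
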