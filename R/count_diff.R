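# Filtering, scaling normalization, common-dispersion estimation and the
# negative-binomial exact test for two-group differential OTU abundance.

#' Filter an OTU table
#'
#' Removes OTUs whose total count is `<= min_total` (an OTU is valid only
#' with strictly more than `min_total` sequences) and OTUs whose variance
#' falls at or below `min_variance`.  The variance filter is applied to
#' relative abundances by default (configurable), matching low-information
#' OTU removal ahead of multivariate analysis.
#'
#' @param table an [otu_count_table()].
#' @param min_total strict lower bound on the OTU's total count (default 3).
#' @param min_variance strict lower bound on the OTU's variance
#'   (default 1e-8).
#' @param variance_on compute the variance on `"relative"` abundances
#'   (default), `"counts"`, or `"normalized"` counts.
#' @return the filtered `otu_table`, OTU order preserved.
#' @export
filter_otus <- function(table, min_total = 3, min_variance = 1e-8,
                        variance_on = c("relative", "counts", "normalized")) {
  stopifnot(inherits(table, "otu_table"))
  variance_on <- match.arg(variance_on)
  if (nrow(table$counts) == 0) stopf("empty OTU table")
  keep <- rowSums(table$counts) > min_total

  x <- switch(variance_on,
    relative = sweep(table$counts, 2, pmax(colSums(table$counts), 1), "/"),
    counts = table$counts,
    normalized = scaling_normalize(table)$normalized)
  keep <- keep & apply(x, 1, var) > min_variance

  if (!any(keep))
    stopf("all %d OTUs removed (min_total = %g, min_variance = %g)",
          nrow(table$counts), min_total, min_variance)
  otu_count_table(table$counts[keep, , drop = FALSE],
                  table$taxonomy[rownames(table$counts)[keep]],
                  table$sample_meta)
}

#' Scaling-factor normalization (median of ratios)
#'
#' Per-sample scaling factors are the medians of the ratios of each
#' sample's counts to the geometric-mean reference profile, computed over
#' OTUs observed in every sample, then rescaled so the factors have
#' geometric mean 1.  If no OTU is present in all samples, total-count
#' factors are used instead (with a warning).
#'
#' @param table an [otu_count_table()].
#' @return list: `factors` (per sample, geometric mean 1 times the common
#'   scale), `normalized` (counts / factor).
#' @export
scaling_normalize <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  cnt <- table$counts
  if (any(colSums(cnt) == 0)) stopf("every sample needs at least one nonzero OTU")
  core <- rowSums(cnt > 0) == ncol(cnt)
  if (any(core)) {
    logref <- rowMeans(log(cnt[core, , drop = FALSE]))
    f <- apply(cnt[core, , drop = FALSE], 2, function(col)
      median(exp(log(col) - logref)))
  } else {
    warning("no OTU nonzero in all samples; falling back to total-count factors")
    f <- colSums(cnt)
  }
  f <- f / exp(mean(log(f)))
  list(factors = f, normalized = sweep(cnt, 2, f, "/"))
}

# pseudo-counts at a common library size: normalized counts rescaled to
# the geometric-mean depth and rounded half-up (exact test needs integers)
.equalize_libraries <- function(counts, factors) {
  eff <- colSums(counts) / factors        # effective depth after scaling
  common <- exp(mean(log(pmax(eff, 1))))
  pseudo <- sweep(sweep(counts, 2, factors, "/"), 2, common / pmax(eff, 1), "*")
  floor(pseudo + 0.5)
}

# conditional log-probabilities of the group-A sum x = 0..t given the
# two-group total t, for NB(phi) counts at equal per-sample means; the
# mean parameter cancels, leaving a Polya (beta-binomial-like) law, which
# degenerates to Binomial(t, nA/(nA+nB)) at phi = 0
.cond_split_prob <- function(t, nA, nB, phi) {
  x <- 0:t
  if (phi <= 0) {
    lp <- dbinom(x, t, nA / (nA + nB), log = TRUE)
  } else {
    sA <- nA / phi; sB <- nB / phi
    lp <- lgamma(x + sA) - lfactorial(x) + lgamma(t - x + sB) - lfactorial(t - x)
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Common-dispersion estimate by conditional maximum likelihood
#'
#' Maximizes, over a single dispersion phi shared across OTUs, the sum of
#' per-OTU conditional log-likelihoods of the counts given their group
#' totals, computed on equal-library pseudo-counts (the standard
#' conditional-likelihood device for NB exact testing).
#'
#' @param table an [otu_count_table()].
#' @param groups two-group factor over samples (defaults to
#'   `sample_meta$group`).
#' @return phi >= 0.
#' @export
estimate_common_dispersion <- function(table, groups = NULL) {
  stopifnot(inherits(table, "otu_table"))
  groups <- groups %||% table$sample_meta$group
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 2))
    stopf("dispersion undefined with a single sample per group; override with phi = 0")
  norm <- scaling_normalize(table)
  pseudo <- .equalize_libraries(table$counts, norm$factors)

  cond_ll <- function(phi) {
    s <- 1 / phi
    ll <- 0
    for (g in names(tab)) {
      y <- pseudo[, groups == g, drop = FALSE]
      ng <- ncol(y)
      z <- rowSums(y)
      ll <- ll + sum(rowSums(lgamma(y + s)) - ng * lgamma(s) +
                       lgamma(ng * s) - lgamma(z + ng * s))
    }
    ll
  }
  opt <- optimize(function(lp) cond_ll(exp(lp)), interval = c(log(1e-6), log(20)),
                  maximum = TRUE)
  phi <- exp(opt$maximum)
  if (phi < 2e-6) phi <- 0
  phi
}

#' Negative-binomial exact test for two-group differential abundance
#'
#' For each OTU, counts are adjusted to a common library size and the test
#' conditions on the two-group total: the two-sided p-value is the sum of
#' the probabilities of all splits of the total no more probable than the
#' observed one under the common-dispersion NB model (`two_sided =
#' "smallp"`; doubling the smaller tail is available).  Log2 fold changes
#' (first group level vs second) use normalized group means with a small
#' prior count so structural zeros stay finite.
#'
#' @param table an [otu_count_table()].
#' @param groups two-group factor over samples; the first level is the
#'   fold-change numerator (defaults to `sample_meta$group`, levels sorted,
#'   so "D" vs "H" unless a factor is supplied).
#' @param phi common NB dispersion; estimated with
#'   [estimate_common_dispersion()] when `NULL`.
#' @param prior_count prior added to group mean normalized counts for the
#'   fold change (default 0.125).
#' @param two_sided `"smallp"` (sum of outcomes no more probable than
#'   observed) or `"doubletail"`.
#' @return data.frame of class `exact_test_result`: `otu_id`, `taxonomy`,
#'   `log2fc`, `p_value`, `fdr`, with `phi` and `factors` as attributes.
#' @export
exact_test <- function(table, groups = NULL, phi = NULL, prior_count = 0.125,
                       two_sided = c("smallp", "doubletail")) {
  stopifnot(inherits(table, "otu_table"))
  two_sided <- match.arg(two_sided)
  groups <- groups %||% table$sample_meta$group
  groups <- factor(groups)
  if (nlevels(groups) != 2) stopf("exact test requires exactly 2 groups")
  if (is.null(phi)) phi <- estimate_common_dispersion(table, groups)
  if (phi < 0) stopf("phi must be >= 0")

  norm <- scaling_normalize(table)
  pseudo <- .equalize_libraries(table$counts, norm$factors)
  gA <- groups == levels(groups)[1]
  nA <- sum(gA); nB <- sum(!gA)

  sumA <- rowSums(pseudo[, gA, drop = FALSE])
  sumB <- rowSums(pseudo[, !gA, drop = FALSE])
  tot <- sumA + sumB

  p <- vapply(seq_len(nrow(pseudo)), function(i) {
    t <- tot[i]
    if (t == 0) return(1)
    pr <- .cond_split_prob(t, nA, nB, phi)
    a <- sumA[i]
    if (two_sided == "smallp") {
      sum(pr[pr <= pr[a + 1] * (1 + 1e-12)])
    } else {
      lo <- sum(pr[seq_len(a + 1)])
      hi <- sum(pr[(a + 1):(t + 1)])
      min(1, 2 * min(lo, hi))
    }
  }, numeric(1))

  mA <- sumA / nA + prior_count
  mB <- sumB / nB + prior_count
  res <- data.frame(
    otu_id = rownames(table$counts),
    taxonomy = unname(table$taxonomy[rownames(table$counts)]),
    log2fc = log2(mA / mB),
    p_value = p,
    fdr = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  attr(res, "phi") <- phi
  attr(res, "factors") <- norm$factors
  attr(res, "comparison") <- sprintf("%s vs %s", levels(groups)[1], levels(groups)[2])
  class(res) <- c("exact_test_result", "data.frame")
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of raw p-values, returned in input order.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted p-values (FDR), same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
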