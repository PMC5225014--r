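# Analysis of similarities (ANOSIM) on a dissimilarity matrix.

# R statistic from the rank vector of the lower triangle and a grouping
.anosim_r <- function(rnk, same_group, n) {
  (mean(rnk[!same_group]) - mean(rnk[same_group])) / (n * (n - 1) / 4)
}

#' ANOSIM permutation test
#'
#' Clarke's analysis of similarities: all pairwise dissimilarities are
#' ranked (ties averaged) and
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
#' so `R` lies in \[-1, 1\], 0 indicating random grouping and 1 that every
#' between-group dissimilarity exceeds every within-group one.
#' Significance is assessed by permuting group labels; the p-value uses the
#' `(1 + #\{R_perm >= R_obs\}) / (1 + n_permutations)` estimator so it can
#' never be zero.  With `exact = TRUE` (2 groups only) the sampled
#' permutations are replaced by the full set of distinct label
#' assignments and the p-value is the exact proportion with
#' `R_perm >= R_obs` (the identity assignment included).
#'
#' @param dist symmetric dissimilarity matrix (or `dist`).
#' @param groups group label per sample; every group needs >= 2 members.
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional seed for the permutation stream.
#' @param exact enumerate all distinct assignments instead of sampling
#'   (2 groups only; intended for small n).
#' @return list of class `anosim_result`: `R`, `p_value`, `n_permutations`,
#'   `permuted_R`.
#' @export
anosim_test <- function(dist, groups, n_permutations = 999, seed = NULL,
                        exact = FALSE) {
  d <- as.matrix(dist)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stopf("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2) stopf("at least 2 groups required")
  if (any(tab < 2)) stopf("every group needs at least 2 members")

  lt <- lower.tri(d)
  rnk <- rank(d[lt])
  idx <- which(lt, arr.ind = TRUE)
  gi <- idx[, 1]; gj <- idx[, 2]
  robs <- .anosim_r(rnk, groups[gi] == groups[gj], n)

  if (exact) {
    if (length(tab) != 2) stopf("exact enumeration implemented for 2 groups only")
    lv <- names(tab)
    combos <- utils::combn(n, tab[[1]])
    rperm <- apply(combos, 2, function(ix) {
      g <- rep(lv[2], n); g[ix] <- lv[1]
      .anosim_r(rnk, g[gi] == g[gj], n)
    })
    p <- mean(rperm >= robs - 1e-12)
    nper <- ncol(combos)
  } else {
    if (!is.null(seed)) set.seed(seed)
    rperm <- vapply(seq_len(n_permutations), function(k) {
      g <- sample(groups)
      .anosim_r(rnk, g[gi] == g[gj], n)
    }, numeric(1))
    p <- (1 + sum(rperm >= robs - 1e-12)) / (1 + n_permutations)
    nper <- n_permutations
  }
  structure(list(R = robs, p_value = p, n_permutations = nper,
                 permuted_R = rperm),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$R, x$p_value, x$n_permutations))
  invisible(x)
}
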