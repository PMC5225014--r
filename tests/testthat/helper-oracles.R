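# Independent oracles used to validate the package's own implementations.
# These deliberately use naive enumeration / direct density evaluation,
# not the code paths they check.

# ANOSIM R by explicit loops over sample pairs
oracle_anosim_r <- function(d, groups) {
  n <- nrow(d)
  pairs <- which(lower.tri(d), arr.ind = TRUE)
  rnk <- rank(d[lower.tri(d)])
  rw <- rb <- c()
  for (k in seq_len(nrow(pairs))) {
    if (groups[pairs[k, 1]] == groups[pairs[k, 2]]) rw <- c(rw, rnk[k])
    else rb <- c(rb, rnk[k])
  }
  (mean(rb) - mean(rw)) / (n * (n - 1) / 4)
}

# full enumeration of all distinct two-group label assignments
oracle_anosim_exact <- function(d, groups) {
  n <- nrow(d)
  lv <- unique(groups)
  n1 <- sum(groups == lv[1])
  robs <- oracle_anosim_r(d, groups)
  combos <- combn(n, n1)
  rall <- apply(combos, 2, function(ix) {
    g <- rep(lv[2], n)
    g[ix] <- lv[1]
    oracle_anosim_r(d, g)
  })
  list(R = robs, p = mean(rall >= robs - 1e-12))
}

# two-sided exact NB split p-value by direct dnbinom evaluation: enumerate
# every split of the two-group total and sum the (normalized) NB
# probabilities no more probable than the observed split.  The mean is
# arbitrary (it cancels); mu = 10 is used for numerical comfort.
oracle_exact_p <- function(a, t, nA, nB, phi, mu = 10) {
  x <- 0:t
  pr <- if (phi <= 0) {
    dpois(x, nA * mu) * dpois(t - x, nB * mu)
  } else {
    dnbinom(x, size = nA / phi, mu = nA * mu) *
      dnbinom(t - x, size = nB / phi, mu = nB * mu)
  }
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[a + 1] * (1 + 1e-12)])
}

# random symmetric dissimilarity matrix with zero diagonal
random_dissim <- function(n) {
  d <- matrix(0, n, n)
  d[lower.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  d
}

# two-group toy matrix with a few informative features at a given shift
planted_matrix <- function(n = 20, p = 100, n_signal = 5, shift = 1.5) {
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  lab <- factor(rep(c("H", "D"), length.out = n), levels = c("H", "D"))
  X[, seq_len(n_signal)] <- X[, seq_len(n_signal)] +
    ifelse(lab == "H", shift, -shift)
  list(X = X, labels = lab)
}

# Gaussian mixture fingerprint trace on a uniform grid, nominal axis
gaussian_trace <- function(means, areas, sigma = 1.5,
                           grid = seq(40, 550, by = 0.25),
                           standards = c(60, 100, 490, 530)) {
  sig <- numeric(length(grid))
  for (i in seq_along(means)) sig <- sig + areas[i] * dnorm(grid, means[i], sigma)
  fingerprint_profile("toy", grid, sig,
                      data.frame(observed = standards, nominal = standards))
}
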