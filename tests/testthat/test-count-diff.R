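test_that("OTU filtering applies the strict total and variance rules", {
  cnt <- rbind(OTU1 = c(1, 0, 0, 0), OTU2 = c(1, 1, 0, 0), OTU3 = c(1, 1, 1, 0),
               OTU4 = c(2, 1, 1, 0), OTU5 = c(2, 2, 1, 0))
  colnames(cnt) <- paste0("s", 1:4)
  tab <- otu_count_table(cnt)
  kept <- filter_otus(tab, min_total = 3, min_variance = 0)
  expect_equal(rownames(kept$counts), c("OTU4", "OTU5"))  # totals > 3 only

  # a constant-count OTU has zero variance and is removed
  cnt2 <- rbind(OTUc = c(5, 5, 5, 5), OTUv = c(1, 9, 2, 8))
  colnames(cnt2) <- paste0("s", 1:4)
  kept2 <- filter_otus(otu_count_table(cnt2), min_total = 0, variance_on = "counts")
  expect_equal(rownames(kept2$counts), "OTUv")

  # permissive thresholds leave a well-behaved table untouched
  set.seed(1)
  cnt3 <- matrix(rpois(40, 20), 10, 4,
                 dimnames = list(paste0("o", 1:10), paste0("s", 1:4)))
  kept3 <- filter_otus(otu_count_table(cnt3), min_total = 0, min_variance = 0)
  expect_identical(kept3$counts, cnt3)

  expect_error(filter_otus(otu_count_table(cnt), min_total = 100), "removed")
})

test_that("median-of-ratios scaling factors behave as constructed", {
  set.seed(2)
  base <- matrix(rpois(200, 50) + 1, 50, 4,
                 dimnames = list(paste0("o", 1:50), paste0("s", 1:4)))
  # identical samples -> all factors 1
  same <- otu_count_table(cbind(s1 = base[, 1], s2 = base[, 1], s3 = base[, 1]))
  expect_equal(unname(scaling_normalize(same)$factors), rep(1, 3), tolerance = 1e-9)

  # doubling one sample cell-wise doubles its factor relative to the others
  doubled <- base; doubled[, 4] <- base[, 1] * 2; doubled[, 3] <- base[, 1]
  f <- scaling_normalize(otu_count_table(doubled))$factors
  expect_equal(unname(f["s4"] / f["s3"]), 2, tolerance = 1e-9)

  # geometric mean of factors is 1 on any input
  set.seed(3)
  for (k in 1:5) {
    cnt <- matrix(rnbinom(120, size = 2, mu = 30) + (k %% 2), 30, 4,
                  dimnames = list(paste0("o", 1:30), paste0("s", 1:4)))
    cnt[1, ] <- cnt[1, ] + 1  # keep every sample nonzero
    fk <- suppressWarnings(scaling_normalize(otu_count_table(cnt))$factors)
    expect_equal(exp(mean(log(fk))), 1, tolerance = 1e-9)
  }

  # no OTU shared by all samples -> total-count fallback with a warning
  sparse <- rbind(o1 = c(5, 0), o2 = c(0, 7))
  colnames(sparse) <- c("s1", "s2")
  expect_warning(scaling_normalize(otu_count_table(sparse)), "fallback|total-count")
})

test_that("common dispersion is recovered from simulated counts", {
  set.seed(4)
  grp <- rep(c("A", "B"), each = 10)
  meta <- data.frame(sample = paste0("s", 1:20), group = grp)
  # Poisson data: phi-hat near 0
  pois <- matrix(rpois(200 * 20, 40), 200, 20,
                 dimnames = list(paste0("o", 1:200), meta$sample))
  expect_lt(estimate_common_dispersion(otu_count_table(pois, sample_meta = meta)), 0.05)
  # phi = 0.3 recovered within [0.2, 0.4] on 500 OTUs
  nb <- matrix(rnbinom(500 * 20, size = 1 / 0.3, mu = 40), 500, 20,
               dimnames = list(paste0("o", 1:500), meta$sample))
  phi <- estimate_common_dispersion(otu_count_table(nb, sample_meta = meta))
  expect_gte(phi, 0.2); expect_lte(phi, 0.4)

  one <- otu_count_table(matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
                         sample_meta = data.frame(sample = c("s1", "s2"),
                                                  group = c("A", "B")))
  expect_error(estimate_common_dispersion(one), "single sample")
})

test_that("the exact test matches brute-force NB split enumeration", {
  # direct check of the conditional split distribution across totals,
  # group sizes and dispersions (sums <= 50)
  cases <- expand.grid(t = c(1, 5, 17, 50), nA = c(1, 3, 10), nB = c(1, 5, 10),
                       phi = c(0, 0.2, 1.5))
  for (i in seq_len(nrow(cases))) {
    t <- cases$t[i]
    pr <- pwdmicro:::.cond_split_prob(t, cases$nA[i], cases$nB[i], cases$phi[i])
    for (a in unique(c(0, floor(t / 2), t))) {
      mine <- sum(pr[pr <= pr[a + 1] * (1 + 1e-12)])
      orac <- oracle_exact_p(a, t, cases$nA[i], cases$nB[i], cases$phi[i])
      expect_lt(abs(mine - orac), 1e-10)
    }
  }
})

test_that("exact-test landmarks and symmetry hold on toy tables", {
  # a perfectly balanced split of equal totals is the modal outcome: p = 1
  cnt <- rbind(o1 = c(5, 5), o2 = c(8, 8))
  colnames(cnt) <- c("s1", "s2")
  tab <- otu_count_table(cnt)
  res <- exact_test(tab, factor(c("A", "B")), phi = 0)
  expect_equal(res$p_value, c(1, 1), tolerance = 1e-12)

  # split (0 | 10), one sample per side, equal library sizes, phi = 0:
  # p = 2/2^10
  cnt2 <- rbind(o1 = c(0, 10), o2 = c(10, 0), o3 = c(20, 20))
  colnames(cnt2) <- c("s1", "s2")
  res2 <- exact_test(otu_count_table(cnt2), factor(c("A", "B")), phi = 0)
  expect_equal(res2$p_value[1], 2 / 1024, tolerance = 1e-12)

  # swapping group labels negates log2FC and leaves p unchanged
  set.seed(5)
  cnt3 <- matrix(rnbinom(60 * 8, size = 5, mu = 30), 60, 8,
                 dimnames = list(paste0("o", 1:60), paste0("s", 1:8)))
  g <- factor(rep(c("A", "B"), each = 4), levels = c("A", "B"))
  r1 <- exact_test(otu_count_table(cnt3), g, phi = 0.1)
  r2 <- exact_test(otu_count_table(cnt3), relevel(g, "B"), phi = 0.1)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)

  expect_error(exact_test(tab, factor(c("A", "B", "C")[c(1, 2)]), phi = -1), "phi")
})

test_that("p-values agree with edgeR's small-p exact test", {
  skip_if_not_installed("edgeR")
  set.seed(6)
  cnt <- matrix(rnbinom(200 * 10, size = 5, mu = 50), 200, 10,
                dimnames = list(paste0("o", 1:200), paste0("s", 1:10)))
  grp <- rep(c("A", "B"), each = 5)
  mine <- exact_test(otu_count_table(cnt), factor(grp), phi = 0.2)
  d <- edgeR::DGEList(counts = cnt, group = grp)
  d$samples$norm.factors <- rep(1, 10)
  et <- edgeR::exactTest(d, dispersion = 0.2, rejection.region = "smallp")
  # library-size equalization differs slightly; concordance must be tight
  expect_gt(cor(mine$p_value, et$table$PValue), 0.999)
  expect_lt(max(abs(mine$p_value - et$table$PValue)), 0.05)

  # Poisson limit, equal single libraries: exact agreement with binomTest
  y1 <- rnbinom(50, size = 100, mu = 40); y2 <- rnbinom(50, size = 100, mu = 40)
  cnt2 <- cbind(s1 = y1, s2 = y2)
  rownames(cnt2) <- paste0("o", 1:50)
  # equalize the two libraries exactly so no pseudo-count rounding occurs
  cnt2[1, ] <- cnt2[1, ] + max(colSums(cnt2)) - colSums(cnt2)
  minep <- exact_test(otu_count_table(cnt2), factor(c("A", "B")), phi = 0)
  bt <- edgeR::binomTest(cnt2[, 1], cnt2[, 2])
  expect_equal(minep$p_value, bt, tolerance = 1e-9)
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-15)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})
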