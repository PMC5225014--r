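test_that("keep-all sPLS-DA equals the dominant singular direction of X'Y", {
  set.seed(20)
  pm <- planted_matrix(n = 20, p = 30, n_signal = 3, shift = 1)
  m <- splsda_fit(pm$X, pm$labels, ncomp = 1, keepX = 30)
  # independent oracle: direct SVD of the scaled cross-product
  Xs <- scale(pm$X)
  Ys <- scale(model.matrix(~ 0 + pm$labels))
  u <- svd(crossprod(Xs, Ys))$u[, 1]
  u <- u * sign(u[which.max(abs(u))])
  expect_lt(max(abs(m$loadings_X[, 1] - u)), 1e-8)
})

test_that("sparsity, orthogonality and unit norm hold by construction", {
  set.seed(21)
  pm <- planted_matrix(n = 20, p = 50)
  for (keep in c(3, 10, 25)) {
    m <- splsda_fit(pm$X, pm$labels, ncomp = 3, keepX = keep)
    expect_equal(colSums(m$loadings_X != 0), rep(keep, 3), ignore_attr = TRUE)
    expect_equal(unname(colSums(m$loadings_X^2)), rep(1, 3), tolerance = 1e-9)
    cc <- crossprod(m$scores)
    off <- cc / sqrt(outer(diag(cc), diag(cc)))
    expect_lt(max(abs(off[upper.tri(off)])), 1e-6)
  }
  expect_error(splsda_fit(pm$X, rep("H", 20)), "two-class")
  expect_error(splsda_fit(pm$X, pm$labels, keepX = 0), "positive")
  expect_error(splsda_fit(pm$X, pm$labels, keepX = 99), "exceeds")
})

test_that("a perfectly separating feature is selected and classified", {
  set.seed(22)
  X <- matrix(rnorm(20 * 40), 20, 40, dimnames = list(NULL, paste0("f", 1:40)))
  lab <- factor(rep(c("H", "D"), each = 10), levels = c("H", "D"))
  X[, 7] <- ifelse(lab == "H", 4, -4) + rnorm(20, 0, 0.2)
  m <- splsda_fit(X, lab, ncomp = 1, keepX = 1)
  expect_equal(unname(which(m$loadings_X[, 1] != 0)), 7)
  pred <- splsda_predict(m, X)
  expect_equal(mean(pred$class != lab), 0)
  # max-distance rule agrees on clearly separated data
  expect_equal(splsda_predict(m, X, method = "max")$class, pred$class)
})

test_that("fitting is invariant to sample duplication and feature order", {
  set.seed(23)
  pm <- planted_matrix(n = 16, p = 25)
  m1 <- splsda_fit(pm$X, pm$labels, ncomp = 2, keepX = 8)
  m2 <- splsda_fit(rbind(pm$X, pm$X), rep(pm$labels, 2), ncomp = 2, keepX = 8)
  expect_equal(m1$loadings_X, m2$loadings_X, tolerance = 1e-6)

  # permuting feature columns (named) leaves predictions unchanged
  perm <- sample(ncol(pm$X))
  p1 <- splsda_predict(m1, pm$X)
  p2 <- splsda_predict(m1, pm$X[, perm])
  expect_identical(p1$class, p2$class)
  expect_error(splsda_predict(m1, pm$X[, 1:10]), "missing features")
})

test_that("a sample at the exact centroid midpoint ties to the first class", {
  set.seed(24)
  X <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("f", 1:5)))
  lab <- factor(rep(c("H", "D"), each = 6), levels = c("H", "D"))
  X[, 1] <- ifelse(lab == "H", 2, -2)
  m <- splsda_fit(X, lab, ncomp = 1, keepX = 5)
  # build the feature vector whose score lands midway between centroids
  mid_score <- mean(m$centroids[, 1])
  x0 <- m$center_X + m$scale_X * (m$loadings_X[, 1] * mid_score /
                                    sum(m$loadings_X[, 1]^2))
  pred <- splsda_predict(m, matrix(x0, 1, dimnames = list(NULL, names(x0))))
  expect_equal(as.character(pred$class), "H")  # first level wins ties
})

test_that("loadings and selected sets match mixOmics", {
  skip_if_not_installed("mixOmics")
  set.seed(25)
  pm <- planted_matrix(n = 20, p = 30, n_signal = 3, shift = 1.5)
  m <- splsda_fit(pm$X, pm$labels, ncomp = 2, keepX = 5)
  mo <- mixOmics::splsda(pm$X, pm$labels, ncomp = 2, keepX = c(5, 5), scale = TRUE)
  for (h in 1:2) {
    expect_setequal(unname(which(m$loadings_X[, h] != 0)),
                    unname(which(mo$loadings$X[, h] != 0)))
    expect_gt(abs(cor(m$loadings_X[, h], mo$loadings$X[, h])), 0.999)
  }
})

test_that("two-block sparse PLS recovers planted relationships", {
  set.seed(26)
  X <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("x", 1:10)))
  # self-regression of a block on itself: scores coincide exactly
  m <- spls_fit(X[, 1, drop = FALSE], X[, 1, drop = FALSE], ncomp = 1)
  expect_equal(abs(cor(m$scores[, 1], m$scores_Y[, 1])), 1, tolerance = 1e-9)

  # independent noise responses: score correlation (inflated by the
  # covariance-maximizing projection at this n) stays well below the
  # deterministic-coupling value of 1
  r0 <- vapply(1:50, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(20 * 10), 20, 10)
    Yn <- matrix(rnorm(20 * 3), 20, 3)
    abs(cor(spls_fit(Xn, Yn, ncomp = 1)$scores[, 1],
            spls_fit(Xn, Yn, ncomp = 1)$scores_Y[, 1]))
  }, numeric(1))
  expect_lt(mean(r0), 0.85)

  # keepX = 1 with a single driving column selects that column
  y <- X[, 4] * 2 + rnorm(30, 0, 0.1)
  m1 <- spls_fit(X, matrix(y), ncomp = 1, keepX = 1)
  expect_equal(unname(which(m1$loadings_X[, 1] != 0)), 4)
  expect_error(spls_fit(X, matrix(y[1:10])), "share samples")
})

test_that("relevance networks threshold signed bilinear similarities", {
  set.seed(27)
  x <- rnorm(30)
  X <- cbind(a = x, b = rnorm(30))
  Y <- cbind(up = 2 * x + rnorm(30, 0, 0.05), down = -x + rnorm(30, 0, 0.05))
  net <- relevance_network(spls_fit(X, Y, ncomp = 2), threshold = 0.5)
  e_up <- net$edges[net$edges$source == "a" & net$edges$target == "up", ]
  e_dn <- net$edges[net$edges$source == "a" & net$edges$target == "down", ]
  expect_equal(e_up$sign, "positive")
  expect_gt(e_up$similarity, 0.9)
  expect_equal(e_dn$sign, "negative")
  expect_lt(e_dn$similarity, -0.9)

  # independent blocks whose similarities all sit below the threshold
  # yield an empty network
  set.seed(127)
  Xn <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, letters[1:4]))
  Yn <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, LETTERS[1:3]))
  none <- relevance_network(spls_fit(Xn, Yn, ncomp = 2), threshold = 0.5)
  expect_true(all(abs(none$similarity) < 0.5))
  expect_equal(nrow(none$edges), 0)
  expect_error(relevance_network(spls_fit(X, Y), threshold = 1.2), "threshold")
})

test_that("full-rank keep-all similarity reproduces Pearson cross-correlation", {
  set.seed(28)
  X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("x", 1:5)))
  Y <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("y", 1:3)))
  Y[, 1] <- X[, 2] + rnorm(30, 0, 0.5)
  m <- spls_fit(X, Y, ncomp = 5, mode = "regression")
  S <- relevance_network(m, threshold = 0)$similarity
  expect_lt(max(abs(S - cor(X, Y))), 0.05)
})

test_that("association matrices expose cross-block structure", {
  set.seed(29)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("otu", 1:6)))
  Y <- cbind(pwA = X[, 3], pwB = rnorm(40))  # pathway duplicating an OTU
  A <- association_matrix(X, Y)
  expect_equal(dim(A), c(6, 2))
  expect_gt(abs(A["otu3", "pwA"]), 0.9)

  # independent blocks concentrate near zero, far below the planted pair
  vals <- unlist(lapply(1:50, function(s) {
    set.seed(200 + s)
    association_matrix(matrix(rnorm(20 * 8), 20, 8), matrix(rnorm(20 * 4), 20, 4))
  }))
  expect_lt(median(abs(vals)), 0.35)
  expect_gt(mean(abs(vals) < 0.5), 0.75)
  expect_error(association_matrix(X[1:2, ], Y[1:2, ]), "3 samples")
})

test_that("selection frequencies under pure noise concentrate near keepX/p", {
  fr <- vapply(1:100, function(s) {
    set.seed(300 + s)
    X <- matrix(rnorm(20 * 50), 20, 50)
    lab <- factor(rep(c("H", "D"), each = 10))
    mean(cv_splsda(X, lab, ncomp = 1, keepX = 10, n_folds = 5,
                   n_repeats = 1, seed = s)$frequency)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 10 / 50), 0.05)
})

test_that("two-stage tuning keeps only features stable across all folds", {
  set.seed(30)
  pm <- planted_matrix(n = 20, p = 60, n_signal = 4, shift = 2)
  ts <- tune_and_stability(pm$X, pm$labels, ncomp_grid = 1:2,
                           keepX_grid = c(4, 8), n_folds = 5, n_repeats = 3,
                           seed = 7)
  expect_true(all(apply(ts$selection_frequency[ts$stable_set, , drop = FALSE],
                        1, max) == 1))
  expect_true(all(ts$selection_frequency >= 0 & ts$selection_frequency <= 1))
  # the strongly shifted features dominate the stable set
  expect_true(all(paste0("f", 1:4) %in% ts$stable_set))
  expect_lte(ts$second_stage_error, ts$first_stage_error + 1e-12)
  expect_s3_class(ts$final_model, "splsda_model")
})
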