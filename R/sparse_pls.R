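# Sparse PLS and sparse PLS-DA with lasso-style loading sparsification,
# two-stage cross-validated stability selection, relevance networks and
# cross-block association matrices.

# center/scale with unit-variance guard
.scale_block <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < .Machine$double.eps] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

# lasso-surrogate soft threshold: keep the `keep` largest |w| (ties broken
# by feature order), shrink them by the largest excluded magnitude, zero
# the rest; a tied survivor is kept at a vanishing magnitude so exactly
# `keep` loadings stay nonzero
.soft_keep <- function(w, keep) {
  p <- length(w)
  if (keep >= p) return(w)
  aw <- abs(w)
  ord <- order(-aw)
  kept <- ord[seq_len(keep)]
  lambda <- aw[ord[keep + 1L]]
  out <- numeric(p)
  shr <- aw[kept] - lambda
  shr[shr <= 0] <- lambda * 1e-9 + .Machine$double.xmin
  out[kept] <- sign(w[kept]) * shr
  out
}

.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps) stopf("degenerate loading (zero norm)")
  v / nv
}

# core sparse-PLS iteration over ncomp components
.spls_core <- function(Xs, Ys, ncomp, keepX, keepY, mode, tol = 1e-9,
                       max_iter = 500) {
  n <- nrow(Xs); p <- ncol(Xs); q <- ncol(Ys)
  Xc <- Xs; Yc <- Ys
  U <- matrix(0, p, ncomp); V <- matrix(0, q, ncomp)
  Ti <- matrix(0, n, ncomp); Om <- matrix(0, n, ncomp)
  Cp <- matrix(0, p, ncomp); Dp <- matrix(0, q, ncomp)
  h_used <- 0L
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xc, Yc)
    sv <- svd(M, nu = 1, nv = 1)
    if (sv$d[1] < 1e-10) break  # cross-covariance exhausted: truncate
    u <- sv$u[, 1]; v <- sv$v[, 1]
    for (it in seq_len(max_iter)) {
      u_new <- .unit(.soft_keep(as.numeric(M %*% v), keepX[h]))
      v_new <- .unit(.soft_keep(as.numeric(crossprod(M, u_new)), keepY[h]))
      delta <- max(abs(u_new - u), abs(v_new - v))
      u <- u_new; v <- v_new
      if (delta < tol) break
    }
    # deterministic sign: largest-|loading| X entry positive
    s <- sign(u[which.max(abs(u))])
    if (s < 0) { u <- -u; v <- -v }
    xi <- as.numeric(Xc %*% u)
    om <- as.numeric(Yc %*% v)
    cc <- as.numeric(crossprod(Xc, xi)) / sum(xi^2)
    Xc <- Xc - tcrossprod(xi, cc)
    if (mode == "regression") {
      dd <- as.numeric(crossprod(Yc, xi)) / sum(xi^2)
      Yc <- Yc - tcrossprod(xi, dd)
    } else {
      dd <- as.numeric(crossprod(Yc, om)) / sum(om^2)
      Yc <- Yc - tcrossprod(om, dd)
    }
    U[, h] <- u; V[, h] <- v; Ti[, h] <- xi; Om[, h] <- om
    Cp[, h] <- cc; Dp[, h] <- dd
    h_used <- h
  }
  if (h_used < ncomp) {
    keep <- seq_len(max(h_used, 1L))
    U <- U[, keep, drop = FALSE]; V <- V[, keep, drop = FALSE]
    Ti <- Ti[, keep, drop = FALSE]; Om <- Om[, keep, drop = FALSE]
    Cp <- Cp[, keep, drop = FALSE]; Dp <- Dp[, keep, drop = FALSE]
    ncomp <- length(keep)
  }
  dimnames(U) <- list(colnames(Xs), paste0("comp", seq_len(ncomp)))
  dimnames(V) <- list(colnames(Ys), colnames(U))
  dimnames(Ti) <- list(rownames(Xs), colnames(U))
  list(loadings_X = U, loadings_Y = V, scores = Ti, scores_Y = Om,
       proj_X = Cp, proj_Y = Dp)
}

#' Fit a sparse PLS model between two blocks
#'
#' Per component, the dominant singular pair of the cross-product of the
#' (centred, unit-variance) blocks is sparsified by soft thresholding so
#' exactly `keepX` (`keepY`) loadings stay nonzero, and the blocks are
#' deflated: in `regression` mode Y is deflated by the X-scores, in
#' `canonical` mode each block by its own scores.
#'
#' @param X sample x feature matrix.
#' @param Y sample x response matrix (same rows as X).
#' @param ncomp number of components.
#' @param keepX,keepY number of nonzero loadings per component (scalar or
#'   length-`ncomp`; default all).
#' @param mode `"regression"` or `"canonical"`.
#' @return list of class `spls_model`.
#' @export
spls_fit <- function(X, Y, ncomp = 2, keepX = NULL, keepY = NULL,
                     mode = c("regression", "canonical")) {
  mode <- match.arg(mode)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y must share samples (rows)")
  if (nrow(X) < 3) stopf("at least 3 samples required")
  keepX <- rep(if (is.null(keepX)) ncol(X) else keepX, length.out = ncomp)
  keepY <- rep(if (is.null(keepY)) ncol(Y) else keepY, length.out = ncomp)
  if (any(keepX <= 0) || any(keepY <= 0)) stopf("keepX/keepY must be positive")
  if (any(keepX > ncol(X))) stopf("keepX exceeds number of X features")
  sx <- .scale_block(X); sy <- .scale_block(Y)
  core <- .spls_core(sx$X, sy$X, ncomp, keepX, keepY, mode)
  ncomp <- ncol(core$scores)
  keepX <- keepX[seq_len(ncomp)]; keepY <- keepY[seq_len(ncomp)]
  structure(c(core, list(mode = mode, ncomp = ncomp, keepX = keepX,
                         keepY = keepY, Xs = sx$X, Ys = sy$X,
                         center_X = sx$center, scale_X = sx$scale,
                         center_Y = sy$center, scale_Y = sy$scale)),
            class = "spls_model")
}

#' Fit a sparse PLS-DA model
#'
#' Sparse PLS in regression mode onto the (centred, scaled) group
#' indicator matrix.  Exactly `keepX` features carry nonzero loadings per
#' component; successive score columns are mutually orthogonal.  Class
#' centroids in score space are stored for prediction.
#'
#' @param X sample x feature matrix.
#' @param labels two-level grouping over samples.
#' @param ncomp number of components.
#' @param keepX nonzero loadings per component (scalar or length-`ncomp`;
#'   default all features).
#' @return list of class `splsda_model`.
#' @export
splsda_fit <- function(X, labels, ncomp = 2, keepX = NULL) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stopf("two-class labels required")
  if (any(table(labels) == 0)) stopf("one class absent")
  if (nrow(X) < 4) stopf("at least 4 samples required")
  keepX <- rep(if (is.null(keepX)) ncol(X) else keepX, length.out = ncomp)
  if (any(keepX <= 0)) stopf("keepX must be positive")
  if (any(keepX > ncol(X))) stopf("keepX exceeds number of features")

  Y <- model.matrix(~ 0 + labels)
  colnames(Y) <- levels(labels)
  sx <- .scale_block(X); sy <- .scale_block(Y)
  core <- .spls_core(sx$X, sy$X, ncomp, keepX, rep(ncol(Y), ncomp), "regression")
  ncomp <- ncol(core$scores)
  keepX <- keepX[seq_len(ncomp)]
  centroids <- apply(core$scores, 2, function(t) tapply(t, labels, mean))
  centroids <- matrix(centroids, nrow = nlevels(labels),
                      dimnames = list(levels(labels), colnames(core$scores)))
  structure(c(core, list(ncomp = ncomp, keepX = keepX, labels = labels,
                         levels = levels(labels), centroids = centroids,
                         Xs = sx$X, Ys = sy$X,
                         center_X = sx$center, scale_X = sx$scale,
                         center_Y = sy$center, scale_Y = sy$scale,
                         mode = "regression")),
            class = c("splsda_model", "spls_model"))
}

#' Predict classes with a sparse PLS-DA model
#'
#' New samples are scaled with the training centre/scale, projected
#' component-wise (with the training deflation), and assigned to the
#' nearest class centroid in score space (Euclidean); ties resolve
#' deterministically to the first class level.  `method = "max"` instead
#' assigns the class with the largest predicted indicator value.
#'
#' @param model an `splsda_model`.
#' @param X_new sample x feature matrix; if it has column names, all model
#'   features must be present (any order).
#' @param method `"centroid"` (default) or `"max"`.
#' @return list: `class` (factor), `scores` (sample x component).
#' @export
splsda_predict <- function(model, X_new, method = c("centroid", "max")) {
  method <- match.arg(method)
  X_new <- as.matrix(X_new)
  feats <- names(model$center_X)
  if (!is.null(colnames(X_new)) && !is.null(feats)) {
    missing <- setdiff(feats, colnames(X_new))
    if (length(missing))
      stopf("missing features: %s", paste(missing, collapse = ", "))
    X_new <- X_new[, feats, drop = FALSE]
  } else if (ncol(X_new) != length(model$center_X)) {
    stopf("feature count mismatch: model has %d, input %d",
          length(model$center_X), ncol(X_new))
  }
  Xc <- sweep(sweep(X_new, 2, model$center_X), 2, model$scale_X, "/")
  n <- nrow(Xc)
  scores <- matrix(0, n, model$ncomp,
                   dimnames = list(rownames(X_new), colnames(model$scores)))
  for (h in seq_len(model$ncomp)) {
    t_h <- as.numeric(Xc %*% model$loadings_X[, h])
    scores[, h] <- t_h
    Xc <- Xc - tcrossprod(t_h, model$proj_X[, h])
  }
  if (method == "centroid") {
    d2 <- outer(rowSums(scores^2), rowSums(model$centroids^2), "+") -
      2 * tcrossprod(scores, model$centroids)
    cls <- model$levels[max.col(-d2, ties.method = "first")]
  } else {
    Yp <- tcrossprod(scores, model$proj_Y[, seq_len(model$ncomp), drop = FALSE])
    Yp <- sweep(sweep(Yp, 2, model$scale_Y, "*"), 2, model$center_Y, "+")
    cls <- model$levels[max.col(Yp, ties.method = "first")]
  }
  list(class = factor(cls, levels = model$levels), scores = scores)
}

# stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into folds
.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  fold
}

#' Cross-validated error and selection frequencies for one configuration
#'
#' Stratified `n_folds`-fold cross-validation repeated `n_repeats` times:
#' each held-out fold is predicted from a model fitted on the remainder;
#' the mean misclassification fraction and, per (feature, component), the
#' fraction of fits in which the feature carried a nonzero loading are
#' returned.
#'
#' @param X sample x feature matrix.
#' @param labels two-level grouping.
#' @param ncomp,keepX sPLS-DA configuration.
#' @param n_folds folds (reduced with a warning if a class is smaller).
#' @param n_repeats repeats.
#' @param seed seed for the fold stream.
#' @return list: `error` (mean CV error), `frequency` (feature x component
#'   selection frequencies), `n_fits`.
#' @export
cv_splsda <- function(X, labels, ncomp, keepX, n_folds = 5, n_repeats = 10,
                      seed = NULL) {
  X <- as.matrix(X)
  labels <- factor(labels)
  minc <- min(table(labels))
  if (minc < n_folds) {
    warning(sprintf("smallest class (%d) < folds (%d); folds reduced", minc, n_folds))
    n_folds <- max(2L, minc)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(X)
  sel <- matrix(0, p, ncomp, dimnames = list(colnames(X), paste0("comp", seq_len(ncomp))))
  err <- 0; nfit <- 0L
  for (r in seq_len(n_repeats)) {
    fold <- .stratified_folds(labels, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- splsda_fit(X[tr, , drop = FALSE], labels[tr], ncomp = ncomp,
                        keepX = pmin(keepX, p))
      pred <- splsda_predict(fit, X[!tr, , drop = FALSE])
      err <- err + mean(pred$class != labels[!tr])
      lx <- fit$loadings_X != 0
      if (ncol(lx) < ncomp)  # component truncated on a degenerate fold
        lx <- cbind(lx, matrix(FALSE, p, ncomp - ncol(lx)))
      sel <- sel + lx
      nfit <- nfit + 1L
    }
  }
  list(error = err / nfit, frequency = sel / nfit, n_fits = nfit)
}

#' Two-stage tuned and stability-selected sparse PLS-DA
#'
#' Stage 1 grid-searches (`ncomp`, `keepX`) by stratified repeated
#' cross-validation, minimizing mean classification error (ties resolved
#' toward fewer components, then fewer kept features), and records each
#' feature's selection frequency across all folds and repeats of the
#' winning configuration.  The stable set keeps the features selected in
#' every fit (frequency = 1, on any component).  Stage 2 refits restricted
#' to the stable set, re-tuning `keepX` on it, and re-estimates the CV
#' error.  If the stable set is empty, features at or above the
#' `fallback_quantile` of the frequency distribution are used instead
#' (with a warning).
#'
#' @param X sample x feature matrix.
#' @param labels two-level grouping.
#' @param ncomp_grid candidate component counts.
#' @param keepX_grid candidate per-component keepX values (values above
#'   the feature count are dropped).
#' @param n_folds,n_repeats cross-validation design.
#' @param seed seed for all fold streams.
#' @param fallback_quantile frequency quantile used when no feature
#'   reaches frequency 1.
#' @return list of class `stability_report`: `selection_frequency`,
#'   `stable_set`, `first_stage_error`, `second_stage_error`,
#'   `stage1_config`, `stage2_config`, `final_model`.
#' @export
tune_and_stability <- function(X, labels, ncomp_grid = 1:3,
                               keepX_grid = seq(5, 50, by = 5),
                               n_folds = 5, n_repeats = 10, seed = 1,
                               fallback_quantile = 0.99) {
  X <- as.matrix(X)
  labels <- factor(labels)
  keepX_grid <- unique(pmin(keepX_grid, ncol(X)))

  grid <- expand.grid(ncomp = ncomp_grid, keepX = keepX_grid,
                      KEEP.OUT.ATTRS = FALSE)
  errs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    errs[i] <- cv_splsda(X, labels, grid$ncomp[i], grid$keepX[i],
                         n_folds, n_repeats,
                         seed = stream_seed(seed, sprintf("cv%d", i)))$error
  }
  ord <- order(errs, grid$ncomp, grid$keepX)
  best <- grid[ord[1], ]
  stage1 <- cv_splsda(X, labels, best$ncomp, best$keepX, n_folds, n_repeats,
                      seed = stream_seed(seed, "stage1"))

  freq <- stage1$frequency
  stable <- rownames(freq)[apply(freq, 1, max) >= 1 - 1e-12]
  if (length(stable) == 0) {
    warning("no feature reached stability 1; falling back to the frequency quantile")
    thr <- quantile(apply(freq, 1, max), fallback_quantile)
    stable <- rownames(freq)[apply(freq, 1, max) >= thr]
  }

  X2 <- X[, stable, drop = FALSE]
  keep2 <- unique(pmin(keepX_grid, ncol(X2)))
  ncomp2 <- unique(pmin(ncomp_grid, ncol(X2)))
  grid2 <- expand.grid(ncomp = ncomp2, keepX = keep2, KEEP.OUT.ATTRS = FALSE)
  errs2 <- numeric(nrow(grid2))
  for (i in seq_len(nrow(grid2))) {
    errs2[i] <- cv_splsda(X2, labels, grid2$ncomp[i], grid2$keepX[i],
                          n_folds, n_repeats,
                          seed = stream_seed(seed, sprintf("cv2_%d", i)))$error
  }
  ord2 <- order(errs2, grid2$ncomp, grid2$keepX)
  best2 <- grid2[ord2[1], ]
  final <- splsda_fit(X2, labels, ncomp = best2$ncomp, keepX = best2$keepX)

  structure(list(selection_frequency = freq, stable_set = stable,
                 first_stage_error = min(errs),
                 second_stage_error = min(errs2),
                 stage1_config = as.list(best), stage2_config = as.list(best2),
                 final_model = final),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("Two-stage sPLS-DA: stage 1 error %.3f (ncomp %d, keepX %d); ",
                     "%d stable features; stage 2 error %.3f (ncomp %d, keepX %d)\n"),
              x$first_stage_error, x$stage1_config$ncomp, x$stage1_config$keepX,
              length(x$stable_set),
              x$second_stage_error, x$stage2_config$ncomp, x$stage2_config$keepX))
  invisible(x)
}

# bilinear cross-block similarity: regression mode projects both blocks on
# the X-scores (which reconstructs the Pearson cross-correlation matrix at
# full rank); canonical mode uses each block's own scores
.spls_similarity <- function(model) {
  cx <- cor(model$Xs, model$scores)
  cy <- if (model$mode == "regression") cor(model$Ys, model$scores)
        else cor(model$Ys, model$scores_Y)
  tcrossprod(cx, cy)
}

#' Relevance network from a sparse PLS model
#'
#' Edges connect cross-block feature pairs whose bilinear similarity
#' (sum over components of the products of feature-score correlations)
#' exceeds the threshold in magnitude, signed by the similarity.
#'
#' @param model an `spls_model` (or `splsda_model`).
#' @param threshold magnitude threshold in \[0, 1).
#' @return list of class `relevance_network`: `edges` (source, target,
#'   similarity, sign), `similarity` matrix, `threshold`.
#' @export
relevance_network <- function(model, threshold = 0.5) {
  stopifnot(inherits(model, "spls_model"))
  if (threshold < 0 || threshold >= 1) stopf("threshold must lie in [0, 1)")
  S <- .spls_similarity(model)
  idx <- which(abs(S) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    source = rownames(S)[idx[, 1]],
    target = colnames(S)[idx[, 2]],
    similarity = S[idx],
    sign = ifelse(S[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  edges <- edges[order(-abs(edges$similarity)), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, similarity = S, threshold = threshold),
            class = "relevance_network")
}

#' @export
print.relevance_network <- function(x, ...) {
  cat(sprintf("Relevance network: %d edges at |similarity| > %.2f\n",
              nrow(x$edges), x$threshold))
  invisible(x)
}

#' Write a relevance network as edge-list TSV / GraphML
#' @param network a `relevance_network`.
#' @param path output file.
#' @export
write_network_edges <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
write_network_graphml <- function(network, path) {
  e <- network$edges
  nodes <- unique(c(e$source, e$target))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="w" for="edge" attr.name="similarity" attr.type="double"/>',
    '<graph edgedefault="undirected">'), con)
  for (nd in nodes) writeLines(sprintf('<node id="%s"/>', nd), con)
  for (i in seq_len(nrow(e)))
    writeLines(sprintf('<edge source="%s" target="%s"><data key="w">%.6f</data></edge>',
                       e$source[i], e$target[i], e$similarity[i]), con)
  writeLines(c('</graph>', '</graphml>'), con)
  invisible(path)
}

#' Cross-block association matrix (for heatmap rendering)
#'
#' Bilinear similarity between OTU features and pathway-like responses
#' from a canonical-mode sparse PLS of the two blocks, with rows and
#' columns ordered by hierarchical clustering.  `method = "pearson"`
#' returns the plain pairwise Pearson cross-correlation instead.
#'
#' @param X_otus sample x OTU matrix.
#' @param Y_pathways sample x pathway matrix (same samples).
#' @param ncomp components for the canonical sPLS.
#' @param method `"spls"` (default) or `"pearson"`.
#' @return similarity matrix (#OTUs x #pathways), clustered ordering.
#' @export
association_matrix <- function(X_otus, Y_pathways, ncomp = 2,
                               method = c("spls", "pearson")) {
  method <- match.arg(method)
  X_otus <- as.matrix(X_otus); Y_pathways <- as.matrix(Y_pathways)
  if (nrow(X_otus) != nrow(Y_pathways)) stopf("blocks must share samples")
  if (nrow(X_otus) < 3) stopf("at least 3 samples required")
  S <- if (method == "pearson") {
    cor(X_otus, Y_pathways)
  } else {
    .spls_similarity(spls_fit(X_otus, Y_pathways,
                              ncomp = min(ncomp, nrow(X_otus) - 1),
                              mode = "canonical"))
  }
  ro <- if (nrow(S) > 2) hclust(dist(S), "average")$order else seq_len(nrow(S))
  co <- if (ncol(S) > 2) hclust(dist(t(S)), "average")$order else seq_len(ncol(S))
  S[ro, co, drop = FALSE]
}
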