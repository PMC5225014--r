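# Fingerprint preprocessing, peak detection, alpha diversity,
# binary Jaccard distances and hierarchical clustering.

# piecewise-linear monotone map through (observed, nominal) anchors,
# linearly extrapolated beyond the outermost anchors
.anchor_map <- function(observed, nominal) {
  o <- order(observed)
  obs <- observed[o]; nom <- nominal[o]
  if (any(diff(obs) <= 0) || any(diff(nom) <= 0))
    stopf("standard anchors must be strictly increasing")
  function(x) {
    y <- approx(obs, nom, xout = x, rule = 2)$y
    k <- length(obs)
    lo <- x < obs[1]
    hi <- x > obs[k]
    sl1 <- (nom[2] - nom[1]) / (obs[2] - obs[1])
    sl2 <- (nom[k] - nom[k - 1]) / (obs[k] - obs[k - 1])
    y[lo] <- nom[1] + sl1 * (x[lo] - obs[1])
    y[hi] <- nom[k] + sl2 * (x[hi] - obs[k])
    y
  }
}

#' Preprocess a fingerprint profile
#'
#' Aligns the trace to the size-standard axis by monotone piecewise-linear
#' interpolation through the (observed, nominal) standard anchors, removes
#' the baseline (rolling minimum over a window of 5% of the trace length,
#' then smoothed by a moving average), floors intensities at zero, and
#' scales the total area under the trace to 1.
#'
#' @param raw a [fingerprint_profile()] carrying at least 2 standard peaks.
#' @param baseline_window baseline window as a fraction of trace length.
#' @return an aligned, baseline-corrected, area-normalized profile.
#' @export
preprocess_profile <- function(raw, baseline_window = 0.05) {
  stopifnot(inherits(raw, "fingerprint_profile"))
  sp <- raw$standard_peaks
  if (is.null(sp) || nrow(sp) < 2)
    stopf("alignment requires at least 2 detectable standard peaks")
  if (all(raw$intensities == 0)) stopf("degenerate input: all-zero trace")

  map <- .anchor_map(sp$observed, sp$nominal)
  pos <- map(raw$positions)

  int <- raw$intensities
  n <- length(int)
  w <- max(3L, as.integer(round(baseline_window * n)))
  if (w %% 2 == 0) w <- w + 1L
  base <- zoo::rollapply(int, width = w, FUN = min, fill = "extend",
                         align = "center")
  sm <- stats::filter(base, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- base[is.na(sm)]
  int <- pmax(int - as.numeric(sm), 0)
  if (all(int == 0)) stopf("degenerate input: trace vanished after baseline removal")
  int <- int / pracma::trapz(pos, int)

  fingerprint_profile(raw$sample_id, pos, int,
                      data.frame(observed = map(sp$observed), nominal = sp$nominal))
}

#' Detect peaks in a preprocessed profile
#'
#' Local maxima with height at least `min_rel_height` times the global
#' maximum are retained; the area of each peak is integrated between its
#' flanking local minima (trapezoid rule) and areas are renormalized to
#' sum to 1.  Plateau maxima resolve to their first point.
#'
#' @param profile a preprocessed [fingerprint_profile()].
#' @param min_rel_height detection threshold as a fraction of the tallest
#'   peak, in (0, 1].
#' @return data.frame of class `peakset` with columns `position`, `area`,
#'   `height`.
#' @export
detect_peaks <- function(profile, min_rel_height = 0.05) {
  stopifnot(inherits(profile, "fingerprint_profile"))
  int <- profile$intensities
  pos <- profile$positions
  if (length(int) < 3 || all(int == 0)) stopf("empty profile: no peaks to detect")

  n <- length(int)
  is_max <- int[2:(n - 1)] > int[1:(n - 2)] & int[2:(n - 1)] >= int[3:n]
  cand <- which(is_max) + 1L
  cand <- cand[int[cand] >= min_rel_height * max(int)]
  if (length(cand) == 0) stopf("no peaks above threshold")

  # flanking local minima (including trace ends) bound each peak's area
  d <- sign(diff(int))
  minima <- c(1L, which(diff(d) > 0) + 1L, n)
  peaks <- do.call(rbind, lapply(cand, function(i) {
    left <- max(minima[minima < i])
    right <- min(minima[minima > i])
    data.frame(position = pos[i],
               area = pracma::trapz(pos[left:right], int[left:right]),
               height = int[i])
  }))
  peaks$area <- peaks$area / sum(peaks$area)
  class(peaks) <- c("peakset", "data.frame")
  peaks
}

#' Alpha diversity of a peak set
#'
#' With `p_i` the normalized peak areas: Gini-Simpson `1 - sum(p_i^2)`
#' (higher = more diverse; the inverse form `1/sum(p_i^2)` is available),
#' Shannon `-sum(p_i log p_i)` (natural log), richness = number of peaks,
#' and Pielou evenness `shannon / log(richness)` (defined as 1 for a
#' single peak).
#'
#' @param peaks a `peakset` from [detect_peaks()], or any data.frame with
#'   an `area` column.
#' @param simpson one of `"gini-simpson"` or `"inverse"`.
#' @return one-row data.frame: `simpson`, `shannon`, `richness`, `evenness`.
#' @export
alpha_diversity <- function(peaks, simpson = c("gini-simpson", "inverse")) {
  simpson <- match.arg(simpson)
  if (nrow(peaks) < 1) stopf("at least one peak required")
  p <- peaks$area / sum(peaks$area)
  s2 <- sum(p^2)
  sh <- -sum(ifelse(p > 0, p * log(p), 0))
  rich <- nrow(peaks)
  data.frame(
    simpson = if (simpson == "gini-simpson") 1 - s2 else 1 / s2,
    shannon = sh,
    richness = rich,
    evenness = if (rich == 1) 1 else sh / log(rich)
  )
}

# single-pass greedy binning of peak positions into phylotype bins;
# a sorted position joins the current bin while within match_tol of the
# bin's first (earliest) position
.bin_positions <- function(positions, match_tol) {
  o <- order(positions)
  bin <- integer(length(positions))
  cur <- 0L
  anchor <- -Inf
  for (i in o) {
    if (positions[i] - anchor > match_tol) {
      cur <- cur + 1L
      anchor <- positions[i]
    }
    bin[i] <- cur
  }
  bin
}

#' Binary Jaccard distances between fingerprint peak sets
#'
#' Peaks across samples are clustered into phylotype bins by position
#' (single-pass binning within `match_tol`, ties resolved toward the
#' earlier-position bin), each sample is reduced to a presence/absence
#' profile over the bins, and pairwise distance is `1 - |A&B| / |A|B|`.
#'
#' @param peaksets named list of `peakset` data.frames, one per sample.
#' @param match_tol position tolerance (size units) for peak matching.
#' @return symmetric distance matrix with sample labels.
#' @export
binarize_and_jaccard <- function(peaksets, match_tol = 0.5) {
  if (length(peaksets) < 2) stopf("at least 2 samples required")
  sizes <- vapply(peaksets, nrow, 1L)
  if (sum(sizes == 0) >= 2)
    stopf("Jaccard distance undefined: more than one sample has no peaks")
  all_pos <- unlist(lapply(peaksets, function(p) p$position))
  sample_of <- rep(names(peaksets), sizes)
  bin <- .bin_positions(all_pos, match_tol)

  pm <- matrix(0L, length(peaksets), max(bin),
               dimnames = list(names(peaksets), NULL))
  pm[cbind(match(sample_of, names(peaksets)), bin)] <- 1L

  inter <- tcrossprod(pm)
  uni <- outer(rowSums(pm), rowSums(pm), "+") - inter
  if (any(uni == 0 & upper.tri(uni))) stopf("Jaccard distance undefined for an empty pair")
  d <- 1 - inter / pmax(uni, 1)
  diag(d) <- 0
  d
}

#' Agglomerative clustering of a distance matrix
#'
#' Average-linkage (UPGMA) by default; the tree can be exported as newick
#' with [write_dendrogram_newick()].
#'
#' @param dist symmetric distance matrix with zero diagonal.
#' @param method linkage passed to [stats::hclust()].
#' @return an `hclust` tree.
#' @export
cluster_dendrogram <- function(dist, method = "average") {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8)) stopf("distance matrix must be symmetric")
  if (any(abs(diag(dist)) > 1e-12)) stopf("distance matrix must have zero diagonal")
  stats::hclust(stats::as.dist(dist), method = method)
}

#' @rdname cluster_dendrogram
#' @param tree an `hclust` tree.
#' @param path output newick file.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
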