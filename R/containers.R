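# S3 containers and plain-text (TSV) input/output.

#' OTU count table
#'
#' @param counts OTU x sample matrix of non-negative integers.
#' @param taxonomy named character vector, OTU id -> lineage string.
#' @param sample_meta data.frame with at least columns `sample` and `group`.
#' @return list of class `otu_table` with elements `counts`, `taxonomy`,
#'   `sample_meta`.
#' @export
otu_count_table <- function(counts, taxonomy = NULL, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("OTU%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  if (is.null(taxonomy))
    taxonomy <- stats::setNames(rep(NA_character_, nrow(counts)), rownames(counts))
  if (!is.null(sample_meta)) {
    missing <- setdiff(colnames(counts), sample_meta$sample)
    if (length(missing))
      stopf("samples missing from metadata: %s", paste(missing, collapse = ", "))
  }
  structure(list(counts = counts, taxonomy = taxonomy, sample_meta = sample_meta),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU count table: %d OTUs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$sample_meta) && "group" %in% names(x$sample_meta))
    print(table(x$sample_meta$group))
  invisible(x)
}

#' Fingerprint profile
#'
#' A continuous electrophoresis trace for one sample, with the observed
#' positions of the internal size-standard peaks.
#'
#' @param sample_id sample label.
#' @param positions strictly increasing numeric vector (scan or size units).
#' @param intensities non-negative numeric vector, same length.
#' @param standard_peaks data.frame with columns `observed`, `nominal`.
#' @return list of class `fingerprint_profile`.
#' @export
fingerprint_profile <- function(sample_id, positions, intensities,
                                standard_peaks = NULL) {
  if (length(positions) != length(intensities))
    stopf("positions and intensities must have equal length")
  if (any(diff(positions) <= 0)) stopf("positions must be strictly increasing")
  if (any(intensities < 0)) stopf("intensities must be non-negative")
  structure(list(sample_id = sample_id, positions = positions,
                 intensities = intensities, standard_peaks = standard_peaks),
            class = "fingerprint_profile")
}

#' @export
print.fingerprint_profile <- function(x, ...) {
  cat(sprintf("Fingerprint '%s': %d points on [%.1f, %.1f]\n", x$sample_id,
              length(x$positions), min(x$positions), max(x$positions)))
  invisible(x)
}

#' Write / read an OTU table as TSV
#'
#' Rows are OTUs; the first two columns are `otu_id` and `taxonomy`,
#' followed by one column per sample.
#'
#' @param table an [otu_count_table()].
#' @param path file path.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(otu_id = rownames(table$counts),
                   taxonomy = table$taxonomy[rownames(table$counts)],
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @param sample_meta optional sample metadata to attach on read.
#' @export
read_otu_table <- function(path, sample_meta = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("otu_id", "taxonomy")), drop = FALSE])
  rownames(counts) <- df$otu_id
  storage.mode(counts) <- "integer"
  otu_count_table(counts, stats::setNames(df$taxonomy, df$otu_id), sample_meta)
}

#' Write a labelled square distance matrix as TSV
#' @param d symmetric matrix with dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(data.frame(sample = rownames(d), d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fingerprint profile as a two-column TSV (position, intensity)
#' @param profile a [fingerprint_profile()].
#' @param path file path.
#' @export
write_fingerprint <- function(profile, path) {
  utils::write.table(
    data.frame(position = profile$positions, intensity = profile$intensities),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
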