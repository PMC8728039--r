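# Quality control for tetraploid allele-dosage matrices. The pipeline order
# is fixed: missingness filter, then population-mode imputation, then MAF
# filter; each step reports per-marker statistics and exact removal counts.

#' Per-marker allele frequency of a dosage matrix
#'
#' The frequency of the A allele at a tetraploid marker is the dosage-
#' weighted mean: `p = sum(dosage) / (4 * n_non_missing)`. The minor allele
#' frequency is `min(p, 1 - p)`.
#'
#' @param x a [dosage_matrix()] or a numeric dosage vector for one marker.
#' @return named numeric vector of allele frequencies in `[0, 1]`.
#' @export
allele_frequency <- function(x) {
  m <- if (inherits(x, "dosage_matrix")) x$dosages else
    matrix(x, ncol = 1, dimnames = list(NULL, "marker"))
  nobs <- colSums(!is.na(m))
  if (any(nobs == 0))
    stop("marker(s) with no observed calls: ",
         paste(colnames(m)[nobs == 0], collapse = ", "))
  p <- colSums(m, na.rm = TRUE) / (4 * nobs)
  if (!inherits(x, "dosage_matrix")) unname(p) else p
}

#' @rdname allele_frequency
#' @export
minor_allele_frequency <- function(x) {
  p <- allele_frequency(x)
  pmin(p, 1 - p)
}

new_qc_report <- function(markers_in, removed_missingness, removed_maf,
                          per_marker) {
  structure(list(markers_in = markers_in,
                 removed_missingness = removed_missingness,
                 removed_maf = removed_maf,
                 markers_out = markers_in - removed_missingness - removed_maf,
                 per_marker = per_marker),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report\n")
  cat(sprintf("  markers in:            %d\n", x$markers_in))
  cat(sprintf("  removed (missingness): %d\n", x$removed_missingness))
  cat(sprintf("  removed (MAF):         %d\n", x$removed_maf))
  cat(sprintf("  markers out:           %d\n", x$markers_out))
  invisible(x)
}

#' Remove markers with excessive missing calls
#'
#' Markers whose fraction of missing calls is strictly greater than
#' `max_rate` are dropped.
#'
#' @param x a [dosage_matrix()].
#' @param max_rate maximum tolerated missing fraction (default 10%).
#' @return list with elements `dosage` (filtered matrix) and `report`
#'   (a `qc_report`).
#' @export
filter_missingness <- function(x, max_rate = 0.10) {
  stopifnot(inherits(x, "dosage_matrix"))
  miss <- colMeans(is.na(x$dosages))
  keep <- miss <= max_rate
  if (!any(keep)) warning("no markers pass the missingness filter")
  per_marker <- data.frame(marker_id = colnames(x$dosages),
                           missing_rate = as.numeric(miss),
                           removed = !keep,
                           stringsAsFactors = FALSE)
  out <- x[, keep]
  list(dosage = out,
       report = new_qc_report(ncol(x$dosages), sum(!keep), 0L, per_marker))
}

#' Impute missing calls with the population mode
#'
#' Every missing call is replaced by the most frequent dosage class of its
#' marker; ties break to the numerically lowest dosage so the result is
#' deterministic. Observed calls are never altered.
#'
#' @param x a [dosage_matrix()]; every marker needs at least one observed
#'   call.
#' @return a [dosage_matrix()] with no missing entries.
#' @export
impute_mode <- function(x) {
  stopifnot(inherits(x, "dosage_matrix"))
  m <- x$dosages
  nobs <- colSums(!is.na(m))
  if (any(nobs == 0))
    stop("cannot impute marker(s) with no observed calls: ",
         paste(colnames(m)[nobs == 0], collapse = ", "))
  miss_cols <- which(colSums(is.na(m)) > 0)
  for (j in miss_cols) {
    counts <- tabulate(m[, j] + 1L, nbins = 5L)
    mode_dosage <- which.max(counts) - 1L  # which.max picks the lowest on ties
    m[is.na(m[, j]), j] <- mode_dosage
  }
  dosage_matrix(m, x$sample_meta)
}

#' Remove markers with low minor allele frequency
#'
#' Markers with MAF strictly smaller than `min_maf` are discarded. The
#' frequency is computed on exactly the samples present in `x`, so
#' subsetting samples before filtering changes the retained marker set.
#'
#' @param x a [dosage_matrix()].
#' @param min_maf minimum retained minor allele frequency (default 0.05).
#' @return list with elements `dosage` and `report`.
#' @export
filter_maf <- function(x, min_maf = 0.05) {
  stopifnot(inherits(x, "dosage_matrix"))
  maf <- minor_allele_frequency(x)
  keep <- maf >= min_maf
  per_marker <- data.frame(marker_id = colnames(x$dosages),
                           allele_freq = as.numeric(allele_frequency(x)),
                           maf = as.numeric(maf),
                           removed = !keep,
                           stringsAsFactors = FALSE)
  out <- x[, keep]
  list(dosage = out,
       report = new_qc_report(ncol(x$dosages), 0L, sum(!keep), per_marker))
}

#' Full marker QC pipeline
#'
#' Fixed order: missingness filter, population-mode imputation, MAF filter.
#' The combined report's counts balance exactly:
#' `markers_in = removed_missingness + removed_maf + markers_out`.
#'
#' @param x a [dosage_matrix()].
#' @param max_missing missingness threshold passed to [filter_missingness()].
#' @param min_maf MAF threshold passed to [filter_maf()].
#' @return list with elements `dosage` (filtered, imputed) and `report`.
#' @export
qc_pipeline <- function(x, max_missing = 0.10, min_maf = 0.05) {
  st1 <- filter_missingness(x, max_missing)
  imp <- impute_mode(st1$dosage)
  st2 <- filter_maf(imp, min_maf)
  per_marker <- merge(st1$report$per_marker,
                      st2$report$per_marker[, c("marker_id", "allele_freq", "maf")],
                      by = "marker_id", all.x = TRUE, sort = FALSE)
  per_marker <- per_marker[match(colnames(x$dosages), per_marker$marker_id), ]
  rownames(per_marker) <- NULL
  report <- new_qc_report(ncol(x$dosages),
                          st1$report$removed_missingness,
                          st2$report$removed_maf,
                          per_marker)
  list(dosage = st2$dosage, report = report)
}

#' Write a QC report as delimited text
#'
#' @param report a `qc_report`.
#' @param path file path; per-marker statistics go to
#'   `<path>` and the count summary to a `# key value` header.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in c("markers_in", "removed_missingness", "removed_maf", "markers_out"))
    writeLines(sprintf("# %s\t%d", k, report[[k]]), con)
  write.table(report$per_marker, con, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Fraction of discordant calls between two samples
#'
#' Compares two samples over all markers jointly observed in both; used as
#' a concordance check for technical duplicates (expected < 0.5%
#' difference) against unrelated individuals (around 50%).
#'
#' @param x a [dosage_matrix()].
#' @param sample_i,sample_j sample ids.
#' @return fraction of jointly observed markers with unequal calls, in
#'   `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_difference <- function(x, sample_i, sample_j) {
  stopifnot(inherits(x, "dosage_matrix"))
  for (s in c(sample_i, sample_j))
    if (!s %in% rownames(x$dosages)) stop("unknown sample: ", s)
  a <- x$dosages[sample_i, ]
  b <- x$dosages[sample_j, ]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop(sprintf("samples %s and %s share no jointly observed markers",
                 sample_i, sample_j))
  mean(a[ok] != b[ok])
}
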