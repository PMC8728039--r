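# Population structure: Euclidean genetic distances between dosage vectors
# and classical (metric) principal coordinate analysis.

#' Euclidean genetic distance matrix from allele dosages
#'
#' `d(i, j) = sqrt(sum_m (x_im - x_jm)^2)` over all markers. Missing calls
#' are not allowed; run [impute_mode()] (or the full [qc_pipeline()]) first.
#'
#' @param x a [dosage_matrix()] with no missing entries.
#' @return symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
euclidean_distance_matrix <- function(x) {
  stopifnot(inherits(x, "dosage_matrix"))
  if (anyNA(x$dosages))
    stop("dosage matrix contains missing calls; impute first (impute_mode)")
  as.matrix(dist(x$dosages, method = "euclidean"))
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers `-D^2/2`, eigendecomposes, and returns coordinates scaled
#' by the square roots of the eigenvalues. Percent variance explained per
#' axis is computed over the positive eigenvalues only (negative
#' eigenvalues, which cannot occur for exact Euclidean input but can appear
#' numerically, are excluded from the denominator and reported). Axis signs
#' are fixed by making the largest-magnitude coordinate of each axis
#' positive, so output is reproducible across platforms.
#'
#' @param d symmetric distance matrix (e.g. from
#'   [euclidean_distance_matrix()]).
#' @param k number of axes to return; truncated with a warning if it
#'   exceeds the number of positive eigenvalues.
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (samples x k), `eigenvalues` (all, descending), `pct_variance`
#'   (per returned axis), `negative_eigenvalues`.
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), k >= 1)
  n <- nrow(d)
  fit <- suppressWarnings(cmdscale(d, k = min(k, n - 1), eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- eig[eig > 1e-8 * max(abs(eig))]
  if (k > min(length(pos), ncol(fit$points))) {
    k <- min(length(pos), ncol(fit$points))
    warning(sprintf("only %d positive eigenvalues; returning %d axes", k, k))
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  for (a in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, a])), a] < 0)
      coords[, a] <- -coords[, a]
  }
  colnames(coords) <- paste0("PC", seq_len(k))
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 pct_variance = 100 * pos[seq_len(k)] / sum(pos),
                 negative_eigenvalues = eig[eig < 0]),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  % variance:",
      paste(sprintf("%s=%.2f%%", colnames(x$coordinates), x$pct_variance),
            collapse = ", "), "\n")
  if (length(x$negative_eigenvalues))
    cat(sprintf("  %d negative eigenvalues (excluded from %% variance)\n",
                length(x$negative_eigenvalues)))
  invisible(x)
}

#' Scatter-ready PCoA table with sample labels
#'
#' Joins generation/family labels onto the principal coordinates for
#' plotting or export.
#'
#' @param p a `pcoa_result`.
#' @param sample_meta metadata `data.frame` with a `sample_id` column.
#' @return `data.frame` with `sample_id`, the coordinate columns, and any
#'   metadata columns.
#' @export
pcoa_table <- function(p, sample_meta = NULL) {
  stopifnot(inherits(p, "pcoa_result"))
  out <- data.frame(sample_id = rownames(p$coordinates), p$coordinates,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(sample_meta))
    out <- merge(out, sample_meta, by = "sample_id", all.x = TRUE, sort = FALSE)
  out
}
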