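#' Allele-dosage matrix for autotetraploid samples
#'
#' Container for a samples x markers matrix of allele dosages. In an
#' autotetraploid each biallelic SNP takes one of five allelic states: 0 and
#' 4 are the two homozygotes (OOOO, AAAA) and 1, 2, 3 the simplex, duplex
#' and triplex heterozygotes. Missing calls are `NA`. Sample metadata
#' (generation label, full-sib family, check-cultivar flag) travel with the
#' matrix so that partitioning by breeding-program cohort stays aligned with
#' the genotypes.
#'
#' @param dosages integer matrix, samples in rows (rownames = sample ids),
#'   markers in columns (colnames = marker ids); entries in `0:4` or `NA`.
#' @param sample_meta optional `data.frame` with columns `sample_id`,
#'   `generation`, `family`, `is_check`; defaults are filled in when absent.
#' @return An object of class `dosage_matrix`: a list with elements
#'   `dosages` and `sample_meta`.
#' @examples
#' m <- matrix(c(0L, 2L, 4L, 1L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("m1", "m2")))
#' dm <- dosage_matrix(m)
#' n_samples(dm)
#' @export
dosage_matrix <- function(dosages, sample_meta = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("M", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("sample ids must be unique")
  if (anyDuplicated(colnames(dosages)))
    stop("marker ids must be unique")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && (any(vals < 0) || any(vals > 4) || any(vals != round(vals))))
    stop("dosages must be integers in 0..4 (tetraploid allele counts) or NA")
  storage.mode(dosages) <- "integer"
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = rownames(dosages),
                              generation = "unknown",
                              family = NA_character_,
                              is_check = FALSE,
                              stringsAsFactors = FALSE)
  } else {
    sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(sample_meta))
      stop("sample_meta must contain a 'sample_id' column")
    if (!"generation" %in% names(sample_meta)) sample_meta$generation <- "unknown"
    if (!"family" %in% names(sample_meta)) sample_meta$family <- NA_character_
    if (!"is_check" %in% names(sample_meta)) sample_meta$is_check <- FALSE
    if (!setequal(sample_meta$sample_id, rownames(dosages)))
      stop("sample_meta$sample_id must match the rownames of the dosage matrix")
    sample_meta <- sample_meta[match(rownames(dosages), sample_meta$sample_id), ,
                               drop = FALSE]
    rownames(sample_meta) <- NULL
  }
  structure(list(dosages = dosages, sample_meta = sample_meta),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d samples x %d markers\n",
              nrow(x$dosages), ncol(x$dosages)))
  nmiss <- sum(is.na(x$dosages))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(x$dosages)))
  gen <- table(x$sample_meta$generation)
  cat("  generations:", paste(sprintf("%s=%d", names(gen), gen), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname dosage_matrix
#' @param x a `dosage_matrix`.
#' @export
n_samples <- function(x) nrow(x$dosages)

#' @rdname dosage_matrix
#' @export
n_markers <- function(x) ncol(x$dosages)

#' Subset a dosage matrix by samples and/or markers
#'
#' @param x a `dosage_matrix`.
#' @param i sample selector (ids, indices or logical).
#' @param j marker selector.
#' @param ... ignored.
#' @param drop ignored; the result is always a `dosage_matrix`.
#' @export
`[.dosage_matrix` <- function(x, i, j, ..., drop = FALSE) {
  d <- x$dosages
  if (missing(i)) i <- seq_len(nrow(d))
  if (missing(j)) j <- seq_len(ncol(d))
  d <- d[i, j, drop = FALSE]
  meta <- x$sample_meta[match(rownames(d), x$sample_meta$sample_id), ,
                        drop = FALSE]
  rownames(meta) <- NULL
  dosage_matrix(d, meta)
}

#' Read and write dosage matrices as delimited text
#'
#' The on-disk format is tab-delimited with a header row of marker ids, one
#' row per sample, the sample id in the first column (`sample_id`) and
#' missing calls written as `NA`.
#'
#' @param x a `dosage_matrix`.
#' @param path file path.
#' @param sample_meta optional metadata `data.frame` joined on read.
#' @return `read_dosage` returns a `dosage_matrix`; `write_dosage` returns
#'   `path` invisibly.
#' @export
write_dosage <- function(x, path) {
  stopifnot(inherits(x, "dosage_matrix"))
  out <- data.frame(sample_id = rownames(x$dosages), x$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path, sample_meta = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  dosage_matrix(m, sample_meta)
}

#' Read and write sample metadata, pedigree and phenotype tables
#'
#' Phenotype tables are long format with one plot record per row:
#' `genotype_id`, `location`, `replicate`, `trait`, `value` (plus any extra
#' columns such as an observation date for repeated disease scores).
#' Pedigrees are three columns: `id`, `parent1`, `parent2` (`NA` for
#' founders).
#'
#' @param x a `data.frame`.
#' @param path file path.
#' @export
write_phenotypes <- function(x, path) {
  stopifnot(is.data.frame(x))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("genotype_id", "location", "replicate", "trait", "value")
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype table is missing columns: ", paste(miss, collapse = ", "))
  ph
}

#' @rdname write_phenotypes
#' @export
write_pedigree <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("id", "parent1", "parent2") %in% names(x)))
  write.table(x[, c("id", "parent1", "parent2")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_pedigree <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname write_phenotypes
#' @export
write_sample_meta <- function(x, path) {
  stopifnot(is.data.frame(x), "sample_id" %in% names(x))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_sample_meta <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
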