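# Dosage QC: allele frequencies, the fixed-order filter pipeline, mode
# imputation and duplicate-sample concordance.

dm_from <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  dosage_matrix(m)
}

test_that("allele frequency is dosage-weighted and missing-aware", {
  expect_equal(unname(allele_frequency(c(4, 4, 4, 4))), 1.0)
  expect_equal(unname(minor_allele_frequency(c(4, 4, 4, 4))), 0.0)
  expect_equal(unname(allele_frequency(c(0, 1, 2, 3, 4))), 0.5)
  expect_equal(unname(allele_frequency(c(2, 2, NA))), 0.5)
  dm <- dm_from(m1 = c(0L, 4L), m2 = c(NA_integer_, NA_integer_))
  expect_error(allele_frequency(dm), "m2")
})

test_that("missingness filter removes strictly-above-threshold markers", {
  miss3 <- c(rep(2L, 17), NA, NA, NA)        # 15% missing
  miss2 <- c(rep(2L, 18), NA, NA)            # 10% missing, retained
  full <- rep_len(c(0L, 3L), 20)
  dm <- dm_from(a = miss3, b = miss2, c = full)
  res <- filter_missingness(dm, max_rate = 0.10)
  expect_equal(colnames(res$dosage$dosages), c("b", "c"))
  expect_equal(res$report$removed_missingness, 1L)
  # fully observed matrix: identity
  dm2 <- dm_from(a = full, b = rep_len(c(1L, 2L), 20))
  res2 <- filter_missingness(dm2)
  expect_identical(res2$dosage$dosages, dm2$dosages)
})

test_that("mode imputation fills every gap with the marker mode, ties low", {
  dm <- dm_from(a = c(1L, 1L, 3L, NA),
                b = c(1L, 1L, 3L, 3L),
                c = c(0L, 2L, 2L, 4L))
  dm$dosages[1, "b"] <- NA  # [NA,1,3,3] -> mode tie 1 vs 3 -> 1
  dm$dosages[4, "b"] <- 1L  # -> [NA,1,3,1]
  dm$dosages <- dm$dosages  # keep types
  imp <- impute_mode(dm)
  expect_equal(unname(imp$dosages[4, "a"]), 1L)
  expect_false(anyNA(imp$dosages))
  # observed entries unchanged
  obs <- !is.na(dm$dosages)
  expect_identical(imp$dosages[obs], dm$dosages[obs])
  # tie broken to the lower dosage
  tie <- dm_from(a = c(1L, 1L, 3L, 3L, NA))
  expect_equal(unname(impute_mode(tie)$dosages[5, "a"]), 1L)
  # no missing: identity
  full <- dm_from(a = c(0L, 1L, 2L, 3L))
  expect_identical(impute_mode(full)$dosages, full$dosages)
  allna <- dm_from(a = c(NA_integer_, NA_integer_))
  expect_error(impute_mode(allna), "a")
})

test_that("MAF filter removes strictly-below-threshold markers", {
  n <- 25
  mono <- rep(4L, n)                       # MAF 0
  low <- c(rep(0L, 21), 1L, 1L, 1L, 1L)    # p = 4/100 = 0.04
  edge <- c(rep(0L, 20), rep(1L, 5))       # p = 5/100 = 0.05
  common <- rep_len(c(1L, 3L), n)
  dm <- dm_from(mono = mono, low = low, edge = edge, common = common)
  res <- filter_maf(dm, min_maf = 0.05)
  expect_equal(colnames(res$dosage$dosages), c("edge", "common"))
  expect_equal(res$report$removed_maf, 2L)
})

test_that("QC pipeline is ordered, balanced and idempotent", {
  set.seed(55)
  X <- random_dosage(60, 300, freq_range = c(0.0, 0.9), missing_rate = 0.05)
  # force some high-missingness markers
  X[sample(60, 20), 5] <- NA
  X[sample(60, 30), 6] <- NA
  dm <- dosage_matrix(X)
  res <- qc_pipeline(dm)
  rep <- res$report
  expect_equal(rep$markers_in,
               rep$removed_missingness + rep$removed_maf + rep$markers_out)
  expect_equal(rep$markers_out, n_markers(res$dosage))
  expect_true(all(colnames(res$dosage$dosages) %in% colnames(X)))
  expect_false(anyNA(res$dosage$dosages))
  # every retained marker satisfies the MAF bound post hoc
  expect_true(all(minor_allele_frequency(res$dosage) >= 0.05))
  # re-running on its own output is the identity
  res2 <- qc_pipeline(res$dosage)
  expect_identical(res2$dosage$dosages, res$dosage$dosages)
  expect_equal(res2$report$removed_missingness + res2$report$removed_maf, 0)
})

test_that("pairwise difference measures duplicate concordance", {
  m <- rbind(a = c(0L, 1L, 2L, 3L, 4L),
             b = c(0L, 1L, 2L, 3L, 4L),
             c = c(4L, 3L, 2L, 1L, 0L),
             d = c(0L, 1L, NA, 3L, 0L))
  colnames(m) <- paste0("m", 1:5)
  dm <- dosage_matrix(m)
  expect_equal(pairwise_difference(dm, "a", "b"), 0)
  expect_equal(pairwise_difference(dm, "a", "c"), 0.8)  # m3 equal (2 vs 2)
  comp <- dosage_matrix(rbind(u = c(0L, 1L, 4L, 3L),
                              v = c(4L, 3L, 0L, 1L)))
  expect_equal(pairwise_difference(comp, "u", "v"), 1.0)
  expect_equal(pairwise_difference(dm, "a", "d"),
               pairwise_difference(dm, "d", "a"))
  expect_equal(pairwise_difference(dm, "a", "d"), 0.25)  # NA excluded
  e <- dosage_matrix(rbind(x = c(1L, NA), y = c(NA, 2L)))
  expect_error(pairwise_difference(e, "x", "y"), "jointly")
  expect_error(pairwise_difference(dm, "a", "zz"), "zz")
})

test_that("dosage matrices round-trip through delimited text", {
  set.seed(66)
  X <- random_dosage(12, 8, missing_rate = 0.1)
  meta <- data.frame(sample_id = rownames(X),
                     generation = rep(c("T1", "T2"), 6),
                     family = NA_character_, is_check = FALSE)
  dm <- dosage_matrix(X, meta)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage(dm, path)
  back <- read_dosage(path, meta)
  expect_identical(back$dosages, dm$dosages)
  expect_identical(back$sample_meta$generation, meta$generation)
  expect_error(dosage_matrix(matrix(5L, 2, 2)), "0..4")
  expect_error(dosage_matrix(matrix(0L, 2, 2,
                                    dimnames = list(c("a", "a"), NULL))),
               "unique")
})
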