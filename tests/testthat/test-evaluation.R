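# Partition designs and Pearson prediction accuracy.

study_meta <- function() {
  data.frame(
    sample_id = c(sprintf("t1_%03d", 1:465), sprintf("t2_%03d", 1:138),
                  sprintf("t37_%02d", 1:62), sprintf("par_%d", 1:4),
                  sprintf("chk_%d", 1:5)),
    generation = c(rep("T1", 465), rep("T2", 138), rep("T3-7", 62),
                   rep("parent", 4), rep("check", 5)),
    stringsAsFactors = FALSE)
}

test_that("prediction accuracy is Pearson correlation with guard rails", {
  expect_equal(prediction_accuracy(1:5, 1:5), 1)
  expect_equal(prediction_accuracy(1:5, -(1:5)), -1)
  expect_equal(prediction_accuracy(c(1, 2, 3), c(1, 2, 4)),
               cor(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(round(prediction_accuracy(c(1, 2, 3), c(1, 2, 4)), 4), 0.982)
  expect_error(prediction_accuracy(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(prediction_accuracy(1:2, 1:2), "three")
})

test_that("generation partitions are deterministic, disjoint and complete", {
  meta <- study_meta()
  p <- split_by_generation(meta, train_gens = c("T2", "T3-7"),
                           test_gens = "T1")
  expect_equal(length(p$test_ids), 465)
  expect_equal(length(p$train_ids), 200)
  expect_length(intersect(p$train_ids, p$test_ids), 0)
  p2 <- split_by_generation(meta, c("T2", "T3-7"), "T1",
                            include_parents = TRUE)
  expect_equal(length(p2$train_ids), 204)
  expect_setequal(setdiff(p2$train_ids, p$train_ids), sprintf("par_%d", 1:4))
  expect_error(split_by_generation(meta, c("T1", "T2"), "T1"), "both")
  expect_error(split_by_generation(meta, "T9", "T1"), "T9")
  # disjointness holds for arbitrary label assignments
  set.seed(61)
  for (i in 1:5) {
    meta$generation <- sample(c("T1", "T2", "T3-7"), nrow(meta), TRUE)
    pr <- split_by_generation(meta, c("T2", "T3-7"), "T1")
    expect_length(intersect(pr$train_ids, pr$test_ids), 0)
    expect_setequal(c(pr$train_ids, pr$test_ids), meta$sample_id)
  }
})

test_that("cross-validation folds partition the samples near-evenly", {
  set.seed(62)
  for (n in c(23, 100, 5)) {
    f <- tetragebv:::cv_folds(n, 5)
    expect_length(f, n)
    sizes <- tabulate(f, 5)
    expect_lte(diff(range(sizes)), 1)
    expect_equal(sum(sizes), n)
  }
})

test_that("k-fold CV recovers strong signal and is reproducible", {
  set.seed(63)
  X <- random_dosage(300, 100)
  sim <- marker_model_phenotype(X, h2 = 1)  # noiseless y = X beta
  spec <- brr_model_spec(n_iter = 3000, burn_in = 1000)
  res <- kfold_cv(sim$y, X, k = 5, reps = 2, spec = spec, seed = 7)
  expect_gt(res$mean_r, 0.9)
  expect_equal(nrow(res$per_rep), 2)
  expect_false(res$not_predictable)
  # reproducibility with one replicate and a fixed seed
  r1 <- kfold_cv(sim$y, X, k = 5, reps = 1, spec = spec, seed = 11)
  r2 <- kfold_cv(sim$y, X, k = 5, reps = 1, spec = spec, seed = 11)
  expect_identical(r1$per_rep$r, r2$per_rep$r)
  expect_error(kfold_cv(sim$y[1:4], X[1:4, ], k = 5, spec = spec), "exceeds")
})

test_that("null phenotypes give near-zero CV accuracy, reported unclipped", {
  set.seed(64)
  X <- random_dosage(120, 80)
  y <- rnorm(120)
  spec <- brr_model_spec(n_iter = 1500, burn_in = 500)
  res <- kfold_cv(y, X, k = 5, reps = 5, spec = spec, seed = 3)
  expect_lt(abs(res$mean_r), 0.3)
  # negative means are reported as-is and flagged not predictable
  if (res$mean_r <= 0) expect_true(res$not_predictable)
  expect_true(all(res$per_rep$r >= -1 & res$per_rep$r <= 1))
})

test_that("cross-generation evaluation trains late and predicts early", {
  set.seed(65)
  X <- random_dosage(200, 60)
  sim <- marker_model_phenotype(X, h2 = 0.9)
  y <- setNames(sim$y, rownames(X))
  meta <- data.frame(sample_id = rownames(X),
                     generation = rep(c("T1", "T2"), each = 100),
                     stringsAsFactors = FALSE)
  p <- split_by_generation(meta, "T2", "T1")
  spec <- brr_model_spec(n_iter = 2000, burn_in = 500, seed = 5)
  res <- cross_generation_eval(y, X, p, spec)
  expect_equal(res$scheme, "cross_generation")
  expect_gt(res$mean_r, 0.5)
  expect_setequal(res$predictions$sample_id, p$test_ids)
  # accuracy is invariant to sample ordering in the input
  ord <- sample(nrow(X))
  res2 <- cross_generation_eval(y[ord], X[ord, ], p, spec)
  expect_equal(res2$mean_r, res$mean_r, tolerance = 1e-10)
  # anti-signal in the test set: negative accuracy is reported, not clipped
  y_neg <- y
  y_neg[p$test_ids] <- -y[p$test_ids]
  res_neg <- cross_generation_eval(y_neg, X, p, spec)
  expect_lt(res_neg$mean_r, 0)
  expect_true(res_neg$not_predictable)
})

test_that("cross-family evaluation reports both directions", {
  # degenerate: single causal marker, two clone-identical families
  X1 <- cbind(m1 = c(0L, 1L, 2L, 3L, 4L, 2L, 1L, 3L))
  X <- rbind(X1, X1)
  rownames(X) <- sprintf("s%02d", 1:16)
  y <- setNames(as.numeric(X[, 1]) * 2 + 1, rownames(X))
  family <- setNames(rep(c("T1-C", "T1-D"), each = 8), rownames(X))
  spec <- brr_model_spec(n_iter = 1500, burn_in = 500, seed = 9)
  res <- cross_family_eval(y, X, family, c("T1-C", "T1-D"), spec)
  expect_setequal(res$per_rep$direction, c("T1-C->T1-D", "T1-D->T1-C"))
  expect_equal(res$per_rep$r, c(1, 1))
  expect_error(cross_family_eval(y, X, family, c("T1-C", "T1-Z"), spec),
               "T1-Z")
})

test_that("cross-family prediction in related families beats the null", {
  spec <- brr_model_spec(n_iter = 1500, burn_in = 500)
  acc <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    set.seed(700 + s)
    founders <- founder_genomes(c("P1", "P2", "P3"), 200)
    famC <- cross(founders$genomes$P1, founders$genomes$P2, 40)
    famD <- cross(founders$genomes$P1, founders$genomes$P3, 40)
    X <- rbind(genotype_dosage(famC), genotype_dosage(famD))
    rownames(X) <- sprintf("s%02d", 1:80)
    colnames(X) <- founders$marker_ids
    sim <- marker_model_phenotype(X, h2 = 0.5)
    y <- setNames(sim$y, rownames(X))
    family <- setNames(rep(c("C", "D"), each = 40), rownames(X))
    res <- cross_family_eval(y, X, family, c("C", "D"), spec)
    acc[s, 1] <- res$mean_r
    ynull <- setNames(sample(y), names(y))
    res0 <- cross_family_eval(ynull, X, family, c("C", "D"), spec)
    acc[s, 2] <- res0$mean_r
  }
  expect_lt(t.test(acc[, 1], acc[, 2], alternative = "greater")$p.value, 0.01)
})
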