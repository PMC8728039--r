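# Prediction-accuracy evaluation: deterministic cross-generation partitions,
# cross-family prediction in both directions, and repeated k-fold
# cross-validation, all scored by Pearson correlation between observed and
# predicted values.

#' Pearson prediction accuracy
#'
#' @param observed,predicted aligned numeric vectors, length >= 3, both
#'   non-constant.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
prediction_accuracy <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- !is.na(observed) & !is.na(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 3)
    stop("at least three paired observations are required")
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop("accuracy is undefined for a constant vector")
  cor(observed, predicted)
}

#' Deterministic train/test partition by breeding-program generation
#'
#' @param sample_meta `data.frame` with `sample_id` and `generation`.
#' @param train_gens,test_gens disjoint sets of generation labels.
#' @param include_parents append samples labelled `"parent"` (the
#'   parents/grandparents of the T1 full-sib families) to the training set.
#' @return list of class `partition` with `train_ids`, `test_ids`,
#'   `scheme = "cross_generation"`.
#' @export
split_by_generation <- function(sample_meta, train_gens, test_gens,
                                include_parents = FALSE) {
  overlap <- intersect(train_gens, test_gens)
  if (length(overlap))
    stop("generations requested in both train and test: ",
         paste(overlap, collapse = ", "))
  gens <- unique(sample_meta$generation)
  absent <- setdiff(c(train_gens, test_gens), gens)
  if (length(absent))
    stop("generation label(s) not present: ", paste(absent, collapse = ", "))
  train <- sample_meta$sample_id[sample_meta$generation %in% train_gens]
  test <- sample_meta$sample_id[sample_meta$generation %in% test_gens]
  if (include_parents)
    train <- union(train,
                   sample_meta$sample_id[sample_meta$generation == "parent"])
  if (!length(train) || !length(test))
    stop("both partitions must be non-empty")
  structure(list(train_ids = train, test_ids = test,
                 scheme = "cross_generation"),
            class = "partition")
}

# Random assignment of n individuals to k folds with sizes differing by at
# most one; uses the current RNG state.
cv_folds <- function(n, k) {
  sample(rep_len(seq_len(k), n))
}

new_accuracy_result <- function(per_rep, scheme, trait = NA_character_) {
  r <- per_rep$r
  structure(list(trait = trait, scheme = scheme, per_rep = per_rep,
                 mean_r = mean(r), sd_r = if (length(r) > 1) sd(r) else NA_real_,
                 not_predictable = mean(r) <= 0),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("accuracy_result [%s]%s\n", x$scheme,
              if (is.na(x$trait)) "" else paste0(" trait ", x$trait)))
  cat(sprintf("  mean r = %.3f (sd %.3f, %d replicate(s))\n",
              x$mean_r, x$sd_r, nrow(x$per_rep)))
  if (x$not_predictable)
    cat("  mean accuracy <= 0: prediction not possible for this trait\n")
  invisible(x)
}

#' Repeated k-fold cross-validation of genomic prediction accuracy
#'
#' Per replicate, individuals are randomly assigned to `k` disjoint folds
#' of near-equal size (differing by at most one); each fold is predicted by
#' a model trained on the remaining folds until every individual has a
#' predicted value, and one Pearson correlation is computed on the
#' assembled prediction vector. The mean correlation over replicates is the
#' reported accuracy; negative values are reported, not clipped.
#'
#' @param y named or plain numeric phenotype vector.
#' @param X aligned samples x markers dosage matrix.
#' @param k number of folds (default 5).
#' @param reps number of random repetitions (default 100).
#' @param spec a [brr_model_spec()]; its `seed` field is ignored here, the
#'   `seed` argument governs the whole procedure.
#' @param seed integer seed.
#' @param trait label carried into the result.
#' @return an `accuracy_result` with one row per replicate.
#' @export
kfold_cv <- function(y, X, k = 5, reps = 100, spec = brr_model_spec(),
                     seed = 1L, trait = NA_character_) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (k > n) stop(sprintf("k = %d exceeds the number of individuals (%d)",
                          k, n))
  spec$seed <- NULL
  set.seed(as.integer(seed))
  rs <- numeric(reps)
  for (r in seq_len(reps)) {
    fold <- cv_folds(n, k)
    pred <- numeric(n)
    for (f in seq_len(k)) {
      test <- fold == f
      fit <- fit_brr(y[!test], X[!test, , drop = FALSE], spec)
      pred[test] <- predict_gebv(fit, X[test, , drop = FALSE])$gebv
    }
    rs[r] <- prediction_accuracy(y, pred)
  }
  new_accuracy_result(data.frame(rep = seq_len(reps), r = rs),
                      scheme = "kfold", trait = trait)
}

#' Cross-generation prediction accuracy
#'
#' Fits the model on the training generations (individuals from later
#' selection cycles) and predicts the earlier-generation test set.
#'
#' @param y named numeric vector of (adjusted) phenotype genotype means.
#' @param X samples x markers dosage matrix with rownames.
#' @param partition a `partition` from [split_by_generation()].
#' @param spec a [brr_model_spec()].
#' @param trait label carried into the result.
#' @return an `accuracy_result` with a single replicate.
#' @export
cross_generation_eval <- function(y, X, partition, spec = brr_model_spec(),
                                  trait = NA_character_) {
  stopifnot(inherits(partition, "partition"), !is.null(rownames(X)),
            !is.null(names(y)))
  train <- intersect(partition$train_ids, intersect(rownames(X), names(y)))
  test <- intersect(partition$test_ids, intersect(rownames(X), names(y)))
  fit <- fit_brr(y[train], X[train, , drop = FALSE], spec)
  pred <- predict_gebv(fit, X[test, , drop = FALSE])
  r <- prediction_accuracy(y[test], pred$gebv)
  res <- new_accuracy_result(data.frame(rep = 1L, r = r),
                             scheme = "cross_generation", trait = trait)
  res$predictions <- data.frame(sample_id = test, observed = as.numeric(y[test]),
                                gebv = pred$gebv, stringsAsFactors = FALSE)
  res
}

#' Cross-family prediction accuracy, both directions
#'
#' Trains on one full-sib family and predicts the other, for each ordered
#' pair of the two families. Optionally refilters markers by MAF within the
#' two families' own sample set first, mirroring subset-specific marker
#' panels.
#'
#' @param y named numeric phenotype vector.
#' @param X samples x markers dosage matrix with rownames.
#' @param family named character vector (or factor) mapping sample ids to
#'   family labels.
#' @param families the two family labels to evaluate.
#' @param spec a [brr_model_spec()].
#' @param min_maf optional within-subset MAF threshold re-applied to the
#'   marker panel before fitting.
#' @param trait label carried into the result.
#' @return an `accuracy_result` whose `per_rep` rows are labelled with the
#'   train and test family.
#' @export
cross_family_eval <- function(y, X, family, families, spec = brr_model_spec(),
                              min_maf = NULL, trait = NA_character_) {
  stopifnot(length(families) == 2, !is.null(rownames(X)), !is.null(names(y)))
  family <- setNames(as.character(family), names(family))
  for (f in families)
    if (!f %in% family) stop("family not present: ", f)
  ids <- names(family)[family %in% families]
  ids <- intersect(ids, intersect(rownames(X), names(y)))
  Xs <- X[ids, , drop = FALSE]
  if (!is.null(min_maf)) {
    keep <- minor_allele_frequency(dosage_matrix(Xs)) >= min_maf
    Xs <- Xs[, keep, drop = FALSE]
  }
  rows <- lapply(1:2, function(i) {
    train_fam <- families[i]; test_fam <- families[3 - i]
    train <- ids[family[ids] == train_fam]
    test <- ids[family[ids] == test_fam]
    fit <- fit_brr(y[train], Xs[train, , drop = FALSE], spec)
    pred <- predict_gebv(fit, Xs[test, , drop = FALSE])
    data.frame(rep = i, train_family = train_fam, test_family = test_fam,
               direction = paste0(train_fam, "->", test_fam),
               r = prediction_accuracy(y[test], pred$gebv),
               stringsAsFactors = FALSE)
  })
  new_accuracy_result(do.call(rbind, rows), scheme = "cross_family",
                      trait = trait)
}

#' Write per-replicate and summary accuracy tables
#'
#' @param x an `accuracy_result`.
#' @param path file path for the per-replicate table; the summary line is
#'   appended as a comment header.
#' @export
write_accuracy <- function(x, path) {
  stopifnot(inherits(x, "accuracy_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scheme\t%s", x$scheme), con)
  writeLines(sprintf("# trait\t%s", x$trait), con)
  writeLines(sprintf("# mean_r\t%.6f", x$mean_r), con)
  writeLines(sprintf("# sd_r\t%.6f", x$sd_r), con)
  writeLines(sprintf("# not_predictable\t%s", x$not_predictable), con)
  write.table(x$per_rep, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
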