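# Variance components for the multi-location trial model
#   y = mu + genotype + location + genotype:location + rep(location) + e
# (all factors random, independent, identity covariance) estimated by
# EM-REML, and broad-sense heritability on an entry-mean basis with
# harmonic-mean replication corrections.

#' Harmonic means of the replication design
#'
#' `Hm1` is the harmonic mean, over genotype-by-location cells with at
#' least one record, of the number of replicates in the cell; `Hm2` is the
#' harmonic mean, over genotypes, of the total number of replicates across
#' all locations.
#'
#' @param pheno long-format phenotype `data.frame`.
#' @param trait optional trait filter.
#' @param genotypes optional subset of genotype ids; every listed genotype
#'   must have at least one record.
#' @return list of class `design_summary` with `Hm1`, `Hm2`,
#'   `n_genotypes`, `n_locations`.
#' @export
harmonic_means <- function(pheno, trait = NULL, genotypes = NULL) {
  ph <- pheno[!is.na(pheno$value), ]
  if (!is.null(trait)) ph <- ph[ph$trait == trait, ]
  if (!is.null(genotypes)) {
    absent <- setdiff(genotypes, unique(ph$genotype_id))
    if (length(absent))
      stop("genotype(s) with no records: ", paste(absent, collapse = ", "))
    ph <- ph[ph$genotype_id %in% genotypes, ]
  }
  if (!nrow(ph)) stop("no phenotype records to summarise")
  cell <- table(ph$genotype_id, ph$location)
  counts1 <- cell[cell > 0]
  hm <- function(x) length(x) / sum(1 / x)
  totals <- rowSums(cell)
  structure(list(Hm1 = hm(counts1), Hm2 = hm(totals[totals > 0]),
                 n_genotypes = nrow(cell),
                 n_locations = sum(colSums(cell) > 0)),
            class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf("design_summary: %d genotypes x %d locations; Hm1 = %.3f, Hm2 = %.3f\n",
              x$n_genotypes, x$n_locations, x$Hm1, x$Hm2))
  invisible(x)
}

#' EM-REML variance components for the multi-location trial model
#'
#' Fits `y = mu + g + l + g:l + rep(l) + e` with a fixed intercept and all
#' other terms random with independent identity covariance, by the EM form
#' of REML: per iteration, `V` is rebuilt, `P = V^-1 - V^-1 1 (1'V^-1 1)^-1
#' 1'V^-1`, and every component is updated by
#' `s_k^2 <- s_k^2 + s_k^4/q_k (y'P Z_k Z_k' P y - tr(Z_k' P Z_k))`,
#' which cannot go negative; estimates that collapse numerically are
#' clamped to zero. Convergence is declared when the largest relative
#' component change falls below `tol`.
#'
#' @param pheno long-format phenotype `data.frame` with `genotype_id`,
#'   `location`, `replicate`, `trait`, `value`.
#' @param trait trait to analyse.
#' @param max_iter iteration cap (default 500).
#' @param tol relative-change convergence tolerance (default 1e-8).
#' @return list of class `variance_components` with `sigma2_g`,
#'   `sigma2_loc`, `sigma2_gxe`, `sigma2_rep`, `sigma2_E`, `n_iter`,
#'   `converged`.
#' @export
fit_varcomp_reml <- function(pheno, trait, max_iter = 500, tol = 1e-8) {
  ph <- pheno[pheno$trait == trait & !is.na(pheno$value), ]
  if (!nrow(ph)) stop("no records for trait '", trait, "'")
  g <- factor(ph$genotype_id)
  l <- factor(ph$location)
  if (nlevels(g) < 2) stop("at least two genotypes are required")
  if (nlevels(l) < 2) stop("at least two locations are required")
  y <- ph$value
  n <- length(y)
  comp_names <- c("sigma2_g", "sigma2_loc", "sigma2_gxe", "sigma2_rep")
  out_zero <- function(n_iter, converged) {
    structure(as.list(c(setNames(rep(0, 4), comp_names), sigma2_E = 0,
                        n_iter = n_iter, converged = converged)),
              class = "variance_components")
  }
  if (var(y) == 0) return(out_zero(0L, TRUE))

  gl <- interaction(g, l, drop = TRUE)
  rl <- interaction(l, factor(ph$replicate), drop = TRUE)
  if (all(table(gl) == 1))
    stop("singular design: one observation per factor level everywhere; ",
         "genotype-by-location effects are confounded with residuals")
  Zs <- list(g = model.matrix(~ 0 + g),
             l = model.matrix(~ 0 + l),
             gl = model.matrix(~ 0 + gl),
             rl = model.matrix(~ 0 + rl))
  ZZt <- lapply(Zs, tcrossprod)
  q <- vapply(Zs, ncol, numeric(1))

  vy <- var(y)
  s2 <- c(rep(vy / 5, 4), E = vy / 5)  # equal-split start
  ones <- matrix(1, n, 1)
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    V <- diag(s2[5], n)
    for (k in 1:4) if (s2[k] > 0) V <- V + s2[k] * ZZt[[k]]
    Vi <- chol2inv(chol(V))
    Vi1 <- Vi %*% ones
    P <- Vi - tcrossprod(Vi1) / sum(Vi1)
    Py <- P %*% y
    s2_new <- s2
    score <- rep(0, 4)
    for (k in 1:4) {
      if (s2[k] == 0) next
      t1 <- as.numeric(crossprod(Py, ZZt[[k]] %*% Py))
      t2 <- sum(ZZt[[k]] * P)
      score[k] <- t1 - t2
      s2_new[k] <- s2[k] + s2[k]^2 / q[k] * (t1 - t2)
    }
    t1 <- sum(Py^2)
    t2 <- sum(diag(P))
    s2_new[5] <- s2[5] + s2[5]^2 / n * (t1 - t2)
    s2_new[s2_new < 0] <- 0
    denom <- pmax(abs(s2), tol * vy)
    delta <- max(abs(s2_new - s2) / denom)
    # EM decays hyperbolically towards the zero boundary; a persistently
    # negative REML score at a near-zero value means the optimum is the
    # boundary, so clamp instead of crawling
    clamp <- (s2_new[1:4] < 5e-3 * vy & score < 0 & it > 10) |
      s2_new[1:4] < 1e-10 * vy
    s2_new[1:4][clamp] <- 0
    s2 <- s2_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM-REML did not reach tolerance ", tol, " in ", max_iter,
            " iterations")
  structure(list(sigma2_g = s2[[1]], sigma2_loc = s2[[2]],
                 sigma2_gxe = s2[[3]], sigma2_rep = s2[[4]],
                 sigma2_E = s2[[5]], n_iter = n_iter, converged = converged),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components (EM-REML)\n")
  for (k in c("sigma2_g", "sigma2_loc", "sigma2_gxe", "sigma2_rep", "sigma2_E"))
    cat(sprintf("  %-10s %.6g\n", k, x[[k]]))
  cat(sprintf("  iterations: %d (converged: %s)\n", x$n_iter, x$converged))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_gxe / Hm1 + sigma2_E / Hm2)`, where
#' `Hm1` and `Hm2` are the harmonic-mean replication corrections of the
#' trial design (see [harmonic_means()]).
#'
#' @param vc a `variance_components` (or any list with `sigma2_g`,
#'   `sigma2_gxe`, `sigma2_E`).
#' @param d a `design_summary` (or list with `Hm1`, `Hm2` > 0).
#' @return heritability in `[0, 1]`.
#' @export
broad_sense_h2 <- function(vc, d) {
  s2g <- vc$sigma2_g; s2gxe <- vc$sigma2_gxe; s2E <- vc$sigma2_E
  stopifnot(s2g >= 0, s2gxe >= 0, s2E >= 0, d$Hm1 > 0, d$Hm2 > 0)
  denom <- s2g + s2gxe / d$Hm1 + s2E / d$Hm2
  if (denom == 0)
    stop("all variance components are zero; heritability is undefined")
  s2g / denom
}
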