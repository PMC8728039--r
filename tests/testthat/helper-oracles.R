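# Independent oracles used across tests: enumeration of tetrasomic gamete
# laws, balanced-ANOVA expected-mean-squares variance components, and
# batch-means Monte-Carlo standard errors.

# Build a one-genotype matrix (L loci x 4 chromatids) with the same dosage
# at every locus, e.g. dosage 2 -> AAOO everywhere.
uniform_parent <- function(n_loci, dosage) {
  g <- matrix(0L, n_loci, 4)
  if (dosage > 0) g[, seq_len(dosage)] <- 1L
  rownames(g) <- sprintf("M%03d", seq_len(n_loci))
  g
}

# Distribution of the gamete A-allele count (0, 1, 2) for a parent carrying
# `dosage` A alleles, by enumeration: with probability 1 - alpha two of the
# four chromatids are drawn without replacement (all 6 unordered pairs
# equally likely); with probability alpha one chromatid is drawn uniformly
# and duplicated.
gamete_count_dist <- function(dosage, alpha) {
  d <- dosage
  no_dr <- c(choose(4 - d, 2), d * (4 - d), choose(d, 2)) / 6
  dr <- c((4 - d) / 4, 0, d / 4)
  (1 - alpha) * no_dr + alpha * dr
}

# Offspring dosage distribution (0..4) for a cross, as the convolution of
# the two parental gamete-count distributions.
offspring_dosage_dist <- function(dosage1, dosage2, alpha) {
  g1 <- gamete_count_dist(dosage1, alpha)
  g2 <- gamete_count_dist(dosage2, alpha)
  conv <- rep(0, 5)
  for (i in 0:2) for (j in 0:2) conv[i + j + 1] <- conv[i + j + 1] + g1[i + 1] * g2[j + 1]
  conv
}

# ANOVA (expected-mean-squares) variance components for a balanced
# genotype x location x replicate-in-location trial; the independent
# oracle for REML on balanced data.
ems_varcomp <- function(d) {
  g <- length(unique(d$genotype_id))
  l <- length(unique(d$location))
  r <- length(unique(d$replicate))
  stopifnot(nrow(d) == g * l * r)
  a <- anova(lm(value ~ genotype_id * location + location:factor(replicate),
                data = d))
  ms <- a$`Mean Sq`
  rn <- rownames(a)
  MSG <- ms[rn == "genotype_id"]
  MSL <- ms[rn == "location"]
  MSGL <- ms[rn == "genotype_id:location"]
  MSR <- ms[rn == "location:factor(replicate)"]
  MSE <- ms[rn == "Residuals"]
  list(sigma2_g = (MSG - MSGL) / (l * r),
       sigma2_loc = (MSL - MSGL - MSR + MSE) / (g * r),
       sigma2_gxe = (MSGL - MSE) / r,
       sigma2_rep = (MSR - MSE) / g,
       sigma2_E = MSE)
}

# Balanced trial data drawn from the random-effects model the EMS oracle
# assumes (includes a replicate-within-location effect).
simulate_balanced_trial <- function(n_g, n_l, n_r, s2g, s2loc, s2gxe, s2rep,
                                    s2E, mu = 0) {
  d <- expand.grid(genotype_id = sprintf("G%02d", seq_len(n_g)),
                   location = sprintf("L%d", seq_len(n_l)),
                   replicate = seq_len(n_r), stringsAsFactors = FALSE)
  gi <- match(d$genotype_id, unique(d$genotype_id))
  li <- match(d$location, unique(d$location))
  ge <- rnorm(n_g, 0, sqrt(s2g))
  le <- rnorm(n_l, 0, sqrt(s2loc))
  gle <- matrix(rnorm(n_g * n_l, 0, sqrt(s2gxe)), n_g, n_l)
  re <- matrix(rnorm(n_l * n_r, 0, sqrt(s2rep)), n_l, n_r)
  d$trait <- "TW"
  d$value <- mu + ge[gi] + le[li] + gle[cbind(gi, li)] +
    re[cbind(li, d$replicate)] + rnorm(nrow(d), 0, sqrt(s2E))
  d
}

# Method-of-moments component estimates for a balanced g x l x r design,
# computed from cell/genotype/location means (no lm() needed at large g).
mom_components <- function(d) {
  cm <- tapply(d$value, list(d$genotype_id, d$location), mean)
  r <- nrow(d) / length(cm)
  gm <- rowMeans(cm); lm_ <- colMeans(cm); grand <- mean(cm)
  n_g <- length(gm); n_l <- length(lm_)
  within <- tapply(d$value, list(d$genotype_id, d$location), var)
  MSE <- mean(within)
  inter <- sweep(sweep(cm, 1, gm), 2, lm_) + grand
  MSGL <- r * sum(inter^2) / ((n_g - 1) * (n_l - 1))
  MSG <- n_l * r * sum((gm - grand)^2) / (n_g - 1)
  list(sigma2_g = (MSG - MSGL) / (n_l * r),
       sigma2_gxe = (MSGL - MSE) / r,
       sigma2_E = MSE)
}

# Batch-means Monte-Carlo standard error of a chain's mean.
mcse_batch <- function(chain, n_batches = 50) {
  m <- floor(length(chain) / n_batches)
  bm <- vapply(seq_len(n_batches),
               function(b) mean(chain[((b - 1) * m + 1):(b * m)]),
               numeric(1))
  sd(bm) / sqrt(n_batches)
}

# Dosage matrix of independent markers at uniform random allele
# frequencies; convenience generator for QC/BRR tests.
random_dosage <- function(n, p, freq_range = c(0.1, 0.9), missing_rate = 0) {
  pr <- runif(p, freq_range[1], freq_range[2])
  X <- vapply(pr, function(f) rbinom(n, 4, f), numeric(n))
  if (missing_rate > 0) X[runif(n * p) < missing_rate] <- NA
  rownames(X) <- sprintf("S%04d", seq_len(n))
  colnames(X) <- sprintf("M%04d", seq_len(p))
  X
}

# Phenotypes from an additive marker model at a target heritability.
marker_model_phenotype <- function(X, n_qtl = ncol(X), h2 = 0.5) {
  beta <- rep(0, ncol(X))
  qtl <- sample(ncol(X), n_qtl)
  beta[qtl] <- rnorm(n_qtl)
  g <- as.numeric(scale(X %*% beta, scale = FALSE))
  vg <- var(g)
  ve <- if (h2 >= 1) 0 else vg * (1 - h2) / h2
  list(y = g + rnorm(nrow(X), 0, sqrt(ve)), g = g, beta = beta)
}
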