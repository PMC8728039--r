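# Simulation of an autotetraploid clonal breeding program: tetrasomic
# meiosis with double reduction, overlapping-parent full-sib families,
# truncation selection across clonal generations, and multi-location
# phenotypes with genotype, location, GxE and residual variance components.

#' Configuration for the breeding-program simulator
#'
#' Defaults emulate a finite-size tetraploid potato breeding program: five
#' bi-parental full-sib families with overlapping parents forming an
#' unselected first clonal generation (T1) of 465 individuals, a
#' once-selected cohort (T2) of 138 and a multi-cycle selected cohort
#' (T3-7) of 62, phenotyped at three locations with one to two replicates
#' and five check cultivars planted everywhere.
#'
#' @param n_markers number of biallelic SNP markers.
#' @param family_sizes sizes of the five T1 full-sib families.
#' @param t2_size,t37_size sizes of the selected cohorts.
#' @param alpha_dr per-locus double-reduction probability; the theoretical
#'   maximum under random chromatid segregation is 1/6.
#' @param sigma2_g,sigma2_loc,sigma2_gxe,sigma2_E variance components of the
#'   phenotype model (genotype, location, genotype-by-location, residual),
#'   in squared trait units.
#' @param mu trait grand mean.
#' @param n_locations,n_reps multi-location trial dimensions.
#' @param n_checks number of check cultivars planted in every location.
#' @param selection_fraction fraction of each candidate cohort kept by
#'   truncation selection on the phenotype.
#' @param n_cycles total selection cycles simulated; cycle 1 produces T2 and
#'   later cycles accumulate into T3-7.
#' @param n_parents size of the crossing-parent pool used for the selected
#'   cohorts (the five named founders plus additional elite clones).
#' @param founder_freq_range range of the uniform distribution founder
#'   allele frequencies are drawn from.
#' @param n_chromosomes chromosomes markers are assigned to (labels only;
#'   loci segregate independently).
#' @param seed integer seed for the whole simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 2000,
                       family_sizes = c(A = 51, B = 51, C = 149, D = 152, E = 62),
                       t2_size = 138,
                       t37_size = 62,
                       alpha_dr = 0.05,
                       sigma2_g = 1,
                       sigma2_loc = 0.5,
                       sigma2_gxe = 0.5,
                       sigma2_E = 1,
                       mu = 0,
                       n_locations = 3,
                       n_reps = 2,
                       n_checks = 5,
                       selection_fraction = 0.3,
                       n_cycles = 3,
                       n_parents = 12,
                       founder_freq_range = c(0.1, 0.9),
                       n_chromosomes = 12,
                       seed = 1L) {
  family_sizes <- unlist(family_sizes)  # tolerate YAML maps
  cfg <- list(n_markers = n_markers, family_sizes = family_sizes,
              t2_size = t2_size, t37_size = t37_size, alpha_dr = alpha_dr,
              sigma2_g = sigma2_g, sigma2_loc = sigma2_loc,
              sigma2_gxe = sigma2_gxe, sigma2_E = sigma2_E, mu = mu,
              n_locations = n_locations, n_reps = n_reps, n_checks = n_checks,
              selection_fraction = selection_fraction, n_cycles = n_cycles,
              n_parents = n_parents, founder_freq_range = founder_freq_range,
              n_chromosomes = n_chromosomes, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  vs <- c("sigma2_g", "sigma2_loc", "sigma2_gxe", "sigma2_E")
  for (v in vs)
    if (cfg[[v]] < 0) stop("variance component ", v, " must be >= 0")
  if (any(cfg$family_sizes < 1)) stop("family sizes must be >= 1")
  if (length(cfg$family_sizes) != 5)
    stop("the simulator models exactly five T1 full-sib families")
  check_alpha_dr(cfg$alpha_dr)
  if (cfg$selection_fraction <= 0 || cfg$selection_fraction > 1)
    stop("selection_fraction must lie in (0, 1]")
  if (cfg$n_cycles < 2) stop("n_cycles must be >= 2 (cycle 1 produces T2)")
  if (cfg$n_parents < 6) stop("n_parents must be >= 6")
  invisible(cfg)
}

check_alpha_dr <- function(alpha_dr) {
  if (!is.numeric(alpha_dr) || length(alpha_dr) != 1L || is.na(alpha_dr) ||
      alpha_dr < 0 || alpha_dr > 1 / 6)
    stop("alpha_dr must lie in [0, 1/6]; 1/6 is the theoretical maximum ",
         "double-reduction rate under random chromatid segregation")
  invisible(alpha_dr)
}

#' Simulate founder genomes
#'
#' Each founder carries four allele copies (chromatids) per locus, coded 0/1
#' for the O/A alleles; its dosage is the count of A copies. Per-marker
#' allele frequencies are drawn once from `Uniform(freq_range)` and shared
#' by all founders, so the founder pool is an outbred panmictic stand-in.
#'
#' @param founder_ids character vector of founder names.
#' @param n_markers number of loci.
#' @param freq_range range of the per-marker allele-frequency distribution.
#' @param n_chromosomes chromosome labels assigned to markers (annotation
#'   only).
#' @return list with `genomes` (named list of n_markers x 4 0/1 matrices),
#'   `marker_ids`, `chromosome` and `freqs`.
#' @export
founder_genomes <- function(founder_ids, n_markers,
                            freq_range = c(0.1, 0.9), n_chromosomes = 12) {
  n_markers <- as.integer(n_markers)
  p <- runif(n_markers, freq_range[1], freq_range[2])
  marker_ids <- sprintf("M%05d", seq_len(n_markers))
  chromosome <- sort(rep_len(seq_len(n_chromosomes), n_markers))
  genomes <- lapply(founder_ids, function(id) {
    g <- matrix(as.integer(runif(n_markers * 4) < p), n_markers, 4)
    rownames(g) <- marker_ids
    g
  })
  names(genomes) <- founder_ids
  list(genomes = genomes, marker_ids = marker_ids,
       chromosome = chromosome, freqs = p)
}

#' Draw one gamete from a tetraploid genotype
#'
#' Tetrasomic meiosis per locus, independently across loci: with probability
#' `alpha_dr` a double-reduction event duplicates one uniformly chosen
#' allele copy into both gamete slots; otherwise two of the four copies are
#' drawn without replacement (random chromatid segregation).
#'
#' @param parent n_loci x 4 matrix of 0/1 allele states (1 = A allele).
#' @param alpha_dr double-reduction probability in `[0, 1/6]`.
#' @return n_loci x 2 matrix of gamete allele states.
#' @export
make_gamete <- function(parent, alpha_dr = 0) {
  parent <- as.matrix(parent)
  if (ncol(parent) != 4)
    stop("a tetraploid genotype must carry exactly 4 allele copies per locus")
  check_alpha_dr(alpha_dr)
  L <- nrow(parent)
  # the six unordered pairs of distinct chromatids, all equally likely
  pair_idx <- cbind(c(1L, 1L, 1L, 2L, 2L, 3L), c(2L, 3L, 4L, 3L, 4L, 4L))
  sel <- sample.int(6L, L, replace = TRUE)
  i1 <- pair_idx[sel, 1L]
  i2 <- pair_idx[sel, 2L]
  if (alpha_dr > 0) {
    dr <- runif(L) < alpha_dr
    if (any(dr)) {
      dup <- sample.int(4L, L, replace = TRUE)
      i1[dr] <- dup[dr]
      i2[dr] <- dup[dr]
    }
  }
  rows <- seq_len(L)
  g <- cbind(parent[cbind(rows, i1)], parent[cbind(rows, i2)])
  rownames(g) <- rownames(parent)
  g
}

#' Cross two tetraploid parents
#'
#' Each offspring unites one bivalent gamete from each parent, giving four
#' allele copies per locus and dosages in `0:4`.
#'
#' @param parent1,parent2 n_loci x 4 matrices of 0/1 allele states with
#'   identical marker sets.
#' @param n_offspring family size (0 gives an empty family).
#' @param alpha_dr double-reduction probability.
#' @return n_loci x 4 x n_offspring array of 0/1 allele states.
#' @export
cross <- function(parent1, parent2, n_offspring, alpha_dr = 0) {
  parent1 <- as.matrix(parent1)
  parent2 <- as.matrix(parent2)
  if (nrow(parent1) != nrow(parent2))
    stop(sprintf("parents carry different marker sets (%d vs %d loci)",
                 nrow(parent1), nrow(parent2)))
  n_offspring <- as.integer(n_offspring)
  out <- array(0L, dim = c(nrow(parent1), 4L, n_offspring),
               dimnames = list(rownames(parent1), NULL, NULL))
  for (i in seq_len(n_offspring)) {
    out[, 1:2, i] <- make_gamete(parent1, alpha_dr)
    out[, 3:4, i] <- make_gamete(parent2, alpha_dr)
  }
  out
}

#' Collapse 4-copy genotypes to allele dosages
#'
#' @param genotypes either one n_loci x 4 matrix or an n_loci x 4 x n array
#'   as returned by [cross()].
#' @return for a matrix, an integer vector of per-locus dosages; for an
#'   array, an n x n_loci integer matrix (samples in rows).
#' @export
genotype_dosage <- function(genotypes) {
  if (is.matrix(genotypes)) return(as.integer(rowSums(genotypes)))
  stopifnot(length(dim(genotypes)) == 3L)
  d <- apply(genotypes, 3L, rowSums)
  d <- t(d)
  storage.mode(d) <- "integer"
  colnames(d) <- dimnames(genotypes)[[1]]
  d
}

#' Simulate multi-location replicated phenotypes
#'
#' Plot values follow the random-effects trial model
#' `y_ijk = mu + g_i + l_j + (gl)_ij + e_ijk` with independent normal
#' location, genotype-by-location and residual draws at the configured
#' variances. True genetic values `g_i` are supplied (e.g. from marker
#' effects); check cultivars are simply genotypes flagged in `check_ids`
#' and, like all entries, appear in every location.
#'
#' @param genetic_values named numeric vector of true genetic values.
#' @param n_locations,n_reps trial dimensions; `n_reps` may be a single
#'   count or a vector recycled over genotype-by-location cells for
#'   unbalanced designs.
#' @param mu grand mean.
#' @param sigma2_loc,sigma2_gxe,sigma2_E variance components (>= 0).
#' @param check_ids optional subset of `names(genetic_values)` flagged as
#'   checks in the output.
#' @param trait trait label written into the table.
#' @return long-format `data.frame` with columns `genotype_id`, `location`,
#'   `replicate`, `trait`, `value`, `is_check`.
#' @export
simulate_phenotypes <- function(genetic_values, n_locations = 3, n_reps = 2,
                                mu = 0, sigma2_loc = 0.5, sigma2_gxe = 0.5,
                                sigma2_E = 1, check_ids = NULL,
                                trait = "TW") {
  if (is.null(names(genetic_values)))
    stop("genetic_values must be a named vector")
  for (v in c(sigma2_loc, sigma2_gxe, sigma2_E))
    if (v < 0) stop("variance components must be >= 0")
  ids <- names(genetic_values)
  n_g <- length(ids)
  locs <- paste0("L", seq_len(n_locations))
  loc_eff <- rnorm(n_locations, 0, sqrt(sigma2_loc))
  gxe <- matrix(rnorm(n_g * n_locations, 0, sqrt(sigma2_gxe)),
                n_g, n_locations)
  cells <- expand.grid(g = seq_len(n_g), l = seq_len(n_locations))
  reps <- rep_len(n_reps, nrow(cells))
  rows <- rep(seq_len(nrow(cells)), reps)
  rep_no <- sequence(reps)
  gi <- cells$g[rows]
  li <- cells$l[rows]
  value <- mu + genetic_values[gi] + loc_eff[li] + gxe[cbind(gi, li)] +
    rnorm(length(gi), 0, sqrt(sigma2_E))
  data.frame(genotype_id = ids[gi],
             location = locs[li],
             replicate = rep_no,
             trait = trait,
             value = as.numeric(value),
             is_check = ids[gi] %in% check_ids,
             stringsAsFactors = FALSE)
}

# Truncation selection on per-genotype phenotype means; returns selected ids.
truncation_select <- function(pheno_means, n_keep) {
  names(sort(pheno_means, decreasing = TRUE))[seq_len(n_keep)]
}

#' Simulate a finite-size tetraploid breeding program
#'
#' Builds the full study structure from founders: four named
#' parents/grandparents, three full-sib L-clones bridging the grandparents
#' into the T1 pedigree, five overlapping-parent T1 families, then
#' truncation selection on single-plot phenotypes producing the T2 cohort
#' and, over further cycles, the T3-7 cohort. Emits the dosage matrix with
#' generation/family labels, a multi-location phenotype table including
#' check cultivars, the pedigree and the true genetic values.
#'
#' Genetic values are additive in dosage: a marker-effect vector is drawn
#' normal and rescaled so the T1 cohort has genetic variance `sigma2_g`.
#' Selection candidates are phenotyped as single unreplicated plots
#' (genetic value plus residual noise), emulating visual field selection of
#' seedlings.
#'
#' @param config a [sim_config()].
#' @return list of class `breeding_program_sim` with elements `dosage`
#'   (a [dosage_matrix()]), `phenotypes`, `pedigree`, `genetic_values`,
#'   `marker_effects`, `chromosome` and `config`.
#' @export
simulate_breeding_program <- function(config = sim_config()) {
  validate_sim_config(config)
  if (config$selection_fraction * sum(config$family_sizes) < 1)
    stop("selection_fraction times the population size is below 1; ",
         "no individual could be selected")
  set.seed(config$seed)
  alpha <- config$alpha_dr

  named <- c("Bionica", "SarpoMira", "SW93-1015", "Desiree")
  extra <- paste0("ELITE", seq_len(max(config$n_parents - 5L, 1L)))
  check_ids <- paste0("CHECK", seq_len(config$n_checks))
  fg <- founder_genomes(c(named, "FounderX", extra, check_ids),
                        config$n_markers, config$founder_freq_range,
                        config$n_chromosomes)
  genomes <- fg$genomes

  pedigree <- data.frame(id = names(genomes), parent1 = NA_character_,
                         parent2 = NA_character_, stringsAsFactors = FALSE)
  add_offspring <- function(ids, p1, p2) {
    pedigree <<- rbind(pedigree,
                       data.frame(id = ids, parent1 = p1, parent2 = p2,
                                  stringsAsFactors = FALSE))
  }

  # bridge clones: L4/L17/L26 are full sibs of SW93-1015 x Desiree;
  # C08II69 has SW93-1015 as one parent
  lsibs <- cross(genomes[["SW93-1015"]], genomes[["Desiree"]], 3, alpha)
  for (k in seq_len(3)) genomes[[c("L4", "L17", "L26")[k]]] <- lsibs[, , k]
  add_offspring(c("L4", "L17", "L26"), "SW93-1015", "Desiree")
  genomes[["C08II69"]] <- cross(genomes[["SW93-1015"]], genomes[["FounderX"]],
                                1, alpha)[, , 1]
  add_offspring("C08II69", "SW93-1015", "FounderX")

  fam_parents <- list(A = c("Bionica", "SarpoMira"),
                      B = c("C08II69", "Bionica"),
                      C = c("L17", "SarpoMira"),
                      D = c("L26", "SarpoMira"),
                      E = c("L4", "SarpoMira"))
  t1_geno <- list()
  t1_meta <- list()
  for (f in names(fam_parents)) {
    sz <- config$family_sizes[[f]]
    pp <- fam_parents[[f]]
    off <- cross(genomes[[pp[1]]], genomes[[pp[2]]], sz, alpha)
    ids <- sprintf("T1%s%03d", f, seq_len(sz))
    for (k in seq_len(sz)) t1_geno[[ids[k]]] <- off[, , k]
    add_offspring(ids, pp[1], pp[2])
    t1_meta[[f]] <- data.frame(sample_id = ids, generation = "T1",
                               family = paste0("T1-", f), is_check = FALSE,
                               stringsAsFactors = FALSE)
  }

  # marker effects scaled so the T1 cohort has genetic variance sigma2_g
  dosage_of <- function(glist) {
    d <- t(vapply(glist, rowSums, numeric(config$n_markers)))
    storage.mode(d) <- "integer"
    d
  }
  X_t1 <- dosage_of(t1_geno)
  beta <- rnorm(config$n_markers)
  g_raw <- as.numeric(X_t1 %*% beta)
  s <- sd(g_raw)
  beta <- if (s > 0) beta * sqrt(config$sigma2_g) / s else beta * 0
  gv_of <- function(glist) {
    X <- dosage_of(glist)
    setNames(as.numeric(X %*% beta), rownames(X))
  }

  # selection cycles: random crosses within the crossing-parent pool,
  # unreplicated seedling phenotypes, truncation selection
  run_cycle <- function(parent_pool, target_size, label_prefix) {
    n_cand <- ceiling(target_size / config$selection_fraction)
    if (floor(n_cand * config$selection_fraction) < 1)
      stop("selection_fraction times the candidate population size is below 1")
    pool_ids <- names(parent_pool)
    n_crosses <- min(29L, choose(length(pool_ids), 2))
    pairs <- t(vapply(seq_len(n_crosses),
                      function(i) sample(pool_ids, 2), character(2)))
    sizes <- diff(round(seq(0, n_cand, length.out = n_crosses + 1)))
    cand <- list()
    ped1 <- character(0); ped2 <- character(0)
    for (ci in seq_len(n_crosses)) {
      if (sizes[ci] == 0) next
      off <- cross(parent_pool[[pairs[ci, 1]]], parent_pool[[pairs[ci, 2]]],
                   sizes[ci], alpha)
      ids <- sprintf("%sC%02dI%03d", label_prefix, ci, seq_len(sizes[ci]))
      for (k in seq_len(sizes[ci])) cand[[ids[k]]] <- off[, , k]
      ped1 <- c(ped1, rep(pairs[ci, 1], sizes[ci]))
      ped2 <- c(ped2, rep(pairs[ci, 2], sizes[ci]))
    }
    add_offspring(names(cand), ped1, ped2)
    gv <- gv_of(cand)
    seedling <- gv + rnorm(length(gv), 0, sqrt(config$sigma2_E))
    keep <- truncation_select(seedling, target_size)
    cand[keep]
  }

  parent_pool <- genomes[c(named, extra)]
  t2_geno <- run_cycle(parent_pool, config$t2_size, "T2")

  t37_geno <- list()
  n_later <- config$n_cycles - 1L
  per_cycle <- diff(round(seq(0, config$t37_size, length.out = n_later + 1)))
  current_pool <- t2_geno
  for (cy in seq_len(n_later)) {
    if (per_cycle[cy] == 0) next
    sel <- run_cycle(current_pool, per_cycle[cy], sprintf("T37Y%d", cy + 1L))
    t37_geno <- c(t37_geno, sel)
    current_pool <- sel
  }

  parent_geno <- genomes[named]
  check_geno <- genomes[check_ids]
  all_geno <- c(parent_geno, t1_geno, t2_geno, t37_geno, check_geno)
  meta <- rbind(
    data.frame(sample_id = named, generation = "parent", family = NA_character_,
               is_check = FALSE, stringsAsFactors = FALSE),
    do.call(rbind, t1_meta),
    data.frame(sample_id = names(t2_geno), generation = "T2",
               family = NA_character_, is_check = FALSE, stringsAsFactors = FALSE),
    data.frame(sample_id = names(t37_geno), generation = "T3-7",
               family = NA_character_, is_check = FALSE, stringsAsFactors = FALSE),
    data.frame(sample_id = check_ids, generation = "check",
               family = NA_character_, is_check = TRUE, stringsAsFactors = FALSE))
  X <- dosage_of(all_geno)
  colnames(X) <- fg$marker_ids
  dm <- dosage_matrix(X, meta)

  gv <- setNames(as.numeric(X %*% beta), rownames(X))
  pheno <- simulate_phenotypes(gv, n_locations = config$n_locations,
                               n_reps = config$n_reps, mu = config$mu,
                               sigma2_loc = config$sigma2_loc,
                               sigma2_gxe = config$sigma2_gxe,
                               sigma2_E = config$sigma2_E,
                               check_ids = check_ids, trait = "TW")
  pedigree <- pedigree[pedigree$id %in% c(rownames(X), "FounderX", extra,
                                          "L4", "L17", "L26", "C08II69"), ]
  rownames(pedigree) <- NULL
  structure(list(dosage = dm, phenotypes = pheno, pedigree = pedigree,
                 genetic_values = gv, marker_effects = setNames(beta, fg$marker_ids),
                 chromosome = setNames(fg$chromosome, fg$marker_ids),
                 config = config),
            class = "breeding_program_sim")
}

#' @export
print.breeding_program_sim <- function(x, ...) {
  cat("breeding_program_sim\n")
  print(x$dosage)
  cat(sprintf("  phenotype records: %d\n", nrow(x$phenotypes)))
  invisible(x)
}

#' Write all simulator outputs as delimited text
#'
#' @param sim a `breeding_program_sim`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of files written.
#' @export
write_breeding_program <- function(sim, dir) {
  stopifnot(inherits(sim, "breeding_program_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             sample_meta = file.path(dir, "sample_meta.tsv"),
             pedigree = file.path(dir, "pedigree.tsv"),
             genetic_values = file.path(dir, "genetic_values.tsv"))
  write_dosage(sim$dosage, files["genotypes"])
  write_phenotypes(sim$phenotypes, files["phenotypes"])
  write_sample_meta(sim$dosage$sample_meta, files["sample_meta"])
  write_pedigree(sim$pedigree, files["pedigree"])
  write.table(data.frame(sample_id = names(sim$genetic_values),
                         genetic_value = as.numeric(sim$genetic_values)),
              files["genetic_values"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(files)
}
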