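# Tetrasomic meiosis, crossing, phenotype simulation and the full
# breeding-program generator.

test_that("gametes from homozygous parents are fixed and alleles are conserved", {
  set.seed(11)
  aaaa <- uniform_parent(50, 4)
  g <- make_gamete(aaaa, alpha_dr = 1 / 6)
  expect_true(all(rowSums(g) == 2))
  oooo <- uniform_parent(50, 0)
  expect_true(all(rowSums(make_gamete(oooo, 0.1)) == 0))
  # without double reduction a gamete never carries more A copies than
  # min(2, parental dosage); a simplex parent yields zero AA gametes exactly
  for (d in 0:4) {
    par <- uniform_parent(5000, d)
    counts <- rowSums(make_gamete(par, alpha_dr = 0))
    expect_lte(max(counts), min(2, d))
    expect_gte(min(counts), max(0, d - 2))
  }
  # with double reduction one parental allele may be duplicated
  simplex <- uniform_parent(20000, 1)
  counts_dr <- rowSums(make_gamete(simplex, alpha_dr = 1 / 6))
  expect_gt(sum(counts_dr == 2), 0)
  expect_error(make_gamete(simplex, 0.2), "1/6")
  expect_error(make_gamete(simplex, -0.01), "1/6")
})

test_that("duplex and simplex gamete frequencies match the enumeration oracle", {
  n <- 50000
  for (alpha in c(0, 1 / 6)) {
    for (dosage in c(1, 2)) {
      set.seed(101 + dosage)
      par <- uniform_parent(n, dosage)
      counts <- tabulate(rowSums(make_gamete(par, alpha)) + 1L, nbins = 3)
      expected <- gamete_count_dist(dosage, alpha)
      keep <- expected > 0
      chi <- suppressWarnings(
        chisq.test(counts[keep], p = expected[keep] / sum(expected[keep])))
      expect_gt(chi$p.value, 0.01)
    }
  }
  # headline laws: duplex AA frequency 1/6 at alpha = 0; simplex AA
  # frequency alpha / 4
  expect_equal(gamete_count_dist(2, 0)[3], 1 / 6)
  expect_equal(gamete_count_dist(1, 1 / 6)[3], (1 / 6) / 4)
})

test_that("cross unites one gamete from each parent", {
  set.seed(21)
  aaaa <- uniform_parent(30, 4)
  oooo <- uniform_parent(30, 0)
  off <- cross(aaaa, oooo, 8, alpha_dr = 0.1)
  expect_equal(dim(off), c(30, 4, 8))
  expect_true(all(genotype_dosage(off) == 2))
  empty <- cross(aaaa, oooo, 0)
  expect_equal(dim(empty)[3], 0)
  expect_error(cross(aaaa, uniform_parent(10, 0), 2), "30.*10|10.*30")
})

test_that("duplex x duplex offspring dosages follow the convolution oracle", {
  n_loci <- 10
  n_off <- 5000  # loci segregate independently: 50,000 draws in total
  for (alpha in c(0, 1 / 6)) {
    set.seed(31)
    p1 <- uniform_parent(n_loci, 2)
    off <- cross(p1, p1, n_off, alpha)
    dos <- as.vector(genotype_dosage(off))
    counts <- tabulate(dos + 1L, nbins = 5)
    expected <- offspring_dosage_dist(2, 2, alpha)
    chi <- suppressWarnings(chisq.test(counts, p = expected))
    expect_gt(chi$p.value, 0.01)
  }
})

test_that("phenotype simulator reproduces its variance components", {
  # no non-genetic variance: every replicate equals mu + g exactly
  g <- setNames(c(-1, 0, 2), c("a", "b", "c"))
  ph <- simulate_phenotypes(g, n_locations = 2, n_reps = 2, mu = 10,
                            sigma2_loc = 0, sigma2_gxe = 0, sigma2_E = 0)
  expect_equal(ph$value, 10 + as.numeric(g[ph$genotype_id]))

  # method-of-moments recovery within 10% at 2000 genotypes x 3 x 2
  set.seed(41)
  gv <- setNames(rnorm(2000), sprintf("G%04d", 1:2000))
  ph <- simulate_phenotypes(gv, n_locations = 3, n_reps = 2, mu = 0,
                            sigma2_loc = 0.5, sigma2_gxe = 0.5, sigma2_E = 1)
  est <- mom_components(ph)
  expect_lt(abs(est$sigma2_g - var(gv)) / var(gv), 0.10)
  expect_lt(abs(est$sigma2_gxe - 0.5) / 0.5, 0.10)
  expect_lt(abs(est$sigma2_E - 1), 0.10)

  # no genetic signal: genotype means uncorrelated with the labels' values
  set.seed(42)
  g0 <- setNames(rep(0, 500), sprintf("G%03d", 1:500))
  ph0 <- simulate_phenotypes(g0 + rnorm(500) * 0, n_locations = 3, n_reps = 2)
  means <- tapply(ph0$value, ph0$genotype_id, mean)
  fake_g <- rnorm(500)
  expect_lt(abs(cor(means[sprintf("G%03d", 1:500)], fake_g)), 0.15)

  expect_error(simulate_phenotypes(g, sigma2_E = -1), ">= 0")
})

test_that("breeding program has the study structure and is reproducible", {
  cfg <- sim_config(n_markers = 200, seed = 77)
  sim <- simulate_breeding_program(cfg)
  meta <- sim$dosage$sample_meta
  gen <- table(meta$generation)
  expect_equal(as.integer(gen[c("T1", "T2", "T3-7")]), c(465, 138, 62))
  expect_equal(as.integer(gen["parent"]), 4)
  expect_equal(as.integer(gen["check"]), 5)
  # T1 family sizes and labels partition the sample set
  fam <- table(meta$family[meta$generation == "T1"])
  expect_equal(as.integer(fam[paste0("T1-", c("A", "B", "C", "D", "E"))]),
               c(51, 51, 149, 152, 62))
  expect_equal(sum(gen), n_samples(sim$dosage))
  # every non-founder has exactly two recorded parents
  ped <- sim$pedigree
  non_founder <- ped[!is.na(ped$parent1), ]
  expect_true(all(!is.na(non_founder$parent2)))
  expect_true(all(meta$sample_id[meta$generation %in% c("T1", "T2", "T3-7")]
                  %in% ped$id))
  # same seed, bit-identical output
  sim2 <- simulate_breeding_program(cfg)
  expect_identical(sim$dosage$dosages, sim2$dosage$dosages)
  expect_identical(sim$phenotypes, sim2$phenotypes)
  expect_error(simulate_breeding_program(
    sim_config(selection_fraction = 1e-4)), "below 1")
})

test_that("truncation selection raises the mean genetic value of T2 over T1", {
  small <- function(sf, seed)
    sim_config(n_markers = 100,
               family_sizes = c(A = 10, B = 10, C = 30, D = 30, E = 12),
               t2_size = 27, t37_size = 12, selection_fraction = sf,
               seed = seed)
  diff_gv <- function(sf, seed) {
    sim <- simulate_breeding_program(small(sf, seed))
    meta <- sim$dosage$sample_meta
    gv <- sim$genetic_values
    mean(gv[meta$sample_id[meta$generation == "T2"]]) -
      mean(gv[meta$sample_id[meta$generation == "T1"]])
  }
  sel <- vapply(1:50, function(s) diff_gv(0.3, s), numeric(1))
  none <- vapply(1:50, function(s) diff_gv(1, s), numeric(1))
  expect_gt(mean(sel), 0)
  expect_gt(mean(sel), mean(none))
  expect_lt(abs(mean(none)), 0.3)  # no selection differential at fraction 1
})
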