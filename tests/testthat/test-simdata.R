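test_that("pedigree simulation is deterministic and counts match the design", {
  cfg <- sim_config(n_founders = 10, n_generations = 0, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 10L)
  expect_true(all(attr(ped, "sire_idx") == 0L))

  cfg2 <- sim_config(n_founders = 30, n_generations = 2, seed = 1)
  expect_identical(simulate_pedigree(cfg2), simulate_pedigree(cfg2))

  # independent hand count of the mating design: females alternate with
  # birth order, every female of generation g-1 produces offspring_per_dam
  cfg3 <- sim_config(n_founders = 20, n_generations = 3,
                     offspring_per_dam = 2, seed = 7)
  ped3 <- simulate_pedigree(cfg3)
  n_exp <- 20L
  n_female <- 10L                       # founders: half male, half female
  for (g in 1:3) {
    n_off <- n_female * 2L
    n_exp <- n_exp + n_off
    n_female <- if (g == 3) n_off else ceiling(n_off / 2)  # final gen all F
  }
  expect_equal(nrow(ped3), n_exp)
  expect_error(simulate_pedigree(sim_config(n_founders = 5,
                                            n_founder_males = 5,
                                            n_generations = 1)),
               "no males|no females|sexes")
})

test_that("gene dropping respects founder frequencies and Mendelian rules", {
  cfg <- sim_config(n_founders = 1000, n_generations = 0, n_snps = 400,
                    maf_range = c(0.3, 0.5), seed = 3)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  freq <- colMeans(g$dosage) / 2
  truef <- attr(g, "founder_freq")
  # empirical frequencies within ~4.4 binomial SDs of the draw (400 loci)
  z <- (freq - truef) / sqrt(truef * (1 - truef) / (2 * 1000))
  expect_lt(max(abs(z)), 4.5)

  cfg2 <- sim_config(n_founders = 20, n_generations = 2, n_snps = 150,
                     seed = 11)
  ped2 <- simulate_pedigree(cfg2)
  g2 <- simulate_genotypes(ped2, cfg2)
  si <- attr(ped2, "sire_idx"); di <- attr(ped2, "dam_idx")
  for (i in which(si > 0L)) {
    hom <- g2$dosage[si[i], ] == 2
    expect_true(all(g2$dosage[i, hom] >= 1))
  }
  expect_identical(simulate_genotypes(ped2, cfg2)$dosage, g2$dosage)
})

test_that("forced identical gamete draws clone a genotype row", {
  hap1 <- c(1L, 0L, 1L, 0L); hap2 <- c(0L, 1L, 1L, 0L)
  u <- c(0.2, 0.7, 0.4, 0.9)
  g1 <- rrmgwas:::.transmit(hap1, hap2, u)
  g2 <- rrmgwas:::.transmit(hap1, hap2, u)
  expect_identical(g1, g2)
  expect_identical(g1, c(1L, 1L, 1L, 0L))
})

test_that("parent-offspring genomic relationship is near one half", {
  cfg <- sim_config(n_founders = 60, n_generations = 1, n_snps = 2000,
                    maf_range = c(0.2, 0.5), seed = 13)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  G <- grm_vanraden(g)
  si <- attr(ped, "sire_idx")
  po <- cbind(which(si > 0L), si[si > 0L])
  expect_equal(mean(G[po]), 0.5, tolerance = 0.06)
})

test_that("simulated coefficients carry the configured covariances", {
  k3 <- diag(c(4, 2, 1))
  cfg <- sim_config(n_founders = 5000, n_generations = 0, basis_order = 2,
                    G_true = k3, P_true = diag(3), n_snps = 10, seed = 21)
  ped <- simulate_pedigree(cfg)
  tr <- simulate_rr_coefficients(ped, cfg)
  emp <- cov(tr$traits$my$a)
  expect_equal(emp, k3, tolerance = 0.15)

  z <- sim_config(n_founders = 50, n_generations = 0, basis_order = 1,
                  G_true = matrix(0, 2, 2), P_true = diag(2), n_snps = 10,
                  seed = 2)
  trz <- simulate_rr_coefficients(simulate_pedigree(z), z)
  expect_true(all(trz$traits$my$a == 0))

  bad <- sim_config(n_founders = 10, n_generations = 0, basis_order = 1,
                    n_snps = 10, seed = 2)
  bad$G_true <- matrix(c(1, 2, 2, 1), 2)   # indefinite
  expect_error(simulate_rr_coefficients(simulate_pedigree(z), bad),
               "G_true")
})

test_that("an explicit singular relationship matrix yields identical twins", {
  cfg <- sim_config(n_founders = 2, n_generations = 0, basis_order = 1,
                    n_snps = 10, seed = 31)
  ped <- simulate_pedigree(cfg)
  A_twin <- matrix(1, 2, 2)
  cors <- vapply(seq_len(400), function(r) {
    cfg$seed <- cfg$seed + r
    a <- simulate_rr_coefficients(ped, cfg, A = A_twin)$traits$my$a
    a[1, 1] - a[2, 1]
  }, numeric(1))
  expect_lt(max(abs(cors)), 1e-8)
})

test_that("half-sib coefficient correlation matches A = 0.25 over replicates", {
  cfg <- sim_config(n_founder_males = 1, offspring_per_dam = 2,
                    pedigree_design = "halfsib", basis_order = 0,
                    G_true = matrix(4), P_true = matrix(1), n_snps = 10,
                    seed = 41)
  ped <- simulate_pedigree(cfg)
  draws <- t(vapply(seq_len(2000), function(r) {
    cfg$seed <- cfg$seed + r
    simulate_rr_coefficients(ped, cfg)$traits$my$a[2:3, 1]
  }, numeric(2)))
  # 3 Monte-Carlo standard errors of a correlation at n = 2000
  expect_lt(abs(cor(draws)[1, 2] - 0.25), 0.07)
})

test_that("test-day records decompose exactly when noise is switched off", {
  k <- 2L
  cfg <- sim_config(n_founders = 12, n_generations = 1, basis_order = k - 1L,
                    G_true = diag(k) * 3, P_true = diag(k) * 2,
                    sigma_e2_true = 1e-12,
                    fixed_effect_spec = list(htd_sd = 0, age_sd = 0,
                                             season_sd = 0, n_age_classes = 2L),
                    trait_mean = c(my = 0, fp = 0, pp = 0, scs = 0),
                    n_snps = 10, seed = 17)
  ped <- simulate_pedigree(cfg)
  tr <- simulate_rr_coefficients(ped, cfg)
  rec <- simulate_test_day_records(tr, ped, cfg)
  basis <- legendre_basis(k - 1L)
  phi <- legendre_matrix(rec$dim, basis)
  expected <- rowSums(phi * (tr$traits$my$a[rec$cow_id, ] +
                               tr$traits$my$p[rec$cow_id, ]))
  # my is floored at 0.1 kg; compare where the floor is not binding
  free <- expected > 0.2
  expect_gt(sum(free), 10)
  expect_equal(rec$my[free], expected[free], tolerance = 1e-4)

  zero <- sim_config(n_founders = 12, n_generations = 1, basis_order = 1,
                     G_true = matrix(0, 2, 2), P_true = matrix(0, 2, 2),
                     sigma_e2_true = 1e-30,
                     fixed_effect_spec = list(htd_sd = 0, age_sd = 0,
                                              season_sd = 0, n_age_classes = 2L),
                     trait_mean = c(my = 5, fp = 5, pp = 5, scs = 5),
                     n_snps = 10, seed = 19)
  pz <- simulate_pedigree(zero)
  rz <- simulate_test_day_records(simulate_rr_coefficients(pz, zero), pz, zero)
  expect_equal(rz$my, rep(5, nrow(rz)), tolerance = 1e-9)

  bad <- cfg
  bad$test_day_schedule <- c(2L, 100L)
  expect_error(rrmgwas:::.validate_sim_config(bad),
               "\\[5, 305\\]")
})

test_that("phenotypic variance at a DIM matches the analytic decomposition", {
  G <- diag(c(6, 2, 1)); P <- diag(c(8, 3, 1))
  cfg <- sim_config(n_founders = 1500, n_generations = 0, basis_order = 2,
                    G_true = G, P_true = P, sigma_e2_true = 5,
                    fixed_effect_spec = list(htd_sd = 0, age_sd = 0,
                                             season_sd = 0, n_age_classes = 2L),
                    n_snps = 10, seed = 23)
  ped <- simulate_pedigree(cfg)
  tr <- simulate_rr_coefficients(ped, cfg)
  rec <- simulate_test_day_records(tr, ped, cfg)
  basis <- legendre_basis(2)
  for (d in c(45L, 165L)) {
    phi <- legendre_row(d, basis)
    v_exp <- drop(phi %*% G %*% phi + phi %*% P %*% phi) + 5
    v_obs <- var(rec$my[rec$dim == d])
    expect_equal(v_obs, v_exp, tolerance = 0.12 * v_exp)
  }
})

test_that("derived trait columns track the primary traits", {
  cfg <- sim_config(n_founders = 40, n_generations = 1, n_snps = 10, seed = 29)
  ped <- simulate_pedigree(cfg)
  rec <- simulate_test_day_records(simulate_rr_coefficients(ped, cfg), ped, cfg)
  expect_equal(rec$fy, rec$fp * rec$my / 100, tolerance = 0.05)
  rec2 <- derive_traits(rec)
  expect_equal(rec2$scs, compute_scs(rec2$scc))
})

test_that("datasets round-trip through their writers and readers", {
  cfg <- sim_config(n_founders = 24, n_generations = 1, n_snps = 40, seed = 37)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  tr <- simulate_rr_coefficients(ped, cfg, g)
  rec <- derive_traits(simulate_test_day_records(tr, ped, cfg))
  out <- withr::local_tempdir()
  paths <- write_dataset(rec, ped, g, out, truth = tr)

  r2 <- read_phenotypes(paths[["phenotypes"]])
  expect_equal(nrow(r2), nrow(rec))
  expect_equal(r2$my, rec$my, tolerance = 1e-12)
  expect_equal(r2$test_date, rec$test_date)

  p2 <- read_pedigree(paths[["pedigree"]])
  expect_equal(p2$id, ped$id)
  expect_identical(attr(p2, "sire_idx"), attr(ped, "sire_idx"))

  vcf_lines <- readLines(paths[["vcf"]])
  expect_equal(vcf_lines[1], "##fileformat=VCFv4.2")
  expect_equal(sum(grepl("^##contig", vcf_lines)),
               length(unique(g$variants$chrom)))
  g2 <- read_vcf(paths[["vcf"]])
  expect_equal(g2$dosage, g$dosage, ignore_attr = TRUE)
  expect_equal(g2$variants$pos, g$variants$pos)

  truth <- utils::read.delim(paths[["truth"]])
  expect_equal(nrow(truth), length(sim_cows(ped)))
})
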