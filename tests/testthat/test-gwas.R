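# shared founder-population fixture for association tests
gwas_fixture <- function(n = 300, m = 400, seed = 5, maf = c(0.1, 0.5)) {
  cfg <- sim_config(n_founders = n, n_generations = 0, n_snps = m,
                    maf_range = maf, seed = seed)
  simulate_genotypes(simulate_pedigree(cfg), cfg)
}

test_that("Hardy-Weinberg exact test matches the enumeration oracle", {
  cases <- rbind(c(50, 0, 0), c(10, 20, 10), c(3, 1, 40), c(0, 2, 0),
                 c(7, 7, 7), c(1, 0, 1), c(12, 1, 12))
  for (i in seq_len(nrow(cases))) {
    expect_equal(hwe_exact_test(cases[i, 1], cases[i, 2], cases[i, 3]),
                 oracle_hwe(cases[i, 1], cases[i, 2], cases[i, 3]),
                 tolerance = 1e-10, label = paste(cases[i, ], collapse = "/"))
  }
  expect_equal(hwe_exact_test(50, 0, 0), 1)
  expect_lt(hwe_exact_test(0, 100, 0), 1e-6)
  expect_error(hwe_exact_test(-1, 0, 3), "non-negative")
  # exhaustive small-n sweep
  for (n in c(5L, 12L)) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hwe_exact_test(nAA, nAa, naa),
                   oracle_hwe(nAA, nAa, naa), tolerance = 1e-10)
    }
  }
})

test_that("genotype QC applies the four filters at their thresholds", {
  g <- gwas_fixture(n = 200, m = 60, seed = 7)
  d <- g$dosage
  # engineer failures: SNP 1 low call rate (0.89), SNP 2 exactly 0.90 kept,
  # SNP 3 low MAF, SNP 4 extreme heterozygote excess; sample 1 call rate 0.94
  d[1:22, 1] <- NA                        # 178/200 = 0.89
  d[1:20, 2] <- NA                        # 180/200 = 0.90
  d[, 3] <- rep(c(rep(0, 19), 1), 10)     # 10 het carriers: maf 0.025
  d[, 4] <- 1                             # all heterozygous
  d[1, 5:28] <- NA                        # sample 1: 36/60 present = 0.6
  g2 <- geno_matrix(g$samples, g$variants, d)
  out <- genotype_qc(g2)
  expect_equal(unname(out$report["samples_call_rate"]), 1L)
  expect_false("snp00001" %in% out$genotypes$variants$id)
  expect_true("snp00002" %in% out$genotypes$variants$id)
  expect_false("snp00003" %in% out$genotypes$variants$id)
  expect_false("snp00004" %in% out$genotypes$variants$id)
  all_na <- geno_matrix(g$samples, g$variants,
                        matrix(NA_real_, nrow(d), ncol(d)))
  expect_error(genotype_qc(all_na), "all samples")
})

test_that("VanRaden GRM has the expected structure", {
  g <- gwas_fixture(n = 400, m = 1500, seed = 9, maf = c(0.2, 0.5))
  G <- grm_vanraden(g)
  expect_equal(G, t(G))
  # mean diagonal ~ 1 under HWE with many markers
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  expect_equal(mean(G[upper.tri(G)]), 0, tolerance = 0.01)
  # identical genotype rows give identical GRM rows and diagonals
  d <- g$dosage; d[2, ] <- d[1, ]
  G2 <- grm_vanraden(geno_matrix(g$samples, g$variants, d))
  expect_equal(G2[1, ], G2[2, ], ignore_attr = TRUE)
  expect_equal(G2[1, 1], G2[2, 2])
  mono <- geno_matrix(c("a", "b"), g$variants[1:2, ],
                      matrix(2, 2, 2))
  expect_error(grm_vanraden(mono), "monomorphic")
})

test_that("genotype PCA separates divergent subpopulations", {
  set.seed(31)
  n <- 120; m <- 600
  f1 <- runif(m, 0.05, 0.5)
  shift <- rbinom(m, 1, 0.4) * runif(m, 0.2, 0.4) * sign(runif(m) - 0.5)
  f2 <- pmin(pmax(f1 + shift, 0.02), 0.98)
  d <- rbind(sapply(f1, function(p) rbinom(n / 2, 2, p)),
             sapply(f2, function(p) rbinom(n / 2, 2, p)))
  g <- geno_matrix(sprintf("s%03d", 1:n),
                   data.frame(chrom = "chr1", pos = seq_len(m) * 1000,
                              id = sprintf("v%04d", 1:m), ref = "A",
                              alt = "C"), d)
  pca <- pca_from_genotypes(g, k = 4)
  pc1 <- pca$coordinates[, 1]
  groups <- rep(c(1, 2), each = n / 2)
  expect_true(abs(cor(pc1, groups)) > 0.9)
  expect_true(all(diff(pca$proportions) <= 1e-12))
  expect_lte(sum(pca$proportions), 1 + 1e-12)
  expect_equal(sum(pca$values), sum(diag(grm_vanraden(g))))
  expect_error(pca_from_genotypes(g, k = 1000), "rank")
})

test_that("MLM with sigma_a2 forced to zero equals per-marker OLS", {
  g <- gwas_fixture(n = 50, m = 120, seed = 13)
  set.seed(13)
  y <- rnorm(50)
  res <- mlm_scan(g, y, n_pcs = 2, delta_override = Inf)
  pcs <- pca_from_genotypes(g, k = 2)$coordinates
  M <- rrmgwas:::.imputed_dosage(g)
  for (j in c(1, 17, 60, 120)) {
    ols <- summary(lm(y ~ pcs + M[, j]))$coefficients
    expect_equal(res$p[j], ols["M[, j]", 4], tolerance = 1e-9)
    expect_equal(res$effect[j], ols["M[, j]", 1], tolerance = 1e-9)
  }
  # duplicated marker column gives identical rows
  g$dosage[, 2] <- g$dosage[, 1]
  res2 <- mlm_scan(g, y, n_pcs = 2, delta_override = Inf)
  expect_equal(res2$p[1], res2$p[2])
  expect_equal(res2$effect[1], res2$effect[2])
  expect_error(mlm_scan(g, rep(1, 50)), "constant")
})

test_that("MLM scans are invariant to sample permutation", {
  g <- gwas_fixture(n = 80, m = 150, seed = 17)
  set.seed(17)
  y <- rnorm(80) + rowMeans(g$dosage[, 1:5])
  r1 <- mlm_scan(g, y)
  perm <- sample(80)
  g2 <- geno_matrix(g$samples[perm], g$variants, g$dosage[perm, ])
  r2 <- mlm_scan(g2, y[perm])
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
})

test_that("genomic inflation factor is calibrated and monotone", {
  p <- (seq_len(1000) - 0.5) / 1000
  expect_equal(genomic_lambda(p), 1, tolerance = 1e-3)
  expect_gt(genomic_lambda(p / 2), genomic_lambda(p))
  expect_error(genomic_lambda(c(p, 0)), "\\(0, 1\\]")
  expect_error(genomic_lambda(p[1:50]), "at least 100")
})

test_that("significance classes follow the two fixed thresholds", {
  expect_equal(classify_significance(c(1e-9, 1e-7, 1e-5, 0.5)),
               c("genome_wide", "suggestive", "ns", "ns"))
  expect_equal(classify_significance(5e-8), "suggestive")  # boundary
  expect_equal(classify_significance(5e-6), "ns")
})

test_that("a planted QTL is detected by the MLM against polygenic background", {
  g <- gwas_fixture(n = 400, m = 800, seed = 19, maf = c(0.1, 0.5))
  set.seed(19)
  M <- rrmgwas:::.imputed_dosage(g)
  Z <- scale(M)
  y <- drop(Z %*% rnorm(800, 0, sqrt(0.35 / 800))) + Z[, 123] * sqrt(0.2) +
    rnorm(400, 0, sqrt(0.45))
  res <- mlm_scan(g, y)
  expect_lt(res$p[123], 5e-8)
  expect_equal(res$class[123], "genome_wide")
  lam <- genomic_lambda(res$p)
  expect_gt(lam, 0.8); expect_lt(lam, 1.25)
})
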