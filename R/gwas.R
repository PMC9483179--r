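#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test given the allele counts: the p-value is the sum of
#' the probabilities of all heterozygote counts (of the same parity as the
#' observed one) that are no more probable than the observed count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes")
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n - nA
  if (nA == 0 || nB == 0) return(1)
  h <- seq.int(nA %% 2, min(nA, nB), by = 2)
  logp <- h * log(2) + lfactorial(n) + lfactorial(nA) + lfactorial(nB) -
    lfactorial((nA - h) / 2) - lfactorial(h) - lfactorial((nB - h) / 2) -
    lfactorial(2 * n)
  p_all <- exp(logp - max(logp))
  p_all <- p_all / sum(p_all)
  p_obs <- p_all[match(n_Aa, h)]
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-9)]))
}

#' Genotype quality control
#'
#' Removes samples with call rate below `sample_cr`, then SNPs with call
#' rate below `snp_cr`, Hardy-Weinberg exact-test p-value below `hwe_p`, or
#' minor allele frequency below `maf`.
#'
#' @param g A [geno_matrix()].
#' @param sample_cr,snp_cr,hwe_p,maf QC thresholds (defaults 0.95, 0.90,
#'   1e-6, 0.05).
#' @return List with the filtered `geno_matrix` and a `report` of per-rule
#'   removal counts.
#' @export
genotype_qc <- function(g, sample_cr = 0.95, snp_cr = 0.90,
                        hwe_p = 1e-6, maf = 0.05) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosage
  cr_sample <- rowMeans(!is.na(d))
  drop_sample <- cr_sample < sample_cr
  if (all(drop_sample)) stop("all samples removed by call-rate filter")
  d <- d[!drop_sample, , drop = FALSE]

  cr_snp <- colMeans(!is.na(d))
  n_AA <- colSums(d == 2, na.rm = TRUE)   # AA = alt homozygote
  n_Aa <- colSums(d == 1, na.rm = TRUE)
  n_aa <- colSums(d == 0, na.rm = TRUE)
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    hwe_exact_test(n_AA[j], n_Aa[j], n_aa[j])
  }, numeric(1))
  freq <- colMeans(d, na.rm = TRUE) / 2
  maf_obs <- pmin(freq, 1 - freq)
  fail_cr <- cr_snp < snp_cr
  fail_hwe <- hwe < hwe_p
  fail_maf <- maf_obs < maf
  keep <- !(fail_cr | fail_hwe | fail_maf)

  out <- geno_matrix(g$samples[!drop_sample], g$variants[keep, , drop = FALSE],
                     d[, keep, drop = FALSE])
  list(genotypes = out,
       report = c(samples_call_rate = sum(drop_sample),
                  snp_call_rate = sum(fail_cr),
                  snp_hwe = sum(fail_hwe),
                  snp_maf = sum(fail_maf),
                  snps_kept = sum(keep)))
}

# dosage matrix with per-SNP mean imputation of missing genotypes
.imputed_dosage <- function(g) {
  d <- g$dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  d
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' G = Z Z' / (2 sum p_j (1 - p_j)) with Z the allele-frequency-centered
#' dosage matrix; missing dosages are mean-imputed per SNP.
#'
#' @param g A QC'd [geno_matrix()].
#' @return Symmetric sample x sample matrix.
#' @export
grm_vanraden <- function(g) {
  d <- .imputed_dosage(g)
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs monomorphic; GRM denominator is zero")
  Z <- sweep(d[, poly, drop = FALSE], 2L, 2 * p[poly], `-`)
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(g$samples, g$samples)
  G
}

#' Principal components from genotypes
#'
#' Eigendecomposition of the VanRaden GRM; per-component variance
#' proportions are lambda_i / sum(lambda).
#'
#' @param g A QC'd [geno_matrix()] (or supply a precomputed `grm`).
#' @param k Number of components to return.
#' @param grm Optional precomputed GRM.
#' @return List with `values`, `coordinates` (samples x k eigenvectors) and
#'   `proportions`.
#' @export
pca_from_genotypes <- function(g, k = 10L, grm = NULL) {
  if (is.null(grm)) grm <- grm_vanraden(g)
  e <- eigen(grm, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  rank <- sum(vals > max(vals) * 1e-10)
  if (k > rank) stop("k exceeds GRM rank (", rank, ")")
  list(values = e$values,
       coordinates = e$vectors[, seq_len(k), drop = FALSE],
       proportions = vals / sum(vals))
}

#' Mixed linear model association scan (P3D)
#'
#' Null model y = W b + a + e with a ~ N(0, G sigma_a2) is fitted once by
#' REML through the spectral decomposition of the GRM; each marker is then
#' tested by generalized least squares in the rotated (whitened) space with
#' a t-test on the substitution effect. Covariates default to an intercept
#' plus the top principal components.
#'
#' @param g A QC'd [geno_matrix()].
#' @param y Response (one value per sample), e.g. a DIM-specific EBV.
#' @param n_pcs Number of genotype principal components as covariates.
#' @param grm Optional precomputed GRM.
#' @param covariates Optional explicit covariate matrix (no intercept
#'   column; one is added).
#' @param delta_override Force the ratio sigma_e2 / sigma_a2; `Inf` forces
#'   sigma_a2 = 0, in which case the scan reduces to ordinary least squares.
#' @return Data frame of [assoc_table()] results (method `"mlm"`).
#' @export
mlm_scan <- function(g, y, n_pcs = 3L, grm = NULL, covariates = NULL,
                     delta_override = NULL) {
  if (stats::var(y) == 0) stop("response is constant")
  n <- length(g$samples)
  stopifnot(length(y) == n)
  if (is.null(grm)) grm <- grm_vanraden(g)
  if (is.null(covariates) && n_pcs > 0L) {
    covariates <- pca_from_genotypes(g, k = n_pcs, grm = grm)$coordinates
  }
  W <- cbind(`(Intercept)` = 1, covariates)
  e <- eigen(grm, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  yt <- drop(crossprod(e$vectors, y))
  Wt <- crossprod(e$vectors, W)

  delta <- if (is.null(delta_override)) {
    .emma_reml_delta(yt, Wt, lambda)
  } else delta_override
  wts <- if (is.infinite(delta)) rep(1, n) else 1 / (lambda + delta)

  M <- .imputed_dosage(g)
  Mt <- crossprod(e$vectors, M)
  res <- .wls_scan(yt, Wt, Mt, wts)
  assoc_table(g, res$effect, res$se, res$p, method = "mlm")
}

# REML estimate of delta = sigma_e2/sigma_a2 for y ~ W with V ~ (K + delta I),
# maximized on the log scale (EMMA-style profiled restricted likelihood)
.emma_reml_delta <- function(yt, Wt, lambda) {
  n <- length(yt); c_ <- ncol(Wt)
  nll <- function(logd) {
    d <- exp(logd)
    w <- 1 / (lambda + d)
    sw <- sqrt(w)
    Ws <- Wt * sw; ys <- yt * sw
    fit <- stats::lm.fit(Ws, ys)
    rss <- sum(fit$residuals^2)
    ldWW <- determinant(crossprod(Ws))$modulus
    (n - c_) * log(rss / (n - c_)) + sum(log(lambda + d)) + as.numeric(ldWW)
  }
  grid <- seq(-8, 8, length.out = 17)
  vals <- vapply(grid, nll, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  exp(stats::optimize(nll, c(lo, hi))$minimum)
}

# weighted least-squares per-marker scan: t-test on the marker coefficient
# given covariates Wt, all in a common (already rotated) basis
.wls_scan <- function(yt, Wt, Mt, wts) {
  n <- length(yt); c_ <- ncol(Wt)
  sw <- sqrt(wts)
  Ws <- Wt * sw; ys <- yt * sw; Ms <- Mt * sw
  A <- crossprod(Ws)
  Ainv <- solve(A)
  b <- drop(crossprod(Ws, ys))
  U <- crossprod(Ws, Ms)                  # c x m
  v <- drop(crossprod(Ms, ys))
  s <- colSums(Ms^2)
  AiU <- Ainv %*% U
  denom <- s - colSums(U * AiU)
  rss0 <- sum(ys^2) - sum(b * (Ainv %*% b))
  df <- n - c_ - 1
  effect <- se <- p <- rep(NA_real_, ncol(Ms))
  ok <- denom > max(s, 1) * 1e-12
  effect[ok] <- (v[ok] - colSums(U[, ok, drop = FALSE] *
                                   drop(Ainv %*% b))) / denom[ok]
  rss <- pmax(rss0 - effect^2 * denom, 0)
  sigma2 <- rss / df
  se[ok] <- sqrt(sigma2[ok] / denom[ok])
  tstat <- effect / se
  p[ok] <- 2 * stats::pt(abs(tstat[ok]), df, lower.tail = FALSE)
  p[!ok] <- 1; effect[!ok] <- 0; se[!ok] <- NA_real_
  list(effect = effect, se = se, p = p)
}

#' Genomic inflation factor
#'
#' lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1).
#'
#' @param p_values Vector of p-values in (0, 1]; at least 100 are required
#'   for a stable median.
#' @return Scalar inflation factor.
#' @export
genomic_lambda <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  if (length(p_values) < 100) stop("need at least 100 p-values")
  stats::median(stats::qchisq(p_values, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Classify association p-values
#'
#' Genome-wide significance below 5e-8, suggestive below 5e-6.
#'
#' @param p Vector of p-values.
#' @param genome_wide,suggestive Thresholds.
#' @return Character vector: `"genome_wide"`, `"suggestive"` or `"ns"`.
#' @export
classify_significance <- function(p, genome_wide = 5e-8, suggestive = 5e-6) {
  ifelse(p < genome_wide, "genome_wide",
         ifelse(p < suggestive, "suggestive", "ns"))
}

#' Assemble a per-variant association result table
#'
#' @param g The scanned [geno_matrix()].
#' @param effect,se,p Per-variant statistics.
#' @param method Method tag (`"mlm"`, `"farmcpu"`, `"glm"`).
#' @param trait,dim Optional annotations.
#' @return Data frame with variant metadata, MAF, statistics and
#'   significance class.
#' @export
assoc_table <- function(g, effect, se, p, method, trait = NA, dim = NA) {
  freq <- colMeans(g$dosage, na.rm = TRUE) / 2
  data.frame(trait = trait, dim = dim, method = method,
             snp_id = g$variants$id, chrom = g$variants$chrom,
             pos = g$variants$pos, ref = g$variants$ref,
             alt = g$variants$alt,
             maf = pmin(freq, 1 - freq),
             effect = effect, se = se, p = p,
             class = classify_significance(p),
             stringsAsFactors = FALSE)
}
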