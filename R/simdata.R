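#' Configuration for the synthetic dairy-population generator
#'
#' Bundles every knob of the simulator: pedigree design, genotype panel,
#' true covariance components of the random-regression model and
#' fixed-effect magnitudes. Defaults emulate a moderate Holstein-like
#' recording scheme: monthly tests between DIM 15 and 285, a fifth-order
#' Legendre basis, and trait scales matching typical first-lactation
#' descriptive statistics (milk yield ~28 kg/d, fat ~3.6%, protein ~3.2%,
#' somatic cell score ~2.8).
#'
#' @param n_founders Number of founder animals.
#' @param n_founder_males How many founders are male (default half).
#' @param n_generations Number of descendant generations (0 = founders only).
#' @param offspring_per_dam Offspring produced by each dam per generation.
#' @param n_herds Number of herds cows are spread across.
#' @param test_day_schedule Increasing integer DIM at which cows are tested.
#' @param basis_order Order of the Legendre basis for the true curves.
#' @param G_true,P_true True additive-genetic and permanent-environment
#'   covariance matrices of the regression coefficients, `(basis_order+1)`
#'   square, on the milk-yield scale (kg^2); other traits are scaled copies.
#' @param sigma_e2_true True residual variance (kg^2, milk-yield scale).
#' @param fixed_effect_spec List with standard deviations of the
#'   herd-test-date (`htd_sd`), calving month-age (`age_sd`) and calving
#'   year-season (`season_sd`) effects (milk-yield scale), plus
#'   `n_age_classes`.
#' @param final_gen_female Make the last generation all-female (the
#'   recorded cow cohort)? Earlier generations alternate sexes.
#' @param pedigree_design `"nested"` (default): dams tracked, hierarchical
#'   multi-generation matings. `"halfsib"`: the founders are
#'   `n_founder_males` sires; one generation of `offspring_per_dam`
#'   daughters per sire with unrecorded (unknown) dams -- the classical
#'   paternal half-sib design used for variance-component estimation.
#' @param n_snps,n_qtl Marker panel size and number of planted QTL.
#' @param qtl_prop Fraction of the additive intercept variance explained by
#'   the planted QTL (ignored when `n_qtl = 0`).
#' @param maf_range Founder minor-allele-frequency range, within (0, 0.5].
#' @param n_chrom Number of autosomes markers are spread over.
#' @param trait_var_scale Named multipliers mapping milk-yield-scale
#'   variances onto the other simulated traits.
#' @param trait_mean Named vector of trait means.
#' @param p_out_of_range Fraction of extra records simulated outside the DIM
#'   schedule range (for exercising record filters; default 0).
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 120L,
                       n_founder_males = NULL,
                       n_generations = 2L,
                       offspring_per_dam = 2L,
                       n_herds = 10L,
                       test_day_schedule = seq(15L, 285L, by = 30L),
                       basis_order = 2L,
                       G_true = NULL,
                       P_true = NULL,
                       sigma_e2_true = 15,
                       fixed_effect_spec = list(htd_sd = 2, age_sd = 1,
                                                season_sd = 1, n_age_classes = 3L),
                       final_gen_female = TRUE,
                       pedigree_design = c("nested", "halfsib"),
                       n_snps = 1000L,
                       n_qtl = 0L,
                       qtl_prop = 0.3,
                       maf_range = c(0.05, 0.5),
                       n_chrom = 10L,
                       trait_var_scale = c(my = 1, fp = 0.012, pp = 0.0022, scs = 0.055),
                       trait_mean = c(my = 28, fp = 3.6, pp = 3.2, scs = 2.8),
                       p_out_of_range = 0,
                       seed = 1L) {
  if (as.integer(basis_order) < 0L) stop("basis_order must be non-negative")
  k <- as.integer(basis_order) + 1L
  if (is.null(G_true)) {
    G_true <- diag(c(20, 3, 1, 0.5, 0.25, 0.1)[seq_len(k)], k)
    if (k >= 2L) G_true[1, 2] <- G_true[2, 1] <- 2
  }
  if (is.null(P_true)) {
    P_true <- diag(c(30, 5, 2, 1, 0.5, 0.2)[seq_len(k)], k)
    if (k >= 2L) P_true[1, 2] <- P_true[2, 1] <- 3
  }
  cfg <- list(n_founders = as.integer(n_founders),
              n_founder_males = if (is.null(n_founder_males))
                max(1L, as.integer(n_founders) %/% 2L) else as.integer(n_founder_males),
              n_generations = as.integer(n_generations),
              offspring_per_dam = as.integer(offspring_per_dam),
              n_herds = as.integer(n_herds),
              test_day_schedule = as.integer(test_day_schedule),
              basis_order = as.integer(basis_order),
              G_true = G_true, P_true = P_true,
              sigma_e2_true = sigma_e2_true,
              fixed_effect_spec = fixed_effect_spec,
              final_gen_female = isTRUE(final_gen_female),
              pedigree_design = match.arg(pedigree_design),
              n_snps = as.integer(n_snps), n_qtl = as.integer(n_qtl),
              qtl_prop = qtl_prop,
              maf_range = maf_range, n_chrom = as.integer(n_chrom),
              trait_var_scale = trait_var_scale, trait_mean = trait_mean,
              p_out_of_range = p_out_of_range,
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.validate_sim_config <- function(cfg) {
  if (cfg$basis_order < 0L) stop("basis_order must be non-negative")
  k <- cfg$basis_order + 1L
  .check_psd(cfg$G_true, "G_true", k)
  .check_psd(cfg$P_true, "P_true", k)
  if (cfg$sigma_e2_true <= 0) stop("sigma_e2_true must be positive")
  ts <- cfg$test_day_schedule
  if (any(diff(ts) <= 0)) stop("test_day_schedule must be strictly increasing")
  if (any(ts < 5L | ts > 305L)) stop("test_day_schedule must lie in [5, 305]")
  if (cfg$n_qtl > cfg$n_snps) stop("n_qtl must not exceed n_snps")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must be an interval within (0, 0.5]")
  }
  if (cfg$n_founders < 2L) stop("need at least 2 founders")
  invisible(cfg)
}

.check_psd <- function(M, name, k = nrow(M)) {
  if (!is.matrix(M) || nrow(M) != k || ncol(M) != k) {
    stop(sprintf("%s must be a %d x %d matrix", name, k, k))
  }
  if (max(abs(M - t(M))) > 1e-8) stop(name, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(name, " is not positive semi-definite")
  }
  invisible(M)
}

# deterministic per-stage sub-seeds from the single config seed
.stage_seed <- function(cfg, stage) {
  stages <- c(pedigree = 1L, genotypes = 2L, coefficients = 3L, records = 4L,
              qc = 5L, gwas = 6L)
  (cfg$seed %% 20000000L) * 100L + stages[[stage]]
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents; in each later generation
#' every dam (female of the previous generation) produces
#' `offspring_per_dam` offspring by a sire sampled at random from the
#' previous generation's males. Sexes alternate with birth order so both
#' sexes persist. Animals are returned in birth order.
#'
#' @param cfg A [sim_config()].
#' @return A [trace_and_sort()] pedigree with extra columns `sex` and `gen`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_founders < 2L) stop("need at least 2 founders")
  set.seed(.stage_seed(cfg, "pedigree"))
  if (identical(cfg$pedigree_design, "halfsib")) return(.simulate_halfsib(cfg))
  nf <- cfg$n_founders
  nm <- cfg$n_founder_males
  if (nm < 1L || nm >= nf) stop("founder sexes leave no males or no females")
  id <- sprintf("G0_%04d", seq_len(nf))
  sex <- c(rep("M", nm), rep("F", nf - nm))
  gen <- rep(0L, nf)
  sire <- dam <- rep("0", nf)
  by <- rep(2000L, nf)
  prev_ids <- id; prev_sex <- sex
  for (g in seq_len(cfg$n_generations)) {
    dams <- prev_ids[prev_sex == "F"]
    sires <- prev_ids[prev_sex == "M"]
    if (!length(dams) || !length(sires)) {
      stop("impossible mating design: generation ", g,
           " has no ", if (length(dams)) "sires" else "dams")
    }
    n_off <- length(dams) * cfg$offspring_per_dam
    off_dam <- rep(dams, each = cfg$offspring_per_dam)
    # one sire per dam and generation, so a dam's offspring are full sibs
    off_sire <- rep(sample(sires, length(dams), replace = TRUE),
                    each = cfg$offspring_per_dam)
    off_id <- sprintf("G%d_%04d", g, seq_len(n_off))
    off_sex <- if (g == cfg$n_generations && isTRUE(cfg$final_gen_female)) {
      rep("F", n_off)   # the recorded cow cohort
    } else rep(c("F", "M"), length.out = n_off)
    id <- c(id, off_id); sex <- c(sex, off_sex); gen <- c(gen, rep(g, n_off))
    sire <- c(sire, off_sire); dam <- c(dam, off_dam)
    by <- c(by, rep(2000L + g, n_off))
    prev_ids <- off_id; prev_sex <- off_sex
  }
  ped <- trace_and_sort(data.frame(animal_id = id, sire_id = sire,
                                   dam_id = dam, birth_year = by))
  ped$sex <- sex[match(ped$id, id)]
  ped$gen <- gen[match(ped$id, id)]
  ped
}

.simulate_halfsib <- function(cfg) {
  ns <- cfg$n_founder_males
  if (ns < 1L) stop("impossible mating design: no sires")
  nd <- cfg$offspring_per_dam        # daughters per sire
  sires <- sprintf("S%04d", seq_len(ns))
  cows <- sprintf("C%04d", seq_len(ns * nd))
  ped <- trace_and_sort(data.frame(
    animal_id = c(sires, cows),
    sire_id = c(rep("0", ns), rep(sires, each = nd)),
    dam_id = "0",
    birth_year = c(rep(2000L, ns), rep(2001L, ns * nd))))
  ped$sex <- ifelse(ped$id %in% sires, "M", "F")
  ped$gen <- ifelse(ped$id %in% sires, 0L, 1L)
  ped
}

#' Phenotyped cows of a simulated pedigree
#'
#' Females of the last simulated generation (all females, for a
#' founders-only pedigree).
#'
#' @param ped Pedigree from [simulate_pedigree()].
#' @return Character vector of cow ids.
#' @export
sim_cows <- function(ped) {
  stopifnot(!is.null(ped$sex), !is.null(ped$gen))
  ped$id[ped$sex == "F" & ped$gen == max(ped$gen)]
}

# one gamete: for each locus pick haplotype 1 or 2 of the parent
.transmit <- function(hap1, hap2, u) ifelse(u < 0.5, hap1, hap2)

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder alleles are drawn at frequencies uniform in `maf_range`
#' (independent loci); each descendant receives one random allele per locus
#' from each parent. Markers are spread evenly over `n_chrom` chromosomes.
#'
#' @param ped Sorted pedigree (parents before offspring).
#' @param cfg A [sim_config()].
#' @return A [geno_matrix()] with one row per animal in pedigree order.
#' @export
simulate_genotypes <- function(ped, cfg) {
  p <- .check_pedigree(ped)
  set.seed(.stage_seed(cfg, "genotypes"))
  m <- cfg$n_snps; n <- p$n
  freq <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    si <- p$sire[i]; di <- p$dam[i]
    h1[i, ] <- if (si == 0L) stats::rbinom(m, 1L, freq) else
      .transmit(h1[si, ], h2[si, ], stats::runif(m))
    h2[i, ] <- if (di == 0L) stats::rbinom(m, 1L, freq) else
      .transmit(h1[di, ], h2[di, ], stats::runif(m))
  }
  chrom <- sort(rep(seq_len(cfg$n_chrom), length.out = m))
  per <- table(factor(chrom, levels = seq_len(cfg$n_chrom)))
  pos <- unlist(lapply(per, function(k) sort(sample.int(1e8L, k))), use.names = FALSE)
  variants <- data.frame(chrom = paste0("chr", chrom), pos = pos,
                         id = sprintf("snp%05d", seq_len(m)),
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  g <- geno_matrix(p$id, variants, h1 + h2)
  attr(g, "founder_freq") <- freq
  g
}

#' Simulate true random-regression coefficients
#'
#' Additive coefficients are sampled with covariance `G_true` (x) `A` by the
#' pedigree recursion a_i = (a_s + a_d)/2 + m_i with Mendelian-sampling
#' covariance d_i * G; permanent-environment coefficients are i.i.d. with
#' covariance `P_true`. When `n_qtl > 0` the intercept coefficient is
#' decomposed into planted marker content plus a polygenic remainder so that
#' downstream association scans have known truth.
#'
#' @param ped Sorted pedigree.
#' @param cfg A [sim_config()].
#' @param genotypes Optional [geno_matrix()]; required when `cfg$n_qtl > 0`.
#' @param A Optional explicit relationship matrix; when supplied the
#'   additive coefficients are sampled through its symmetric square root
#'   instead of the pedigree recursion (useful for irregular covariances).
#' @return A `sim_truth` list: per-trait additive (`a`) and permanent
#'   environment (`p`) coefficient matrices, QTL positions and effects.
#' @export
simulate_rr_coefficients <- function(ped, cfg, genotypes = NULL, A = NULL) {
  p <- .check_pedigree(ped)
  .validate_sim_config(cfg)
  set.seed(.stage_seed(cfg, "coefficients"))
  k <- cfg$basis_order + 1L
  n <- p$n
  traits <- names(cfg$trait_var_scale)
  cows <- if (!is.null(ped$sex)) sim_cows(ped) else p$id

  qtl_idx <- integer(0); qtl_eff <- NULL
  G_poly <- cfg$G_true
  Qcontent <- NULL
  if (cfg$n_qtl > 0L) {
    if (is.null(genotypes)) stop("genotypes required when n_qtl > 0")
    qtl_idx <- sort(sample.int(cfg$n_snps, cfg$n_qtl))
    raw <- stats::rnorm(cfg$n_qtl)
    Z <- scale(genotypes$dosage[p$id, qtl_idx, drop = FALSE],
               center = TRUE, scale = FALSE)
    content <- drop(Z %*% raw)
    target_var <- cfg$qtl_prop * cfg$G_true[1, 1]
    sc <- sqrt(target_var / max(stats::var(content), .Machine$double.eps))
    qtl_eff <- matrix(0, cfg$n_qtl, k)
    qtl_eff[, 1] <- raw * sc
    Qcontent <- content * sc
    G_poly[1, 1] <- G_poly[1, 1] - target_var
    .check_psd(G_poly, "G_true minus QTL variance", k)
  }

  Lg_base <- .mat_sqrt(G_poly)
  if (!is.null(A)) {
    La <- .mat_sqrt(A)
  } else {
    Fd <- .ped_F_d(ped)
  }
  out <- list()
  for (tr in traits) {
    s <- sqrt(cfg$trait_var_scale[[tr]])
    Lg <- Lg_base * s
    if (!is.null(A)) {
      a <- La %*% matrix(stats::rnorm(n * k), n, k) %*% t(Lg)
    } else {
      a <- matrix(0, n, k)
      E <- matrix(stats::rnorm(n * k), n, k) %*% t(Lg)
      for (i in seq_len(n)) {
        m_i <- sqrt(Fd$d[i]) * E[i, ]
        a[i, ] <- m_i +
          (if (p$sire[i] > 0L) 0.5 * a[p$sire[i], ] else 0) +
          (if (p$dam[i] > 0L) 0.5 * a[p$dam[i], ] else 0)
      }
    }
    if (!is.null(Qcontent)) a[, 1] <- a[, 1] + Qcontent * s
    rownames(a) <- p$id
    Lp <- .mat_sqrt(cfg$P_true) * s
    pe <- matrix(stats::rnorm(length(cows) * k), length(cows), k) %*% t(Lp)
    rownames(pe) <- cows
    out[[tr]] <- list(a = a, p = pe)
  }
  structure(list(traits = out, qtl_idx = qtl_idx, qtl_effects = qtl_eff,
                 cows = cows, basis_order = cfg$basis_order),
            class = "sim_truth")
}

# symmetric PSD square root (tolerates semi-definite input, e.g. twins)
.mat_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Simulate test-day records for the six milk traits
#'
#' Each record is fixed effects + phi(dim)' (a + p) + e on the trait's own
#' scale. Milk yield, fat percentage, protein percentage and somatic cell
#' score are primary simulated traits; fat and protein yield are derived by
#' the component-yield product formulas (plus measurement noise of 0.01
#' kg/d) and somatic cell count by inverting the somatic cell score
#' transform, so the downstream derivation step is exercised nontrivially.
#'
#' @param truth From [simulate_rr_coefficients()].
#' @param ped Sorted pedigree.
#' @param cfg A [sim_config()].
#' @return Data frame of test-day records (one row per cow x test day) with
#'   identifiers, dates, DIM and raw trait measurements.
#' @export
simulate_test_day_records <- function(truth, ped, cfg) {
  p <- .check_pedigree(ped)
  stopifnot(inherits(truth, "sim_truth"))
  if (truth$basis_order != cfg$basis_order) stop("basis order mismatch")
  set.seed(.stage_seed(cfg, "records"))
  basis <- legendre_basis(cfg$basis_order)
  sched <- cfg$test_day_schedule
  if (any(sched < basis$dim_min | sched > basis$dim_max)) {
    stop("test_day_schedule outside DIM [5, 305]")
  }
  cows <- truth$cows
  nc <- length(cows)
  herd <- sprintf("H%02d", 1 + (seq_len(nc) - 1L) %% cfg$n_herds)
  # Calving cohorts are spaced in multiples of the 30-day test interval over
  # two years, so cohorts share herd-test-date cells (keeping season
  # estimable alongside herd-test-date) and each season contains several
  # calving months across years (keeping season estimable alongside the
  # calving month-age classes).
  cohort_dates <- as.Date("2017-01-15") + c(0, 30, 180, 210, 360, 390, 540, 570)
  calving <- sample(cohort_dates, nc, replace = TRUE)
  age_mo <- sample(20:34, nc, replace = TRUE)
  birth <- calving
  for (i in seq_len(nc)) birth[i] <- .add_months(calving[i], -age_mo[i])

  fes <- cfg$fixed_effect_spec
  n_age <- fes$n_age_classes
  age_class <- sprintf("A%02d", cut(age_mo, breaks = n_age, labels = FALSE))
  season_class <- paste0(format(calving, "%Y"), "_Q",
                         (as.integer(format(calving, "%m")) - 1L) %/% 3L + 1L)

  rec <- data.frame(cow_id = rep(cows, each = length(sched)),
                    herd = rep(herd, each = length(sched)),
                    dim = rep(sched, nc),
                    calving_date = rep(calving, each = length(sched)),
                    birth_date = rep(birth, each = length(sched)),
                    age_class = rep(age_class, each = length(sched)),
                    season_class = rep(season_class, each = length(sched)),
                    stringsAsFactors = FALSE)
  rec$test_date <- rec$calving_date + rec$dim
  rec$htd <- paste(rec$herd, format(rec$test_date, "%Y%m%d"), sep = ":")

  phi <- legendre_matrix(rec$dim, basis)
  cow_i <- match(rec$cow_id, cows)
  traits <- names(cfg$trait_var_scale)
  vals <- list()
  for (tr in traits) {
    s <- sqrt(cfg$trait_var_scale[[tr]])
    lev_eff <- function(labels, sd) {
      u <- unique(labels)
      stats::setNames(stats::rnorm(length(u), 0, sd * s), u)[labels]
    }
    fixed <- cfg$trait_mean[[tr]] +
      lev_eff(rec$htd, fes$htd_sd) +
      lev_eff(rec$age_class, fes$age_sd) +
      lev_eff(rec$season_class, fes$season_sd)
    coefs <- truth$traits[[tr]]
    gen_val <- rowSums(phi * coefs$a[rec$cow_id, , drop = FALSE])
    pe_val <- rowSums(phi * coefs$p[cow_i, , drop = FALSE])
    e <- stats::rnorm(nrow(rec), 0, sqrt(cfg$sigma_e2_true) * s)
    vals[[tr]] <- as.numeric(fixed) + gen_val + pe_val + e
  }
  rec$my <- pmax(vals$my, 0.1)
  rec$fp <- pmax(vals$fp, 0.05)
  rec$pp <- pmax(vals$pp, 0.05)
  scs <- vals$scs
  rec$scc <- pmax(100 * 2^(scs - 3), 0.1)
  rec$fy <- rec$fp * rec$my / 100 + stats::rnorm(nrow(rec), 0, 0.01)
  rec$py <- rec$pp * rec$my / 100 + stats::rnorm(nrow(rec), 0, 0.01)
  if (cfg$p_out_of_range > 0) {
    n_extra <- ceiling(cfg$p_out_of_range * nrow(rec))
    extra <- rec[sample.int(nrow(rec), n_extra, replace = TRUE), ]
    extra$dim <- sample(c(1:4, 306:330), n_extra, replace = TRUE)
    extra$test_date <- extra$calving_date + extra$dim
    extra$htd <- paste(extra$herd, format(extra$test_date, "%Y%m%d"), sep = ":")
    rec <- rbind(rec, extra)
  }
  rownames(rec) <- NULL
  rec[order(rec$cow_id, rec$dim), ]
}

.add_months <- function(date, k) {
  lt <- as.POSIXlt(date)
  lt$mon <- lt$mon + k
  as.Date(lt)
}

#' Write a simulated dataset to disk
#'
#' Emits `phenotypes.csv`, `pedigree.csv`, `genotypes.vcf` and, when truth
#' is supplied, `truth.tsv` (per-cow true additive intercepts per trait).
#' The files round-trip losslessly through [read_phenotypes()],
#' [read_pedigree()] and [read_vcf()].
#'
#' @param records From [simulate_test_day_records()].
#' @param ped Pedigree.
#' @param genotypes A [geno_matrix()] or NULL.
#' @param outdir Output directory (created if needed).
#' @param truth Optional `sim_truth`.
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(records, ped, genotypes, outdir, truth = NULL) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop("cannot create output directory ", outdir)
  }
  paths <- c(phenotypes = file.path(outdir, "phenotypes.csv"),
             pedigree = file.path(outdir, "pedigree.csv"))
  out <- data.frame(cow_id = records$cow_id, herd = records$herd,
                    test_date = format(records$test_date),
                    calving_date = format(records$calving_date),
                    birth_date = format(records$birth_date),
                    dim = records$dim,
                    my_kg = records$my, fp_pct = records$fp,
                    pp_pct = records$pp, scc_kcells_per_ml = records$scc,
                    fy_kg = if (is.null(records$fy)) NA else records$fy,
                    py_kg = if (is.null(records$py)) NA else records$py,
                    scs = if (is.null(records$scs)) NA else records$scs)
  utils::write.csv(out, paths[["phenotypes"]], row.names = FALSE, quote = FALSE)
  pedout <- data.frame(animal_id = ped$id,
                       sire_id = ifelse(ped$sire_id == "0", 0, ped$sire_id),
                       dam_id = ifelse(ped$dam_id == "0", 0, ped$dam_id),
                       birth_year = ped$birth_year)
  utils::write.csv(pedout, paths[["pedigree"]], row.names = FALSE, quote = FALSE)
  if (!is.null(genotypes)) {
    paths["vcf"] <- file.path(outdir, "genotypes.vcf")
    write_vcf(genotypes, paths[["vcf"]])
  }
  if (!is.null(truth)) {
    paths["truth"] <- file.path(outdir, "truth.tsv")
    tt <- data.frame(cow_id = truth$cows)
    for (tr in names(truth$traits)) {
      a <- truth$traits[[tr]]$a
      tt[[paste0("a0_", tr)]] <- a[match(truth$cows, rownames(a)), 1]
    }
    utils::write.table(tt, paths[["truth"]], sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(paths)
}

#' Read a phenotype CSV written by [write_dataset()]
#'
#' @param path CSV path.
#' @return Data frame of test-day records with internal column names.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(cow_id = as.character(d$cow_id), herd = as.character(d$herd),
             test_date = as.Date(d$test_date),
             calving_date = as.Date(d$calving_date),
             birth_date = as.Date(d$birth_date),
             dim = as.integer(d$dim),
             my = d$my_kg, fp = d$fp_pct, pp = d$pp_pct,
             scc = d$scc_kcells_per_ml,
             fy = d$fy_kg, py = d$py_kg, scs = d$scs,
             stringsAsFactors = FALSE)
}

#' Read a pedigree CSV (animal_id, sire_id, dam_id, birth_year; 0 = unknown)
#'
#' @param path CSV path.
#' @return A sorted [trace_and_sort()] pedigree.
#' @export
read_pedigree <- function(path) {
  trace_and_sort(utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = "character"))
}
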