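#' Default analysis configuration
#'
#' Bundles the simulation settings with the model, GWAS and annotation
#' parameters used by [run_pipeline()]. Every threshold of the standard
#' workflow is surfaced here with its conventional value: DIM window 5-305,
#' QC cuts (sample call rate 0.95, SNP call rate 0.90, HWE 1e-6, MAF
#' 0.05), three principal components, significance thresholds 5e-8 / 5e-6,
#' 150 kb annotation flank, and the five-stage DIM grid 7/35/50/140/280.
#'
#' @param sim A [sim_config()].
#' @param traits Traits to fit and scan.
#' @param basis_order Legendre order of the fitted model (defaults to the
#'   simulation's).
#' @param dim_grid DIM at which EBVs, heritabilities and scans are
#'   evaluated.
#' @param reml A [reml_control()].
#' @param gwas List of GWAS settings (`n_pcs`, thresholds, QC cuts).
#' @param flank Annotation window flank in bp.
#' @param seed Master seed (defaults to the simulation's).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       traits = c("my", "scs"),
                       basis_order = NULL,
                       dim_grid = c(7L, 35L, 50L, 140L, 280L),
                       reml = reml_control(tol = 1e-5, max_iter = 50L),
                       gwas = list(n_pcs = 3L, genome_wide = 5e-8,
                                   suggestive = 5e-6, sample_cr = 0.95,
                                   snp_cr = 0.90, hwe_p = 1e-6, maf = 0.05),
                       flank = 150000L,
                       seed = NULL) {
  cfg <- list(sim = sim, traits = traits,
              basis_order = if (is.null(basis_order)) sim$basis_order
              else as.integer(basis_order),
              dim_grid = as.integer(dim_grid), reml = reml, gwas = gwas,
              flank = as.integer(flank),
              seed = if (is.null(seed)) sim$seed else as.integer(seed))
  if (cfg$basis_order < 0L) stop("basis_order must be non-negative")
  if (any(cfg$dim_grid < 5L | cfg$dim_grid > 305L)) {
    stop("dim_grid must lie in [5, 305]")
  }
  class(cfg) <- "run_config"
  cfg
}

# tiny FNV-1a hash of a deparsed object, for run manifests
.param_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- bitwAnd(bitwXor(h, b) * 16777619, 0xFFFFFFFF)
  sprintf("%08x", h)
}

.write_manifest <- function(outdir, stage, cfg, inputs, outputs,
                            root = dirname(outdir)) {
  # paths are stored relative to the run directory so a run is
  # byte-reproducible regardless of where it is placed
  rel <- function(p) sub(paste0("^", gsub("([.\\|()^$*+?{}\\[\\]])",
                                          "\\\\\\1", root), "/?"), "",
                         unlist(p))
  man <- list(stage = stage, seed = cfg$seed,
              package_version = as.character(utils::packageVersion("rrmgwas")),
              parameter_hash = .param_hash(unclass(cfg)),
              inputs = as.list(rel(inputs)), outputs = as.list(rel(outputs)))
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Run the full simulated analysis pipeline
#'
#' Chains the stages end to end on a simulated dataset: data generation,
#' phenotype derivation and filtering, pedigree relationship matrices,
#' single-trait random-regression REML fits, DIM-specific EBV association
#' scans (MLM and FarmCPU) and QTL/gene window annotation. Every stage
#' writes its artifacts plus a JSON manifest under `outdir`; the run is a
#' pure function of the configuration (same config and seed give identical
#' outputs).
#'
#' @param outdir Output directory.
#' @param config A [run_config()].
#' @param stages Stages to run (subset of simulate/qc/fit/gwas/annotate,
#'   in that order).
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(outdir, config = run_config(),
                         stages = c("simulate", "qc", "fit", "gwas",
                                    "annotate"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  res <- list()
  basis <- legendre_basis(config$basis_order)

  if ("simulate" %in% stages) {
    say("[simulate] generating pedigree, genotypes and test-day records")
    ped <- simulate_pedigree(config$sim)
    geno <- simulate_genotypes(ped, config$sim)
    truth <- simulate_rr_coefficients(ped, config$sim, geno)
    rec <- simulate_test_day_records(truth, ped, config$sim)
    simdir <- file.path(outdir, "sim")
    paths <- write_dataset(rec, ped, geno, simdir, truth)
    .write_manifest(simdir, "simulate", config, list(), paths)
    res$simulate <- list(ped = ped, geno = geno, truth = truth,
                         records = rec, paths = paths)
  }
  ped <- res$simulate$ped
  geno <- res$simulate$geno

  if ("qc" %in% stages) {
    say("[qc] deriving traits and applying record/cow filters")
    rec <- read_phenotypes(res$simulate$paths[["phenotypes"]])
    rec <- derive_traits(rec)
    rf <- apply_record_filters(rec)
    cf <- apply_cow_filters(rf$records)
    rec <- assign_factor_levels(cf$records)
    qcdir <- file.path(outdir, "qc")
    dir.create(qcdir, showWarnings = FALSE)
    paths <- c(filtered = file.path(qcdir, "records_filtered.csv"),
               summary = file.path(qcdir, "trait_summary.tsv"),
               report = file.path(qcdir, "filter_report.json"))
    utils::write.csv(rec, paths[["filtered"]], row.names = FALSE)
    utils::write.table(summarize_traits(rec), paths[["summary"]],
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(record_filters = rf$report[1:5],
                              cow_filters = cf$report[1:5]),
                         paths[["report"]], auto_unbox = TRUE, pretty = TRUE)
    .write_manifest(qcdir, "qc", config,
                    list(phenotypes = unname(res$simulate$paths[["phenotypes"]])),
                    paths)
    res$qc <- list(records = rec, record_report = rf$report,
                   cow_report = cf$report)
  }

  if ("fit" %in% stages) {
    say("[fit] REML random-regression fits: ",
        paste(config$traits, collapse = ", "))
    rec <- res$qc$records
    fitdir <- file.path(outdir, "fit")
    dir.create(fitdir, showWarnings = FALSE)
    fits <- list()
    paths <- character(0)
    for (tr in config$traits) {
      fit <- reml_fit(rec, ped, basis, trait = tr, control = config$reml)
      fits[[tr]] <- fit
      h2 <- heritability_curve(fit$components, basis, config$dim_grid)
      rg <- genetic_correlation_grid(fit$components, basis, config$dim_grid)
      cows <- sim_cows(ped)
      ebv <- sapply(config$dim_grid, function(d) ebv_at_dim(fit, cows, d))
      colnames(ebv) <- config$dim_grid
      p <- c(file.path(fitdir, paste0(tr, "_components_G.tsv")),
             file.path(fitdir, paste0(tr, "_components_P.tsv")),
             file.path(fitdir, paste0(tr, "_h2.tsv")),
             file.path(fitdir, paste0(tr, "_genetic_correlations.tsv")),
             file.path(fitdir, paste0(tr, "_ebv.tsv")))
      utils::write.table(fit$components$G, p[1], sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      utils::write.table(fit$components$P, p[2], sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      utils::write.table(data.frame(dim = config$dim_grid, h2 = h2), p[3],
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(rg, p[4], sep = "\t", quote = FALSE)
      utils::write.table(data.frame(animal_id = cows, ebv), p[5],
                         sep = "\t", row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
    .write_manifest(fitdir, "fit", config, list(), paths)
    res$fit <- fits
  }

  if ("gwas" %in% stages) {
    say("[gwas] genotype QC, PCA, MLM and FarmCPU scans")
    gdir <- file.path(outdir, "gwas")
    dir.create(gdir, showWarnings = FALSE)
    qc <- genotype_qc(geno, sample_cr = config$gwas$sample_cr,
                      snp_cr = config$gwas$snp_cr,
                      hwe_p = config$gwas$hwe_p, maf = config$gwas$maf)
    cows <- sim_cows(ped)
    gsub_ <- .subset_samples(qc$genotypes, cows)
    grm <- grm_vanraden(gsub_)
    pcs <- pca_from_genotypes(gsub_, k = config$gwas$n_pcs, grm = grm)
    scans <- list(); lambdas <- list()
    paths <- character(0)
    for (tr in names(res$fit)) {
      for (d in config$dim_grid) {
        y <- ebv_at_dim(res$fit[[tr]], gsub_$samples, d)
        mlm <- mlm_scan(gsub_, y, grm = grm,
                        covariates = pcs$coordinates)
        fcpu <- suppressWarnings(
          farmcpu_scan(gsub_, y, covariates = pcs$coordinates))
        mlm$trait <- fcpu$trait <- tr
        mlm$dim <- fcpu$dim <- d
        key <- paste(tr, d, sep = "_")
        scans[[key]] <- rbind(mlm, fcpu)
        lambdas[[key]] <- c(mlm = genomic_lambda(mlm$p),
                            farmcpu = genomic_lambda(fcpu$p))
        p <- file.path(gdir, paste0("assoc_", key, ".tsv"))
        utils::write.table(scans[[key]], p, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        paths <- c(paths, p)
      }
    }
    lam_path <- file.path(gdir, "lambda.json")
    jsonlite::write_json(lambdas, lam_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    qc_path <- file.path(gdir, "genotype_qc.json")
    jsonlite::write_json(as.list(qc$report), qc_path, auto_unbox = TRUE,
                         pretty = TRUE)
    .write_manifest(gdir, "gwas", config, list(),
                    c(paths, lam_path, qc_path))
    res$gwas <- list(scans = scans, lambdas = lambdas, qc_report = qc$report,
                     pca = pcs)
  }

  if ("annotate" %in% stages) {
    say("[annotate] windowing significant SNPs against gene/QTL tables")
    adir <- file.path(outdir, "annotate")
    dir.create(adir, showWarnings = FALSE)
    ann <- make_toy_annotation(seed = config$seed)
    windows_by_cell <- lapply(res$gwas$scans, function(sc) {
      sig <- sc[sc$class != "ns", , drop = FALSE]
      make_windows(sig, flank = config$flank)
    })
    counts <- overlap_qtls(windows_by_cell, ann$qtls)
    gene_hits <- lapply(windows_by_cell, function(w) {
      if (nrow(w)) overlap_genes(w, ann$genes)$genes else character(0)
    })
    paths <- c(counts = file.path(adir, "qtl_class_counts.tsv"),
               genes = file.path(adir, "candidate_genes.json"))
    utils::write.table(counts, paths[["counts"]], sep = "\t", quote = FALSE)
    jsonlite::write_json(gene_hits, paths[["genes"]], pretty = TRUE)
    .write_manifest(adir, "annotate", config, list(), paths)
    res$annotate <- list(counts = counts, genes = gene_hits)
  }
  invisible(res)
}

# restrict a geno_matrix to a sample subset (in the given order)
.subset_samples <- function(g, samples) {
  idx <- match(samples, g$samples)
  if (anyNA(idx)) stop("samples absent from genotype matrix")
  geno_matrix(samples, g$variants, g$dosage[idx, , drop = FALSE])
}
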