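#!/usr/bin/env Rscript
# Stage 4: genotype QC, GRM and PCA, then MLM and FarmCPU scans of the
# DIM-specific EBVs for each trait and lactation stage.
source("analysis/00_config.R")
cfg <- analysis_config()
dims <- cfg$dim_grid

geno <- read_vcf(file.path("results", "data", "genotypes.vcf"))
qc <- genotype_qc(geno, sample_cr = cfg$gwas$sample_cr,
                  snp_cr = cfg$gwas$snp_cr, hwe_p = cfg$gwas$hwe_p,
                  maf = cfg$gwas$maf)
cat("Genotype QC:", paste(names(qc$report), qc$report, collapse = "; "), "\n")

out <- res_dir("gwas")
lambdas <- list()
for (tr in cfg$traits) {
  ebv <- utils::read.delim(file.path("results", "genetic_parameters",
                                     paste0(tr, "_ebv.tsv")))
  g <- rrmgwas:::.subset_samples(qc$genotypes, ebv$animal_id)
  grm <- grm_vanraden(g)
  pcs <- pca_from_genotypes(g, k = cfg$gwas$n_pcs, grm = grm)
  cat(sprintf("%s: top-3 PC variance proportions: %s\n", toupper(tr),
              paste(sprintf("%.1f%%", 100 * pcs$proportions[1:3]),
                    collapse = " ")))
  for (d in dims) {
    y <- ebv[[paste0("TD", d)]]
    mlm <- mlm_scan(g, y, grm = grm, covariates = pcs$coordinates)
    fc <- suppressWarnings(farmcpu_scan(g, y, covariates = pcs$coordinates))
    mlm$trait <- fc$trait <- tr; mlm$dim <- fc$dim <- d
    tab <- rbind(mlm, fc)
    utils::write.table(tab, file.path(out, sprintf("assoc_%s_TD%d.tsv", tr, d)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    lambdas[[sprintf("%s_TD%d", tr, d)]] <-
      c(mlm = genomic_lambda(mlm$p), farmcpu = genomic_lambda(fc$p))
    n_sig <- sum(tab$class != "ns")
    cat(sprintf("  %s TD%-3d lambda(mlm)=%.3f lambda(farmcpu)=%.3f significant SNP rows: %d\n",
                tr, d, lambdas[[sprintf("%s_TD%d", tr, d)]]["mlm"],
                lambdas[[sprintf("%s_TD%d", tr, d)]]["farmcpu"], n_sig))
  }
}
jsonlite::write_json(lambdas, file.path(out, "lambda.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
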