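#!/usr/bin/env Rscript
# Stage 1: generate the synthetic dairy population -- pedigree, gene-dropped
# SNP genotypes and first-lactation test-day records for six milk traits.
source("analysis/00_config.R")
cfg <- analysis_config()

ped <- simulate_pedigree(cfg$sim)
geno <- simulate_genotypes(ped, cfg$sim)
truth <- simulate_rr_coefficients(ped, cfg$sim, geno)
records <- simulate_test_day_records(truth, ped, cfg$sim)

paths <- write_dataset(records, ped, geno, res_dir("data"), truth)
cat(sprintf("Simulated %d animals (%d recorded cows), %d test-day records, %d SNPs\n",
            nrow(ped), length(sim_cows(ped)), nrow(records),
            nrow(geno$variants)))
cat("Planted QTL at marker indices:",
    paste(truth$qtl_idx, collapse = ", "), "\n")
cat("Files:", paste(paths, collapse = "\n       "), "\n")
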