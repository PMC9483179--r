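# Shared settings for the numbered analysis scripts. Desk-scale study:
# 400 recorded cows in 40 paternal half-sib families, monthly test days,
# order-2 Legendre curves, 1,500 gene-dropped SNPs with 5 planted QTL.
library(rrmgwas)

analysis_config <- function() {
  run_config(
    sim = sim_config(n_founder_males = 40, offspring_per_dam = 10,
                     pedigree_design = "halfsib", n_herds = 8,
                     basis_order = 2, n_snps = 1500, n_qtl = 5,
                     qtl_prop = 0.3, maf_range = c(0.05, 0.5),
                     seed = 20240915),
    traits = c("my", "scs"),
    reml = reml_control(tol = 1e-5, max_iter = 40),
    seed = 20240915)
}

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
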