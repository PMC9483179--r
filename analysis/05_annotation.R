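#!/usr/bin/env Rscript
# Stage 5: window the significant SNPs +/-150 kb and count overlaps with
# synthetic gene models and classified QTL intervals.
source("analysis/00_config.R")
cfg <- analysis_config()

ann <- make_toy_annotation(n_genes = 500, n_qtls = 300, seed = cfg$seed)
out <- res_dir("annotation")
utils::write.table(ann$genes, file.path(out, "genes_synthetic.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(ann$qtls, file.path(out, "qtls_synthetic.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)

files <- list.files(file.path("results", "gwas"), pattern = "^assoc_.*tsv$",
                    full.names = TRUE)
windows_by_cell <- list()
genes_by_cell <- list()
for (f in files) {
  tab <- utils::read.delim(f)
  cell <- sub("^assoc_(.*)\\.tsv$", "\\1", basename(f))
  sig <- tab[tab$class != "ns", , drop = FALSE]
  w <- make_windows(sig, flank = cfg$flank)
  windows_by_cell[[cell]] <- w
  genes_by_cell[[cell]] <- if (nrow(w)) overlap_genes(w, ann$genes)$genes
                           else character(0)
}
counts <- overlap_qtls(windows_by_cell, ann$qtls)
utils::write.table(counts, file.path(out, "qtl_class_counts.tsv"),
                   sep = "\t", quote = FALSE)
jsonlite::write_json(genes_by_cell, file.path(out, "candidate_genes.json"),
                     pretty = TRUE)
cat("Significant-SNP QTL-class counts (rows = trait x DIM):\n")
print(counts)
cat("Candidate genes per cell written to candidate_genes.json\n")
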