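#' Genotype dosage matrix
#'
#' Container for biallelic SNP genotypes: a samples x variants matrix of
#' alt-allele dosages (0/1/2, `NA` for missing) plus a variant table with
#' 1-based positions, non-decreasing within chromosome.
#'
#' @param samples Character vector of sample ids.
#' @param variants Data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param dosage Numeric matrix, `length(samples)` rows, `nrow(variants)` cols.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(samples, variants, dosage) {
  samples <- as.character(samples)
  variants <- as.data.frame(variants)
  stopifnot(all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)),
            nrow(dosage) == length(samples),
            ncol(dosage) == nrow(variants))
  bad <- unlist(tapply(variants$pos, variants$chrom, function(p) any(diff(p) < 0)))
  if (any(bad)) stop("positions must be non-decreasing within chromosome")
  if (any(!is.na(dosage))) {
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  }
  dimnames(dosage) <- list(samples, variants$id)
  structure(list(samples = samples, variants = variants, dosage = dosage),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants (%.1f%% missing)\n",
              length(x$samples), nrow(x$variants),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Write genotypes to a plain-text VCF v4.2 (GT only)
#'
#' @param g A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(sprintf("##source=rrmgwas %s",
                     as.character(utils::packageVersion("rrmgwas"))), con)
  for (chr in unique(g$variants$chrom)) {
    len <- max(g$variants$pos[g$variants$chrom == chr]) + 1L
    writeLines(sprintf("##contig=<ID=%s,length=%d>", chr, len), con)
  }
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$samples), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(g$variants))) {
    d <- g$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    v <- g$variants[j, ]
    writeLines(paste(c(as.character(v$chrom), v$pos, v$id, v$ref, v$alt,
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype dosage matrix
#'
#' Parses with \pkg{vcfR}; only the GT subfield is used. Genotypes other than
#' biallelic 0/1 calls are rejected.
#'
#' @param path VCF file path.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  alleles <- gsub("[/|]", "", gt)
  dos <- matrix(NA_real_, nrow(gt), ncol(gt))
  dos[alleles == "00"] <- 0
  dos[alleles == "01" | alleles == "10"] <- 1
  dos[alleles == "11"] <- 2
  if (any(!is.na(gt) & is.na(dos) & alleles != "..")) {
    stop("non-biallelic or half-missing genotypes in ", path)
  }
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = fix[, "ID"], ref = fix[, "REF"],
                         alt = fix[, "ALT"], stringsAsFactors = FALSE)
  geno_matrix(colnames(gt), variants, t(dos))
}
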