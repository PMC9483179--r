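#' Flanking windows around significant SNPs
#'
#' Each window spans `flank` bp up- and downstream of the SNP position
#' (150 kb by default), clipped at position 1; coordinates are 1-based
#' inclusive.
#'
#' @param variants Data frame with columns `chrom`, `pos` and optionally
#'   `id` (e.g. the significant rows of an association table, using
#'   `snp_id` when `id` is absent).
#' @param flank Flank size in bp.
#' @return Data frame of windows: `chrom`, `start`, `end`, `source_snp`.
#' @export
make_windows <- function(variants, flank = 150000L) {
  id <- variants$id
  if (is.null(id)) id <- variants$snp_id
  if (is.null(id)) id <- paste0(variants$chrom, ":", variants$pos)
  data.frame(chrom = as.character(variants$chrom),
             start = pmax(1L, as.integer(variants$pos) - as.integer(flank)),
             end = as.integer(variants$pos) + as.integer(flank),
             source_snp = as.character(id),
             stringsAsFactors = FALSE)
}

.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start, end = df$end))
}

#' Genes overlapping SNP windows
#'
#' A gene is reported when its interval intersects the window (1-based
#' inclusive, closed-interval convention); windows hitting nothing report
#' the nearest gene on the same chromosome with its distance.
#'
#' @param windows From [make_windows()].
#' @param gene_table Data frame `chrom`, `start`, `end`, `name` (from
#'   [read_gene_table()] or constructed). Rows with `start > end` are
#'   rejected with a warning.
#' @return List: `hits` (window x gene pairs), `genes` (unique overlapped
#'   gene names), `nearest` (per empty window: nearest gene and distance).
#' @export
overlap_genes <- function(windows, gene_table) {
  bad <- gene_table$start > gene_table$end
  if (any(bad)) {
    warning(sum(bad), " malformed gene interval(s) (start > end) dropped")
    gene_table <- gene_table[!bad, , drop = FALSE]
  }
  gw <- .as_granges(windows)
  gg <- .as_granges(gene_table)
  ov <- GenomicRanges::findOverlaps(gw, gg)
  hits <- data.frame(
    source_snp = windows$source_snp[S4Vectors::queryHits(ov)],
    gene = gene_table$name[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE)
  empty <- setdiff(seq_len(nrow(windows)), unique(S4Vectors::queryHits(ov)))
  nearest <- NULL
  if (length(empty)) {
    dn <- GenomicRanges::distanceToNearest(gw[empty], gg)
    nearest <- data.frame(
      source_snp = windows$source_snp[empty][S4Vectors::queryHits(dn)],
      gene = gene_table$name[S4Vectors::subjectHits(dn)],
      distance = S4Vectors::mcols(dn)$distance,
      stringsAsFactors = FALSE)
  }
  list(hits = hits, genes = unique(hits$gene), nearest = nearest)
}

#' QTL-class overlap counts per trait-DIM cell
#'
#' QTL intervals of 1 Mb or larger are discarded first. For every
#' trait-DIM combination, counts the significant SNPs whose window
#' overlaps at least one QTL of each class; a SNP overlapping several
#' classes counts once in each.
#'
#' @param windows_by_cell Named list (names are trait-DIM labels) of window
#'   data frames from [make_windows()].
#' @param qtl_table Data frame `chrom`, `start`, `end`, `qtl_class`,
#'   `name`; classes must be among Exterior, Health, Milk, Production,
#'   Reproduction.
#' @param max_size QTL size cap in bp (intervals of this size or larger
#'   are dropped; the conventional cap is 1 Mb).
#' @return Integer matrix, one row per trait-DIM cell, one column per QTL
#'   class.
#' @export
overlap_qtls <- function(windows_by_cell, qtl_table, max_size = 1e6) {
  classes <- c("Exterior", "Health", "Milk", "Production", "Reproduction")
  unknown <- setdiff(unique(qtl_table$qtl_class), classes)
  if (length(unknown)) {
    stop("unknown QTL class label(s): ", paste(unknown, collapse = ", "))
  }
  qtl_table <- qtl_table[(qtl_table$end - qtl_table$start + 1) < max_size, ,
                         drop = FALSE]
  out <- matrix(0L, length(windows_by_cell), length(classes),
                dimnames = list(names(windows_by_cell), classes))
  if (!nrow(qtl_table)) return(out)
  gq <- .as_granges(qtl_table)
  for (cell in names(windows_by_cell)) {
    w <- windows_by_cell[[cell]]
    if (!nrow(w)) next
    gw <- .as_granges(w)
    ov <- GenomicRanges::findOverlaps(gw, gq)
    if (!length(ov)) next
    pair_class <- qtl_table$qtl_class[S4Vectors::subjectHits(ov)]
    pair_snp <- w$source_snp[S4Vectors::queryHits(ov)]
    for (cl in classes) {
      out[cell, cl] <- length(unique(pair_snp[pair_class == cl]))
    }
  }
  out
}

#' Read a gene annotation table (TSV or BED)
#'
#' BED input (0-based half-open, detected by the `.bed` extension) is
#' shifted to 1-based inclusive coordinates on read.
#'
#' @param path File path. TSV needs a header with `chrom`, `start`, `end`,
#'   `name`; BED is headerless with those columns in BED order.
#' @return Data frame with 1-based inclusive `chrom`, `start`, `end`,
#'   `name`.
#' @export
read_gene_table <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    names(d)[1:4] <- c("chrom", "start", "end", "name")
    d$start <- d$start + 1L          # BED 0-based half-open -> 1-based
    return(d[, c("chrom", "start", "end", "name")])
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a QTL interval table (TSV: chrom, start, end, qtl_class, name)
#'
#' @param path File path.
#' @return Data frame of QTL intervals.
#' @export
read_qtl_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Generate toy gene and QTL interval tables
#'
#' Synthetic fixture generator for annotation tests and the simulated
#' pipeline: genes of 5-50 kb and QTL of 50-900 kb placed uniformly over
#' the given chromosome lengths, with QTL classes sampled from the five
#' standard categories.
#'
#' @param n_genes,n_qtls Numbers of intervals.
#' @param chrom_names Chromosome names.
#' @param chrom_len Common chromosome length (bp).
#' @param seed Integer seed.
#' @return List with `genes` and `qtls` data frames.
#' @export
make_toy_annotation <- function(n_genes = 50L, n_qtls = 30L,
                                chrom_names = paste0("chr", 1:10),
                                chrom_len = 1e8, seed = 1L) {
  set.seed(seed)
  classes <- c("Exterior", "Health", "Milk", "Production", "Reproduction")
  g_start <- sort(sample.int(chrom_len - 60000L, n_genes))
  genes <- data.frame(
    chrom = sample(chrom_names, n_genes, replace = TRUE),
    start = g_start,
    end = g_start + sample(5000:50000, n_genes, replace = TRUE),
    name = sprintf("GENE%03d", seq_len(n_genes)),
    stringsAsFactors = FALSE)
  q_start <- sort(sample.int(chrom_len - 1000000L, n_qtls))
  qtls <- data.frame(
    chrom = sample(chrom_names, n_qtls, replace = TRUE),
    start = q_start,
    end = q_start + sample(50000:900000, n_qtls, replace = TRUE),
    qtl_class = sample(classes, n_qtls, replace = TRUE),
    name = sprintf("QTL%03d", seq_len(n_qtls)),
    stringsAsFactors = FALSE)
  list(genes = genes, qtls = qtls)
}
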