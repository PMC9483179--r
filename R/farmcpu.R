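#' Fixed-effect (GLM) marker scan
#'
#' Ordinary least squares of the response on each marker with the given
#' covariates; the workhorse of the FarmCPU fixed-effect step and the
#' reduction of the first FarmCPU iteration.
#'
#' @param g A QC'd [geno_matrix()].
#' @param y Response vector.
#' @param covariates Covariate matrix without intercept (one is added).
#' @return Data frame of [assoc_table()] results (method `"glm"`).
#' @export
glm_scan <- function(g, y, covariates = NULL) {
  W <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  M <- .imputed_dosage(g)
  res <- .wls_scan(y, W, M, rep(1, length(y)))
  assoc_table(g, res$effect, res$se, res$p, method = "glm")
}

#' FarmCPU control parameters
#'
#' Defaults follow the published method: genomic bin sizes of 0.5, 5 and
#' 50 Mb, candidate pseudo-QTN counts bounded by n/10, at most 10
#' iterations, and an entry screen requiring some marker to reach
#' 0.01 / n_markers in the first scan.
#'
#' @param bin_sizes Candidate bin sizes in bp.
#' @param qtn_counts Candidate pseudo-QTN counts.
#' @param max_iter Maximum fixed/random iterations.
#' @param screen_p First-iteration inclusion screen (default `0.01 / m` at
#'   run time when `NULL`).
#' @return List of control values.
#' @export
farmcpu_control <- function(bin_sizes = c(5e5, 5e6, 5e7),
                            qtn_counts = c(5, 10, 20, 50),
                            max_iter = 10L, screen_p = NULL) {
  list(bin_sizes = bin_sizes, qtn_counts = qtn_counts,
       max_iter = as.integer(max_iter), screen_p = screen_p)
}

# REML log-likelihood of the random model y = mu + u + e with
# u ~ N(0, 2 K sigma_u2), K built from t pseudo-QTN dosages; evaluated
# through the low-rank SVD of the centered, scaled QTN matrix.
.random_model_loglik <- function(y, Zq) {
  n <- length(y)
  yc <- y - mean(y)
  p <- colMeans(Zq) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) return(-Inf)
  Z <- sweep(Zq[, poly, drop = FALSE], 2L, 2 * p[poly], `-`)
  cden <- 2 * sum(p[poly] * (1 - p[poly]))
  B <- Z * sqrt(2 / cden)               # V = su2 (B B' + delta I)
  sv <- svd(B, nu = min(n, ncol(B)), nv = 0)
  d2 <- sv$d^2
  y1 <- drop(crossprod(sv$u, yc))
  r2 <- max(sum(yc^2) - sum(y1^2), 0)
  t_ <- length(d2)
  nll <- function(logd) {
    d <- exp(logd)
    rss <- sum(y1^2 / (d2 + d)) + r2 / d
    (n - 1) * log(rss / (n - 1)) + sum(log(d2 + d)) + (n - 1 - t_) * log(d)
  }
  grid <- seq(-8, 8, length.out = 9)
  vals <- vapply(grid, nll, numeric(1))
  i <- which.min(vals)
  opt <- stats::optimize(nll, c(grid[max(1, i - 1)],
                                grid[min(length(grid), i + 1)]))
  -0.5 * opt$objective
}

# best marker per genomic bin, in increasing p-value order, up to n_qtn
.bin_representatives <- function(variants, p, bin_size, n_qtn) {
  bin <- paste(variants$chrom, variants$pos %/% as.integer(bin_size))
  ord <- order(p)
  sel <- ord[!duplicated(bin[ord])]
  utils::head(sel, n_qtn)
}

#' FarmCPU-style multi-locus association scan
#'
#' Alternates (i) a fixed-effect scan testing every marker with the current
#' pseudo-QTNs as covariates (pseudo-QTN markers are tested leaving their
#' own bin's QTNs out) and (ii) pseudo-QTN reselection, ranking markers by
#' p-value within genomic bins and choosing the bin-size / QTN-count
#' combination that maximizes the restricted likelihood of the random model
#' whose kinship is built from the candidate QTNs. Stops when the
#' pseudo-QTN set repeats or after `max_iter` iterations; p-values come
#' from the last fixed-effect scan.
#'
#' @param g A QC'd [geno_matrix()].
#' @param y Response vector (e.g. DIM-specific EBVs).
#' @param n_pcs Number of genotype principal components as covariates.
#' @param covariates Optional explicit covariate matrix (overrides PCs).
#' @param control A [farmcpu_control()].
#' @return Data frame of [assoc_table()] results (method `"farmcpu"`), with
#'   the selected pseudo-QTN indices in attribute `pseudo_qtns` and the
#'   number of iterations in attribute `iterations`.
#' @export
farmcpu_scan <- function(g, y, n_pcs = 3L, covariates = NULL,
                         control = farmcpu_control()) {
  if (stats::var(y) == 0) stop("response is constant")
  n <- length(y); m <- nrow(g$variants)
  stopifnot(length(g$samples) == n)
  if (is.null(covariates) && n_pcs > 0L) {
    covariates <- pca_from_genotypes(g, k = n_pcs)$coordinates
  }
  W <- cbind(`(Intercept)` = rep(1, n), covariates)
  M <- .imputed_dosage(g)
  screen_p <- if (is.null(control$screen_p)) 0.01 / m else control$screen_p

  scan <- .wls_scan(y, W, M, rep(1, n))
  qtns <- integer(0)
  n_iter <- 1L
  history <- list(integer(0))

  if (min(scan$p, na.rm = TRUE) > screen_p) {
    warning("no marker passes the FarmCPU inclusion screen; ",
            "returning first-iteration GLM results")
  } else {
    max_qtn <- max(1L, n %/% 10L)
    repeat {
      if (n_iter >= control$max_iter) break
      # (ii) pseudo-QTN reselection by random-model likelihood
      best <- NULL; best_ll <- -Inf
      for (bs in control$bin_sizes) {
        for (nq in unique(pmin(control$qtn_counts, max_qtn))) {
          cand <- .bin_representatives(g$variants, scan$p, bs, nq)
          if (!length(cand)) next
          ll <- .random_model_loglik(y, M[, cand, drop = FALSE])
          if (ll > best_ll) { best_ll <- ll; best <- cand }
        }
      }
      qtns_new <- sort(best)
      n_iter <- n_iter + 1L
      repeated <- any(vapply(history, identical, logical(1), y = qtns_new))
      qtns <- qtns_new
      history <- c(history, list(qtns))
      # (i) fixed-effect scan with pseudo-QTN covariates
      scan <- .farmcpu_fixed_scan(y, W, M, g$variants, qtns,
                                  control$bin_sizes[1])
      if (repeated) break
    }
  }
  out <- assoc_table(g, scan$effect, scan$se, scan$p, method = "farmcpu")
  attr(out, "pseudo_qtns") <- qtns
  attr(out, "iterations") <- n_iter
  out
}

# fixed-effect scan with pseudo-QTN covariates; markers sharing a bin with
# a pseudo-QTN (including the QTNs themselves) are tested with those QTNs
# left out so a QTN's own signal is not absorbed by its covariate copy
.farmcpu_fixed_scan <- function(y, W, M, variants, qtns, bin_size) {
  n <- length(y)
  Wq <- cbind(W, M[, qtns, drop = FALSE])
  Wq <- .drop_aliased(Wq)
  scan <- .wls_scan(y, Wq, M, rep(1, n))
  if (length(qtns)) {
    bin <- paste(variants$chrom, variants$pos %/% as.integer(bin_size))
    qtn_bins <- unique(bin[qtns])
    redo <- which(bin %in% qtn_bins)
    for (j in redo) {
      keep_q <- qtns[bin[qtns] != bin[j]]
      Wj <- .drop_aliased(cbind(W, M[, keep_q, drop = FALSE]))
      sj <- .wls_scan(y, Wj, M[, j, drop = FALSE], rep(1, n))
      scan$effect[j] <- sj$effect; scan$se[j] <- sj$se; scan$p[j] <- sj$p
    }
  }
  scan
}

# drop linearly dependent columns (keeps the first of each aliased group)
.drop_aliased <- function(X) {
  qr_ <- qr(X)
  if (qr_$rank == ncol(X)) return(X)
  X[, qr_$pivot[seq_len(qr_$rank)], drop = FALSE]
}
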