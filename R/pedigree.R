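#' Pedigree objects
#'
#' A pedigree is a topologically sorted table of animal/sire/dam triples:
#' every parent appears before any of its offspring and unknown parents are
#' coded `0`. Use [trace_and_sort()] to build one from raw records; it
#' inserts referenced-but-absent parents as founders and detects cycles.
#'
#' @param entries Data frame with columns `animal_id`, `sire_id`, `dam_id`
#'   and optionally `birth_year`. Unknown parents may be `0`, `NA` or `""`.
#' @return A `pedigree`: data frame `(id, sire_id, dam_id, birth_year)` with
#'   integer parent indices in attributes `sire_idx` / `dam_idx` (0 = unknown).
#' @export
trace_and_sort <- function(entries) {
  entries <- as.data.frame(entries)
  need <- c("animal_id", "sire_id", "dam_id")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns animal_id, sire_id, dam_id")
  }
  id   <- as.character(entries$animal_id)
  sire <- .clean_parent(entries$sire_id)
  dam  <- .clean_parent(entries$dam_id)
  if (anyDuplicated(id)) stop("duplicate animal ids in pedigree entries")
  if (any(id == "0")) stop("animal id '0' is reserved for unknown parents")
  by <- if ("birth_year" %in% names(entries)) entries$birth_year else rep(NA_integer_, length(id))

  # referenced parents without their own entry become founders, listed first
  parents <- setdiff(unique(c(sire, dam)), c("0", id))
  if (length(parents)) {
    id   <- c(parents, id)
    sire <- c(rep("0", length(parents)), sire)
    dam  <- c(rep("0", length(parents)), dam)
    by   <- c(rep(NA_integer_, length(parents)), by)
  }
  n <- length(id)
  pos <- seq_len(n)
  names(pos) <- id
  si <- ifelse(sire == "0", 0L, pos[sire])
  di <- ifelse(dam == "0", 0L, pos[dam])
  if (any(si == pos | di == pos, na.rm = TRUE)) stop("animal listed as its own parent")

  # Kahn topological sort, stable in the input order
  placed <- logical(n)
  order_out <- integer(0)
  repeat {
    ready <- which(!placed &
                     (si == 0L | placed[pmax(si, 1L)]) &
                     (di == 0L | placed[pmax(di, 1L)]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
  }
  if (length(order_out) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(id[!placed], collapse = ", "))
  }
  newpos <- integer(n)
  newpos[order_out] <- seq_len(n)
  ped <- data.frame(id = id[order_out],
                    sire_id = sire[order_out],
                    dam_id  = dam[order_out],
                    birth_year = by[order_out],
                    stringsAsFactors = FALSE)
  remap <- function(idx) {
    out <- integer(n)
    out[idx > 0L] <- newpos[idx[idx > 0L]]
    out
  }
  attr(ped, "sire_idx") <- remap(si[order_out])
  attr(ped, "dam_idx")  <- remap(di[order_out])
  class(ped) <- c("pedigree", "data.frame")
  ped
}

.clean_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- "0"
  x
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree with %d animals (%d founders)\n", nrow(x),
              sum(attr(x, "sire_idx") == 0L & attr(x, "dam_idx") == 0L)))
  invisible(x)
}

.check_pedigree <- function(ped) {
  if (!inherits(ped, "pedigree")) stop("not a pedigree; use trace_and_sort()")
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  if (any(si >= seq_along(si)) || any(di >= seq_along(di))) {
    stop("pedigree not sorted parents-before-offspring")
  }
  list(sire = si, dam = di, n = nrow(ped), id = ped$id)
}

# Mendelian-sampling variances d_i and inbreeding F_i in one sweep.
# d_i = 1 - 0.25 (1 + F_s) - 0.25 (1 + F_d), terms dropped for unknown parents.
# F_i is obtained from the diagonal a_ii = sum_j L_ij^2 d_j of A = L D L'
# by back-tracing the ancestor contributions of each animal (Meuwissen-Luo
# style), so no dense matrix is formed.
.ped_F_d <- function(ped) {
  p <- .check_pedigree(ped)
  n <- p$n; si <- p$sire; di <- p$dam
  Fc <- numeric(n); d <- numeric(n)
  v <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- 1 -
      (if (si[i] > 0L) 0.25 * (1 + Fc[si[i]]) else 0) -
      (if (di[i] > 0L) 0.25 * (1 + Fc[di[i]]) else 0)
    if (si[i] == 0L || di[i] == 0L) next   # F = 0 with an unknown parent
    v[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (v[j] == 0) next
      aii <- aii + v[j]^2 * d[j]
      if (si[j] > 0L) v[si[j]] <- v[si[j]] + 0.5 * v[j]
      if (di[j] > 0L) v[di[j]] <- v[di[j]] + 0.5 * v[j]
      v[j] <- 0
    }
    Fc[i] <- aii - 1
  }
  list(F = Fc, d = d)
}

#' Inbreeding coefficients, optionally depth-capped
#'
#' With `max_generations = Inf` the exact coefficients are computed from the
#' full pedigree. A finite cap truncates each animal's ancestor pedigree at
#' that depth (the animal's parents are depth 1); ancestors at the cap are
#' treated as unrelated, non-inbred founders, mirroring the common practice
#' of computing F "going back only g generations".
#'
#' @param ped A [trace_and_sort()] pedigree.
#' @param max_generations Ancestor depth to retain, or `Inf` for exact.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped, max_generations = Inf) {
  p <- .check_pedigree(ped)
  if (is.infinite(max_generations)) {
    return(stats::setNames(.ped_F_d(ped)$F, p$id))
  }
  g <- as.integer(max_generations)
  if (g < 0L) stop("max_generations must be >= 0")
  si <- p$sire; di <- p$dam
  out <- numeric(p$n)
  for (i in seq_len(p$n)) {
    if (si[i] == 0L || di[i] == 0L) next
    # minimal-depth ancestor set of i up to depth g
    depth <- rep(NA_integer_, p$n)
    depth[i] <- 0L
    frontier <- i
    for (dstep in seq_len(g)) {
      nxt <- integer(0)
      for (a in frontier) {
        for (par in c(si[a], di[a])) {
          if (par > 0L && is.na(depth[par])) { depth[par] <- dstep; nxt <- c(nxt, par) }
        }
      }
      frontier <- nxt
      if (!length(frontier)) break
    }
    keep <- which(!is.na(depth))
    # parents of animals at the cap depth are dropped (truncated founders)
    keep_par <- function(par, dep) if (par > 0L && dep < g) p$id[par] else "0"
    sub <- data.frame(
      animal_id = p$id[keep],
      sire_id = vapply(keep, function(a) keep_par(si[a], depth[a]), character(1)),
      dam_id  = vapply(keep, function(a) keep_par(di[a], depth[a]), character(1)))
    subped <- trace_and_sort(sub)
    out[i] <- inbreeding(subped, Inf)[p$id[i]]
  }
  stats::setNames(out, p$id)
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense additive relationship matrix A with `a_ii = 1 + F_i`,
#' `a_ij = (a(j, s_i) + a(j, d_i)) / 2`; unknown parents contribute 0.
#'
#' @param ped A sorted pedigree.
#' @return Symmetric dense matrix with animal ids as dimnames.
#' @export
nrm <- function(ped) {
  p <- .check_pedigree(ped)
  n <- p$n; si <- p$sire; di <- p$dam
  A <- matrix(0, n, n, dimnames = list(p$id, p$id))
  for (i in seq_len(n)) {
    row <- numeric(n)
    if (si[i] > 0L) row <- row + 0.5 * A[si[i], ]
    if (di[i] > 0L) row <- row + 0.5 * A[di[i], ]
    asd <- if (si[i] > 0L && di[i] > 0L) A[si[i], di[i]] else 0
    row[i] <- 1 + 0.5 * asd
    A[i, ] <- row
    A[, i] <- row
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules: each animal contributes `alpha_i = 1 / d_i` to the
#' (animal, sire, dam) block, with `d_i` the Mendelian-sampling variance
#' (inbreeding-corrected when `with_inbreeding = TRUE`).
#'
#' @param ped A sorted pedigree.
#' @param with_inbreeding Correct `d_i` for parental inbreeding (default TRUE;
#'   FALSE gives the classical approximation for non-inbred pedigrees).
#' @return Sparse symmetric `Matrix::dgCMatrix`.
#' @export
nrm_inverse <- function(ped, with_inbreeding = TRUE) {
  p <- .check_pedigree(ped)
  n <- p$n; si <- p$sire; di <- p$dam
  if (with_inbreeding) {
    d <- .ped_F_d(ped)$d
  } else {
    d <- 1 - 0.25 * (si > 0L) - 0.25 * (di > 0L)
  }
  alpha <- 1 / d
  ii <- jj <- integer(0); vv <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }
  for (i in seq_len(n)) {
    a <- alpha[i]
    add(i, i, a)
    for (par in c(si[i], di[i])) {
      if (par > 0L) {
        add(i, par, -a / 2); add(par, i, -a / 2)
        add(par, par, a / 4)
      }
    }
    if (si[i] > 0L && di[i] > 0L) {
      add(si[i], di[i], a / 4); add(di[i], si[i], a / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n),
                               dimnames = list(p$id, p$id))
  methods::as(Ainv, "CsparseMatrix")
}

# log-determinant of A: log|A| = sum(log d_i)  (A = L D L', L unit lower-tri)
.nrm_logdet <- function(ped) sum(log(.ped_F_d(ped)$d))
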