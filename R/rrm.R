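#' Variance components of the random-regression model
#'
#' @param G Additive-genetic covariance matrix of the regression
#'   coefficients (trait units squared, coefficient scale).
#' @param P Permanent-environment covariance matrix, same dimension.
#' @param sigma_e2 Residual variance (homogeneous over DIM).
#' @return An object of class `var_components`.
#' @export
var_components <- function(G, P, sigma_e2) {
  G <- as.matrix(G); P <- as.matrix(P)
  .check_psd(G, "G"); .check_psd(P, "P")
  if (nrow(G) != nrow(P)) stop("G and P must have the same dimension")
  if (sigma_e2 <= 0) stop("sigma_e2 must be positive")
  structure(list(G = G, P = P, sigma_e2 = sigma_e2), class = "var_components")
}

#' @export
print.var_components <- function(x, ...) {
  cat("Random-regression variance components (coefficient scale)\n")
  cat("G (additive):\n"); print(round(x$G, 4))
  cat("P (permanent environment):\n"); print(round(x$P, 4))
  cat(sprintf("sigma_e2 (residual): %.4f\n", x$sigma_e2))
  invisible(x)
}

#' Control parameters for the REML fit
#'
#' @param tol Relative parameter-change convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param accel Attempt guarded extrapolation steps (accepted only when the
#'   restricted likelihood does not decrease, so the monotone-likelihood
#'   property of EM is preserved)?
#' @param verbose Print per-iteration restricted log-likelihood?
#' @return List of control values.
#' @export
reml_control <- function(tol = 1e-6, max_iter = 500L, accel = TRUE,
                         verbose = FALSE) {
  list(tol = tol, max_iter = as.integer(max_iter), accel = isTRUE(accel),
       verbose = isTRUE(verbose))
}

# --- design assembly -------------------------------------------------------

# Shared design builder: sparse fixed-effect matrix (intercept + treatment
# contrasts), random-regression incidence for additive (all pedigree
# animals) and permanent-environment (recorded cows only) coefficients,
# plus the crossproducts the solver needs.
.rrm_design <- function(records, ped, basis, trait = "my",
                        fixed = c("htd", "age_class", "season_class"),
                        include_pe = TRUE, on_alias = c("error", "drop")) {
  on_alias <- match.arg(on_alias)
  p <- .check_pedigree(ped)
  y <- records[[trait]]
  if (is.null(y)) stop("trait column '", trait, "' not found")
  if (any(is.na(y))) stop("missing trait values; filter records first")
  if (stats::var(y) == 0) stop("response is constant")
  miss <- setdiff(fixed, names(records))
  if (length(miss)) stop("missing factor columns: ", paste(miss, collapse = ", "),
                         "; run assign_factor_levels() first")
  n <- nrow(records)
  k <- basis$order + 1L

  fdat <- records[fixed]
  fdat[] <- lapply(fdat, factor)
  multi <- vapply(fdat, function(f) nlevels(f) > 1L, logical(1))
  fml <- if (any(multi)) {
    stats::as.formula(paste("~", paste(fixed[multi], collapse = " + ")))
  } else ~1   # single-level factors reduce to the intercept
  X <- Matrix::sparse.model.matrix(fml, fdat)
  XtX <- as.matrix(Matrix::crossprod(X))
  piv <- suppressWarnings(chol(XtX, pivot = TRUE))
  rankX <- attr(piv, "rank")
  if (rankX < ncol(X)) {
    aliased <- colnames(X)[attr(piv, "pivot")[(rankX + 1L):ncol(X)]]
    if (on_alias == "error") {
      stop("confounded fixed-effect levels: ", paste(aliased, collapse = ", "))
    }
    # generalized-inverse behaviour: absorb aliased levels into the rest
    keep <- sort(attr(piv, "pivot")[seq_len(rankX)])
    X <- X[, keep, drop = FALSE]
  }

  phi <- legendre_matrix(records$dim, basis)
  aidx <- match(records$cow_id, p$id)
  if (anyNA(aidx)) stop("records contain cows absent from the pedigree")
  trip_i <- rep(seq_len(n), k)
  trip_j <- as.vector(vapply(seq_len(k), function(m) (aidx - 1L) * k + m,
                             integer(n)))
  Za <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = as.vector(phi),
                             dims = c(n, p$n * k))

  cows <- sort(unique(records$cow_id))
  nc <- length(cows)
  Zp <- NULL; cow_rows <- NULL
  if (include_pe) {
    cidx <- match(records$cow_id, cows)
    trip_jc <- as.vector(vapply(seq_len(k), function(m) (cidx - 1L) * k + m,
                                integer(n)))
    Zp <- Matrix::sparseMatrix(i = trip_i, j = trip_jc, x = as.vector(phi),
                               dims = c(n, nc * k))
    cow_rows <- split(seq_len(n), factor(records$cow_id, levels = cows))
  }

  W1 <- cbind(X, Za)
  des <- list(y = y, N = n, k = k, X = X, Za = Za, Zp = Zp,
              n_fixed = ncol(X), fixed_names = colnames(X), rankX = rankX,
              animal_ids = p$id, cows = cows, nc = nc, phi = phi,
              include_pe = include_pe,
              W1 = W1,
              W1tW1 = Matrix::crossprod(W1),
              W1ty = as.numeric(Matrix::crossprod(W1, y)),
              yty = sum(y^2))
  if (include_pe) {
    des$M12raw <- Matrix::crossprod(W1, Zp)     # n1 x (nc k)
    des$PhiTPhi <- array(0, c(k, k, nc))
    des$Phity <- matrix(0, k, nc)
    for (c_ in seq_len(nc)) {
      rows <- cow_rows[[c_]]
      Pc <- phi[rows, , drop = FALSE]
      des$PhiTPhi[, , c_] <- crossprod(Pc)
      des$Phity[, c_] <- crossprod(Pc, y[rows])
    }
    # constant sparsity pattern of each cow's coupling block
    M12t <- methods::as(des$M12raw, "TsparseMatrix")
    colcow <- (M12t@j) %/% k + 1L
    des$cow_nz <- vector("list", nc)
    for (c_ in seq_len(nc)) des$cow_nz[[c_]] <- integer(0)
    nzl <- split(M12t@i + 1L, colcow)
    for (nm in names(nzl)) des$cow_nz[[as.integer(nm)]] <- sort(unique(nzl[[nm]]))
    des$M12sub <- lapply(seq_len(nc), function(c_) {
      as.matrix(des$M12raw[des$cow_nz[[c_]],
                           ((c_ - 1L) * k + 1L):(c_ * k), drop = FALSE])
    })
  }
  des
}

#' Assemble Henderson's mixed-model equations for the test-day model
#'
#' Builds the full coefficient matrix and right-hand side, in the
#' R-inverse form `W' W / sigma_e2 + ridge`, with ridge terms
#' `A^-1 (x) G^-1` for the additive regressions and `I (x) P^-1` for the
#' permanent-environment regressions.
#'
#' @param records Filtered records with factor levels assigned.
#' @param ped Sorted pedigree.
#' @param basis A [legendre_basis()].
#' @param components A [var_components()].
#' @param trait Trait column to model.
#' @param fixed Fixed-effect factor columns.
#' @param include_pe Include permanent-environment regressions?
#' @return List with sparse `M`, `rhs` and index metadata; solve with
#'   [solve_mme()].
#' @export
build_mme <- function(records, ped, basis, components, trait = "my",
                      fixed = c("htd", "age_class", "season_class"),
                      include_pe = TRUE) {
  des <- .rrm_design(records, ped, basis, trait, fixed, include_pe)
  Ainv <- nrm_inverse(ped)
  se2 <- components$sigma_e2
  Ginv <- solve(components$G)
  Ka <- Matrix::kronecker(Ainv, Ginv)
  blocks <- list(Matrix::Matrix(0, des$n_fixed, des$n_fixed, sparse = TRUE), Ka)
  W <- des$W1
  if (include_pe) {
    Pinv <- solve(components$P)
    blocks <- c(blocks, list(Matrix::kronecker(Matrix::Diagonal(des$nc), Pinv)))
    W <- cbind(W, des$Zp)
  }
  M <- Matrix::crossprod(W) / se2 + Matrix::bdiag(blocks)
  rhs <- as.numeric(Matrix::crossprod(W, des$y)) / se2
  list(M = M, rhs = rhs, des = des, components = components)
}

#' Solve assembled mixed-model equations
#'
#' @param mme From [build_mme()].
#' @return List with `fixed`, `a_hat` (animals x coefficients) and `p_hat`.
#' @export
solve_mme <- function(mme) {
  sol <- as.numeric(Matrix::solve(mme$M, mme$rhs))
  .split_solutions(sol, mme$des)
}

.split_solutions <- function(sol, des) {
  p <- des$n_fixed; k <- des$k
  q <- length(des$animal_ids)
  fixed <- stats::setNames(sol[seq_len(p)], des$fixed_names)
  a_hat <- matrix(sol[p + seq_len(q * k)], q, k, byrow = TRUE,
                  dimnames = list(des$animal_ids, paste0("leg", 0:(k - 1))))
  p_hat <- NULL
  if (des$include_pe) {
    p_hat <- matrix(sol[p + q * k + seq_len(des$nc * k)], des$nc, k,
                    byrow = TRUE,
                    dimnames = list(des$cows, paste0("leg", 0:(k - 1))))
  }
  list(fixed = fixed, a_hat = a_hat, p_hat = p_hat)
}

# --- one REML iteration ----------------------------------------------------

# Absorbs the (block-diagonal) permanent-environment equations, factorizes
# the remaining fixed+additive system densely, and returns, at the current
# components: the restricted log-likelihood, BLUP/BLUE solutions, the EM
# variance-component update and (optionally) the REML score and
# average-information matrix with the proposed Newton step.
.rrm_iterate <- function(des, Ainv, Ainv_trip, logdetA, comp,
                         want_ai = FALSE) {
  k <- des$k; q <- length(des$animal_ids); p <- des$n_fixed
  se2 <- comp$sigma_e2
  Ginv <- solve(comp$G)
  Sig_ainv <- Matrix::kronecker(Ainv, Ginv)
  M11 <- des$W1tW1 / se2 +
    Matrix::bdiag(Matrix::Matrix(0, p, p, sparse = TRUE), Sig_ainv)
  r1 <- des$W1ty / se2

  logdet_M22 <- 0
  Bsp <- NULL; M12d <- NULL; M22inv <- NULL; Pinv <- NULL
  if (des$include_pe) {
    Pinv <- solve(comp$P)
    nc <- des$nc
    M22inv <- array(0, c(k, k, nc))
    Br2 <- matrix(0, k, nc)
    for (c_ in seq_len(nc)) {
      M22c <- des$PhiTPhi[, , c_] / se2 + Pinv
      ch22 <- chol(M22c)
      logdet_M22 <- logdet_M22 + 2 * sum(log(diag(ch22)))
      M22inv[, , c_] <- chol2inv(ch22)
      Br2[, c_] <- M22inv[, , c_] %*% (des$Phity[, c_] / se2)
    }
    Bsp <- Matrix::bdiag(lapply(seq_len(nc), function(c_) M22inv[, , c_]))
    M12d <- des$M12raw / se2
    S <- M11 - M12d %*% Bsp %*% Matrix::t(M12d)
    r1s <- r1 - as.numeric(M12d %*% as.numeric(Br2))
  } else {
    S <- M11
    r1s <- r1
  }
  Sd <- as.matrix(Matrix::forceSymmetric(S))
  ch <- tryCatch(chol(Sd), error = function(e) {
    stop("mixed-model equations not positive definite: ", conditionMessage(e))
  })
  logdetS <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  sol1 <- drop(Sinv %*% r1s)

  # PE solutions, per-cow inverse blocks, EM update of P
  p_hat <- NULL
  Pnew <- comp$P
  sol_dot_Wty <- sum(sol1 * des$W1ty)
  C22sum <- NULL
  if (des$include_pe) {
    p_hat <- matrix(0, des$nc, k, dimnames = list(des$cows, NULL))
    Pacc <- matrix(0, k, k)
    C22sum <- matrix(0, k, k)
    for (c_ in seq_len(des$nc)) {
      nz <- des$cow_nz[[c_]]
      Msub <- des$M12sub[[c_]] / se2            # |nz| x k
      r2c <- des$Phity[, c_] / se2
      ph <- M22inv[, , c_] %*% (r2c - crossprod(Msub, sol1[nz]))
      p_hat[c_, ] <- ph
      U <- Msub %*% M22inv[, , c_]              # |nz| x k
      C22 <- M22inv[, , c_] + crossprod(U, Sinv[nz, nz, drop = FALSE] %*% U)
      C22sum <- C22sum + C22
      Pacc <- Pacc + tcrossprod(ph) + C22
    }
    Pnew <- Pacc / des$nc
    sol_dot_Wty <- sol_dot_Wty + sum(p_hat * t(des$Phity))
  }

  a_hat <- matrix(sol1[p + seq_len(q * k)], q, k, byrow = TRUE,
                  dimnames = list(des$animal_ids, NULL))

  # EM update of G: (1/q) sum_ij Ainv_ij (a_i a_j' + C^{a_i a_j}); the
  # trace part TrA = sum_ij Ainv_ij C^{a_i a_j} is reused by the
  # average-information traces below
  ti <- Ainv_trip$i; tj <- Ainv_trip$j; tx <- Ainv_trip$x
  TrA <- matrix(0, k, k); Ha <- matrix(0, k, k)
  for (m in seq_len(k)) {
    rows <- p + (ti - 1L) * k + m
    for (n_ in seq_len(k)) {
      cols <- p + (tj - 1L) * k + n_
      TrA[m, n_] <- sum(tx * Sinv[cbind(rows, cols)])
      Ha[m, n_] <- sum(tx * a_hat[ti, m] * a_hat[tj, n_])
    }
  }
  Gnew <- (Ha + TrA + t(Ha + TrA)) / (2 * q)

  yPy <- (des$yty - sol_dot_Wty) / se2
  se2_new <- (des$yty - sol_dot_Wty) / (des$N - des$rankX)

  m2ll <- des$N * log(se2) + k * logdetA + q * determinant(comp$G)$modulus +
    logdetS + logdet_M22 + yPy
  if (des$include_pe) m2ll <- m2ll + des$nc * determinant(comp$P)$modulus

  out <- list(loglik = -0.5 * as.numeric(m2ll),
              G = Gnew, P = Pnew, sigma_e2 = se2_new,
              sol_fixed = stats::setNames(sol1[seq_len(p)], des$fixed_names),
              a_hat = a_hat, p_hat = p_hat)
  if (!want_ai) return(out)

  # ---- REML score and average information --------------------------------
  # parameters ordered as vech(G), vech(P), sigma_e2 (column-major upper
  # triangles, matching the pack()/unpack() convention in reml_fit)
  pairs <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 2], pairs[, 1]), , drop = FALSE]
  npair <- nrow(pairs)
  np <- npair * (1L + des$include_pe) + 1L

  fitted <- as.numeric(des$W1 %*% sol1)
  if (des$include_pe) fitted <- fitted + as.numeric(des$Zp %*% as.vector(t(p_hat)))
  Py <- (des$y - fitted) / se2

  # traces via tr(P Za (A x Es) Za') = q tr(Es Ginv)
  #                                     - tr((Ainv x Ginv Es Ginv) Caa),
  # using Sig^-1 (A x Es) Sig^-1 = Ainv x (Ginv Es Ginv); the sparse
  # contraction with Caa is the TrA matrix already computed above
  tr_CinvPsi_a <- sum(Ginv * TrA)

  Vmat <- matrix(as.numeric(Matrix::crossprod(des$Za, Py)), q, k, byrow = TRUE)
  AV <- as.matrix(Matrix::solve(Ainv, Vmat))      # A %*% Vmat
  Fmat <- matrix(0, des$N, np)
  trv <- numeric(np); quadv <- numeric(np)
  for (j in seq_len(npair)) {
    m <- pairs[j, 1]; n_ <- pairs[j, 2]
    Es <- matrix(0, k, k); Es[m, n_] <- Es[n_, m] <- 1
    trv[j] <- q * sum(Es * Ginv) - sum((Ginv %*% Es %*% Ginv) * TrA)
    W_es <- AV %*% Es
    quadv[j] <- sum(Vmat * W_es)
    Fmat[, j] <- as.numeric(des$Za %*% as.vector(t(W_es)))
  }
  if (des$include_pe) {
    Hsum <- des$nc * Pinv - Pinv %*% C22sum %*% Pinv
    Umat <- matrix(as.numeric(Matrix::crossprod(des$Zp, Py)), des$nc, k,
                   byrow = TRUE)
    for (j in seq_len(npair)) {
      m <- pairs[j, 1]; n_ <- pairs[j, 2]
      Es <- matrix(0, k, k); Es[m, n_] <- Es[n_, m] <- 1
      trv[npair + j] <- if (m == n_) Hsum[m, m] else 2 * Hsum[m, n_]
      U_es <- Umat %*% Es
      quadv[npair + j] <- sum(Umat * U_es)
      Fmat[, npair + j] <- as.numeric(des$Zp %*% as.vector(t(U_es)))
    }
  }
  neq <- p + q * k + (if (des$include_pe) des$nc * k else 0L)
  tr_CinvPsi <- tr_CinvPsi_a +
    (if (des$include_pe) sum(Pinv * C22sum) else 0)
  trv[np] <- (des$N - neq + tr_CinvPsi) / se2
  quadv[np] <- sum(Py^2)
  Fmat[, np] <- Py

  score <- -0.5 * (trv - quadv)

  FtF <- crossprod(Fmat)
  W1tF <- as.matrix(Matrix::crossprod(des$W1, Fmat)) / se2
  if (des$include_pe) {
    ZptF <- as.matrix(Matrix::crossprod(des$Zp, Fmat)) / se2
    BZ <- as.matrix(Bsp %*% ZptF)
    sol1M <- Sinv %*% (W1tF - as.matrix(M12d %*% BZ))
    sol2M <- BZ - as.matrix(Bsp %*% (Matrix::crossprod(M12d, sol1M)))
    FtWU <- se2 * (crossprod(W1tF, sol1M) + crossprod(ZptF, sol2M))
  } else {
    sol1M <- Sinv %*% W1tF
    FtWU <- se2 * crossprod(W1tF, sol1M)
  }
  AI <- 0.5 * (FtF - FtWU) / se2
  AI <- (AI + t(AI)) / 2
  ridge <- 1e-8 * max(diag(AI))
  step <- tryCatch(solve(AI + diag(ridge, np), score),
                   error = function(e) NULL)
  out$score <- score
  out$ai <- AI
  out$ai_step <- step
  out
}

.project_psd <- function(M, floor_frac = 1e-8) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lo <- floor_frac * max(abs(e$values), .Machine$double.eps)
  if (min(e$values) >= lo) return((M + t(M)) / 2)
  vals <- pmax(e$values, lo)
  e$vectors %*% (vals * t(e$vectors))
}

#' Fit the random-regression test-day model by REML
#'
#' Single-trait animal model with fixed herd-test-date, calving month-age
#' and calving year-season effects and two sets of random Legendre
#' regressions (additive genetic with pedigree covariance `G (x) A`;
#' permanent environment `I (x) P`), homogeneous residual variance.
#' Variance components are estimated by EM-REML; when `control$accel` is on
#' (the default), average-information Newton steps are proposed and accepted
#' only if they do not decrease the restricted likelihood, with the EM
#' update as fallback, so the likelihood is non-decreasing over iterations
#' either way.
#'
#' @param records Filtered records with factor levels assigned.
#' @param ped Sorted pedigree covering all recorded cows.
#' @param basis A [legendre_basis()].
#' @param init Optional [var_components()] starting values.
#' @param trait Trait column to fit.
#' @param fixed Fixed-effect factor columns.
#' @param include_pe Include permanent-environment regressions (default
#'   TRUE; FALSE gives a plain repeatability-free animal model).
#' @param control A [reml_control()].
#' @return An object of class `rrm_fit`: estimated `components`, solutions
#'   (`a_hat` for every pedigree animal, `p_hat` per recorded cow,
#'   `fixed_solutions`), `loglik`, `loglik_trace`, `n_iter`, `converged`.
#' @export
reml_fit <- function(records, ped, basis, init = NULL, trait = "my",
                     fixed = c("htd", "age_class", "season_class"),
                     include_pe = TRUE, control = reml_control()) {
  des <- .rrm_design(records, ped, basis, trait, fixed, include_pe,
                     on_alias = "drop")
  Ainv <- nrm_inverse(ped)
  Ainv_t <- methods::as(Ainv, "TsparseMatrix")
  Ainv_trip <- list(i = Ainv_t@i + 1L, j = Ainv_t@j + 1L, x = Ainv_t@x)
  logdetA <- .nrm_logdet(ped)
  k <- des$k

  if (is.null(init)) {
    vy <- stats::var(des$y)
    Gd <- c(0.6, rep(0.1, k - 1L)) * vy
    init <- var_components(diag(Gd, k), diag(Gd, k), 0.4 * vy)
  }
  theta <- list(G = init$G, P = init$P, sigma_e2 = init$sigma_e2)

  pack <- function(th) {
    v <- c(th$G[upper.tri(th$G, diag = TRUE)])
    if (include_pe) v <- c(v, th$P[upper.tri(th$P, diag = TRUE)])
    c(v, th$sigma_e2)
  }
  unpack <- function(v) {
    nh <- k * (k + 1) / 2
    G <- matrix(0, k, k); G[upper.tri(G, diag = TRUE)] <- v[seq_len(nh)]
    G[lower.tri(G)] <- t(G)[lower.tri(G)]
    P <- theta$P
    if (include_pe) {
      P <- matrix(0, k, k); P[upper.tri(P, diag = TRUE)] <- v[nh + seq_len(nh)]
      P[lower.tri(P)] <- t(P)[lower.tri(P)]
      P <- .project_psd(P)
    }
    list(G = .project_psd(G), P = P, sigma_e2 = max(v[length(v)], 1e-12))
  }
  it <- function(th, ai = FALSE) {
    .rrm_iterate(des, Ainv, Ainv_trip, logdetA, th, want_ai = ai)
  }

  trace_ll <- numeric(0)
  st <- it(theta, ai = control$accel)
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    trace_ll <- c(trace_ll, st$loglik)
    if (control$verbose) {
      message(sprintf("iter %3d logL %.6f se2 %.5f", iter, st$loglik,
                      theta$sigma_e2))
    }
    theta_em <- list(G = .project_psd(st$G),
                     P = if (include_pe) .project_psd(st$P) else theta$P,
                     sigma_e2 = st$sigma_e2)
    accepted <- FALSE
    if (control$accel && !is.null(st$ai_step) && iter > 1L) {
      for (sfrac in c(1, 0.5, 0.25)) {   # Newton step with halving on failure
        theta_ai <- unpack(pack(theta) + sfrac * st$ai_step)
        st_try <- tryCatch(it(theta_ai, ai = TRUE), error = function(e) NULL)
        if (!is.null(st_try) && is.finite(st_try$loglik) &&
            st_try$loglik >= st$loglik - 1e-8) {
          theta_new <- theta_ai; st_new <- st_try; accepted <- TRUE
          break
        }
      }
    }
    if (!accepted) {
      theta_new <- theta_em
      st_new <- tryCatch(it(theta_new, ai = control$accel),
                         error = function(e) NULL)
      if (is.null(st_new)) {
        # boundary collapse: retreat halfway toward the previous estimate
        theta_new <- unpack((pack(theta) + pack(theta_em)) / 2)
        st_new <- it(theta_new, ai = control$accel)
      }
    }
    delta <- pack(theta_new) - pack(theta)
    scale <- max(abs(pack(theta)), 1e-12)
    theta <- theta_new
    st <- st_new
    if (max(abs(delta)) / scale < control$tol) {
      trace_ll <- c(trace_ll, st$loglik)
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("REML did not converge in ", control$max_iter, " iterations")
  }
  comp <- var_components(.project_psd(theta$G), .project_psd(theta$P),
                         theta$sigma_e2)
  structure(list(components = comp,
                 a_hat = st$a_hat, p_hat = st$p_hat,
                 fixed_solutions = st$sol_fixed,
                 loglik = st$loglik, loglik_trace = trace_ll,
                 n_iter = iter, converged = converged,
                 basis = basis, trait = trait,
                 rankX = des$rankX, N = des$N),
            class = "rrm_fit")
}

#' @export
print.rrm_fit <- function(x, ...) {
  cat(sprintf("RRM fit (%s): %d records, logL %.3f, %d iterations%s\n",
              x$trait, x$N, x$loglik, x$n_iter,
              if (x$converged) "" else " (NOT converged)"))
  print(x$components)
  invisible(x)
}

# --- DIM-specific quantities -----------------------------------------------

#' Variance components at a given day in milk
#'
#' @param components A [var_components()].
#' @param basis A [legendre_basis()].
#' @param dim Day in milk.
#' @return Named vector: additive `v_a = phi' G phi`, permanent environment
#'   `v_pe = phi' P phi`, phenotypic `v_p = v_a + v_pe + sigma_e2`.
#' @export
variance_at <- function(components, basis, dim) {
  phi <- legendre_row(dim, basis)
  v_a <- drop(phi %*% components$G %*% phi)
  v_pe <- drop(phi %*% components$P %*% phi)
  c(v_a = v_a, v_pe = v_pe, v_p = v_a + v_pe + components$sigma_e2)
}

#' Heritability along the lactation trajectory
#'
#' h2(t) = phi(t)' G phi(t) / (phi(t)' G phi(t) + phi(t)' P phi(t) +
#' sigma_e2).
#'
#' @inheritParams variance_at
#' @param dims Integer vector of days in milk.
#' @return Named numeric vector of heritabilities in \[0, 1\].
#' @export
heritability_curve <- function(components, basis, dims) {
  vapply(dims, function(d) {
    v <- variance_at(components, basis, d)
    if (v[["v_p"]] <= 0) stop("zero phenotypic variance at DIM ", d)
    v[["v_a"]] / v[["v_p"]]
  }, numeric(1)) -> h2
  stats::setNames(h2, dims)
}

#' Genetic correlation between two days in milk
#'
#' r(t1, t2) = phi1' G phi2 / sqrt(phi1' G phi1 * phi2' G phi2).
#'
#' @inheritParams variance_at
#' @param dim1,dim2 Days in milk.
#' @return Correlation in \[-1, 1\].
#' @export
genetic_correlation <- function(components, basis, dim1, dim2) {
  p1 <- legendre_row(dim1, basis); p2 <- legendre_row(dim2, basis)
  v1 <- drop(p1 %*% components$G %*% p1)
  v2 <- drop(p2 %*% components$G %*% p2)
  if (v1 <= 0 || v2 <= 0) {
    stop("zero additive variance at DIM ", if (v1 <= 0) dim1 else dim2)
  }
  drop(p1 %*% components$G %*% p2) / sqrt(v1 * v2)
}

#' Genetic-correlation matrix over a DIM grid
#'
#' @inheritParams variance_at
#' @param dims Integer vector of days in milk.
#' @return Correlation matrix with unit diagonal.
#' @export
genetic_correlation_grid <- function(components, basis, dims) {
  Phi <- legendre_matrix(dims, basis)
  V <- Phi %*% components$G %*% t(Phi)
  d <- sqrt(diag(V))
  if (any(d <= 0)) stop("zero additive variance on the DIM grid")
  R <- V / tcrossprod(d)
  dimnames(R) <- list(dims, dims)
  R
}

#' Estimated breeding value at a day in milk
#'
#' The DIM-specific EBV is the fitted additive trajectory value
#' phi(dim)' a_hat.
#'
#' @param fit An [reml_fit()] result.
#' @param animal Animal id(s).
#' @param dim Day in milk.
#' @param basis Basis (defaults to the fit's).
#' @return Named numeric vector of EBVs (trait units).
#' @export
ebv_at_dim <- function(fit, animal, dim, basis = fit$basis) {
  idx <- match(animal, rownames(fit$a_hat))
  if (anyNA(idx)) {
    stop("unknown animal(s): ", paste(animal[is.na(idx)], collapse = ", "))
  }
  phi <- legendre_row(dim, basis)
  stats::setNames(drop(fit$a_hat[idx, , drop = FALSE] %*% phi), animal)
}
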