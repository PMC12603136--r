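# ---------------------------------------------------------------------------
# Classical residue-level deconvolution baselines
#
# All four comparators operate per fixed exposure time on the linear system
# U_peptide = C U_residue, with U_peptide in exchangeable-amide units and
# U_residue in fraction-of-FD units (C's row sums are the amide counts l_i,
# which keeps the units consistent).
# ---------------------------------------------------------------------------

#' Generalised-inverse (pseudo-inverse) residue uptake
#'
#' Solves U_residue = C^+ U_peptide with the Moore-Penrose pseudo-inverse
#' (minimum-norm least-squares solution). No constraints are imposed, so
#' estimates may be negative or exceed 1 -- the documented pathology of this
#' approach on noisy data.
#'
#' @param C binary coupling matrix (peptides x residues), see
#'   \code{\link{coupling_matrix}}.
#' @param u_pep numeric vector (one timepoint) or N x M matrix of peptide
#'   uptakes in amide units.
#' @return residue uptakes: vector or R x M matrix.
#' @export
pinv_uptake <- function(C, u_pep) {
  Cp <- MASS::ginv(C)
  out <- Cp %*% as.matrix(u_pep)
  if (is.vector(u_pep)) drop(out) else out
}

#' Box-constrained least-squares residue uptake
#'
#' Minimizes ||U_peptide - C U_residue||_2 subject to every residue uptake
#' lying in \[0, 1\], via L-BFGS-B started from the clipped pseudo-inverse
#' solution.
#'
#' @inheritParams pinv_uptake
#' @param tol convergence tolerance passed to the optimizer.
#' @return residue uptakes in \[0, 1\]: vector or R x M matrix.
#' @export
leastsq_uptake <- function(C, u_pep, tol = 1e-10) {
  U <- as.matrix(u_pep)
  start <- pmin(pmax(pinv_uptake(C, U), 0), 1)
  out <- vapply(seq_len(ncol(U)), function(m) {
    y <- U[, m]
    fn <- function(u) 0.5 * sum((y - C %*% u)^2)
    gr <- function(u) as.numeric(crossprod(C, C %*% u - y))
    res <- optim(start[, m], fn, gr, method = "L-BFGS-B",
                 lower = 0, upper = 1,
                 control = list(maxit = 2000L, factr = tol / .Machine$double.eps))
    if (res$convergence != 0)
      stop("box-constrained least squares failed to converge: ",
           res$message)
    res$par
  }, numeric(nrow(start)))
  if (is.vector(u_pep)) drop(out) else out
}

#' Fused-LASSO residue uptake
#'
#' Minimizes
#' \deqn{0.5\,||U_{pep} - C U_{res}||_2^2 +
#'       \lambda \sum_j |U_{res,j} - U_{res,j+1}|}
#' subject to the \[0, 1\] box, encouraging neighbouring residues to share
#' uptake values. Solved by ADMM with two splits (one for the total-
#' variation term, one for the box), so each iteration is a cached linear
#' solve plus soft-thresholding and clipping. \code{lambda = 0} reduces to
#' the box-constrained least-squares solution; \code{lambda -> Inf} yields a
#' constant vector.
#'
#' @inheritParams pinv_uptake
#' @param lambda non-negative fusion penalty (the conventional strong
#'   setting in cross-method comparisons is 5).
#' @param rho ADMM penalty parameter.
#' @param tol stopping tolerance on primal/dual residual norms.
#' @param max_iter iteration cap; non-convergence raises an error with the
#'   attained residuals.
#' @return residue uptakes in \[0, 1\]: vector or R x M matrix.
#' @export
fused_lasso_uptake <- function(C, u_pep, lambda, rho = 1,
                               tol = 1e-8, max_iter = 100000L) {
  stopifnot(lambda >= 0)
  if (lambda == 0) return(leastsq_uptake(C, u_pep))
  U <- as.matrix(u_pep)
  R <- ncol(C)
  D <- diff(diag(R))                      # (R-1) x R first differences
  CtC <- crossprod(C)
  DtD <- crossprod(D)
  soft <- function(x, k) sign(x) * pmax(abs(x) - k, 0)

  out <- vapply(seq_len(ncol(U)), function(m) {
    y <- U[, m]
    Cty <- as.numeric(crossprod(C, y))
    u <- pmin(pmax(pinv_uptake(C, y), 0), 1)
    z1 <- as.numeric(D %*% u); z2 <- u
    w1 <- numeric(R - 1L); w2 <- numeric(R)
    rho_m <- rho
    ch <- chol(CtC + rho_m * DtD + rho_m * diag(R))
    for (it in seq_len(max_iter)) {
      rhs <- Cty + rho_m * crossprod(D, z1 - w1) + rho_m * (z2 - w2)
      u <- as.numeric(backsolve(ch, forwardsolve(t(ch), rhs)))
      Du <- as.numeric(D %*% u)
      z1_new <- soft(Du + w1, lambda / rho_m)
      z2_new <- pmin(pmax(u + w2, 0), 1)
      w1 <- w1 + Du - z1_new
      w2 <- w2 + u - z2_new
      r_prim <- sqrt(sum((Du - z1_new)^2) + sum((u - z2_new)^2))
      r_dual <- rho_m * sqrt(sum((crossprod(D, z1_new - z1))^2) +
                               sum((z2_new - z2)^2))
      z1 <- z1_new; z2 <- z2_new
      if (r_prim < tol && r_dual < tol) break
      # residual balancing keeps the two convergence rates comparable
      if (it %% 100L == 0L && (r_prim > 10 * r_dual ||
                               r_dual > 10 * r_prim)) {
        fac <- if (r_prim > 10 * r_dual) 2 else 0.5
        rho_m <- rho_m * fac
        w1 <- w1 / fac
        w2 <- w2 / fac
        ch <- chol(CtC + rho_m * DtD + rho_m * diag(R))
      }
    }
    if (r_prim >= tol || r_dual >= tol)
      stop(sprintf(paste0("fused-LASSO ADMM did not converge: primal %.2e,",
                          " dual %.2e after %d iterations"),
                   r_prim, r_dual, max_iter))
    z2                                    # the box-feasible iterate
  }, numeric(R))
  if (is.vector(u_pep)) drop(out) else out
}

#' Redundancy-weighted residue averaging
#'
#' Each residue's uptake is the mean of the length-normalized uptakes of the
#' peptides covering it (the weighted-average comparator). Heavily smoothed
#' by construction: it cannot adapt to sharp changes between neighbours.
#'
#' @param pt a \code{\link{peptide_table}} (single state).
#' @return R x M matrix of residue uptake fractions; residues covered by no
#'   peptide are NA.
#' @export
residue_average_uptake <- function(pt) {
  cache <- pt_cache(pt)
  M <- length(cache$times)
  out <- matrix(NA_real_, cache$R, M)
  # mean uptake fraction per (peptide, time) across replicates
  for (m in seq_len(M)) {
    sel <- cache$obs_idx[, 2L] == m
    pep <- cache$obs_idx[sel, 1L]
    yfrac <- cache$obs_y[sel] / cache$obs_l[sel]
    pep_mean <- tapply(yfrac, pep, mean)
    rows <- as.integer(names(pep_mean))
    Csub <- cache$C[rows, , drop = FALSE]
    n_r <- colSums(Csub)
    tot <- as.numeric(crossprod(Csub, as.numeric(pep_mean)))
    out[n_r > 0, m] <- tot[n_r > 0] / n_r[n_r > 0]
  }
  out
}

# ---------------------------------------------------------------------------
# Common baseline interface for the benchmark: peptide_table -> R x M matrix
# ---------------------------------------------------------------------------

# Replicate-averaged peptide uptake matrix in amide units (N x M).
peptide_uptake_matrix <- function(cache) {
  M <- length(cache$times)
  N <- nrow(cache$C)
  Y <- matrix(NA_real_, N, M)
  for (m in seq_len(M)) {
    sel <- cache$obs_idx[, 2L] == m
    pep_mean <- tapply(cache$obs_y[sel], cache$obs_idx[sel, 1L], mean)
    Y[as.integer(names(pep_mean)), m] <- pep_mean
  }
  if (any(is.na(Y))) stop("incomplete peptide x time uptake grid")
  Y
}

#' Baseline residue-uptake fits under a common interface
#'
#' Convenience dispatcher mapping a single-state \code{\link{peptide_table}}
#' to a residues x times uptake matrix, for use as a plug-in method in the
#' leave-digests-out benchmark. Each timepoint is solved independently
#' (the comparators carry no temporal coupling, hence their documented
#' monotonicity violations).
#'
#' @param pt a single-state \code{\link{peptide_table}}.
#' @param method one of "pinv", "leastsq", "fused", "average".
#' @param lambda fusion penalty for \code{method = "fused"}.
#' @return R x M matrix of residue uptake fractions.
#' @export
baseline_uptake <- function(pt, method = c("pinv", "leastsq", "fused",
                                           "average"), lambda = 5) {
  method <- match.arg(method)
  if (method == "average") return(residue_average_uptake(pt))
  cache <- pt_cache(pt)
  Y <- peptide_uptake_matrix(cache)
  switch(method,
         pinv = pinv_uptake(cache$C, Y),
         leastsq = leastsq_uptake(cache$C, Y),
         fused = fused_lasso_uptake(cache$C, Y, lambda))
}
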