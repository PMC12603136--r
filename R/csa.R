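# ---------------------------------------------------------------------------
# Conformational signature analysis: states x residues TRE matrices,
# PCA, OPLS-DA, Procrustes-aligned posterior uncertainty
# ---------------------------------------------------------------------------

# Time-averaged differential TRE profile (length R) from an N x M peptide
# prediction matrix against the reference cache. Sign: predicted - observed
# (protection negative).
tre_profile_from_pred <- function(pred, cache) {
  M <- length(cache$times)
  tre_t <- matrix(NA_real_, cache$R, M)
  e_obs <- (pred[cache$obs_idx] - cache$obs_y) / cache$obs_l
  for (m in seq_len(M)) {
    sel <- cache$obs_idx[, 2L] == m
    pep_mean <- tapply(e_obs[sel], cache$obs_idx[sel, 1L], mean)
    rows <- as.integer(names(pep_mean))
    tre_t[, m] <- as.numeric(crossprod(cache$C[rows, , drop = FALSE],
                                       as.numeric(pep_mean)))
  }
  n_r <- colSums(cache$C)
  out <- rowMeans(tre_t)
  out[n_r == 0] <- NA_real_
  out
}

#' Assemble a conformational signature matrix
#'
#' Row c is the time-averaged differential TRE profile of state c against
#' the common reference peptide table (each state's fitted model predicts
#' the reference's peptides; predicted minus observed, summed over covering
#' peptides, averaged over timepoints). Optional per-posterior-sample
#' replicate matrices support downstream uncertainty quantification.
#'
#' @param fits named list of \code{hdx_posterior} objects, one per state,
#'   all fitted against the same protein coordinates.
#' @param reference the reference (APO) \code{\link{peptide_table}}.
#' @param n_replicates number of posterior-sample replicate matrices to
#'   draw (0 = none; 50 is the conventional choice for uncertainty work).
#' @param seed RNG seed for the replicate subsampling.
#' @return list of class \code{signature_matrix}: \code{X} (states x
#'   residues, NA-free columns only are informative), \code{labels},
#'   \code{replicates} (list of matrices shaped like X), \code{residues}.
#' @export
build_signature_matrix <- function(fits, reference, n_replicates = 0L,
                                   seed = NULL) {
  cache <- pt_cache(reference)
  R <- cache$R
  if (!all(vapply(fits, function(f) f$R, 0L) == R))
    stop("all fitted states must share the reference protein length")
  profile_of <- function(fit, s = NULL) {
    mu <- if (is.null(s))
      apply(posterior_uptake_at(fit, cache$times), c(1L, 2L), mean)
    else residue_uptake_matrix(state_theta_by_residue(fit$states[[s]]),
                               cache$times)
    tre_profile_from_pred(cache$C %*% mu, cache)
  }
  X <- t(vapply(fits, profile_of, numeric(R)))
  rownames(X) <- names(fits)
  reps <- list()
  if (n_replicates > 0L) {
    reps <- with_seed(seed, {
      idx <- lapply(fits, function(f)
        sample.int(length(f$states), n_replicates, replace = TRUE))
      lapply(seq_len(n_replicates), function(b) {
        Xi <- t(vapply(seq_along(fits), function(c)
          profile_of(fits[[c]], idx[[c]][b]), numeric(R)))
        rownames(Xi) <- names(fits)
        Xi
      })
    })
  }
  out <- list(X = X, labels = names(fits), replicates = reps,
              residues = seq_len(R))
  class(out) <- "signature_matrix"
  out
}

# Drop all-NA / zero-coverage columns, remember which were kept.
usable_columns <- function(X) which(apply(X, 2L, function(v) all(!is.na(v))))

#' PCA of a signature matrix
#'
#' Column-centered (not variance-scaled: residues share units) principal
#' component analysis. Scores are the states' coordinates, loadings the
#' residues' contributions; columns with missing values (uncovered
#' residues) are excluded and reported.
#'
#' @param X states x residues matrix, or a \code{signature_matrix}.
#' @param n_comp number of components to keep (default all).
#' @return list: scores (C x k), loadings (R_used x k, orthonormal),
#'   var_explained (fractions), center, cols (column indices used).
#' @export
pca_signatures <- function(X, n_comp = NULL) {
  if (inherits(X, "signature_matrix")) X <- X$X
  if (nrow(X) < 2L) stop("need at least two states")
  cols <- usable_columns(X)
  pc <- prcomp(X[, cols, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- if (is.null(n_comp)) ncol(pc$rotation) else
    min(n_comp, ncol(pc$rotation))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       var_explained = ve[seq_len(k)], center = pc$center, cols = cols)
}

#' OPLS-DA of a signature matrix
#'
#' One predictive component maximally covarying with the annotation y plus
#' orthogonal components capturing y-uncorrelated variation (the O-PLS
#' decomposition). y may be a two-level factor (dummy-coded) or a numeric
#' vector (standardized); rows with missing y are excluded from fitting and
#' projected afterwards.
#'
#' @param X states x residues matrix or \code{signature_matrix}.
#' @param y annotation vector, length nrow(X), NAs allowed.
#' @param n_orth number of orthogonal components (default 1).
#' @return list: scores_pred, loadings_pred, scores_orth, loadings_orth,
#'   var_explained_pred (fraction of X variance captured by the predictive
#'   component), projected (scores of all rows incl. missing-y rows), cols.
#' @export
oplsda_signatures <- function(X, y, n_orth = 1L) {
  if (inherits(X, "signature_matrix")) X <- X$X
  cols <- usable_columns(X)
  Xu <- X[, cols, drop = FALSE]
  if (is.character(y)) y <- factor(y)
  if (is.factor(y)) {
    if (nlevels(droplevels(y[!is.na(y)])) != 2L)
      stop("categorical y must have exactly two observed classes")
    yn <- ifelse(y == levels(droplevels(y[!is.na(y)]))[1L], -1, 1)
  } else {
    if (stats::var(y, na.rm = TRUE) == 0) stop("continuous y has no variance")
    yn <- as.numeric(scale(y))
  }
  obs <- which(!is.na(yn))
  if (length(obs) < 3L) stop("need at least three annotated states")
  ctr <- colMeans(Xu[obs, , drop = FALSE])
  Xc_all <- sweep(Xu, 2L, ctr)
  Xc <- Xc_all[obs, , drop = FALSE]
  yv <- yn[obs] - mean(yn[obs])
  tot_var <- sum(Xc^2)
  if (sum(abs(crossprod(Xc, yv))) < 1e-12)
    stop("singular cross-covariance between X and y")

  w <- as.numeric(crossprod(Xc, yv)); w <- w / sqrt(sum(w^2))
  E <- Xc; E_all <- Xc_all
  W_o <- NULL; P_o <- NULL; T_o <- NULL; T_o_all <- NULL
  for (j in seq_len(n_orth)) {
    t_ <- as.numeric(E %*% w)
    p_ <- as.numeric(crossprod(E, t_)) / sum(t_^2)
    w_o <- p_ - sum(w * p_) * w
    n_w <- sqrt(sum(w_o^2))
    if (n_w < 1e-12) break                    # no orthogonal variation left
    w_o <- w_o / n_w
    t_o <- as.numeric(E %*% w_o)
    p_o <- as.numeric(crossprod(E, t_o)) / sum(t_o^2)
    E <- E - tcrossprod(t_o, p_o)
    t_o_all <- as.numeric(E_all %*% w_o)
    E_all <- E_all - tcrossprod(t_o_all, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o); T_o_all <- cbind(T_o_all, t_o_all)
  }
  t_pred <- as.numeric(E %*% w)
  p_pred <- as.numeric(crossprod(E, t_pred)) / sum(t_pred^2)
  t_pred_all <- as.numeric(E_all %*% w)

  list(scores_pred = t_pred, loadings_pred = p_pred,
       scores_orth = T_o, loadings_orth = P_o,
       weights_pred = w, weights_orth = W_o,
       var_explained_pred = sum(t_pred^2) * sum(p_pred^2) / tot_var,
       projected = list(pred = t_pred_all, orth = T_o_all),
       y_used = obs, cols = cols)
}

#' Procrustes-aligned posterior uncertainty of CSA projections
#'
#' Re-runs the PCA on each posterior-replicate signature matrix, aligns
#' each replicate's scores to the reference configuration by a rigid
#' Procrustes transform (rotation/reflection plus translation, no scaling),
#' applies the same rotation to the replicate loadings, and summarizes the
#' per-state score clouds and per-residue loading quantiles. A loading
#' interval that crosses zero marks a residue whose contribution cannot be
#' asserted as non-zero.
#'
#' @param sig a \code{signature_matrix} with replicates (see
#'   \code{\link{build_signature_matrix}}).
#' @param n_comp number of components to align (default 2).
#' @return list: reference (PCA of the mean matrix), score_clouds (array
#'   states x n_comp x n_replicates), loading_quantiles (data frame:
#'   residue, component, q2.5, q50, q97.5, uncertain_zero).
#' @export
projection_uncertainty <- function(sig, n_comp = 2L) {
  stopifnot(inherits(sig, "signature_matrix"))
  if (length(sig$replicates) < 2L)
    stop("need >= 2 replicate matrices; rebuild with n_replicates > 1")
  if (nrow(sig$X) <= n_comp)
    stop("fewer states than requested dimensions + 1: alignment degenerate")
  ref <- pca_signatures(sig$X, n_comp = n_comp)
  fix_signs <- function(sc, ld) {
    for (j in seq_len(ncol(ld))) {
      i_max <- which.max(abs(ld[, j]))
      if (ld[i_max, j] < 0) { ld[, j] <- -ld[, j]; sc[, j] <- -sc[, j] }
    }
    list(scores = sc, loadings = ld)
  }
  rf <- fix_signs(ref$scores, ref$loadings)
  C <- nrow(sig$X)
  B <- length(sig$replicates)
  clouds <- array(NA_real_, c(C, n_comp, B),
                  dimnames = list(sig$labels, NULL, NULL))
  load_arr <- array(NA_real_, c(length(ref$cols), n_comp, B))
  for (b in seq_len(B)) {
    pb <- pca_signatures(sig$replicates[[b]], n_comp = n_comp)
    if (!identical(pb$cols, ref$cols))
      stop("replicate ", b, " covers different residues than the reference")
    fb <- fix_signs(pb$scores, pb$loadings)
    pr <- vegan::procrustes(rf$scores, fb$scores, scale = FALSE)
    clouds[, , b] <- pr$Yrot
    load_arr[, , b] <- fb$loadings %*% pr$rotation
  }
  lq <- do.call(rbind, lapply(seq_len(n_comp), function(j) {
    qs <- t(apply(load_arr[, j, , drop = TRUE], 1L, quantile,
                  probs = c(0.025, 0.5, 0.975)))
    data.frame(residue = sig$residues[ref$cols], component = j,
               q2.5 = qs[, 1L], q50 = qs[, 2L], q97.5 = qs[, 3L],
               uncertain_zero = qs[, 1L] < 0 & qs[, 3L] > 0)
  }))
  rownames(lq) <- NULL
  ref$scores <- rf$scores
  ref$loadings <- rf$loadings
  list(reference = ref, score_clouds = clouds, loading_quantiles = lq)
}
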