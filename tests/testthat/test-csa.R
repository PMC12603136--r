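# Build a small panel of fitted states against a common reference. Kept
# deliberately tiny: CSA consumes fitted posteriors, so correctness of the
# multivariate layer is what matters here, not posterior quality.
make_panel <- function(n_states = 4L, seed = 161L) {
  fx <- sim_fixture(R = 30L, n_pep = 25L, sigma = 0.004, seed = seed)
  red <- residue_redundancy(fx$pt)
  target <- which(red >= 3)[2]
  fits <- list()
  for (c in seq_len(n_states)) {
    ptc <- simulate_uptake_data(fx$truth, fx$map, sigma = 0.004,
                                seed = seed + 10L * c)
    # first half of the states carry a protection effect at the target
    if (c <= n_states / 2) ptc <- apply_protection_effect(ptc, target, 0.85)
    fits[[paste0("state", c)]] <-
      run_rjmcmc(ptc, config = quick_config(seed = seed + c,
                                            n_iter = 900L, burn_in = 300L,
                                            thin = 6L))
  }
  list(fits = fits, reference = fx$pt, target = target)
}

panel <- make_panel()

test_that("signature rows are per-state differential TRE profiles", {
  sig <- build_signature_matrix(panel$fits, panel$reference)
  expect_equal(dim(sig$X), c(4L, 30L))
  # column-by-column consistency with differential_tre's time average
  d1 <- differential_tre(panel$fits[[1]], panel$reference, seed = 1)
  avg1 <- d1[is.na(d1$exposure), ]
  expect_equal(unname(sig$X[1, ]), avg1$tre, tolerance = 1e-10)
  # a state fitted to data distributed like the reference: near-zero row;
  # protected states deviate more
  norms <- sqrt(rowSums(sig$X^2, na.rm = TRUE))
  expect_gt(mean(norms[1:2]), mean(norms[3:4]))
})

test_that("PCA on signatures is orthonormal and permutation-equivariant", {
  sig <- build_signature_matrix(panel$fits, panel$reference)
  pc <- pca_signatures(sig)
  L <- pc$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-10)
  # reconstruction of the centered matrix from scores and loadings
  Xc <- sweep(sig$X[, pc$cols], 2, pc$center)
  expect_equal(Xc, pc$scores %*% t(L), tolerance = 1e-8,
               ignore_attr = TRUE)
  # identical rows collapse to identical (zero) scores after centering
  X2 <- rbind(sig$X[1, ], sig$X[1, ], sig$X[1, ])
  pc2 <- pca_signatures(X2)
  expect_lt(max(abs(pc2$scores)), 1e-10)
  # row permutation permutes scores, leaves loadings fixed up to sign
  perm <- c(3L, 1L, 4L, 2L)
  pc3 <- pca_signatures(sig$X[perm, ])
  agree <- vapply(seq_len(ncol(pc$scores)), function(j)
    min(max(abs(pc3$scores[, j] - pc$scores[perm, j])),
        max(abs(pc3$scores[, j] + pc$scores[perm, j]))), numeric(1))
  expect_lt(max(agree), 1e-8)
})

test_that("OPLS-DA separates constructed classes and passes a null check", {
  # constructed example: two linearly separable classes in a residue block
  set.seed(21)
  X <- matrix(rnorm(8 * 20, 0, 0.05), 8, 20)
  X[1:4, 3:6] <- X[1:4, 3:6] + 1
  # add structured y-orthogonal variation
  X <- X + outer(rnorm(8), c(rep(0, 10), rep(1, 10)) * 0.5)
  y <- factor(rep(c("on", "off"), each = 4))
  fit <- oplsda_signatures(X, y)
  cls <- split(fit$scores_pred, y)
  expect_true(max(cls$off) < min(cls$on) || max(cls$on) < min(cls$off))
  # predictive and orthogonal scores are orthogonal
  expect_lt(abs(sum(fit$scores_pred * fit$scores_orth[, 1])), 1e-8)
  # permutation null: random labels explain about chance-level variance
  obs_stat <- fit$var_explained_pred
  set.seed(22)
  Xnull <- matrix(rnorm(8 * 20), 8, 20)
  stat_null <- oplsda_signatures(Xnull, y)$var_explained_pred
  perms <- replicate(199, {
    oplsda_signatures(Xnull, sample(y))$var_explained_pred
  })
  p_val <- (1 + sum(perms >= stat_null)) / 200
  expect_gt(p_val, 0.05)
  # missing labels are projected, not fitted
  y_na <- y
  y_na[1] <- NA
  fit_na <- oplsda_signatures(X, y_na)
  expect_equal(length(fit_na$projected$pred), 8L)
  expect_equal(length(fit_na$y_used), 7L)
  # degenerate annotations are rejected
  expect_error(oplsda_signatures(X, factor(rep("a", 8))), "two observed")
  expect_error(oplsda_signatures(X, rep(1, 8)), "no variance")
})

test_that("Procrustes alignment recovers rotations and zero spread", {
  sig <- build_signature_matrix(panel$fits, panel$reference,
                                n_replicates = 6L, seed = 31)
  # identical replicates: clouds collapse onto the reference scores
  sig0 <- sig
  sig0$replicates <- list(sig$X, sig$X, sig$X)
  pu0 <- projection_uncertainty(sig0, n_comp = 2L)
  spread <- apply(pu0$score_clouds, c(1, 2), sd)
  expect_lt(max(spread), 1e-8)
  # a rotated copy of the reference scores aligns with residual zero
  ref <- pca_signatures(sig$X, n_comp = 2L)
  ang <- pi / 5
  Rot <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2)
  pr <- vegan::procrustes(ref$scores, ref$scores %*% Rot, scale = FALSE)
  expect_lt(sum((pr$Yrot - ref$scores)^2), 1e-16)
  # genuine posterior replicates: finite spread, loading intervals defined
  pu <- projection_uncertainty(sig, n_comp = 2L)
  expect_equal(dim(pu$score_clouds), c(4L, 2L, 6L))
  lq <- pu$loading_quantiles
  expect_true(all(lq$q2.5 <= lq$q50 & lq$q50 <= lq$q97.5))
  # the zero-crossing flag is exactly the interval test
  expect_equal(lq$uncertain_zero, lq$q2.5 < 0 & lq$q97.5 > 0)
  # sign convention: invariance to flipping a replicate's column signs is
  # enforced by the max-|loading| rule inside the alignment
  expect_error(projection_uncertainty(sig, n_comp = 4L), "degenerate")
})
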