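test_that("exchangeable residues follow the amide-set definition", {
  # 11-mer without proline: first two residues and the C-terminus drop out
  expect_equal(exchangeable_residues(10, 20, "ACDEFGHIKLM"), 12:19)
  # proline at residue 15 additionally removed
  expect_equal(exchangeable_residues(10, 20, "ACDEFPHIKLM"),
               c(12:14, 16:19))
  # boundary peptide: end-exclusive reading empties the set
  expect_equal(exchangeable_residues(10, 12, "ACD"), integer(0))
  # the inclusive-end switch keeps the C-terminal residue
  expect_equal(exchangeable_residues(10, 12, "ACD", inclusive_end = TRUE),
               12L)
  expect_error(exchangeable_residues(10, 9, "A"), "start < end")
  expect_error(exchangeable_residues(10, 20, "ACD"), "length")
})

test_that("residue uptake curve is a bounded monotone mixture", {
  th <- kinetic_params(pi = 0.999999, p = 0.5, b = 0.1, d = 0.1)
  # essentially pure exponential branch: 1 - e^{-1} at d*t = 1
  expect_equal(residue_uptake(th, 10), 1 - exp(-1), tolerance = 1e-5)
  expect_equal(residue_uptake(th, 0), 0)
  # mixture collapse: p -> 1 and b = d reduces to one exponential
  th2 <- kinetic_params(pi = 0.5, p = 1 - 1e-12, b = 0.02, d = 0.02)
  t <- c(0.5, 5, 50, 500)
  expect_equal(residue_uptake(th2, t), 1 - exp(-0.02 * t),
               tolerance = 1e-8)
  # property: monotone non-decreasing and in [0, 1] over random params
  set.seed(42)
  for (i in 1:25) {
    th3 <- kinetic_params(runif(1, .01, .99), runif(1, .01, .99),
                          rexp(1, 10), rexp(1, 10))
    u <- residue_uptake(th3, sort(c(0, 10^runif(20, -2, 6))))
    expect_true(all(diff(u) >= -1e-12))
    expect_true(all(u >= 0 & u < 1 + 1e-12))
  }
})

test_that("segment lookup is a step function with K jumps", {
  th <- rbind(c(0.3, 0.5, 0.01, 0.001), c(0.7, 0.4, 0.02, 0.005))
  st <- chain_state(1L, 10.5, th, sigma = 0.05, d_rate = 1, b_rate = 1,
                    R = 20L)
  expect_equal(unclass(segment_lookup(st, 10))[1:4], unname(th[1, ]),
               ignore_attr = TRUE)
  expect_equal(unclass(segment_lookup(st, 11))[1:4], unname(th[2, ]),
               ignore_attr = TRUE)
  st0 <- chain_state(0L, numeric(0), th[1, , drop = FALSE], 0.05, 1, 1, 20L)
  expect_true(all(segment_index(st0, 1:20) == 1L))
  # random states: brute-force segment assignment oracle
  set.seed(7)
  for (i in 1:10) {
    K <- sample(0:4, 1)
    tau <- sort(runif(K, 1, 30))
    stK <- chain_state(K, tau, matrix(rep(c(0.5, 0.5, 0.01, 0.001), K + 1),
                                      ncol = 4, byrow = TRUE),
                       0.05, 1, 1, 30L)
    oracle <- vapply(1:30, function(r) {
      k <- 1L
      for (tj in tau) if (tj <= r) k <- k + 1L
      k
    }, integer(1))
    expect_equal(segment_index(stK, 1:30), oracle)
    expect_equal(sum(diff(segment_index(stK, 1:30)) != 0), K)
  }
})

test_that("peptide prediction sums residue curves over the amide set", {
  # all residues share params chosen so each component equals 0.4 at t = 10
  d <- -log(0.6) / 10
  b <- -log(0.6) / sqrt(10)
  th <- matrix(c(0.5, 0.5, b, d), 1)
  st <- chain_state(0L, numeric(0), th, 0.05, 1, 1, 20L)
  pep <- list(start = 5L, end = 12L, sequence = "ACDEFGHI")  # l = 5
  expect_equal(predict_peptide_uptake(st, pep, 10), 2.0, tolerance = 1e-12)
  expect_equal(predict_peptide_uptake(st, pep, 0), 0)
  # oracle: explicit per-residue loop on a random multi-segment state
  set.seed(11)
  stK <- chain_state(2L, c(8.2, 14.7),
                     cbind(runif(3, .2, .8), runif(3, .2, .8),
                           rexp(3, 5), rexp(3, 50)), 0.05, 1, 1, 20L)
  exch <- exchangeable_residues(5, 12, "ACDEFGHI") + 0L
  t <- c(15, 150)
  oracle <- colSums(t(vapply(exch, function(r)
    residue_uptake(segment_lookup(stK, r), t), numeric(2))))
  expect_equal(predict_peptide_uptake(stK, list(exch = exch), t), oracle)
})

test_that("Laplace likelihood matches hand-computed sums", {
  pt <- toy_table()
  th <- matrix(c(0.5, 0.5, 0.01, 0.001), 1)
  st <- chain_state(0L, numeric(0), th, sigma = 0.1, d_rate = 1,
                    b_rate = 1, R = 13L)
  # independent arithmetic: per-observation Laplace terms assembled by hand
  expected <- 0
  for (i in seq_len(nrow(pt$observations))) {
    ob <- pt$observations[i, ]
    pep <- pt$peptides[pt$peptides$id == ob$peptide_id, ]
    l <- pep$l
    mu <- sum(vapply(pep$exch[[1]], function(r)
      residue_uptake(segment_lookup(st, r), ob$exposure), numeric(1)))
    s <- l * 0.1^2
    expected <- expected + (-log(2 * s) - abs(ob$uptake * l - mu) / s)
  }
  expect_equal(log_likelihood(st, pt), expected, tolerance = 1e-12)
  # zero-residual observation contributes exactly -log(2 s)
  one <- toy_table()
  one$observations <- one$observations[1, , drop = FALSE]
  mu1 <- predict_peptide_uptake(st, one$peptides[1, ], 15)
  one$observations$uptake <- mu1 / one$peptides$l[1]
  s1 <- one$peptides$l[1] * 0.1^2
  expect_equal(log_likelihood(st, one), -log(2 * s1))
  # inflating all residuals can only decrease the likelihood
  worse <- toy_table(uptakes = c(0.9, 0.95, 0.9, 0.95, 0.9, 0.95))
  expect_lt(log_likelihood(st, worse), log_likelihood(st, pt))
})

test_that("log prior assembles Poisson, ordered-uniform and density terms", {
  hyper <- default_hyperparameters(101, lambda = 3)
  th1 <- matrix(c(0.5, 0.5, 0.01, 0.001), 1)
  st0 <- chain_state(0L, numeric(0), th1, 0.05, 1, 1, 101L)
  st1 <- chain_state(1L, 50, rbind(th1, th1), 0.05, 1, 1, 101L)
  # independent assembly of each factor with stats densities
  term_theta <- dbeta(0.5, 1, 1, log = TRUE) * 2 +
    dgamma(0.01, 1, rate = 1, log = TRUE) +
    dgamma(0.001, 1, rate = 1, log = TRUE)
  base <- dlnorm(0.05, -3, 1, log = TRUE) +
    dgamma(1, 1, rate = 1, log = TRUE) * 2
  expect_equal(log_prior(st0, hyper),
               dpois(0, 3, log = TRUE) + term_theta + base)
  # K = 1 on R = 101: the change-point term is log(1/100)
  expect_equal(log_prior(st1, hyper),
               dpois(1, 3, log = TRUE) + log(1 / 100) + 2 * term_theta +
                 base)
  # K = 2 on R = 11: the change-point term is log(2!/10^2)
  hyper11 <- default_hyperparameters(11, lambda = 3)
  st2 <- chain_state(2L, c(3, 7), rbind(th1, th1, th1), 0.05, 1, 1, 11L)
  expect_equal(log_prior(st2, hyper11),
               dpois(2, 3, log = TRUE) + log(2 / 100) + 3 * term_theta +
                 base)
  # out-of-support parameters signal auto-reject
  bad <- st1
  bad$sigma <- -1
  expect_identical(log_prior(bad, hyper), -Inf)
})
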