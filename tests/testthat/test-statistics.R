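# A minimal hand-held posterior: one stored state, known sigma, so all
# downstream quantities are deterministic given the state.
fixed_posterior <- function(st, sigma = NULL, times = c(15, 150)) {
  if (!is.null(sigma)) st$sigma <- sigma
  out <- list(states = list(st),
              uptake_draws = array(
                hdxcp:::residue_uptake_matrix(
                  hdxcp:::state_theta_by_residue(st), times),
                c(st$R, length(times), 1)),
              sigma = st$sigma, times = times, R = st$R)
  class(out) <- "hdx_posterior"
  out
}

toy_state <- function(R = 13L, sigma = 0.1)
  chain_state(0L, numeric(0), matrix(c(0.5, 0.5, 0.01, 0.001), 1),
              sigma = sigma, d_rate = 1, b_rate = 1, R = R)

test_that("reconstruction errors are observed minus predicted", {
  pt <- toy_table()
  st <- toy_state()
  fit <- fixed_posterior(st)
  # perfect fit: set observations to the model predictions exactly
  perfect <- pt
  for (i in seq_len(nrow(perfect$observations))) {
    ob <- perfect$observations[i, ]
    pep <- perfect$peptides[perfect$peptides$id == ob$peptide_id, ]
    perfect$observations$uptake[i] <-
      predict_peptide_uptake(st, pep, ob$exposure) / pep$l
  }
  re0 <- reconstruction_errors(fit, perfect)
  expect_equal(re0$re, rep(0, 6), tolerance = 1e-12)
  # constant offset in fraction units shifts RE by delta * l (linearity)
  shifted <- perfect
  shifted$observations$uptake <- shifted$observations$uptake + 0.05
  re1 <- reconstruction_errors(fit, shifted)
  expect_equal(re1$re, 0.05 * re1$l, tolerance = 1e-12)
  expect_equal(re1$re_norm, rep(0.05, 6), tolerance = 1e-12)
  # arithmetic oracle on the 3-peptide toy
  re2 <- reconstruction_errors(fit, pt)
  i <- 4L  # peptide 2 at t = 150
  ob <- pt$observations[i, ]
  pep <- pt$peptides[pt$peptides$id == ob$peptide_id, ]
  expect_equal(re2$re[i],
               ob$uptake * pep$l -
                 predict_peptide_uptake(st, pep, ob$exposure),
               tolerance = 1e-12)
})

test_that("residue summaries amplify consistent errors and cancel opposed",
{
  # two peptides, both covering residue 8; equal normalized RE +0.1
  peps <- data.frame(id = 1:2, sequence = c("ACDEFGHI", "DEFGHIKL"),
                     start = c(1L, 3L), end = c(8L, 10L))
  obs <- data.frame(peptide_id = 1:2, state = "A", exposure = 15,
                    replicate = 1L, uptake = 0.5)
  pt <- peptide_table(peps, obs)
  re <- data.frame(peptide_id = 1:2, exposure = 15, replicate = 1L,
                   l = 5L, re = 0.5, re_norm = 0.1)
  st8 <- residue_errors(re, pt)
  # amide sets are 3..7 and 5..9: residue 6 is covered by both peptides
  row8 <- st8[st8$residue == 6 & !is.na(st8$exposure), ]
  expect_equal(row8$signed_are, 0.1)
  expect_equal(row8$are, 0.1)
  expect_equal(row8$tre, 0.2)           # summed, not averaged
  # opposite-signed pair cancels TRE but not ARE
  re$re_norm <- c(0.1, -0.1)
  st8b <- residue_errors(re, pt)
  row8b <- st8b[st8b$residue == 6 & !is.na(st8b$exposure), ]
  expect_equal(row8b$signed_are, 0)
  expect_equal(row8b$are, 0.1)
  expect_equal(row8b$tre, 0)
  # uncovered residues are missing, never zero
  expect_true(all(is.na(st8$tre[st8$residue == 1])))
  # random tables match an explicit double loop
  fx <- sim_fixture(seed = 111)
  fit <- fixed_posterior(toy_state(R = fx$pt$R, sigma = 0.05),
                         times = c(15, 150, 1500, 15000))
  reF <- reconstruction_errors(fit, fx$pt)
  stF <- residue_errors(reF, fx$pt)
  cache <- hdxcp:::pt_cache(fx$pt)
  for (r in c(7L, 19L)) {
    cov <- which(cache$C[, r] == 1)
    t0 <- 150
    vals <- vapply(cov, function(i) {
      id <- cache$peptides$id[i]
      mean(reF$re_norm[reF$peptide_id == id & reF$exposure == t0])
    }, numeric(1))
    row <- stF[stF$residue == r & !is.na(stF$exposure) &
                 stF$exposure == t0, ]
    if (length(cov) == 0) { expect_true(is.na(row$tre)); next }
    expect_equal(row$tre, sum(vals), tolerance = 1e-12)
    expect_equal(row$signed_are, mean(vals), tolerance = 1e-12)
    expect_equal(row$are, mean(abs(vals)), tolerance = 1e-12)
    expect_equal(row$n, length(cov))
  }
})

test_that("effect probabilities match a large-sample Monte-Carlo oracle", {
  st <- toy_state(R = 13L, sigma = 0.1)
  fit <- fixed_posterior(st)
  base <- data.frame(residue = 1:3, exposure = 15, n = c(2L, 2L, 3L),
                     signed_are = c(0, 0.15, 2), are = c(0, 0.15, 2),
                     tre = c(0, 0.3, 6))
  pr <- effect_probabilities(base, fit, n_inner = 50000L, seed = 5)
  # TRE = 0 can never exceed |tau|; huge TRE always does
  expect_equal(pr$prob_tre[1], 0)
  expect_gt(pr$prob_tre[3], 0.999)
  # brute-force oracle for the middle case: P(|0.3| > |L1 + L2|),
  # L ~ Laplace(0, 0.1), via direct simulation with its own RNG
  set.seed(99)
  rl <- function(n) { u <- runif(n) - 0.5; -0.1 * sign(u) * log1p(-2*abs(u)) }
  oracle <- mean(abs(0.3) > abs(rl(1e6) + rl(1e6)))
  se <- sqrt(oracle * (1 - oracle) / 50000)
  expect_lt(abs(pr$prob_tre[2] - oracle), 4 * se)
  # monotone in |TRE| for fixed sigma draws
  sweep_tre <- data.frame(residue = 1:5, exposure = 15, n = 2L,
                          signed_are = 0, are = 0,
                          tre = c(0.05, 0.1, 0.2, 0.4, 0.8))
  pr2 <- effect_probabilities(sweep_tre, fit, n_inner = 20000L, seed = 6)
  expect_true(all(diff(pr2$prob_tre) >= 0))
})

test_that("EFDR arithmetic and threshold search follow the definitions", {
  probs <- c(0.99, 0.95, 0.6)
  expect_equal(efdr(probs, 0.95), (0.01 + 0.05) / 2)
  expect_equal(efdr(rep(1, 5), 0.9), 0)
  expect_warning(out <- efdr(probs, 0.999), "undefined")
  expect_true(is.na(out))
  # threshold search equals an exhaustive scan over observed values
  set.seed(8)
  for (rep in 1:5) {
    p <- round(runif(30), 3)
    lvl <- 0.1
    got <- efdr_threshold(p, lvl)
    cand <- sort(unique(p), decreasing = TRUE)
    ok <- vapply(seq_along(cand), function(i)
      all(vapply(cand[1:i], function(q) efdr(p, q) < lvl, logical(1))),
      logical(1))
    want <- if (any(ok)) min(cand[seq_len(max(which(ok)))]) else NA_real_
    expect_identical(got, want)
  }
})

test_that("differential analysis has the documented sign and null behaviour",
{
  fx <- sim_fixture(R = 30L, n_pep = 25L, sigma = 0.004, seed = 121)
  fit <- run_rjmcmc(fx$pt, config = quick_config(seed = 122, n_iter = 1200L,
                                                 burn_in = 400L, thin = 4L))
  # null contract: comparing the fitted state against its own data gives
  # small TRE and no calls at EFDR 0.05
  diff0 <- differential_tre(fit, fx$pt, seed = 1)
  avg0 <- diff0[is.na(diff0$exposure), ]
  expect_lt(max(abs(avg0$tre), na.rm = TRUE), 0.2)
  expect_true(all(!avg0$call, na.rm = TRUE))
  # uniformly reduced uptake in the fitted state's data -> the reference
  # (higher uptake) shows negative TRE: protection is negative by convention
  apo <- fx$pt
  apo$observations$uptake <- apo$observations$uptake / 0.9
  diff1 <- differential_tre(fit, apo, seed = 2)
  avg1 <- diff1[is.na(diff1$exposure), ]
  expect_lt(median(avg1$tre, na.rm = TRUE), 0)
  # swapping the direction flips the sign of the effect
  apo2 <- fx$pt
  apo2$observations$uptake <- apo2$observations$uptake * 0.9
  diff2 <- differential_tre(fit, apo2, seed = 3)
  avg2 <- diff2[is.na(diff2$exposure), ]
  expect_gt(median(avg2$tre, na.rm = TRUE), 0)
  # disjoint coordinates are rejected
  bad <- fx$pt
  bad$R <- 99L
  expect_error(differential_tre(fit, bad), "does not match")
})
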