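# ---------------------------------------------------------------------------
# Reversible-jump MCMC over the change-point model
# ---------------------------------------------------------------------------

#' Sampler configuration
#'
#' @param n_iter total iterations.
#' @param burn_in iterations discarded (must be < n_iter).
#' @param thin keep every thin-th post-burn-in state.
#' @param theta_scale random-walk SD for segment parameters on their
#'   transformed scales (logit for pi and p, log for b and d).
#' @param sigma_scale random-walk SD for log sigma.
#' @param adapt Robbins-Monro adaptation of the two proposal scales during
#'   burn-in, targeting 30% acceptance; frozen afterwards so the post-burn-in
#'   kernel satisfies detailed balance.
#' @param n_rj dimension (birth/death) moves attempted per iteration;
#'   raising it decorrelates the K and tau chains at small cost (each move
#'   is one likelihood evaluation).
#' @param seed RNG seed for the whole run (reproducibility contract:
#'   identical seed and config give identical chains).
#' @param flat_likelihood replace the likelihood by a constant; the chain
#'   then samples the prior exactly (used for prior-recovery validation).
#' @param max_K hard cap on the number of change points (guards runaway
#'   dimension under pathological inputs).
#' @return list of class \code{sampler_config}.
#' @export
sampler_config <- function(n_iter = 30000L, burn_in = 10000L, thin = 10L,
                           theta_scale = 0.4, sigma_scale = 0.25,
                           adapt = TRUE, n_rj = 1L, seed = NULL,
                           flat_likelihood = FALSE, max_K = 50L) {
  stopifnot(burn_in < n_iter, thin >= 1L, n_rj >= 1L)
  cfg <- list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
              thin = as.integer(thin), theta_scale = theta_scale,
              sigma_scale = sigma_scale, adapt = adapt,
              n_rj = as.integer(n_rj), seed = seed,
              flat_likelihood = flat_likelihood, max_K = as.integer(max_K))
  class(cfg) <- "sampler_config"
  cfg
}

# -- transforms -------------------------------------------------------------

theta_to_z <- function(row)
  c(qlogis(row[[1L]]), qlogis(row[[2L]]), log(row[[3L]]), log(row[[4L]]))

z_to_theta <- function(z)
  c(pi = plogis(z[[1L]]), p = plogis(z[[2L]]), b = exp(z[[3L]]),
    d = exp(z[[4L]]))

# log prior density of a segment parameter row expressed in z-space
# (includes the Jacobian of the transform).
log_theta_prior_z <- function(row, hyper, d_rate, b_rate) {
  log_theta_prior(row, hyper, d_rate, b_rate) +
    log(row[[1L]] * (1 - row[[1L]])) + log(row[[2L]] * (1 - row[[2L]])) +
    log(row[[3L]]) + log(row[[4L]])
}

# ---------------------------------------------------------------------------
# Initialization: pseudo-inverse -> per-residue curve fits -> L1 trend filter
# ---------------------------------------------------------------------------

# Total-variation (piecewise-constant L1 trend) denoising of a signal,
# by the same ADMM scheme as the fused-LASSO solver with identity design.
tv_denoise <- function(y, lambda, rho = 1, tol = 1e-8, max_iter = 20000L) {
  n <- length(y)
  if (n < 3L || lambda == 0) return(y)
  D <- diff(diag(n))
  A <- diag(n) + rho * crossprod(D)
  ch <- chol(A)
  soft <- function(x, k) sign(x) * pmax(abs(x) - k, 0)
  z <- as.numeric(D %*% y); w <- numeric(n - 1L); u <- y
  for (it in seq_len(max_iter)) {
    u <- backsolve(ch, forwardsolve(t(ch), y + rho * crossprod(D, z - w)))
    u <- as.numeric(u)
    Du <- as.numeric(D %*% u)
    z_new <- soft(Du + w, lambda / rho)
    w <- w + Du - z_new
    r_prim <- sqrt(sum((Du - z_new)^2))
    r_dual <- rho * sqrt(sum(crossprod(D, z_new - z)^2))
    z <- z_new
    if (r_prim < tol && r_dual < tol) break
  }
  u
}

# Least-squares fit of the residue uptake curve to one residue's estimated
# uptakes across the time grid; returns transformed parameters z.
fit_residue_curve <- function(u, times, z0 = NULL) {
  if (is.null(z0)) {
    u_end <- min(0.99, max(0.01, u[length(u)]))
    rate0 <- -log(1 - u_end) / times[length(times)]
    z0 <- c(0, 0, log(rate0), log(rate0))
  }
  obj <- function(z) {
    th <- z_to_theta(z)
    mu <- (1 - th[["pi"]]) * (1 - exp(-th[["b"]] * times^th[["p"]])) +
      th[["pi"]] * (1 - exp(-th[["d"]] * times))
    sum((u - mu)^2) + 1e-6 * sum(z^2)   # tiny ridge: 4 params, few times
  }
  res <- tryCatch(optim(z0, obj, method = "BFGS",
                        control = list(maxit = 300L)),
                  error = function(e) NULL)
  if (is.null(res) || any(!is.finite(res$par))) z0 else res$par
}

#' Data-driven initialization of the chain
#'
#' Pipeline: per-timepoint pseudo-inverse residue estimates, projected onto
#' \[0, 1\]; per-residue least-squares fits of the kinetic curve on
#' transformed scales; L1 trend filtering (total-variation denoising) of the
#' four fitted parameter tracks; segment extraction from the joint jump
#' pattern of the filtered tracks; sigma from the median absolute
#' length-normalized residual.
#'
#' @param data a single-state \code{\link{peptide_table}}.
#' @param hyper hyperparameters.
#' @param tv_lambda trend-filter penalty on the transformed-parameter scale.
#' @param jump_tol minimum filtered-track jump treated as a change point.
#' @return a \code{\link{chain_state}}.
#' @export
initialize_chain <- function(data, hyper, tv_lambda = 2, jump_tol = 0.1) {
  cache <- pt_cache(data)
  R <- cache$R
  Y <- peptide_uptake_matrix(cache)
  U <- pinv_uptake(cache$C, Y)
  U <- pmin(pmax(U, 0), 1)                # project onto [0,1]
  covered <- colSums(cache$C) > 0
  Z <- matrix(0, R, 4L)
  for (r in which(covered)) Z[r, ] <- fit_residue_curve(U[r, ], cache$times)
  if (any(!covered)) {                     # carry nearest covered fit over
    idx <- which(covered)
    for (r in which(!covered)) Z[r, ] <- Z[idx[which.min(abs(idx - r))], ]
  }
  Zf <- apply(Z, 2L, tv_denoise, lambda = tv_lambda)
  jump <- rowSums(abs(apply(Zf, 2L, diff)) > jump_tol) > 0
  cp <- which(jump)                        # change between residue r, r+1
  if (length(cp) > max(1L, 3L * ceiling(hyper$lambda))) {
    sizes <- apply(abs(apply(Zf, 2L, diff)), 1L, max)[cp]
    cp <- sort(cp[order(sizes, decreasing = TRUE)[
      seq_len(3L * ceiling(hyper$lambda))]])
  }
  K <- length(cp)
  tau <- cp + 0.5
  bounds <- c(1, tau, R + 1e-9)
  theta <- t(vapply(seq_len(K + 1L), function(k) {
    rs <- which(seq_len(R) >= bounds[k] & seq_len(R) < bounds[k + 1L])
    if (length(rs) == 0L) rs <- max(1L, floor(bounds[k]))
    z <- colMeans(Zf[rs, , drop = FALSE])
    z_to_theta(z)
  }, numeric(4L)))
  # sigma from residual spread: |y - C mu| / l estimates sigma^2
  st0 <- chain_state(K, tau, theta, sigma = 0.05, d_rate = 1, b_rate = 1,
                     R = R)
  mu_res <- residue_uptake_matrix(state_theta_by_residue(st0), cache$times)
  pred <- cache$C %*% mu_res
  res_norm <- abs(cache$obs_y - pred[cache$obs_idx]) / cache$obs_l
  sigma0 <- sqrt(max(1e-6, median(res_norm)))
  chain_state(K, tau, theta, sigma = sigma0, d_rate = 1, b_rate = 1, R = R)
}

# ---------------------------------------------------------------------------
# Moves. Each returns list(state, loglik, accepted). `ll_fun(state)` is the
# (possibly flat) log-likelihood closure.
# ---------------------------------------------------------------------------

birth_move <- function(st, ll, ll_fun, hyper) {
  K <- st$K
  j <- if (K == 0L) 1L else sample.int(K + 1L, 1L)
  lo <- if (j == 1L) 1 else st$tau[j - 1L]
  hi <- if (j == K + 1L) st$R else st$tau[j]
  tau_new <- runif(1, lo, hi)
  if (tau_new <= lo || tau_new >= hi || tau_new %in% st$tau)
    return(list(state = st, loglik = ll, accepted = FALSE))
  th_new <- draw_theta_prior(hyper, st$d_rate, st$b_rate, n = 2L)
  prop <- st
  prop$K <- K + 1L
  prop$tau <- append(st$tau, tau_new, after = j - 1L)
  prop$theta <- rbind(
    st$theta[seq_len(j - 1L), , drop = FALSE], th_new,
    if (j + 1L <= K + 1L) st$theta[seq(j + 1L, K + 1L), , drop = FALSE])
  ll_prop <- ll_fun(prop)
  # prior ratio (theta terms cancel with the kernels; kept explicit)
  d_lp <- log_prior(prop, hyper) - log_prior(st, hyper)
  log_q_fwd <- log(hyper$rho) - log(K + 1) - log(hi - lo) +
    log_theta_prior(th_new[1L, ], hyper, st$d_rate, st$b_rate) +
    log_theta_prior(th_new[2L, ], hyper, st$d_rate, st$b_rate)
  log_q_rev <- log(1 - hyper$rho) - log(K + 1) +
    log_theta_prior(st$theta[j, ], hyper, st$d_rate, st$b_rate)
  log_alpha <- (ll_prop - ll) + d_lp + log_q_rev - log_q_fwd
  if (is.finite(log_alpha) && log(runif(1)) < log_alpha)
    list(state = prop, loglik = ll_prop, accepted = TRUE)
  else list(state = st, loglik = ll, accepted = FALSE)
}

death_move <- function(st, ll, ll_fun, hyper) {
  K <- st$K
  if (K == 0L) return(list(state = st, loglik = ll, accepted = FALSE))
  j <- sample.int(K, 1L)
  lo <- if (j == 1L) 1 else st$tau[j - 1L]
  hi <- if (j == K) st$R else st$tau[j + 1L]
  th_merge <- draw_theta_prior(hyper, st$d_rate, st$b_rate, n = 1L)
  prop <- st
  prop$K <- K - 1L
  prop$tau <- st$tau[-j]
  prop$theta <- rbind(
    st$theta[seq_len(j - 1L), , drop = FALSE], th_merge,
    if (j + 2L <= K + 1L) st$theta[seq(j + 2L, K + 1L), , drop = FALSE])
  ll_prop <- ll_fun(prop)
  d_lp <- log_prior(prop, hyper) - log_prior(st, hyper)
  log_q_fwd <- log(1 - hyper$rho) - log(K) +
    log_theta_prior(th_merge[1L, ], hyper, st$d_rate, st$b_rate)
  log_q_rev <- log(hyper$rho) - log(K) - log(hi - lo) +
    log_theta_prior(st$theta[j, ], hyper, st$d_rate, st$b_rate) +
    log_theta_prior(st$theta[j + 1L, ], hyper, st$d_rate, st$b_rate)
  log_alpha <- (ll_prop - ll) + d_lp + log_q_rev - log_q_fwd
  if (is.finite(log_alpha) && log(runif(1)) < log_alpha)
    list(state = prop, loglik = ll_prop, accepted = TRUE)
  else list(state = st, loglik = ll, accepted = FALSE)
}

# One random-walk MH sweep over segment parameters and sigma; returns the
# updated state plus acceptance counts.
mh_sweep <- function(st, ll, ll_fun, hyper, theta_scale, sigma_scale) {
  acc_theta <- 0L; n_theta <- 0L
  for (k in seq_len(st$K + 1L)) {
    z <- theta_to_z(st$theta[k, ])
    z_prop <- z + rnorm(4L, 0, theta_scale)
    row_prop <- z_to_theta(z_prop)
    prop <- st
    prop$theta[k, ] <- row_prop
    ll_prop <- ll_fun(prop)
    log_alpha <- (ll_prop - ll) +
      log_theta_prior_z(row_prop, hyper, st$d_rate, st$b_rate) -
      log_theta_prior_z(st$theta[k, ], hyper, st$d_rate, st$b_rate)
    n_theta <- n_theta + 1L
    if (is.finite(log_alpha) && log(runif(1)) < log_alpha) {
      st <- prop; ll <- ll_prop; acc_theta <- acc_theta + 1L
    }
  }
  # sigma on the log scale (log sigma ~ Normal(m, v))
  z <- log(st$sigma)
  z_prop <- z + rnorm(1L, 0, sigma_scale)
  prop <- st
  prop$sigma <- exp(z_prop)
  ll_prop <- ll_fun(prop)
  log_alpha <- (ll_prop - ll) +
    dnorm(z_prop, hyper$m, hyper$v, log = TRUE) -
    dnorm(z, hyper$m, hyper$v, log = TRUE)
  acc_sigma <- FALSE
  if (is.finite(log_alpha) && log(runif(1)) < log_alpha) {
    st <- prop; ll <- ll_prop; acc_sigma <- TRUE
  }
  list(state = st, loglik = ll, acc_theta = acc_theta, n_theta = n_theta,
       acc_sigma = acc_sigma)
}

# Conjugate Gibbs update of the Gamma hyper-rates.
gibbs_rates <- function(st, hyper) {
  Kp1 <- st$K + 1L
  st$d_rate <- rgamma(1, hyper$d_alpha + Kp1 * hyper$d_shape,
                      rate = hyper$d_beta + sum(st$theta[, 4L]))
  st$b_rate <- rgamma(1, hyper$b_alpha + Kp1 * hyper$b_shape,
                      rate = hyper$b_beta + sum(st$theta[, 3L]))
  st
}

# ---------------------------------------------------------------------------
# The main sampler
# ---------------------------------------------------------------------------

#' Run the reversible-jump sampler
#'
#' Alternates one dimension move (birth with probability rho, else death)
#' with a fixed-dimension Metropolis-Hastings sweep over segment parameters
#' and sigma, and a conjugate Gibbs update of the Gamma hyper-rates, in a
#' fixed order for reproducibility. Thinned post-burn-in states are stored
#' together with their residue x time uptake trajectories, which are by
#' construction bounded in \[0, 1\] and monotone in time.
#'
#' @param data a single-state \code{\link{peptide_table}}; may be NULL when
#'   \code{config$flat_likelihood} is TRUE.
#' @param hyper hyperparameters; defaults to
#'   \code{default_hyperparameters(R)} from the data.
#' @param config a \code{\link{sampler_config}}.
#' @param times time grid for the stored uptake trajectories (defaults to
#'   the data's exposure times).
#' @param R protein length (required in flat-likelihood mode without data).
#' @param init optional starting \code{\link{chain_state}}; defaults to
#'   \code{\link{initialize_chain}} (or a prior draw in flat mode).
#' @return object of class \code{hdx_posterior}: stored states, uptake draw
#'   array (R x M x S), sigma and K traces, acceptance counters, config.
#' @export
run_rjmcmc <- function(data = NULL, hyper = NULL, config = sampler_config(),
                       times = NULL, R = NULL, init = NULL) {
  flat <- isTRUE(config$flat_likelihood)
  if (!flat && is.null(data)) stop("data required unless flat_likelihood")
  cache <- if (!flat) pt_cache(data) else NULL
  if (is.null(R)) R <- if (!flat) cache$R else stop("R required in flat mode")
  if (is.null(hyper)) hyper <- default_hyperparameters(R)
  if (is.null(times)) times <- if (!flat) cache$times else
    c(15, 150, 1500, 15000)
  ll_fun <- if (flat) function(st) 0 else function(st) loglik_cached(st, cache)

  run <- function() {
    st <- if (!is.null(init)) init else if (flat) {
      d_rate <- rgamma(1, hyper$d_alpha, rate = hyper$d_beta)
      b_rate <- rgamma(1, hyper$b_alpha, rate = hyper$b_beta)
      chain_state(0L, numeric(0), draw_theta_prior(hyper, d_rate, b_rate),
                  sigma = exp(hyper$m), d_rate = d_rate, b_rate = b_rate,
                  R = R)
    } else initialize_chain(data, hyper)
    ll <- ll_fun(st)
    if (!is.finite(ll)) stop("non-finite likelihood at initialization")

    n_keep <- (config$n_iter - config$burn_in) %/% config$thin
    uptake_draws <- array(NA_real_, c(R, length(times), n_keep))
    states <- vector("list", n_keep)
    sigma_draws <- numeric(n_keep)
    K_trace <- integer(config$n_iter)
    acc <- c(birth = 0L, death = 0L, theta = 0L, sigma = 0L)
    tries <- c(birth = 0L, death = 0L, theta = 0L, sigma = 0L)
    theta_scale <- config$theta_scale
    sigma_scale <- config$sigma_scale
    kept <- 0L
    reject_window <- 0L

    for (it in seq_len(config$n_iter)) {
      # dimension move(s)
      for (b in seq_len(config$n_rj)) {
        if (runif(1) < hyper$rho) {
          if (st$K < config$max_K) {
            mv <- birth_move(st, ll, ll_fun, hyper)
            tries["birth"] <- tries["birth"] + 1L
            if (mv$accepted) acc["birth"] <- acc["birth"] + 1L
            st <- mv$state; ll <- mv$loglik
          }
        } else {
          mv <- death_move(st, ll, ll_fun, hyper)
          tries["death"] <- tries["death"] + 1L
          if (mv$accepted) acc["death"] <- acc["death"] + 1L
          st <- mv$state; ll <- mv$loglik
        }
      }
      # fixed-dimension sweep
      sw <- mh_sweep(st, ll, ll_fun, hyper, theta_scale, sigma_scale)
      st <- sw$state; ll <- sw$loglik
      acc["theta"] <- acc["theta"] + sw$acc_theta
      tries["theta"] <- tries["theta"] + sw$n_theta
      acc["sigma"] <- acc["sigma"] + sw$acc_sigma
      tries["sigma"] <- tries["sigma"] + 1L
      st <- gibbs_rates(st, hyper)

      # Robbins-Monro adaptation toward 30% acceptance, burn-in only
      if (config$adapt && it <= config$burn_in && it %% 50L == 0L) {
        gain <- min(0.5, 5 / sqrt(it))
        rate_t <- if (tries["theta"]) acc["theta"] / tries["theta"] else 0.3
        rate_s <- if (tries["sigma"]) acc["sigma"] / tries["sigma"] else 0.3
        theta_scale <- theta_scale * exp(gain * (rate_t - 0.3))
        sigma_scale <- sigma_scale * exp(gain * (rate_s - 0.3))
      }

      reject_window <- if (sw$acc_theta == 0L && !sw$acc_sigma)
        reject_window + 1L else 0L
      if (!is.finite(ll) || st$sigma > 1e6)
        stop("sampler divergence at iteration ", it,
             ": sigma = ", st$sigma, ", loglik = ", ll)
      if (reject_window > 5000L)
        stop("sampler stalled: no accepted parameter move in 5000 sweeps")

      K_trace[it] <- st$K
      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thin == 0L) {
        kept <- kept + 1L
        states[[kept]] <- st
        sigma_draws[kept] <- st$sigma
        uptake_draws[, , kept] <-
          residue_uptake_matrix(state_theta_by_residue(st), times)
      }
    }

    out <- list(states = states[seq_len(kept)],
                uptake_draws = uptake_draws[, , seq_len(kept), drop = FALSE],
                sigma = sigma_draws[seq_len(kept)],
                K_trace = K_trace, accept = acc, tries = tries,
                times = times, R = R, hyper = hyper, config = config,
                scales = c(theta = theta_scale, sigma = sigma_scale))
    class(out) <- "hdx_posterior"
    out
  }
  with_seed(config$seed, run())
}

#' @export
print.hdx_posterior <- function(x, ...) {
  S <- length(x$states)
  cat("hdx_posterior:", S, "stored samples | R =", x$R,
      "| mean K =", round(mean(vapply(x$states, `[[`, 0L, "K")), 2),
      "| mean sigma =", signif(mean(x$sigma), 3), "\n")
  ar <- ifelse(x$tries > 0, x$accept / x$tries, NA)
  cat("acceptance rates:",
      paste(names(ar), round(ar, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior-mean residue uptake matrix
#'
#' Elementwise mean of the stored residue uptake trajectories. Every entry
#' lies in \[0, 1\] and each residue's trajectory is monotone
#' non-decreasing in time, since each stored draw has those properties.
#'
#' @param samples an \code{hdx_posterior} from \code{\link{run_rjmcmc}}.
#' @return R x M matrix.
#' @export
posterior_mean_uptake <- function(samples) {
  stopifnot(length(samples$states) >= 1L)
  apply(samples$uptake_draws, c(1L, 2L), mean)
}

#' Residue uptake draws at arbitrary times
#'
#' Re-evaluates each stored state's residue kinetics on a new time grid.
#'
#' @param samples an \code{hdx_posterior}.
#' @param times time grid in seconds.
#' @return array R x length(times) x S.
#' @export
posterior_uptake_at <- function(samples, times) {
  S <- length(samples$states)
  out <- array(NA_real_, c(samples$R, length(times), S))
  for (s in seq_len(S))
    out[, , s] <- residue_uptake_matrix(
      state_theta_by_residue(samples$states[[s]]), times)
  out
}
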