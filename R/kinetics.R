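#' @importFrom stats dbeta dgamma dlnorm dnorm dpois median optim plogis
#'   prcomp qlogis quantile rbeta rgamma rlnorm rnorm rpois runif sd
#'   setNames var
#' @importFrom utils read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Kinetic parameters and residue-level forward model
# ---------------------------------------------------------------------------

#' Kinetic parameters for one residue segment
#'
#' A residue's exchange kinetics are a two-component mixture: a stretched
#' exponential (Weibull) component with rate \code{b} and stretch \code{p},
#' and a single-exponential component with rate \code{d}, mixed by
#' \code{pi}. The mixture of the two cumulative distribution functions is by
#' construction bounded in \[0, 1\] and monotone in time.
#'
#' @param pi mixture proportion in (0, 1); weight of the single-exponential
#'   component.
#' @param p Weibull stretch exponent in (0, 1).
#' @param b Weibull rate, > 0, units 1/time^p.
#' @param d exponential rate, > 0, units 1/time.
#' @return a named numeric vector of class \code{kinetic_params}.
#' @export
#' @examples
#' th <- kinetic_params(pi = 0.5, p = 0.8, b = 0.01, d = 0.001)
#' residue_uptake(th, c(0, 15, 150, 1500))
kinetic_params <- function(pi, p, b, d) {
  x <- c(pi = pi, p = p, b = b, d = d)
  validate_kinetic_params(x)
  class(x) <- "kinetic_params"
  x
}

validate_kinetic_params <- function(x) {
  if (any(!is.finite(x))) stop("kinetic parameters must be finite")
  if (x[["pi"]] <= 0 || x[["pi"]] >= 1) stop("pi must lie strictly in (0,1)")
  if (x[["p"]] <= 0 || x[["p"]] >= 1) stop("p must lie strictly in (0,1)")
  if (x[["b"]] <= 0 || x[["d"]] <= 0) stop("b and d must be strictly positive")
  invisible(x)
}

#' Residue-level deuterium uptake curve
#'
#' Evaluates the latent residue process
#' \deqn{\mu(t) = (1-\pi)(1-e^{-b t^p}) + \pi (1-e^{-d t}),}
#' a convex mixture of Weibull and exponential uptake CDFs, so the value is
#' always in \[0, 1\], zero at \code{t = 0} and non-decreasing in \code{t}.
#'
#' @param params a \code{\link{kinetic_params}} object (or any numeric vector
#'   with named entries pi, p, b, d).
#' @param t non-negative time(s) in seconds.
#' @return numeric vector of uptake fractions, same length as \code{t}.
#' @export
residue_uptake <- function(params, t) {
  stopifnot(all(t >= 0))
  (1 - params[["pi"]]) * (1 - exp(-params[["b"]] * t^params[["p"]])) +
    params[["pi"]] * (1 - exp(-params[["d"]] * t))
}

# Vectorised over residues: theta is an R x 4 matrix (pi, p, b, d per row),
# times a length-M vector. Returns R x M matrix of uptake fractions.
residue_uptake_matrix <- function(theta, times) {
  R <- nrow(theta)
  M <- length(times)
  out <- matrix(0, R, M)
  pi_ <- theta[, 1L]; p_ <- theta[, 2L]; b_ <- theta[, 3L]; d_ <- theta[, 4L]
  for (m in seq_len(M)) {
    t <- times[m]
    out[, m] <- (1 - pi_) * (1 - exp(-b_ * t^p_)) + pi_ * (1 - exp(-d_ * t))
  }
  out
}

# ---------------------------------------------------------------------------
# Exchangeable residues
# ---------------------------------------------------------------------------

#' Exchangeable backbone amides of a peptide
#'
#' The peptide's first two residues are lost to rapid back-exchange and
#' prolines carry no backbone amide hydrogen, so the exchangeable set is
#' \{r : start + 2 <= r < end, residue r is not proline\}. The end-exclusive
#' bound is the literal convention used throughout this package; set
#' \code{inclusive_end = TRUE} to retain the C-terminal residue.
#'
#' @param start,end first and last residue of the peptide in 1-based
#'   inclusive protein coordinates.
#' @param sequence amino-acid string of the peptide itself
#'   (length \code{end - start + 1}).
#' @param inclusive_end include residue \code{end} in the set (default FALSE).
#' @return integer vector of exchangeable residue indices in protein
#'   coordinates (possibly empty, in which case the peptide is
#'   non-informative and is excluded from the likelihood).
#' @export
#' @examples
#' exchangeable_residues(10, 20, "ACDEFGHIKLM")
#' exchangeable_residues(10, 20, "ACDEFPHIKLM")  # Pro at residue 15 dropped
exchangeable_residues <- function(start, end, sequence,
                                  inclusive_end = FALSE) {
  if (start >= end) stop("peptide must satisfy start < end")
  if (nchar(sequence) != end - start + 1L)
    stop("sequence length must equal end - start + 1")
  hi <- if (inclusive_end) end else end - 1L
  if (hi < start + 2L) return(integer(0))
  r <- seq.int(start + 2L, hi)
  aa <- strsplit(sequence, "")[[1L]]
  r[aa[r - start + 1L] != "P"]
}

# ---------------------------------------------------------------------------
# Chain state
# ---------------------------------------------------------------------------

#' One state of the change-point sampler
#'
#' @param K number of change points, >= 0.
#' @param tau strictly increasing numeric vector of K change-point locations
#'   in the open interval (1, R). Locations are continuous reals; residue
#'   membership uses the indicator tau_(k-1) <= r < tau_k.
#' @param theta (K+1) x 4 matrix of segment kinetic parameters with columns
#'   pi, p, b, d; row k applies to the k-th segment.
#' @param sigma observation noise scale, > 0 (the Laplace scale of a peptide
#'   is \code{l * sigma^2}).
#' @param d_rate,b_rate current values of the Gamma hyper-rate parameters for
#'   the exponential and Weibull rates.
#' @param R protein length (number of residues).
#' @return object of class \code{chain_state}.
#' @export
chain_state <- function(K, tau, theta, sigma, d_rate, b_rate, R) {
  theta <- as.matrix(theta)
  colnames(theta) <- c("pi", "p", "b", "d")
  st <- list(K = as.integer(K), tau = as.numeric(tau), theta = theta,
             sigma = sigma, d_rate = d_rate, b_rate = b_rate,
             R = as.integer(R))
  validate_chain_state(st)
  class(st) <- "chain_state"
  st
}

validate_chain_state <- function(st) {
  if (st$K < 0L) stop("K must be non-negative")
  if (length(st$tau) != st$K) stop("length(tau) must equal K")
  if (nrow(st$theta) != st$K + 1L) stop("theta must have K + 1 rows")
  if (st$K > 1L && any(diff(st$tau) <= 0)) stop("tau must increase strictly")
  if (length(st$tau) && (min(st$tau) <= 1 || max(st$tau) >= st$R))
    stop("tau must lie strictly inside (1, R)")
  if (!is.finite(st$sigma) || st$sigma <= 0) stop("sigma must be positive")
  apply(st$theta, 1L, function(row) validate_kinetic_params(
    c(pi = row[[1]], p = row[[2]], b = row[[3]], d = row[[4]])))
  invisible(st)
}

#' Map residues to change-point segments
#'
#' Residue r belongs to segment k iff tau_(k-1) <= r < tau_k, with tau_0 = 1
#' and tau_(K+1) just beyond R, so the map is a non-decreasing step function
#' with exactly K jumps.
#'
#' @param state a \code{\link{chain_state}}.
#' @param r residue index or vector of indices in 1..R.
#' @return integer segment indices in 1..(K+1).
#' @export
segment_index <- function(state, r) {
  stopifnot(all(r >= 1), all(r <= state$R))
  findInterval(r, state$tau) + 1L
}

#' Kinetic parameters assigned to a residue by the current state
#'
#' @inheritParams segment_index
#' @return for scalar \code{r}, a \code{\link{kinetic_params}} vector; for
#'   vector \code{r}, a length(r) x 4 matrix.
#' @export
segment_lookup <- function(state, r) {
  k <- segment_index(state, r)
  if (length(r) == 1L) {
    row <- state$theta[k, ]
    return(kinetic_params(row[["pi"]], row[["p"]], row[["b"]], row[["d"]]))
  }
  state$theta[k, , drop = FALSE]
}

# Per-residue parameter matrix (R x 4) implied by a chain state.
state_theta_by_residue <- function(state) {
  state$theta[segment_index(state, seq_len(state$R)), , drop = FALSE]
}

#' Expected uptake of a peptide under a chain state
#'
#' Sums the residue-level uptake curves over the peptide's exchangeable
#' amides, giving the model's peptide-level location in exchangeable-amide
#' units (bounded in \[0, l\]).
#'
#' @param state a \code{\link{chain_state}}.
#' @param peptide a list or one-row data frame with fields \code{start},
#'   \code{end}, \code{sequence} (or a precomputed integer vector
#'   \code{exch}).
#' @param t time(s) in seconds.
#' @return numeric vector of expected uptake (amide units), length of
#'   \code{t}.
#' @export
predict_peptide_uptake <- function(state, peptide, t) {
  exch <- if (!is.null(peptide$exch)) unlist(peptide$exch) else
    exchangeable_residues(peptide$start, peptide$end, peptide$sequence)
  if (length(exch) == 0L) stop("peptide has no exchangeable residues")
  th <- state$theta[segment_index(state, exch), , drop = FALSE]
  colSums(residue_uptake_matrix(th, t))
}

# ---------------------------------------------------------------------------
# Hyperparameters
# ---------------------------------------------------------------------------

#' Prior hyperparameters for the change-point model
#'
#' The hierarchy: K ~ Pois(lambda); change points ordered uniform on (1, R);
#' per segment pi ~ Beta, p ~ Beta, b ~ Gamma(b_shape, b_rate),
#' d ~ Gamma(d_shape, d_rate); log sigma ~ Normal(m, v^2); and Gamma
#' hyperpriors on the rates d_rate and b_rate. Defaults are weakly
#' informative: uniform Beta(1,1) mixing/stretch priors, unit-shape Gamma
#' rate priors with Exp(1) hyper-rates, and log sigma ~ N(-3, 1). lambda
#' defaults to max(1, R/25) and should grow proportionally with protein
#' length.
#'
#' @param R protein length.
#' @param lambda prior expected number of change points.
#' @param d_shape,b_shape Gamma shapes for the exponential/Weibull rates.
#' @param pi_shape1,pi_shape2,p_shape1,p_shape2 Beta shapes.
#' @param m,v mean and SD of the log-normal prior on sigma.
#' @param d_alpha,d_beta,b_alpha,b_beta Gamma hyperprior shape/rate for
#'   d_rate and b_rate.
#' @param rho probability of proposing a birth (dimension-increasing) move.
#' @return list of class \code{hdx_hyperparameters}.
#' @export
default_hyperparameters <- function(R, lambda = max(1, R / 25),
                                    d_shape = 1, b_shape = 1,
                                    pi_shape1 = 1, pi_shape2 = 1,
                                    p_shape1 = 1, p_shape2 = 1,
                                    m = -3, v = 1,
                                    d_alpha = 1, d_beta = 1,
                                    b_alpha = 1, b_beta = 1,
                                    rho = 0.5) {
  h <- list(R = as.integer(R), lambda = lambda,
            d_shape = d_shape, b_shape = b_shape,
            pi_shape1 = pi_shape1, pi_shape2 = pi_shape2,
            p_shape1 = p_shape1, p_shape2 = p_shape2,
            m = m, v = v, d_alpha = d_alpha, d_beta = d_beta,
            b_alpha = b_alpha, b_beta = b_beta, rho = rho)
  nums <- unlist(h[setdiff(names(h), c("m", "rho", "R"))])
  if (any(!is.finite(nums)) || any(nums <= 0))
    stop("hyperparameters must be positive and finite")
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0,1)")
  class(h) <- "hdx_hyperparameters"
  h
}

# Draw one segment parameter vector from the prior given current hyper-rates.
draw_theta_prior <- function(hyper, d_rate, b_rate, n = 1L) {
  cbind(pi = rbeta(n, hyper$pi_shape1, hyper$pi_shape2),
        p  = rbeta(n, hyper$p_shape1, hyper$p_shape2),
        b  = rgamma(n, hyper$b_shape, rate = b_rate),
        d  = rgamma(n, hyper$d_shape, rate = d_rate))
}

# Log prior density of one segment parameter vector (row: pi, p, b, d).
log_theta_prior <- function(row, hyper, d_rate, b_rate) {
  dbeta(row[[1L]], hyper$pi_shape1, hyper$pi_shape2, log = TRUE) +
    dbeta(row[[2L]], hyper$p_shape1, hyper$p_shape2, log = TRUE) +
    dgamma(row[[3L]], hyper$b_shape, rate = b_rate, log = TRUE) +
    dgamma(row[[4L]], hyper$d_shape, rate = d_rate, log = TRUE)
}

# ---------------------------------------------------------------------------
# Densities
# ---------------------------------------------------------------------------

# Laplace log-density with location mu and scale s.
dlaplace_log <- function(x, mu, s) -log(2 * s) - abs(x - mu) / s

# Laplace random draws (inverse-CDF).
rlaplace <- function(n, mu = 0, s = 1) {
  u <- runif(n) - 0.5
  mu - s * sign(u) * log1p(-2 * abs(u))
}

#' Log-likelihood of a chain state given a peptide table
#'
#' Each observation contributes a Laplace log-density with location equal to
#' the summed residue uptake over the peptide's exchangeable amides and
#' scale \code{l * sigma^2}; the length factor lets longer peptides be more
#' variable. Observations are stored as fractions of the fully deuterated
#' control and rescaled to amide units at this boundary.
#'
#' @param state a \code{\link{chain_state}}.
#' @param data a \code{\link{peptide_table}} (only informative peptides,
#'   those with at least one exchangeable amide, enter).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(state, data) {
  cache <- pt_cache(data)
  loglik_cached(state, cache)
}

loglik_cached <- function(state, cache) {
  theta_r <- state_theta_by_residue(state)
  mu_res <- residue_uptake_matrix(theta_r, cache$times)  # R x M fractions
  pred <- cache$C %*% mu_res                             # N x M amide units
  s <- cache$obs_l * state$sigma^2
  sum(dlaplace_log(cache$obs_y, pred[cache$obs_idx], s))
}

#' Log prior density of a chain state
#'
#' Sum of the Poisson log-pmf of K, the ordered-uniform change-point term
#' log(K!/(R-1)^K), the segment parameter priors, the log-normal prior on
#' sigma and the Gamma hyperpriors on d_rate and b_rate. Out-of-support
#' states return -Inf (auto-reject).
#'
#' @param state a \code{\link{chain_state}}.
#' @param hyper a \code{\link{default_hyperparameters}} list.
#' @return scalar log prior density.
#' @export
log_prior <- function(state, hyper) {
  K <- state$K
  th <- state$theta
  if (any(th[, 1L] <= 0) || any(th[, 1L] >= 1) ||
      any(th[, 2L] <= 0) || any(th[, 2L] >= 1) ||
      any(th[, 3L] <= 0) || any(th[, 4L] <= 0) ||
      state$sigma <= 0 || state$d_rate <= 0 || state$b_rate <= 0)
    return(-Inf)
  if (K > 0L && (any(diff(c(1, state$tau, state$R)) <= 0)))
    return(-Inf)
  lp <- dpois(K, hyper$lambda, log = TRUE) +
    lfactorial(K) - K * log(hyper$R - 1)
  lp <- lp +
    sum(dbeta(th[, 1L], hyper$pi_shape1, hyper$pi_shape2, log = TRUE)) +
    sum(dbeta(th[, 2L], hyper$p_shape1, hyper$p_shape2, log = TRUE)) +
    sum(dgamma(th[, 3L], hyper$b_shape, rate = state$b_rate, log = TRUE)) +
    sum(dgamma(th[, 4L], hyper$d_shape, rate = state$d_rate, log = TRUE))
  lp <- lp + dlnorm(state$sigma, hyper$m, hyper$v, log = TRUE) +
    dgamma(state$d_rate, hyper$d_alpha, rate = hyper$d_beta, log = TRUE) +
    dgamma(state$b_rate, hyper$b_alpha, rate = hyper$b_beta, log = TRUE)
  lp
}
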