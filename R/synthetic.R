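# ---------------------------------------------------------------------------
# Synthetic data: ground-truth kinetics, peptide maps, noisy observations
# ---------------------------------------------------------------------------

# Evaluate expr with a temporarily seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Random protein sequence
#'
#' Uniform draw over the 20 standard amino acids except that proline is
#' given its own frequency (default 5%, around its natural abundance), since
#' prolines carve holes in the exchangeable-amide sets.
#'
#' @param R protein length.
#' @param p_pro proline frequency.
#' @param seed RNG seed (restored on exit).
#' @return single character string of length R.
#' @export
random_protein <- function(R, p_pro = 0.05, seed = NULL) {
  aa <- setdiff(strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]], "P")
  with_seed(seed, {
    s <- sample(aa, R, replace = TRUE)
    s[runif(R) < p_pro] <- "P"
    paste(s, collapse = "")
  })
}

#' Draw a ground-truth chain state from the prior
#'
#' K ~ Pois(lambda); change points ordered uniform on (1, R); hyper-rates
#' from their Gamma hyperpriors; segment parameters and sigma from their
#' priors. The returned \code{\link{chain_state}} defines a piecewise-
#' constant residue kinetic landscape usable as simulation truth.
#'
#' @param R protein length (>= 2).
#' @param hyper hyperparameters; default \code{default_hyperparameters(R)}.
#' @param seed RNG seed.
#' @return a \code{\link{chain_state}}.
#' @export
simulate_truth <- function(R, hyper = default_hyperparameters(R),
                           seed = NULL) {
  stopifnot(R >= 2)
  with_seed(seed, {
    d_rate <- rgamma(1, hyper$d_alpha, rate = hyper$d_beta)
    b_rate <- rgamma(1, hyper$b_alpha, rate = hyper$b_beta)
    K <- rpois(1, hyper$lambda)
    tau <- sort(runif(K, 1, R))
    theta <- draw_theta_prior(hyper, d_rate, b_rate, n = K + 1L)
    sigma <- rlnorm(1, hyper$m, hyper$v)
    chain_state(K, tau, theta, sigma, d_rate, b_rate, R)
  })
}

#' Simulate a protease peptide map
#'
#' Random peptides with uniform start positions and lengths, emulating one
#' protease digest. Peptides whose exchangeable-amide set would be empty are
#' redrawn, so every returned peptide is informative. Different seeds give
#' different maps of the same protein, emulating a multi-protease design.
#'
#' @param sequence protein sequence string (use \code{\link{random_protein}})
#'   or an integer protein length, in which case a sequence is drawn too.
#' @param n_peptides number of peptides.
#' @param length_range inclusive peptide-length range (default 5--20,
#'   typical of quality-filtered bottom-up digests).
#' @param seed RNG seed.
#' @return data frame with columns id, sequence, start, end plus the parent
#'   sequence as attribute \code{"protein"}.
#' @export
simulate_peptide_map <- function(sequence, n_peptides,
                                 length_range = c(5L, 20L), seed = NULL) {
  with_seed(seed, {
    if (is.numeric(sequence)) sequence <- random_protein(sequence)
    R <- nchar(sequence)
    stopifnot(length_range[1] >= 3, length_range[2] <= R)
    peps <- data.frame(sequence = character(0), start = integer(0),
                       end = integer(0))
    tries <- 0L
    while (nrow(peps) < n_peptides && tries < 50L * n_peptides) {
      tries <- tries + 1L
      len <- sample(seq(length_range[1], length_range[2]), 1L)
      start <- sample(seq_len(R - len + 1L), 1L)
      end <- start + len - 1L
      sub <- substr(sequence, start, end)
      if (length(exchangeable_residues(start, end, sub)) == 0L) next
      peps <- rbind(peps, data.frame(sequence = sub, start = start,
                                     end = end))
    }
    peps$id <- seq_len(nrow(peps))
    attr(peps, "protein") <- sequence
    peps
  })
}

#' Simulate peptide-level uptake observations from a ground truth
#'
#' The forward model: for each (peptide, time), location = sum of residue
#' uptake over exchangeable amides; Laplace noise with scale
#' \code{l * sigma^2} is added independently per replicate; observations are
#' stored as fractions of the fully deuterated control (amide units / l).
#'
#' @param truth a \code{\link{chain_state}} (see
#'   \code{\link{simulate_truth}}).
#' @param peptides peptide map data frame (see
#'   \code{\link{simulate_peptide_map}}).
#' @param times exposure times in seconds (default the benchmark grid
#'   15, 150, 1500, 15000).
#' @param replicates number of i.i.d. replicates (default 3).
#' @param sigma noise scale; the Laplace scale of peptide i is
#'   \code{l_i * sigma^2}. Use 0 for noise-free data.
#' @param state state label for the observations.
#' @param seed RNG seed.
#' @return a \code{\link{peptide_table}}.
#' @export
simulate_uptake_data <- function(truth, peptides,
                                 times = c(15, 150, 1500, 15000),
                                 replicates = 3L, sigma = 0.005,
                                 state = "A", seed = NULL) {
  with_seed(seed, {
    exch <- Map(exchangeable_residues, peptides$start, peptides$end,
                peptides$sequence)
    l <- lengths(exch)
    keep <- which(l > 0L)
    theta_r <- state_theta_by_residue(truth)
    mu_res <- residue_uptake_matrix(theta_r, times)    # R x M
    obs <- do.call(rbind, lapply(keep, function(i) {
      loc <- colSums(mu_res[exch[[i]], , drop = FALSE]) # amide units
      do.call(rbind, lapply(seq_len(replicates), function(rep) {
        y <- loc + if (sigma > 0) rlaplace(length(times),
                                           s = l[i] * sigma^2) else 0
        data.frame(peptide_id = peptides$id[i], state = state,
                   exposure = times, replicate = rep, uptake = y / l[i])
      }))
    }))
    peptide_table(peptides[keep, c("id", "sequence", "start", "end")], obs,
                  R = truth$R)
  })
}

#' Apply a localized protection effect
#'
#' Multiplies the uptake of every peptide covering a chosen residue by a
#' factor in (0, 1], at all times and replicates, leaving all other peptides
#' untouched. This is the standard simulated-epitope protocol; 0.80 is the
#' strongest protection level of the three conventional settings
#' (0.80 / 0.90 / 0.95).
#'
#' @param pt a \code{\link{peptide_table}}.
#' @param residue residue index that must be covered by >= 1 informative
#'   peptide.
#' @param factor multiplicative protection factor in (0, 1].
#' @return the modified \code{peptide_table}.
#' @export
apply_protection_effect <- function(pt, residue, factor) {
  stopifnot(factor > 0, factor <= 1)
  covering <- pt$peptides$id[vapply(pt$peptides$exch,
                                    function(e) residue %in% e, logical(1))]
  if (length(covering) == 0L)
    stop("residue ", residue, " is not covered by any informative peptide")
  out <- pt
  hit <- out$observations$peptide_id %in% covering
  out$observations$uptake[hit] <- out$observations$uptake[hit] * factor
  out
}
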