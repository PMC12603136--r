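# ---------------------------------------------------------------------------
# Post-inference statistics: reconstruction errors, ARE/TRE, probabilities,
# expected FDR, differential analysis
# ---------------------------------------------------------------------------

# Posterior-mean peptide predictions for an arbitrary peptide table (amide
# units), evaluated on that table's time grid using the stored states.
posterior_peptide_predictions <- function(samples, data) {
  cache <- pt_cache(data)
  if (cache$R != samples$R)
    stop("peptide table protein length (", cache$R,
         ") does not match fitted model (", samples$R, ")")
  mu_mean <- apply(posterior_uptake_at(samples, cache$times), c(1L, 2L),
                   mean)
  list(cache = cache, pred = cache$C %*% mu_mean)   # N x M amide units
}

#' Per-observation reconstruction errors
#'
#' RE = observed minus posterior-mean predicted peptide uptake (amide
#' units), one row per (peptide, time, replicate), with the
#' length-normalized version alongside.
#'
#' @param samples an \code{hdx_posterior}.
#' @param data the \code{\link{peptide_table}} to reconstruct (typically the
#'   fitted data, or the reference state in a differential analysis).
#' @return data frame: peptide_id, exposure, replicate, l, re, re_norm.
#' @export
reconstruction_errors <- function(samples, data) {
  pp <- posterior_peptide_predictions(samples, data)
  cache <- pp$cache
  re <- cache$obs_y - pp$pred[cache$obs_idx]
  data.frame(peptide_id = cache$observations$peptide_id,
             exposure = cache$observations$exposure,
             replicate = cache$observations$replicate,
             l = cache$obs_l, re = re, re_norm = re / cache$obs_l)
}

#' Per-residue reconstruction-error summaries
#'
#' For every residue r covered by n_r peptides, computes from the
#' replicate-averaged normalized reconstruction errors of the covering
#' peptides: the signed average (SignedARE), the average of absolute values
#' (ARE), and the plain sum (TRE). TRE deliberately sums rather than
#' averages, so consistent-direction errors across redundant peptides
#' amplify while opposing errors cancel. Residues with no coverage are
#' returned as NA, never zero.
#'
#' @param re data frame from \code{\link{reconstruction_errors}}.
#' @param data the matching \code{\link{peptide_table}}.
#' @return data frame: residue, exposure, n, signed_are, are, tre; plus the
#'   time-averaged rows with exposure NA.
#' @export
residue_errors <- function(re, data) {
  cache <- pt_cache(data)
  if (!all(re$peptide_id %in% cache$peptides$id))
    stop("reconstruction errors reference peptides absent from the table")
  times <- sort(unique(re$exposure))
  # replicate-averaged normalized RE per (peptide, time)
  out <- do.call(rbind, lapply(times, function(t) {
    sub <- re[re$exposure == t, , drop = FALSE]
    pep_mean <- tapply(sub$re_norm, sub$peptide_id, mean)
    rows <- match(as.integer(names(pep_mean)), cache$peptides$id)
    Csub <- cache$C[rows, , drop = FALSE]
    e <- as.numeric(pep_mean)
    n_r <- colSums(Csub)
    signed <- as.numeric(crossprod(Csub, e))
    abssum <- as.numeric(crossprod(Csub, abs(e)))
    data.frame(residue = seq_len(cache$R), exposure = t, n = n_r,
               signed_are = ifelse(n_r > 0, signed / n_r, NA_real_),
               are = ifelse(n_r > 0, abssum / n_r, NA_real_),
               tre = ifelse(n_r > 0, signed, NA_real_))
  }))
  avg <- do.call(rbind, lapply(split(out, out$residue), function(d) {
    data.frame(residue = d$residue[1L], exposure = NA_real_, n = d$n[1L],
               signed_are = mean(d$signed_are), are = mean(d$are),
               tre = mean(d$tre))
  }))
  rownames(avg) <- NULL
  rbind(out, avg)
}

#' Monte-Carlo effect probabilities for residue statistics
#'
#' For each residue, the probability that its observed TRE magnitude exceeds
#' the magnitude of a null draw: per posterior sample m, the null is the sum
#' of n_r independent Laplace(0, sigma^(m)) variates (the model's per-
#' peptide normalized-error null under the current noise draw). The
#' analogous one-draw forms are returned for ARE and SignedARE.
#'
#' @param res_stats data frame from \code{\link{residue_errors}} (one
#'   exposure slice, or the time-averaged rows).
#' @param samples an \code{hdx_posterior} providing the sigma draws.
#' @param n_inner independent null draws per posterior sample (default 1).
#' @param seed RNG seed (Monte-Carlo reproducibility).
#' @return \code{res_stats} with columns prob_tre, prob_are,
#'   prob_signed_are appended.
#' @export
effect_probabilities <- function(res_stats, samples, n_inner = 1L,
                                 seed = NULL) {
  sig <- rep(samples$sigma, each = n_inner)
  S <- length(sig)
  with_seed(seed, {
    probs <- t(vapply(seq_len(nrow(res_stats)), function(i) {
      n_r <- res_stats$n[i]
      if (is.na(res_stats$tre[i]) || n_r == 0L)
        return(c(NA_real_, NA_real_, NA_real_))
      tau_sum <- colSums(matrix(rlaplace(n_r * S, s = rep(sig, each = n_r)),
                                nrow = n_r))
      tau_one <- rlaplace(S, s = sig)
      c(mean(abs(res_stats$tre[i]) > abs(tau_sum)),
        mean(res_stats$are[i] > abs(tau_one)),
        mean(res_stats$signed_are[i] > tau_one))
    }, numeric(3L)))
  })
  res_stats$prob_tre <- probs[, 1L]
  res_stats$prob_are <- probs[, 2L]
  res_stats$prob_signed_are <- probs[, 3L]
  res_stats
}

#' Expected false discovery rate at a probability threshold
#'
#' EFDR(tau) = sum (1 - p_i) 1\{p_i >= tau\} / sum 1\{p_i >= tau\}: the
#' average posterior error probability among the calls made at threshold
#' tau. Undefined (NA, with a warning) if no probability reaches tau.
#'
#' @param probs vector of posterior probabilities in \[0, 1\] (NAs dropped).
#' @param threshold calling threshold tau.
#' @return scalar EFDR estimate.
#' @export
efdr <- function(probs, threshold) {
  probs <- probs[!is.na(probs)]
  sel <- probs >= threshold
  if (!any(sel)) {
    warning("no probabilities at or above threshold; EFDR undefined")
    return(NA_real_)
  }
  sum(1 - probs[sel]) / sum(sel)
}

#' Probability cutoff controlling the EFDR at a level
#'
#' Scans the observed probabilities from largest to smallest and returns the
#' smallest observed p such that EFDR(p') stays below the level for every
#' observed p' >= p (the sequential search rule).
#'
#' @param probs vector of posterior probabilities (NAs dropped).
#' @param level target EFDR level (e.g. 0.05).
#' @return the probability cutoff, or NA if even the largest probability
#'   fails the level.
#' @export
efdr_threshold <- function(probs, level = 0.05) {
  probs <- probs[!is.na(probs)]
  cand <- sort(unique(probs), decreasing = TRUE)
  cutoff <- NA_real_
  for (p in cand) {
    if (efdr(probs, p) < level) cutoff <- p else break
  }
  cutoff
}

#' Differential residue-level analysis against a reference state
#'
#' The model is fitted on the state of interest; its posterior-mean peptide
#' predictions are then compared against the observations of the reference
#' (APO) table on the reference's own peptide map. The reported effect is
#' predicted-minus-observed, so protection in the fitted state (reduced
#' uptake relative to APO) gives negative TRE, de-protection positive.
#' Probabilities and an EFDR call at the requested level are attached both
#' per timepoint and time-averaged (TRE averaged across timepoints before
#' the probability computation, the recommended summary when effects are
#' small).
#'
#' @param samples \code{hdx_posterior} fitted on the non-reference state.
#' @param apo_data reference-state \code{\link{peptide_table}} sharing the
#'   protein coordinates.
#' @param level EFDR level for calls (default 0.05).
#' @param seed RNG seed for the probability Monte Carlo.
#' @return data frame: residue, exposure (NA rows = time-averaged), n,
#'   signed_are, are, tre, prob_* columns, and logical \code{call} at the
#'   EFDR level (time-averaged rows only).
#' @export
differential_tre <- function(samples, apo_data, level = 0.05, seed = NULL) {
  re <- reconstruction_errors(samples, apo_data)
  # predicted-minus-observed sign convention: flip the RE sign
  re$re <- -re$re
  re$re_norm <- -re$re_norm
  stats <- residue_errors(re, apo_data)
  per_t <- stats[!is.na(stats$exposure), , drop = FALSE]
  avg <- stats[is.na(stats$exposure), , drop = FALSE]
  per_t <- effect_probabilities(per_t, samples, seed = seed)
  avg <- effect_probabilities(avg, samples,
                              seed = if (is.null(seed)) NULL else seed + 1L)
  cutoff <- efdr_threshold(avg$prob_tre, level)
  avg$call <- !is.na(avg$prob_tre) & !is.na(cutoff) &
    avg$prob_tre >= cutoff
  per_t$call <- NA
  out <- rbind(per_t, avg)
  attr(out, "efdr_cutoff") <- cutoff
  attr(out, "level") <- level
  out
}

#' Write residue-level results to CSV
#'
#' @param res residue results data frame (e.g. from
#'   \code{\link{differential_tre}}).
#' @param path output path.
#' @param method optional method label column.
#' @return path, invisibly.
#' @export
write_residue_results <- function(res, path, method = NULL) {
  out <- res
  out$timepoint <- ifelse(is.na(out$exposure), "avg",
                          as.character(out$exposure))
  out$exposure <- NULL
  if (!is.null(method)) out$method <- method
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export residue values into a PDB B-factor column
#'
#' Writes a copy of a PDB file with the B-factor of every atom replaced by
#' the residue-level value (e.g. TRE or probability), for structure
#' colouring in molecular viewers. Residues without a value get 0.
#'
#' @param pdb_file input PDB path.
#' @param values numeric vector indexed by residue number.
#' @param path output PDB path.
#' @return path, invisibly.
#' @export
write_bfactor_pdb <- function(pdb_file, values, path) {
  lines <- readLines(pdb_file)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    resno <- suppressWarnings(as.integer(substr(lines[i], 23, 26)))
    v <- if (!is.na(resno) && resno >= 1 && resno <= length(values) &&
             !is.na(values[resno])) values[resno] else 0
    substr(lines[i], 61, 66) <- sprintf("%6.2f", min(999.99, max(-99.99, v)))
  }
  writeLines(lines, path)
  invisible(path)
}
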