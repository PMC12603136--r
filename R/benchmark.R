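# ---------------------------------------------------------------------------
# Leave-digests-out benchmark across protease peptide maps
# ---------------------------------------------------------------------------

#' Inter-digest correction factors
#'
#' Even after FD normalization, different protease digests of the same
#' protein sit on slightly different uptake scales. The per-timepoint
#' multiplicative factor is the ratio of the medians of the uptakes of the
#' peptides common to both digests (same sequence and coordinates):
#' factor_t = median(common in a at t) / median(common in b at t). Applying
#' the factors to table b puts it on table a's scale.
#'
#' @param table_a,table_b two \code{\link{peptide_table}}s of the same
#'   protein.
#' @return named numeric vector of factors, one per shared timepoint.
#' @export
digest_correction_factor <- function(table_a, table_b) {
  key <- function(p) paste(p$sequence, p$start, p$end, sep = "|")
  ka <- key(table_a$peptides); kb <- key(table_b$peptides)
  common <- intersect(ka, kb)
  if (length(common) == 0L)
    stop("no peptides common to the two digests")
  ids_a <- table_a$peptides$id[match(common, ka)]
  ids_b <- table_b$peptides$id[match(common, kb)]
  times <- intersect(unique(table_a$observations$exposure),
                     unique(table_b$observations$exposure))
  vapply(setNames(times, times), function(t) {
    ua <- table_a$observations
    ub <- table_b$observations
    ma <- median(ua$uptake[ua$peptide_id %in% ids_a & ua$exposure == t])
    mb <- median(ub$uptake[ub$peptide_id %in% ids_b & ub$exposure == t])
    ma / mb
  }, numeric(1))
}

# Rescale a table's uptakes by per-timepoint factors.
apply_correction <- function(pt, factors) {
  out <- pt
  f <- factors[as.character(out$observations$exposure)]
  if (any(is.na(f))) stop("correction factor missing for some timepoints")
  out$observations$uptake <- out$observations$uptake * f
  out
}

#' Leave-digests-out cross-protease evaluation
#'
#' Fits residue-level uptake on the training digest only (via any method
#' mapping a peptide table to a residues x times matrix), scales each
#' held-out digest onto the training scale with
#' \code{\link{digest_correction_factor}}, and predicts every held-out
#' peptide's uptake by summing the inferred residue values over its
#' exchangeable amides. Held-out peptides that span residues with no
#' training coverage (NA estimates) are excluded and counted.
#'
#' @param train_table training \code{\link{peptide_table}}.
#' @param held_out_tables list of held-out \code{peptide_table}s.
#' @param method function(peptide_table) -> R x M residue uptake matrix
#'   (fractions), e.g. \code{\link{baseline_uptake}} partially applied, or a
#'   wrapper around \code{\link{run_rjmcmc}} +
#'   \code{\link{posterior_mean_uptake}}.
#' @param correct apply the inter-digest correction (default TRUE).
#' @param U optional precomputed R x M residue fit for the training digest
#'   (skips refitting).
#' @return data frame of paired records: digest, peptide_id, exposure,
#'   predicted, observed (both uptake fractions), l; attribute
#'   \code{"excluded"} counts peptides dropped for missing coverage.
#' @export
leave_digests_out <- function(train_table, held_out_tables, method,
                              correct = TRUE, U = NULL) {
  if (is.null(U)) U <- method(train_table)       # R x M fractions
  times <- sort(unique(train_table$observations$exposure))
  stopifnot(ncol(U) == length(times))
  excluded <- 0L
  recs <- list()
  for (d in seq_along(held_out_tables)) {
    ht <- held_out_tables[[d]]
    if (correct) {
      f <- digest_correction_factor(train_table, ht)
      ht <- apply_correction(ht, f)
    }
    cache <- pt_cache(ht)
    for (i in seq_len(nrow(cache$peptides))) {
      exch <- cache$peptides$exch[[i]]
      vals <- U[exch, , drop = FALSE]
      if (any(is.na(vals))) { excluded <- excluded + 1L; next }
      pred <- colSums(vals) / length(exch)       # fraction scale
      obs <- cache$observations[
        cache$observations$peptide_id == cache$peptides$id[i], ]
      m <- match(obs$exposure, times)
      ok <- !is.na(m)
      if (!any(ok)) next
      recs[[length(recs) + 1L]] <- data.frame(
        digest = d, peptide_id = cache$peptides$id[i],
        exposure = obs$exposure[ok], replicate = obs$replicate[ok],
        predicted = pred[m[ok]], observed = obs$uptake[ok],
        l = length(exch))
    }
  }
  out <- do.call(rbind, recs)
  attr(out, "excluded") <- excluded
  out
}

#' Bootstrap distribution of the median absolute deviation
#'
#' MAD = median(|predicted - observed|) per (digest, timepoint) cell;
#' peptides (the exchangeable observational unit) are resampled with
#' replacement.
#'
#' @param records paired records from \code{\link{leave_digests_out}}.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return data frame: digest, exposure, mad (plug-in), ci_low, ci_high
#'   (2.5/97.5% bootstrap quantiles), boot_mean.
#' @export
mad_bootstrap <- function(records, n_boot = 1000L, seed = NULL) {
  stopifnot(n_boot >= 1L)
  with_seed(seed, {
    cells <- unique(records[, c("digest", "exposure")])
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sub <- records[records$digest == cells$digest[i] &
                       records$exposure == cells$exposure[i], ]
      dev <- abs(sub$predicted - sub$observed)
      peps <- unique(sub$peptide_id)
      by_pep <- split(dev, sub$peptide_id)
      boots <- vapply(seq_len(n_boot), function(b) {
        take <- sample(names(by_pep), length(by_pep), replace = TRUE)
        median(unlist(by_pep[take], use.names = FALSE))
      }, numeric(1))
      data.frame(digest = cells$digest[i], exposure = cells$exposure[i],
                 mad = median(dev),
                 ci_low = unname(quantile(boots, 0.025)),
                 ci_high = unname(quantile(boots, 0.975)),
                 boot_mean = mean(boots))
    }))
  })
}

#' Physical-constraint violation rates of a residue uptake matrix
#'
#' Deuterium uptake must lie in \[0, 1\] and be non-decreasing in time.
#' Returns the percentage of entries outside the bounds and the percentage
#' of consecutive-time pairs that decrease, both with a numerical tolerance
#' eps.
#'
#' @param U R x M residue uptake matrix (columns ordered by time); NAs
#'   (uncovered residues) are ignored.
#' @param eps numerical tolerance (default 1e-9).
#' @return named vector: bounds_pct, mono_pct.
#' @export
violation_rates <- function(U, eps = 1e-9) {
  vals <- U[!is.na(U)]
  bounds <- 100 * mean(vals < -eps | vals > 1 + eps)
  d <- t(diff(t(U)))
  dv <- d[!is.na(d)]
  mono <- 100 * mean(dv < -eps)
  c(bounds_pct = bounds, mono_pct = mono)
}

#' Run the full cross-digest benchmark for a set of methods
#'
#' For each method, leave-digests-out records, per-cell bootstrap MADs, and
#' the violation rates of the training-digest residue fit are assembled into
#' one tidy report.
#'
#' @param train_table training digest.
#' @param held_out_tables list of held-out digests.
#' @param methods named list of method functions (see
#'   \code{\link{leave_digests_out}}).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return data frame: method, digest, exposure, mad, ci_low, ci_high,
#'   bounds_pct, mono_pct.
#' @export
benchmark_report <- function(train_table, held_out_tables, methods,
                             n_boot = 1000L, seed = NULL) {
  do.call(rbind, lapply(names(methods), function(nm) {
    U <- methods[[nm]](train_table)
    vr <- violation_rates(U)
    rec <- leave_digests_out(train_table, held_out_tables, methods[[nm]],
                             U = U)
    madtab <- mad_bootstrap(rec, n_boot = n_boot, seed = seed)
    madtab$method <- nm
    madtab$bounds_pct <- vr[["bounds_pct"]]
    madtab$mono_pct <- vr[["mono_pct"]]
    madtab
  }))
}
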