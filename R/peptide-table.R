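# ---------------------------------------------------------------------------
# Peptide tables: the tidy container for peptide-level uptake observations
# ---------------------------------------------------------------------------

#' Construct a peptide table
#'
#' The central data container: a set of peptides (protein coordinates,
#' 1-based inclusive) plus long-format uptake observations per
#' (peptide, state, exposure time, replicate). Uptake is stored as the
#' fraction of the fully deuterated control. Peptides whose exchangeable
#' amide set is empty (short peptides, proline-rich stretches) are flagged
#' non-informative with a warning and excluded from likelihood computations
#' but retained in the table.
#'
#' @param peptides data frame with columns \code{sequence}, \code{start},
#'   \code{end} (and optionally \code{id}).
#' @param observations data frame with columns \code{peptide_id},
#'   \code{state}, \code{exposure} (seconds, > 0), \code{replicate},
#'   \code{uptake} (fraction of fully deuterated control).
#' @param R protein length; defaults to \code{max(peptides$end)}.
#' @param inclusive_end passed to \code{\link{exchangeable_residues}}.
#' @return object of class \code{peptide_table}.
#' @export
peptide_table <- function(peptides, observations, R = max(peptides$end),
                          inclusive_end = FALSE) {
  peptides <- as.data.frame(peptides)
  observations <- as.data.frame(observations)
  req_p <- c("sequence", "start", "end")
  req_o <- c("peptide_id", "state", "exposure", "replicate", "uptake")
  if (!all(req_p %in% names(peptides)))
    stop("peptides must have columns: ", paste(req_p, collapse = ", "))
  if (!all(req_o %in% names(observations)))
    stop("observations must have columns: ", paste(req_o, collapse = ", "))
  if (is.null(peptides$id)) peptides$id <- seq_len(nrow(peptides))
  if (any(peptides$start >= peptides$end))
    stop("all peptides must satisfy start < end")
  if (!is.numeric(observations$uptake) || any(!is.finite(observations$uptake)))
    stop("uptake must be finite numeric")
  if (any(observations$exposure <= 0))
    stop("exposure times must be strictly positive")
  if (!all(observations$peptide_id %in% peptides$id))
    stop("observations reference unknown peptide ids")
  dup <- duplicated(observations[, c("peptide_id", "state", "exposure",
                                     "replicate")])
  if (any(dup))
    stop("duplicate observation rows: ", paste(which(dup), collapse = ", "))

  peptides$exch <- Map(exchangeable_residues, peptides$start, peptides$end,
                       peptides$sequence, inclusive_end = inclusive_end)
  peptides$l <- lengths(peptides$exch)
  if (any(peptides$l == 0L))
    warning(sum(peptides$l == 0L),
            " peptide(s) have no exchangeable amides and are excluded ",
            "from the likelihood")
  pt <- list(peptides = peptides, observations = observations,
             R = as.integer(R))
  class(pt) <- "peptide_table"
  pt
}

#' @export
print.peptide_table <- function(x, ...) {
  cat("peptide_table:", nrow(x$peptides), "peptides (",
      sum(x$peptides$l > 0), "informative ),",
      nrow(x$observations), "observations,\n  protein length R =", x$R,
      "| states:", paste(unique(x$observations$state), collapse = ", "),
      "| times (s):",
      paste(sort(unique(x$observations$exposure)), collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a peptide table to one state
#' @param pt a \code{\link{peptide_table}}.
#' @param state state label to keep.
#' @return a \code{peptide_table} containing only that state's observations.
#' @export
filter_state <- function(pt, state) {
  obs <- pt$observations[pt$observations$state == state, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no observations for state ", state)
  out <- pt
  out$observations <- obs
  out
}

#' Coupling matrix between peptides and residues
#'
#' Binary N x R matrix with entry (i, r) = 1 iff residue r is an
#' exchangeable amide of peptide i; row sums equal the peptides'
#' exchangeable-amide counts. Only informative peptides produce rows unless
#' \code{all = TRUE}.
#'
#' @param pt a \code{\link{peptide_table}} (or its \code{$peptides} frame).
#' @param R protein length.
#' @param all keep rows for non-informative peptides too.
#' @return matrix with rownames = peptide ids.
#' @export
coupling_matrix <- function(pt, R = NULL, all = FALSE) {
  peps <- if (inherits(pt, "peptide_table")) pt$peptides else pt
  if (is.null(R)) R <- if (inherits(pt, "peptide_table")) pt$R else
    max(peps$end)
  if (!all) peps <- peps[peps$l > 0L, , drop = FALSE]
  C <- matrix(0, nrow(peps), R, dimnames = list(peps$id, NULL))
  for (i in seq_len(nrow(peps))) C[i, peps$exch[[i]]] <- 1
  C
}

#' Per-residue redundancy
#'
#' Number of informative peptides whose exchangeable-amide set covers each
#' residue.
#'
#' @param pt a \code{\link{peptide_table}}.
#' @return integer vector of length R.
#' @export
residue_redundancy <- function(pt) {
  as.integer(colSums(coupling_matrix(pt)))
}

# Internal: flatten a peptide table into arrays for fast likelihood
# evaluation. Only informative peptides and, by convention, a single state
# (filter first for multi-state tables).
pt_cache <- function(pt) {
  stopifnot(inherits(pt, "peptide_table"))
  peps <- pt$peptides[pt$peptides$l > 0L, , drop = FALSE]
  if (nrow(peps) == 0L) stop("no informative peptides in table")
  obs <- pt$observations
  obs <- obs[obs$peptide_id %in% peps$id, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no observations on informative peptides")
  times <- sort(unique(obs$exposure))
  C <- coupling_matrix(pt)
  pep_row <- match(obs$peptide_id, peps$id)
  time_col <- match(obs$exposure, times)
  l <- peps$l[pep_row]
  list(C = C, times = times, R = pt$R,
       obs_idx = cbind(pep_row, time_col),
       obs_y = obs$uptake * l,   # amide units
       obs_l = l,
       peptides = peps, observations = obs)
}

# ---------------------------------------------------------------------------
# Readers / writers
# ---------------------------------------------------------------------------

#' Read a peptide-level uptake CSV
#'
#' Native tidy dialect: one row per (peptide, state, exposure, replicate)
#' with columns \code{sequence, start, end, state, exposure, replicate,
#' uptake} and optionally \code{fd_uptake} (uptake of the fully deuterated
#' control, same units as \code{uptake}) and \code{maxuptake}. Residue
#' coordinates are 1-based inclusive. Unknown columns are preserved on the
#' observation frame but otherwise ignored. State-data exports from common
#' HDX processing tools map onto this dialect by column renaming.
#'
#' @param path CSV file path.
#' @param normalize if TRUE and an \code{fd_uptake} column is present,
#'   divide uptake by it (see \code{\link{normalize_to_fd}}).
#' @param inclusive_end exchangeable-set convention switch.
#' @return a \code{\link{peptide_table}}.
#' @export
read_peptide_table <- function(path, normalize = FALSE,
                               inclusive_end = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sequence", "start", "end", "state", "exposure", "replicate",
           "uptake")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(df$uptake)) stop("uptake column must be numeric")
  if (any(df$start >= df$end)) stop("rows with start >= end: ",
                                    paste(which(df$start >= df$end),
                                          collapse = ", "))
  key <- paste(df$sequence, df$start, df$end, sep = "|")
  peps <- df[!duplicated(key), c("sequence", "start", "end")]
  peps$id <- seq_len(nrow(peps))
  obs <- df
  obs$peptide_id <- peps$id[match(key, paste(peps$sequence, peps$start,
                                             peps$end, sep = "|"))]
  keep <- c("peptide_id", "state", "exposure", "replicate", "uptake",
            intersect(c("fd_uptake", "maxuptake"), names(df)))
  obs <- obs[, keep]
  pt <- peptide_table(peps, obs, inclusive_end = inclusive_end)
  if (normalize && "fd_uptake" %in% names(obs)) pt <- normalize_to_fd(pt)
  pt
}

#' Write a peptide table to the native CSV dialect
#'
#' Produces a file that \code{\link{read_peptide_table}} accepts unchanged
#' (round-trip identity on the shared columns).
#'
#' @param pt a \code{\link{peptide_table}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_peptide_table <- function(pt, path) {
  obs <- pt$observations
  i <- match(obs$peptide_id, pt$peptides$id)
  out <- cbind(pt$peptides[i, c("sequence", "start", "end")],
               obs[, setdiff(names(obs), "peptide_id"), drop = FALSE])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize uptake by the fully deuterated control
#'
#' Divides each observation's uptake by the peptide's FD uptake, yielding
#' fractional uptake (which may exceed 1 under noise; values are preserved,
#' not clipped -- clipping is a model concern). Rows with FD <= 0 are
#' dropped with a warning; peptides lacking an FD value raise an error.
#'
#' @param pt a \code{\link{peptide_table}} whose observations carry an
#'   \code{fd_uptake} column, or supply \code{fd}.
#' @param fd optional data frame (\code{peptide_id}, \code{fd_uptake}) used
#'   when the observations lack the column.
#' @return a normalized \code{peptide_table} (fd_uptake column removed).
#' @export
normalize_to_fd <- function(pt, fd = NULL) {
  obs <- pt$observations
  if (is.null(obs$fd_uptake)) {
    if (is.null(fd)) stop("no fd_uptake column and no fd table supplied")
    obs$fd_uptake <- fd$fd_uptake[match(obs$peptide_id, fd$peptide_id)]
  }
  if (any(is.na(obs$fd_uptake))) {
    bad <- unique(obs$peptide_id[is.na(obs$fd_uptake)])
    stop("missing FD uptake for peptide id(s): ", paste(bad, collapse = ", "))
  }
  drop <- obs$fd_uptake <= 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " observation(s) with FD uptake <= 0")
    obs <- obs[!drop, , drop = FALSE]
  }
  obs$uptake <- obs$uptake / obs$fd_uptake
  obs$fd_uptake <- NULL
  out <- pt
  out$observations <- obs
  out
}
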