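# ---------------------------------------------------------------------------
# JSON checkpointing of chain states
#
# Layout (documented contract): a JSON object with fields
#   K        integer change-point count
#   tau      array of K locations in (1, R)
#   theta    (K+1) x 4 array, rows [pi, p, b, d]
#   sigma, d_rate, b_rate   scalars
#   R        integer protein length
# ---------------------------------------------------------------------------

#' Write a chain state to a JSON checkpoint
#'
#' Serializes a \code{\link{chain_state}} (e.g. the last stored state of a
#' run, to resume via the \code{init} argument of \code{\link{run_rjmcmc}})
#' into a small self-describing JSON file.
#'
#' @param state a \code{\link{chain_state}}.
#' @param path output file path.
#' @return path, invisibly.
#' @export
write_chain_checkpoint <- function(state, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for checkpointing")
  obj <- list(K = state$K, tau = as.numeric(state$tau),
              theta = unname(state$theta), sigma = state$sigma,
              d_rate = state$d_rate, b_rate = state$b_rate, R = state$R)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a chain state from a JSON checkpoint
#'
#' @param path checkpoint file written by
#'   \code{\link{write_chain_checkpoint}}.
#' @return a validated \code{\link{chain_state}}.
#' @export
read_chain_checkpoint <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for checkpointing")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- matrix(as.numeric(obj$theta), ncol = 4L)
  chain_state(obj$K, as.numeric(obj$tau), theta, obj$sigma,
              obj$d_rate, obj$b_rate, obj$R)
}
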