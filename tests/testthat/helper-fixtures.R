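# Shared fixture builders. Everything is generated in code; no data files.

# A tiny deterministic peptide table: 3 peptides on a 12-residue protein,
# one state, two timepoints, one replicate, hand-set uptakes.
toy_table <- function(uptakes = c(0.2, 0.4, 0.3, 0.6, 0.25, 0.5)) {
  peps <- data.frame(id = 1:3,
                     sequence = c("ACDEFGHI", "DEFGHIKL", "GHIKLMNQ"),
                     start = c(1L, 3L, 6L), end = c(8L, 10L, 13L))
  obs <- data.frame(peptide_id = rep(1:3, each = 2), state = "A",
                    exposure = rep(c(15, 150), 3), replicate = 1L,
                    uptake = uptakes)
  suppressWarnings(peptide_table(peps, obs, R = 13L))
}

# A mid-sized simulated dataset with known truth, reused across tests.
sim_fixture <- function(R = 40L, n_pep = 30L, sigma = 0.005, seed = 101L,
                        truth_seed = 7L, map_seed = 21L, replicates = 2L) {
  prot <- random_protein(R, seed = map_seed + 1L)
  truth <- simulate_truth(R, seed = truth_seed)
  map <- simulate_peptide_map(prot, n_pep, seed = map_seed)
  pt <- simulate_uptake_data(truth, map, replicates = replicates,
                             sigma = sigma, seed = seed)
  list(truth = truth, map = map, pt = pt, protein = prot)
}

# Truth residue x time uptake matrix.
truth_uptake <- function(truth, times = c(15, 150, 1500, 15000)) {
  th <- truth$theta[findInterval(seq_len(truth$R), truth$tau) + 1L, ,
                    drop = FALSE]
  vapply(times, function(t)
    (1 - th[, 1]) * (1 - exp(-th[, 3] * t^th[, 2])) +
      th[, 1] * (1 - exp(-th[, 4] * t)), numeric(truth$R))
}

# A quick sampler configuration for tests that only need a rough posterior.
quick_config <- function(seed, n_iter = 3000L, burn_in = 1000L, thin = 5L)
  sampler_config(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed)
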