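# shared fixtures: small motif spaces, a parameter-recovery scenario and the
# matrix-exponential oracle for linear (mass-action) dynamics

net4 <- transition_network(h4_sites())
net2 <- transition_network(c("K12", "K16"))
net1 <- transition_network("K16")

# independent linear-ODE oracle: y(t) = expm(A t) y(0)
expm_trajectory <- function(model, times) {
  A <- h4zip:::edge_generator(model$net, h4zip:::edge_rates(model))
  y0 <- initial_state(model)
  sapply(times, function(t) as.numeric(Matrix::expm(A * t) %*% y0))
}

# mass-action recovery scenario on the wild-type lattice: slow enough that
# every site rate is informed by the 0-60 min grid
recovery_truth <- c(K5 = 0.01, K8 = 0.02, K12 = 0.05, K16 = 0.12)

recovery_preset <- function(seed, sigma = 0.01) {
  structure(
    list(name = "recovery", family = "mass_action", mode = "site",
         sites = h4_sites(), kcat = recovery_truth,
         kon = NULL, koff = NULL, k_transfer = 0, E_tot = 0.25,
         times = c(0, 5, 15, 30, 60), n_replicates = 3L, sigma = sigma,
         detection_limit = 3e-5, seed = as.integer(seed), version = "1"),
    class = "scenario_preset"
  )
}

# random admissible parameter draws for property tests
random_site_kcat <- function(sites = h4_sites(), lo = -2, hi = 0.5) {
  stats::setNames(10^stats::runif(length(sites), lo, hi), sites)
}
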