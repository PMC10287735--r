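# shared shortcuts and generators for the test suite

scn_ext <- function() pest_scenario("extinction")
scn_perm <- function() pest_scenario("permanence")

# random valid parameter records, reproducible under the caller's seed
random_rates <- function() {
  d <- stats::runif(1, 0.5, 2)
  rate_params(
    Pi = stats::runif(1, 1, 10), mu = stats::runif(1, 0.2, 2),
    beta = stats::runif(1, 0.05, 5), eta = stats::runif(1, 0.05, 2),
    K = stats::runif(1, 0.5, 5), theta = stats::runif(1, 0, 1),
    rho = stats::runif(1, 0.2, 2), varpi = stats::runif(1, 0.2, 2),
    tau1 = stats::runif(1, 0.2, 5), tau2 = stats::runif(1, 0.2, 2),
    d1 = stats::runif(1, 0.05, 1), lambda1 = stats::runif(1, 0.05, 1),
    lambda2 = stats::runif(1, 0.05, 1),
    b = stats::runif(1, 0.05, 0.9) * d, d = d
  )
}

random_pulses <- function() {
  pulse_params(T = stats::runif(1, 0.3, 3),
               theta1 = stats::runif(1, 0.02, 0.95),
               xi = stats::runif(1, 0.02, 0.95))
}

# random nonnegative full-system state (not necessarily in the region)
random_full_state <- function(scale = 5) {
  v <- stats::runif(6, 0, scale)
  state_vec(v[1], v[2], v[3], v[4], v[5], v[6], system = "full")
}

# deviation between two trajectories at their shared pulse instants
pulse_state_deviation <- function(a, b) {
  stopifnot(nrow(a$pre_jump) == nrow(b$pre_jump))
  max(abs(as.matrix(a$pre_jump[-1]) - as.matrix(b$pre_jump[-1])),
      abs(as.matrix(a$post_jump[-1]) - as.matrix(b$post_jump[-1])))
}
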