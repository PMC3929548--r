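# Shared small fixtures, built in code at test time.

two_neuron_net <- function(S = 0.02, model_kind = "IF") {
  A <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)  # 1 -> 2 only
  network_spec(A, S_ee = S, model_kind = model_kind)
}

chain_net <- function(S = 0.05) {
  A <- matrix(0, 3, 3)
  A[1, 2] <- 1
  A[2, 3] <- 1
  network_spec(A, S_ee = S)
}

# Drive regimes (events/ms): fluctuation-driven, intermediate, mean-driven.
regime_rates <- c(fluctuation = 0.25, intermediate = 0.5, mean_driven = 1.0)

sim_two_neuron <- function(rate = 0.5, strength = 0.02, S = 0.02,
                           duration = 120e3, seed = 1, ...) {
  simulate_network(two_neuron_net(S = S, ...),
                   drive = drive_spec(rate = rate, strength = strength),
                   duration = duration, seed = seed)
}
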