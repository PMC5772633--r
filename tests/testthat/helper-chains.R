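# shared small-chain fixtures

two_state_chain <- function(p01 = 0.1, p10 = 0.5, lag_time = 1) {
  ground_truth_chain(rbind(c(1 - p01, p01), c(p10, 1 - p10)),
                     lag_time = lag_time)
}

linear_three_chain <- function() {
  ground_truth_chain(rbind(c(0.5, 0.5, 0),
                           c(0, 0.5, 0.5),
                           c(0, 0, 1)))
}

# AR(1) series with coefficient phi, unit innovations
ar1_series <- function(n, phi, seed = 1) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n))
}

# relative detailed-balance violation of a model
db_violation <- function(model) {
  T_mat <- model$transition_matrix
  pi <- model$stationary_distribution
  F1 <- pi * T_mat
  F2 <- t(F1)
  num <- abs(F1 - F2)
  den <- pmax(F1 + F2, 1e-300)
  max(num / den)
}
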