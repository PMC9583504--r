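# Independent brute-force oracles used to freeze expected values.

# enumerate every cross-group M-tuple and count strictly increasing chains
ehum_brute <- function(scores) {
  idx <- expand.grid(lapply(scores, seq_along))
  ok <- rep(TRUE, nrow(idx))
  for (j in 2:length(scores)) {
    ok <- ok & (scores[[j]][idx[[j]]] > scores[[j - 1]][idx[[j - 1]]])
  }
  mean(ok)
}

exceedance_brute <- function(lower, upper) {
  mean(outer(upper, lower, ">"))
}

# dense angular search: the certified lower bound for d = 2 maximization
grid_max_d2 <- function(objective, n_angles = 20000L) {
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  max(vapply(theta, function(a) objective(c(cos(a), sin(a))), numeric(1)))
}

# random grouped data with finite scores
random_groups <- function(M, d, n_range = 2:6, shift = 0.5) {
  lapply(seq_len(M) - 1L, function(i) {
    matrix(rnorm(sample(n_range, 1) * d, mean = i * shift), ncol = d)
  })
}

random_data <- function(M, d, n_range = 2:6, shift = 0.5) {
  biomarker_groups(random_groups(M, d, n_range, shift))
}

random_unit <- function(d) {
  v <- rnorm(d)
  v / sqrt(sum(v^2))
}
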