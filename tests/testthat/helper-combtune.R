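# Shared fixture builders; everything is generated in code at test time.

# Trial-level session without trace rendering: amplitudes are the responses.
amp_session <- function(n_neurons = 20, mixture = c(0.5, 0.35, 0.15),
                        noise_frac = 0.2, seed = 1, pupil = FALSE,
                        trials_per_condition = 20) {
  cfg <- session_config(n_neurons = n_neurons, noise_frac = noise_frac,
                        trials_per_condition = trials_per_condition,
                        pupil = pupil, seed = seed)
  pop <- sample_population(cfg, mixture = mixture)
  sim <- simulate_trials(pop, cfg)
  space <- enumerate_conditions(cfg$n_elements)
  list(cfg = cfg, pop = pop, space = space,
       trial_table = sim$trial_table,
       resp = response_matrix(sim$amplitudes, sim$trial_table, space))
}

# Purely linear ground-truth population: tuning(s) = sum of element weights.
linear_population <- function(n_neurons, space, noise_frac = 0.3,
                              seed = 1) {
  set.seed(seed)
  X <- design_matrix(space)
  lapply(seq_len(n_neurons), function(i) {
    w <- stats::runif(ncol(X), 0.1, 0.5)
    tun <- as.numeric(X %*% w)
    list(kind = "tabulated", params = NULL, tuning = tun, catch_mean = 0,
         trial_noise_sd = noise_frac * max(tun),
         contamination_k_true = 0.5)
  })
}

# Raw condition means (no catch subtraction) from a response matrix.
condition_means <- function(resp, neuron, trials = NULL) {
  use <- resp$state & resp$inlier[neuron, ]
  if (!is.null(trials)) {
    keep <- logical(length(use)); keep[trials] <- TRUE
    use <- use & keep
  }
  conds <- which(!resp$space$is_catch)
  vapply(conds, function(c_id)
    mean(resp$values[neuron, resp$trial_table$condition == c_id & use]),
    numeric(1))
}

# Closed-form LN tuning evaluated directly from the printed formula (erf via
# its pnorm identity is NOT used here: independent brute-force oracle).
ln_tuning_bruteforce <- function(w, h, a, n_elements = 5) {
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  f <- function(x) (x / 2) * (1 + erf(x / sqrt(2))) +
    (1 / sqrt(2 * pi)) * exp(-x^2 / 2)
  out <- c()
  for (k in 1:n_elements) {
    sets <- utils::combn(n_elements, k)
    for (j in seq_len(ncol(sets)))
      out <- c(out, a * f(sum(w[sets[, j]]) + h))
  }
  out
}
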