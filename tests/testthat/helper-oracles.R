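# Independent oracles used across the suite. These deliberately avoid the
# package's recursions: likelihoods by explicit summation over all latent
# paths, passage/recurrence times by direct chain simulation.

# all K^T latent paths as rows
enumerate_paths <- function(K, Tn) {
  as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
}

# joint probability of one path and the observations (contiguous weeks)
path_joint_prob <- function(path, obs, Gamma, emission, init) {
  p <- init[path[1]]
  for (t in seq_along(path)[-1]) p <- p * Gamma[path[t - 1], path[t]]
  for (t in seq_along(path)) for (j in seq_len(ncol(obs))) {
    if (!is.na(obs[t, j])) p <- p * emission[path[t], j, obs[t, j]]
  }
  p
}

enum_loglik <- function(obs, Gamma, emission, init) {
  paths <- enumerate_paths(nrow(Gamma), nrow(obs))
  log(sum(apply(paths, 1, path_joint_prob, obs = obs, Gamma = Gamma,
                emission = emission, init = init)))
}

enum_posterior <- function(obs, Gamma, emission, init) {
  K <- nrow(Gamma); Tn <- nrow(obs)
  paths <- enumerate_paths(K, Tn)
  w <- apply(paths, 1, path_joint_prob, obs = obs, Gamma = Gamma,
             emission = emission, init = init)
  post <- matrix(0, Tn, K)
  for (t in seq_len(Tn)) for (k in seq_len(K))
    post[t, k] <- sum(w[paths[, t] == k])
  post / rowSums(post)
}

enum_viterbi <- function(obs, Gamma, emission, init) {
  paths <- enumerate_paths(nrow(Gamma), nrow(obs))
  w <- apply(paths, 1, path_joint_prob, obs = obs, Gamma = Gamma,
             emission = emission, init = init)
  best <- which(w == max(w))
  list(score = log(max(w)), paths = paths[best, , drop = FALSE])
}

# Monte-Carlo mean hit time: steps from `from` until first arrival in `to`
# (from == to gives the recurrence time). Returns mean and its MC SE.
mc_hit_time <- function(Gamma, from, to, n = 1e5, cap = 1e5) {
  K <- nrow(Gamma)
  cum <- t(apply(Gamma, 1, cumsum))
  states <- rep.int(from, n)
  times <- integer(n)
  alive <- seq_len(n)
  t <- 0L
  while (length(alive) && t < cap) {
    t <- t + 1L
    u <- stats::runif(length(alive))
    s <- states[alive]
    ns <- 1L + rowSums(u > cum[s, -K, drop = FALSE])
    hit <- ns == to
    times[alive[hit]] <- t
    states[alive] <- ns
    alive <- alive[!hit]
  }
  list(mean = mean(times), se = stats::sd(times) / sqrt(n))
}

random_stochastic_matrix <- function(K = 3) {
  M <- matrix(stats::rgamma(K * K, 1), K, K)
  M / rowSums(M)
}

# small, fast generator configuration for fit tests; the demographic logit
# shift is zeroed so group-level estimands equal the configured parameters
small_config <- function(n_subjects = 12, n_weeks = 60, seed = 1, ...) {
  cohort_config(n_subjects = n_subjects, n_weeks = n_weeks, seed = seed,
                heavy_missing_subject_fraction = 0, missing_rate = 0,
                female_transition_effects = data.frame(
                  from = integer(), to = integer(), shift = numeric()), ...)
}

fast_mcmc <- function(n_iterations = 400, n_burnin = 150, seed = 1, ...) {
  mcmc_config(n_iterations = n_iterations, n_burnin = n_burnin, seed = seed,
              ...)
}

# canonical truth for the default generator: states ordered by ascending
# endorsement (low, cognitive-physical, elevated)
canonical_true_inertia <- function() c(0.887, 0.870, 0.865)

# crude ESS from the initial-positive autocorrelation sum (test-side twin of
# the package's diagnostic, used for Monte-Carlo standard errors)
effective_n <- function(v) {
  ac <- stats::acf(v, lag.max = min(100, length(v) %/% 4), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) { if (r < 0.05) break; s <- s + r }
  length(v) / (1 + 2 * s)
}
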