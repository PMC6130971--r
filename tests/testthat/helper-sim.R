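# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

# Small two-state configuration used throughout: the reference noise level
# sigma/total = 0.08, zero bleaching unless a test wants it.
quiet_config <- function(...) {
  defaults <- list(
    total_intensity = 1000, noise_sigma = 0,
    leakage = leakage_matrix(0, 0),
    donor_bleach_rate = 0, acceptor_bleach_rate = 0,
    label_efficiency = 1, donor_prob = 0.5,
    n_molecules_per_field = 4, n_fields = 1, trace_length = 20
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Simulate one molecule's noisy efficiency trace (efficiency-level noise),
# returning the noisy trace, the exact frame-averaged ideal efficiency and
# the underlying continuous-time path.
sim_e_trace <- function(rates = matrix(c(-0.2, 0.2, 0.1, -0.1), 2, byrow = TRUE),
                        state_fret = c(0.2, 0.8), sigma_e = 0.08,
                        trace_length = 200, frame_rate = 10, seed = 1) {
  cfg <- sim_config(
    state_fret = state_fret, rate_matrix = rates,
    total_intensity = 1000, noise_sigma = 0,
    leakage = leakage_matrix(0, 0),
    donor_bleach_rate = 0, acceptor_bleach_rate = 0,
    trace_length = trace_length, frame_rate = frame_rate,
    n_molecules_per_field = 1, n_fields = 1, seed = seed
  )
  set.seed(seed)
  path <- simulate_state_path(cfg)
  tr <- render_intensities(path, cfg, donor_bleach_time = Inf,
                           acceptor_bleach_time = Inf)
  e_ideal <- tr$acceptor / (tr$acceptor + tr$donor)
  list(e = e_ideal + rnorm(length(e_ideal), 0, sigma_e),
       e_ideal = e_ideal, path = path, config = cfg)
}

# Random valid HMM instance for Viterbi brute-force comparisons.
random_hmm_instance <- function(t_max = 12, n_states = 2) {
  t_len <- sample(3:t_max, 1)
  means <- sort(runif(n_states, 0, 1))
  sigmas <- runif(n_states, 0.05, 0.3)
  trans <- matrix(runif(n_states^2, 0.05, 1), n_states)
  trans <- trans / rowSums(trans)
  init <- runif(n_states, 0.05, 1)
  init <- init / sum(init)
  e <- runif(t_len, -0.2, 1.2)
  list(e = e, means = means, sigmas = sigmas, trans = trans, init = init,
       t_len = t_len, n_states = n_states)
}

# Exhaustive maximum-probability path: the independent oracle for Viterbi.
brute_force_best_path <- function(inst) {
  grid <- expand.grid(rep(list(seq_len(inst$n_states)), inst$t_len))
  logb <- sapply(seq_len(inst$n_states), function(k) {
    dnorm(inst$e, inst$means[k], inst$sigmas[k], log = TRUE)
  })
  if (inst$t_len == 1) logb <- matrix(logb, nrow = 1)
  scores <- apply(grid, 1, function(p) {
    p <- as.integer(p)
    s <- log(inst$init[p[1]]) + logb[1, p[1]]
    if (inst$t_len > 1) {
      for (t in 2:inst$t_len) {
        s <- s + log(inst$trans[p[t - 1], p[t]]) + logb[t, p[t]]
      }
    }
    s
  })
  list(best_score = max(scores),
       best_path = as.integer(grid[which.max(scores), ]))
}

# Joint log-probability of a given path on an instance.
path_log_prob <- function(inst, path) {
  logb <- sapply(seq_len(inst$n_states), function(k) {
    dnorm(inst$e, inst$means[k], inst$sigmas[k], log = TRUE)
  })
  if (inst$t_len == 1) logb <- matrix(logb, nrow = 1)
  s <- log(inst$init[path[1]]) + logb[1, path[1]]
  if (inst$t_len > 1) {
    for (t in 2:inst$t_len) {
      s <- s + log(inst$trans[path[t - 1], path[t]]) + logb[t, path[t]]
    }
  }
  s
}
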