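# Reference parameter sets used across the suite (baseline exclusion noise
# gamma = 0.05, tau = 10 at r* = 1, K = 1).

baseline_noise <- function(r_star = 1, gamma = 0.05, tau = 10)
  noise_params(mean_fitness = r_star, gamma = gamma, tau = tau)

fig1_params <- function(S = 100)
  community_params(n_species = S, noise = baseline_noise())

# Exclusion-regime reference point (B ~ 1e-4, Sigma = 1)
ex_params <- function(S = 500)
  community_params(n_species = S, epsilon = 0.05, lam = 1e-8,
                   noise = baseline_noise())

# Buffered-and-Stabilised reference point (B = 0.32, Sigma = 1000)
bust_params <- function(S = 500)
  community_params(n_species = S, epsilon = 50, lam = 3.2e-5,
                   noise = baseline_noise())

# first time a (time, value) series drops to or below a level; censored ->
# the final time
time_to_level <- function(times, values, level) {
  k <- which(values <= level)[1]
  if (is.na(k)) max(times) else times[k]
}
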