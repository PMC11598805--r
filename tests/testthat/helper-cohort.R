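## Shared fixtures, built in code at test time.

quick_config <- function(epochs = 400) rprop_config(epochs = epochs)

small_cohort <- function(n = 80, seed = 101, noise_sd = 0.02, ...)
  simulate_cohort(cohort_config(n = n, n_male = round(n * 54 / 242),
                                noise_sd = noise_sd, seed = seed, ...))

## independent brute-force retention pipeline used as oracle against the
## package implementation (plain arithmetic, no package calls)
oracle_retention <- function(urine, blood, diuresis, bs) {
  cl <- urine * diuresis / (blood * 1440 * bs)
  sig <- sqrt(sum((cl - mean(cl))^2) / length(cl))
  exp(-cl^2 / (2 * sig^2))
}
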