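# Shared fixtures, all built in code.

# small default-calibration cohort
small_cohort <- function(n = 40, seed = 1, delta = 1.0) {
  generate_cohort(default_config(n_patients = n, signal_strength = delta),
                  seed = seed)
}

# effect-free configuration: no treatment effects, marginally stationary
# categorical transitions with ample discordance (so the paired tests see
# a genuine null with power to reject only at their nominal rate)
null_config <- function(n = 50) {
  cfg <- default_config(n_patients = n, signal_strength = 0)
  cfg$treatment_effects[] <- 0
  cont <- names(cfg$pre_sds)
  cfg$post_sds[cont] <- cfg$pre_sds[cont]
  # balanced flows: pre marginal p is stationary under each matrix
  stationary_flow <- function(p, rate) {
    k <- length(p)
    Tm <- diag(1, k)
    for (i in seq_len(k - 1)) {
      f <- rate * min(p[i], p[i + 1])   # mass exchanged between i and i+1
      Tm[i, i + 1] <- Tm[i, i + 1] + f / p[i]
      Tm[i, i] <- Tm[i, i] - f / p[i]
      Tm[i + 1, i] <- Tm[i + 1, i] + f / p[i + 1]
      Tm[i + 1, i + 1] <- Tm[i + 1, i + 1] - f / p[i + 1]
    }
    Tm
  }
  # use the largest feasible exchange rate below 0.9 per marker, so the
  # expected discordant-pair counts stay large enough (around 20 at n = 50)
  # for the asymptotic chi-square references to be reliable
  for (mk in names(cfg$categorical_pre_frequencies)) {
    p <- cfg$categorical_pre_frequencies[[mk]]
    rate <- 0.9
    while (any(diag(stationary_flow(p, rate)) < 0)) rate <- rate * 0.8
    cfg$transition_matrices[[mk]] <- stationary_flow(p, rate)
  }
  validate_config(cfg)
  cfg
}

# two well-separated clusters with a clean binary endpoint, as a cohort
separable_cohort <- function(n = 20, gap = 8, seed = 1) {
  cfg <- default_config(n_patients = n, signal_strength = 0)
  cohort <- generate_cohort(cfg, seed = seed)
  y <- binarize_trg(cohort$trg)
  shift <- ifelse(y == "pos", gap, -gap)
  for (mk in c("sagittal_longest_diameter", "adc_value")) {
    cn <- paste0("pre_", mk)
    cohort[[cn]] <- cohort[[cn]] + shift * sd(cohort[[cn]])
  }
  cohort
}
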