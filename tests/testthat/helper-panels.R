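# Shared fixtures, all generated in code.

# tiny deterministic binary panel: 3 subjects x 4 waves
tiny_binary_panel <- function(seed = 42) {
  set.seed(seed)
  df <- data.frame(id = rep(1:3, each = 4), time = rep(c(3, 8, 12, 17), 3),
                   y = rbinom(12, 1, 0.6))
  long_panel(df, family = "binomial")
}

# conditions for the parameter-recovery study: moderate heterogeneity where
# the Laplace expansion is accurate, so the study isolates finite-sample error
recovery_truth <- function() {
  list(beta = c(1.0, -3e-4),
       psi = matrix(c(0.25, 0, 0, 2.5e-9), 2, 2))
}

recovery_config <- function(seed, n_subjects = 500) {
  tr <- recovery_truth()
  sim_config("binomial", n_subjects = n_subjects, times = c(3, 8, 12, 17),
             powers = 3, beta = tr$beta, psi = tr$psi, seed = seed)
}

# conditions for the selection-recovery study: a pronounced flat-then-drop
# cubic logit trend with slope heterogeneity sized so the true model's
# dominance matches the magnitudes seen in the motivating risk-panel analysis
selection_truth_config <- function(seed, n_subjects = 1500) {
  sim_config("binomial", n_subjects = n_subjects, times = c(3, 8, 12, 17),
             powers = 3, beta = c(1.0, -7.2e-4),
             psi = matrix(c(1, -0.2 * 1e-3, -0.2 * 1e-3, 1e-6), 2, 2),
             seed = seed)
}

# minimal fitted-model stub for testing criterion arithmetic (GLRT, deltas)
# at given log-likelihoods without running an optimizer
fit_stub <- function(loglik, spec, n = 6156, n_subjects = 1539) {
  k <- n_parameters(spec)
  ic <- information_criteria(loglik, k, n)
  structure(list(beta = NULL, se = NULL, psi = NULL, loglik = loglik, k = k,
                 n_obs = n, n_subjects = n_subjects,
                 aic = ic[["aic"]], aicc = ic[["aicc"]], bic = ic[["bic"]],
                 converged = TRUE, boundary = FALSE, spec = spec,
                 family = spec$family),
            class = "gfpmm_fit")
}
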