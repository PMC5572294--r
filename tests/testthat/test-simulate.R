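test_that("simulation is reproducible and produces valid panels", {
  cfg <- cls_sim_config(n_subjects = 100, seed = 6)
  p1 <- simulate_binary_panel(cfg)
  p2 <- simulate_binary_panel(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_s3_class(p1, "long_panel")
  expect_equal(attr(p1, "n_obs"), 400L)

  q1 <- simulate_count_panel(rmet_sim_config(seed = 6))
  q2 <- simulate_count_panel(rmet_sim_config(seed = 6))
  expect_identical(as.data.frame(q1), as.data.frame(q2))
  expect_false(identical(as.data.frame(q1),
                         as.data.frame(simulate_count_panel(
                           rmet_sim_config(seed = 7)))))
  # family mismatches refused
  expect_error(simulate_count_panel(cls_sim_config()), "poisson")
  expect_error(simulate_binary_panel(rmet_sim_config()), "binomial")
})

test_that("marginal proportions and means match their generating values", {
  # no random effects: wave-1 at-risk proportion equals the target within
  # binomial sampling error
  cfg <- sim_config("binomial", n_subjects = 5000, times = 3, powers = 1,
                    beta = c(qlogis(0.729), 0), psi = matrix(1e-13, 1, 1),
                    seed = 14)
  pan <- simulate_binary_panel(cfg)
  expect_lt(abs(mean(pan$y) - 0.729), 3 * sqrt(0.729 * 0.271 / 5000))

  # poisson mean
  cfgp <- sim_config("poisson", n_subjects = 5000, times = c(1, 2, 3),
                     powers = 1, beta = c(log(5), 0),
                     psi = matrix(1e-13, 1, 1), seed = 15)
  panp <- simulate_count_panel(cfgp)
  expect_lt(abs(mean(panp$y) - 5), 3 * sqrt(5 / 15000))

  # log-link gender effect: group mean ratio ~ exp(gamma)
  cfgg <- sim_config("poisson", n_subjects = 4000, times = c(1, 2, 3),
                     powers = 2, beta = c(log(5), 0, 0.3),
                     psi = matrix(1e-13, 1, 1),
                     covariates = list(gender = function(n)
                       1 + rbinom(n, 1, 0.5)),
                     seed = 2)
  d <- as.data.frame(simulate_count_panel(cfgg))
  ratio <- mean(d$y[d$gender == 2]) / mean(d$y[d$gender == 1])
  expect_equal(ratio, exp(0.3), tolerance = 0.02)
})

test_that("intercept calibration solves the attenuated-marginal equation", {
  # without random effects the offset is the link-transformed target
  expect_equal(calibrate_intercepts(0.729, 3, matrix(1e-14, 1, 1),
                                    "binomial"),
               qlogis(0.729), tolerance = 1e-6)
  # with a unit-variance intercept the offset over-shoots the naive logit
  # and re-integrating reproduces the target
  off <- calibrate_intercepts(0.729, 3, matrix(1, 1, 1), "binomial")
  expect_gt(off, qlogis(0.729))
  gh <- pracma::gaussHermite(61)
  back <- sum(gh$w * plogis(off + sqrt(2) * gh$x)) / sqrt(pi)
  expect_equal(back, 0.729, tolerance = 1e-6)
  # offsets are strictly increasing in the target
  offs <- calibrate_intercepts(c(0.3, 0.5, 0.7, 0.9), c(3, 8, 12, 17),
                               matrix(1, 1, 1), "binomial")
  expect_true(all(diff(offs) > 0))
  expect_error(calibrate_intercepts(1.2, 3, matrix(1, 1, 1), "binomial"),
               "0,1")
})

test_that("the risk-panel preset tracks its published marginal targets", {
  pan <- simulate_binary_panel(cls_sim_config(seed = 1))
  ws <- panel_wave_summary(pan)
  expect_equal(ws$time, c(3, 8, 12, 17))
  expect_equal(ws$n, rep(1539, 4))
  targets <- c(0.729, 0.652, 0.639, 0.535)
  expect_true(all(abs(ws$mean - targets) < 0.03))
})

test_that("generated random-effect variance is consistent with the
          configured covariance", {
  # large-N, large-count check: with mean counts ~50 per wave the subject
  # intercepts are essentially observable, so the variance of the subject
  # log-means estimates the configured variance directly (the small
  # log-of-mean sampling correction 1/(T*mu) is added)
  s2 <- 0.25
  cfg <- sim_config("poisson", n_subjects = 20000, times = c(1, 2, 3),
                    powers = 1, beta = c(log(50), 0), psi = matrix(s2, 1, 1),
                    seed = 20)
  pan <- simulate_count_panel(cfg)
  subj_mean <- tapply(pan$y, pan$id, mean)
  v <- var(log(subj_mean)) - mean(1 / (3 * subj_mean))
  expect_lt(abs(v - s2) / s2, 0.10)
})

test_that("end-to-end recovery: fitting the generating model finds the
          truth", {
  tr <- recovery_truth()
  pan <- simulate_binary_panel(recovery_config(99))
  fit <- fit_gfpmm(pan, model_spec("binomial", powers = 3, random = "slope"))
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[1] - tr$beta[1]), 3 * fit$se[1])
  expect_lt(abs(fit$beta[2] - tr$beta[2]), 3 * fit$se[2])
})
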