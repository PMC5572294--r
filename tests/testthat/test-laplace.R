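test_that("degenerate random effects reduce to the fixed-effects GLM
          log-likelihood", {
  pan <- tiny_binary_panel()
  spec <- model_spec("binomial", powers = 1, random = "intercept")
  beta <- c(0.5, -0.02)
  glm0 <- sum(dbinom(pan$y, 1, plogis(beta[1] + beta[2] * pan$time),
                     log = TRUE))
  expect_equal(laplace_loglik(beta, matrix(1e-11, 1, 1), pan, spec), glm0,
               tolerance = 1e-6)
  expect_equal(agq_loglik(beta, matrix(1e-13, 1, 1), pan, spec), glm0,
               tolerance = 1e-8)

  # poisson family too
  cfg <- sim_config("poisson", n_subjects = 4, times = c(1, 2, 3),
                    powers = 1, beta = c(1.5, 0.1), psi = matrix(1e-13, 1, 1),
                    seed = 3)
  panp <- simulate_count_panel(cfg)
  specp <- model_spec("poisson", powers = 1, random = "intercept")
  glmp <- sum(dpois(panp$y, exp(1.5 + 0.1 * panp$time), log = TRUE))
  expect_equal(laplace_loglik(c(1.5, 0.1), matrix(1e-13, 1, 1), panp, specp),
               glmp, tolerance = 1e-6)
})

test_that("one-node adaptive quadrature equals the Laplace value", {
  pan <- tiny_binary_panel()
  spec <- model_spec("binomial", powers = 1, random = "intercept")
  for (s2 in c(0.04, 0.25, 1)) {
    psi <- matrix(s2, 1, 1)
    expect_equal(agq_loglik(c(0.5, -0.02), psi, pan, spec, nodes = 1),
                 laplace_loglik(c(0.5, -0.02), psi, pan, spec),
                 tolerance = 1e-10)
  }
  # two-dimensional random effects
  spec2 <- model_spec("binomial", powers = 1, random = "slope")
  psi2 <- matrix(c(0.3, 0.01, 0.01, 0.02), 2, 2)
  expect_equal(agq_loglik(c(0.5, -0.02), psi2, pan, spec2, nodes = 1),
               laplace_loglik(c(0.5, -0.02), psi2, pan, spec2),
               tolerance = 1e-10)
})

test_that("Laplace matches 31-node quadrature on a small binomial instance", {
  pan <- tiny_binary_panel()
  spec <- model_spec("binomial", powers = 1, random = "intercept")
  psi <- matrix(0.01, 1, 1)
  expect_equal(laplace_loglik(c(0.5, -0.02), psi, pan, spec),
               agq_loglik(c(0.5, -0.02), psi, pan, spec, nodes = 31),
               tolerance = 1e-4)
})

test_that("single-subject Poisson marginal matches a wide-grid trapezoid
          integral", {
  df <- data.frame(id = 1, time = 1:3, y = c(5, 7, 4))
  pan <- long_panel(df, family = "poisson")
  spec <- model_spec("poisson", powers = 1, random = "intercept")
  beta <- c(1.5, 0.05)
  s <- 0.15
  psi <- matrix(s^2, 1, 1)
  # independent oracle: trapezoid rule over b in mu +- 10 sigma
  bg <- seq(-10 * s, 10 * s, length.out = 20001)
  f <- vapply(bg, function(b) {
    sum(dpois(pan$y, exp(beta[1] + beta[2] * pan$time + b), log = TRUE)) +
      dnorm(b, 0, s, log = TRUE)
  }, numeric(1))
  m <- max(f)
  trap <- m + log(sum(exp(f - m)) * (bg[2] - bg[1]))
  expect_equal(laplace_loglik(beta, psi, pan, spec), trap, tolerance = 1e-4)
  expect_equal(agq_loglik(beta, psi, pan, spec, nodes = 41), trap,
               tolerance = 1e-8)
})

test_that("quadrature error shrinks monotonically with the node count", {
  cfg <- sim_config("poisson", n_subjects = 5, times = c(1, 2, 3),
                    powers = 1, beta = c(1.6, 0.05), psi = matrix(0.36, 1, 1),
                    seed = 12)
  pan <- simulate_count_panel(cfg)
  spec <- model_spec("poisson", powers = 1, random = "intercept")
  v <- vapply(c(7, 15, 31), function(k) {
    agq_loglik(c(1.6, 0.05), matrix(0.36, 1, 1), pan, spec, nodes = k)
  }, numeric(1))
  d <- abs(diff(v))
  expect_lt(d[2], d[1])
})

test_that("Laplace tracks 31-node quadrature across 20 random small-variance
          instances of both families", {
  set.seed(77)
  worst <- 0
  for (r in 1:20) {
    fam <- if (r %% 2) "binomial" else "poisson"
    q <- if (r %% 3 == 0) 2L else 1L
    J <- sample(4:8, 1)
    sd0 <- runif(1, 0.02, 0.1)
    psi <- if (q == 1) matrix(sd0^2, 1, 1) else {
      s1 <- runif(1, 1e-5, 1e-4)
      rho <- runif(1, -0.5, 0.5)
      matrix(c(sd0^2, rho * sd0 * s1, rho * sd0 * s1, s1^2), 2, 2)
    }
    beta <- if (fam == "binomial") c(runif(1, -1, 1), runif(1, -0.05, 0.05))
            else c(runif(1, 0.5, 2), runif(1, -0.05, 0.02))
    cfg <- sim_config(fam, n_subjects = J, times = c(3, 8, 12, 17),
                      powers = 1, beta = beta, psi = psi, seed = 700 + r)
    pan <- if (fam == "binomial") simulate_binary_panel(cfg) else
      simulate_count_panel(cfg)
    spec <- model_spec(fam, powers = 1,
                       random = if (q == 1) "intercept" else "slope")
    worst <- max(worst, abs(laplace_loglik(beta, psi, pan, spec) -
                              agq_loglik(beta, psi, pan, spec, nodes = 31)))
  }
  expect_lt(worst, 1e-3)
})

test_that("invalid covariance and node arguments are refused", {
  pan <- tiny_binary_panel()
  spec <- model_spec("binomial", powers = 1, random = "slope")
  psi_bad <- matrix(c(1, 2, 2, 1), 2, 2)   # indefinite
  expect_error(laplace_loglik(c(0, 0), psi_bad, pan, spec),
               "positive definite")
  expect_error(agq_loglik(c(0, 0), matrix(1, 1, 1), pan,
                          model_spec("binomial", powers = 1,
                                     random = "intercept"), nodes = 0),
               "nodes")
})
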