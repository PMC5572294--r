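#' Simulation configuration
#'
#' Describes a generating model for a synthetic panel: family, wave times,
#' true FP powers, fixed effects, random-effect covariance, optional static
#' covariate generation, and optional per-wave marginal targets.  When
#' `marginal_targets` is given, per-wave intercept offsets are calibrated with
#' [calibrate_intercepts()] so the simulated marginal means hit the targets
#' despite random-effect attenuation, and `beta` is ignored.
#'
#' @param family `"binomial"` or `"poisson"`.
#' @param n_subjects Number of subjects (>= 2).
#' @param times Strictly increasing positive wave times.
#' @param powers True FP powers of the time trend.
#' @param beta True fixed effects: intercept, one coefficient per FP term,
#'   then one per covariate.
#' @param psi True random-effect covariance (1x1 intercept-only or 2x2
#'   intercept + slope-on-first-FP-term).
#' @param covariates Named list of covariate generators; each element is a
#'   function(n) returning one value per subject (e.g. gender coded 1/2).
#' @param marginal_targets Optional per-wave marginal means (proportions in
#'   (0,1) for binomial).
#' @param seed Integer seed driving all draws.
#' @return A `sim_config` list.
#' @export
sim_config <- function(family = c("binomial", "poisson"), n_subjects,
                       times, powers = 1, beta = NULL,
                       psi = matrix(1, 1, 1), covariates = list(),
                       marginal_targets = NULL, seed = 1L) {
  family <- match.arg(family)
  stopifnot(n_subjects >= 2, length(times) >= 1, all(times > 0),
            !is.unsorted(times, strictly = TRUE))
  psi <- as.matrix(psi)
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("'psi' must be positive semi-definite", call. = FALSE)
  if (!is.null(marginal_targets)) {
    stopifnot(length(marginal_targets) == length(times))
    if (family == "binomial" && !all(marginal_targets > 0 & marginal_targets < 1)) {
      stop("binomial marginal targets must lie in (0,1)", call. = FALSE)
    }
  } else if (is.null(beta)) {
    stop("give 'beta' or 'marginal_targets'", call. = FALSE)
  }
  powers <- as.double(fp_powers(powers, max_order = 2L))
  structure(list(family = family, n_subjects = as.integer(n_subjects),
                 times = as.double(times), powers = powers, beta = beta,
                 psi = psi, covariates = covariates,
                 marginal_targets = marginal_targets, seed = as.integer(seed)),
            class = "sim_config")
}

## Shared panel generation: linear predictor per Eq-(3)-style structure,
## response drawn by family.  One seeded stream drives covariates, random
## effects, then responses, in that fixed order.
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  J <- config$n_subjects
  Tt <- length(config$times)
  fb <- fp_basis(config$times, config$powers)     # Tt x p
  q <- ncol(config$psi)
  z2 <- if (q == 2) fb[, 1] else NULL

  covs <- lapply(config$covariates, function(gen) gen(J))
  ev <- eigen(config$psi, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q) %*% t(ev$vectors)
  b <- matrix(stats::rnorm(J * q), J, q) %*% rt    # b ~ N(0, psi)

  if (!is.null(config$marginal_targets)) {
    off <- calibrate_intercepts(config$marginal_targets, config$times,
                                config$psi, config$family,
                                powers = config$powers)
    eta_fix <- matrix(off, nrow = J, ncol = Tt, byrow = TRUE)
  } else {
    p <- length(config$powers)
    beta <- config$beta
    stopifnot(length(beta) == 1 + p + length(covs))
    eta_fix <- matrix(beta[1] + drop(fb %*% beta[2:(1 + p)]),
                      nrow = J, ncol = Tt, byrow = TRUE)
    if (length(covs)) {
      gam <- beta[(2 + p):length(beta)]
      for (e in seq_along(covs)) eta_fix <- eta_fix + gam[e] * covs[[e]]
    }
  }
  eta_ran <- b[, 1] + if (q == 2) outer(b[, 2], z2) else 0
  eta <- eta_fix + eta_ran                         # J x Tt

  mu <- family_funs(config$family)$mu(eta)
  y <- if (config$family == "binomial") {
    stats::rbinom(J * Tt, 1, as.vector(t(mu)))
  } else {
    stats::rpois(J * Tt, as.vector(t(mu)))
  }
  df <- data.frame(id = rep(seq_len(J), each = Tt),
                   time = rep(config$times, J), y = y)
  for (nm in names(covs)) df[[nm]] <- rep(covs[[nm]], each = Tt)
  long_panel(df, family = config$family, covariates = names(covs))
}

#' Simulate a binary longitudinal panel
#'
#' Draws subject random effects b ~ N(0, psi), builds the logit-scale linear
#' predictor from the configured FP time trend (or calibrated per-wave
#' offsets) plus covariate effects, and samples Bernoulli responses.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] with binomial family.
#' @return A [long_panel()].
#' @export
simulate_binary_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$family != "binomial") stop("config family must be binomial",
                                        call. = FALSE)
  simulate_panel(config)
}

#' Simulate a count longitudinal panel
#'
#' As [simulate_binary_panel()] but with a log link and Poisson responses.
#'
#' @param config A [sim_config()] with poisson family.
#' @return A [long_panel()].
#' @export
simulate_count_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$family != "poisson") stop("config family must be poisson",
                                       call. = FALSE)
  simulate_panel(config)
}

#' Calibrate per-wave intercept offsets against marginal targets
#'
#' Random effects attenuate marginal means relative to the conditional
#' (median-subject) curve, so hitting target marginal proportions requires
#' offsets larger than the naive link-transformed targets.  For each wave this
#' solves for the offset c such that the integral of g^{-1}(c + u) over
#' u ~ N(0, z' psi z) equals the target, using 31-node Gauss-Hermite
#' quadrature inside monotone bisection (tolerance 1e-8 on the marginal mean).
#'
#' @param targets Per-wave target marginal means.
#' @param times Wave times (same length as `targets`).
#' @param psi Random-effect covariance (1x1 or 2x2; the slope loads on the
#'   first FP term of `powers`).
#' @param family `"binomial"` or `"poisson"`.
#' @param powers FP powers defining the random-slope loading (default 1).
#' @return Numeric vector of offsets, one per wave.
#' @export
calibrate_intercepts <- function(targets, times, psi,
                                 family = c("binomial", "poisson"),
                                 powers = 1) {
  family <- match.arg(family)
  psi <- as.matrix(psi)
  stopifnot(length(targets) == length(times), all(times > 0))
  if (family == "binomial" && !all(targets > 0 & targets < 1)) {
    stop("binomial targets must lie in (0,1)", call. = FALSE)
  }
  if (family == "poisson" && !all(targets > 0)) {
    stop("poisson targets must be positive", call. = FALSE)
  }
  fb <- fp_basis(times, powers)
  q <- ncol(psi)
  ginv <- family_funs(family)$mu
  gh <- pracma::gaussHermite(31)
  vapply(seq_along(targets), function(i) {
    z <- if (q == 1) 1 else c(1, fb[i, 1])
    s2 <- drop(t(z) %*% psi %*% z)
    marg <- function(c0) sum(gh$w * ginv(c0 + sqrt(2 * s2) * gh$x)) / sqrt(pi)
    f <- function(c0) marg(c0) - targets[i]
    lo <- -1; hi <- 1
    while (f(lo) > 0) lo <- lo * 2
    while (f(hi) < 0) hi <- hi * 2
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (abs(f(mid)) < 1e-8) break
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1))
}

#' Preset: CLS-like binary risk panel
#'
#' Four waves at ages 3, 8, 12 and 17 with 1,539 subjects, a cubic-power
#' (FP power 3) time structure with a correlated random intercept and random
#' slope on t^3, and per-wave offsets calibrated so the marginal at-risk
#' proportions track 0.729, 0.652, 0.639 and 0.535.
#'
#' @param n_subjects Number of subjects (default 1539).
#' @param seed Seed.
#' @return A [sim_config()].
#' @export
cls_sim_config <- function(n_subjects = 1539L, seed = 1L) {
  sd0 <- 1.0                 # between-subject logit-scale level spread
  sd1 <- 2e-4                # slope spread on the t^3 scale (t^3 up to 4913)
  rho <- -0.2
  psi <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2, 2)
  sim_config("binomial", n_subjects = n_subjects, times = c(3, 8, 12, 17),
             powers = 3, psi = psi,
             marginal_targets = c(0.729, 0.652, 0.639, 0.535), seed = seed)
}

#' Preset: RMET-R-like count panel
#'
#' Three waves at times 1, 2, 3 with 212 subjects, Poisson counts with an
#' FP power-2 declining trend, a gender main effect (coded 1 girl / 2 boy,
#' girls' mean lower), and a correlated random intercept and slope on t^2.
#'
#' @param n_subjects Number of subjects (default 212).
#' @param seed Seed.
#' @return A [sim_config()].
#' @export
rmet_sim_config <- function(n_subjects = 212L, seed = 1L) {
  psi <- matrix(c(0.3^2, 0, 0, 0.05^2), 2, 2)
  sim_config("poisson", n_subjects = n_subjects, times = c(1, 2, 3),
             powers = 2,
             beta = c(log(8) - 0.15, -0.05, 0.15),   # intercept, t^2, gender
             psi = psi,
             covariates = list(gender = function(n) 1 + stats::rbinom(n, 1, 0.5)),
             seed = seed)
}
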