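#' Optimizer settings for [fit_gfpmm()]
#'
#' @param inner_tol Gradient tolerance for the per-subject Newton mode search.
#' @param inner_max_iter Maximum inner Newton iterations.
#' @param rel_tol Relative convergence tolerance of the outer quasi-Newton
#'   optimizer.
#' @param max_iter Maximum outer iterations.
#' @param var_floor Lower floor on the diagonal Cholesky factors of the
#'   random-effect covariance (variances cannot drop below `var_floor^2`).
#' @return List of control settings.
#' @export
gfpmm_control <- function(inner_tol = 1e-8, inner_max_iter = 100L,
                          rel_tol = 1e-10, max_iter = 500L,
                          var_floor = 1e-10) {
  list(inner_tol = inner_tol, inner_max_iter = inner_max_iter,
       rel_tol = rel_tol, max_iter = max_iter, var_floor = var_floor)
}

## theta -> lower-triangular Cholesky factor of Psi (log-diagonal
## parameterization): q=1: theta = log L11; q=2: theta = (log L11, L21, log L22).
## Diagonal entries are floored so Psi stays numerically positive definite on
## every evaluation path (the simplex polish is unbounded).
theta_to_L <- function(theta, q, floor = 1e-10) {
  lf <- log(floor)
  if (q == 1) matrix(exp(max(theta[1], lf)), 1, 1) else
    matrix(c(exp(max(theta[1], lf)), theta[2], 0, exp(max(theta[3], lf))), 2, 2)
}

#' Fit a GFPMM/GCPMM by Laplace maximum likelihood
#'
#' Maximizes the Laplace-approximated marginal log-likelihood jointly over the
#' fixed effects and the log-Cholesky factor of the random-effect covariance,
#' using a quasi-Newton outer optimizer with per-subject conditional modes
#' warm-started across evaluations.  Internally, non-intercept design columns
#' are rescaled to unit maximum absolute value so that coefficients of
#' high-power time terms (e.g. t^3 over ages 3-17) are well conditioned; all
#' reported quantities are back on the original scale.  The fit is fully
#' deterministic: the same panel and spec always give the same result.
#'
#' @param panel A [long_panel()].
#' @param spec A [model_spec()].
#' @param control A [gfpmm_control()] list.
#' @return A `gfpmm_fit` object with components `beta` (named estimates),
#'   `se` (standard errors from the observed information of the fixed
#'   effects), `psi` (estimated random-effect covariance), `loglik`, `k`
#'   (parameter count), `n_obs`, `n_subjects`, `aic`, `aicc`, `bic`,
#'   `converged`, `boundary` (variance floor hit), `conditional_modes`
#'   (per-subject random-effect predictions), `spec`, and `panel`.
#' @export
fit_gfpmm <- function(panel, spec, control = gfpmm_control()) {
  des <- build_design(panel, spec)
  p <- ncol(des$X)
  q <- ncol(des$Z)
  if (length(des$subjects) <= q) {
    stop("random-effects covariance unidentifiable: ",
         length(des$subjects), " subject(s) for a ", q,
         "-dimensional random structure", call. = FALSE)
  }
  fam_str <- spec$family

  # column scaling for conditioning (intercepts untouched)
  sx <- apply(abs(des$X), 2, max); sx[1] <- 1
  sz <- apply(abs(des$Z), 2, max); sz[1] <- 1
  desS <- des
  desS$X <- sweep(des$X, 2, sx, "/")
  desS$Z <- sweep(des$Z, 2, sz, "/")

  glm_fam <- if (fam_str == "binomial") stats::binomial() else stats::poisson()
  beta0 <- stats::glm.fit(desS$X, des$y, family = glm_fam)$coefficients
  # fixed starting points; random-slope fits add two asymmetric covariance
  # starts because the variance floor is an absorbing corner for the
  # quasi-Newton search when one component starts too large
  theta_starts <- if (q == 1) list(log(sqrt(0.5))) else
    list(c(log(sqrt(0.5)), 0, log(sqrt(0.5))),
         c(log(sqrt(0.5)), 0, log(0.05)),
         c(log(0.05), 0, log(sqrt(0.5))))
  n_th <- length(theta_starts[[1]])
  lower <- c(rep(-Inf, p),
             if (q == 1) log(control$var_floor) else
               c(log(control$var_floor), -Inf, log(control$var_floor)))

  warm <- new.env(parent = emptyenv())
  warm$b <- matrix(0, length(des$subjects), q)

  negll <- function(par) {
    beta <- par[seq_len(p)]
    L <- theta_to_L(par[p + seq_len(n_th)], q, floor = control$var_floor)
    psi <- L %*% t(L)
    # closed-form inverse of the 1x1/2x2 lower-triangular factor
    Linv <- if (q == 1) matrix(1 / L[1, 1], 1, 1) else
      matrix(c(1 / L[1, 1], -L[2, 1] / (L[1, 1] * L[2, 2]), 0, 1 / L[2, 2]),
             2, 2)
    # a 1e-10 decrement suffices inside the optimizer loop (value error is
    # second order in the mode error); direct likelihood evaluation uses the
    # machine-precision default so the one-node quadrature identity holds
    md <- find_modes(beta, psi, desS, b_init = warm$b,
                     tol = control$inner_tol, max_iter = control$inner_max_iter,
                     Linv = Linv, decr_tol = 1e-10)
    warm$b <- md$b
    if (!md$converged) return(1e10)
    val <- sum(md$joint) - 0.5 * sum(laplace_logdet(L, md))
    if (!is.finite(val)) 1e10 else -val
  }

  # central-difference gradient with a fixed relative step; each perturbed
  # evaluation restarts the inner Newton from the base point's modes so the
  # differences are consistent
  negll_grad <- function(par) {
    negll(par)
    b0 <- warm$b
    g <- numeric(length(par))
    for (i in seq_along(par)) {
      h <- 1e-6 * max(1, abs(par[i]))
      pp <- par; pp[i] <- par[i] + h
      warm$b <- b0; f1 <- negll(pp)
      pm <- par; pm[i] <- par[i] - h
      warm$b <- b0; f2 <- negll(pm)
      g[i] <- (f1 - f2) / (2 * h)
    }
    warm$b <- b0
    g
  }

  run_opt <- function(par) {
    stats::nlminb(par, negll, gradient = negll_grad, lower = lower,
                  control = list(rel.tol = control$rel_tol,
                                 iter.max = control$max_iter,
                                 eval.max = 10L * control$max_iter))
  }
  # The profile surface is extremely flat along the log-Cholesky directions
  # when a variance component is small or the intercept-slope correlation
  # approaches +-1, and gradient-based quasi-Newton alone can stall or fall
  # into a collapsed-variance basin there.  Derivative-free BOBYQA from each
  # fixed start is both robust and cheap on this surface; the best result
  # then gets one quasi-Newton gradient polish for a tight final point.
  opt <- NULL
  for (th0 in theta_starts) {
    warm$b <- matrix(0, length(des$subjects), q)
    bb <- minqa::bobyqa(c(beta0, th0), negll, lower = lower,
                        control = list(rhobeg = 0.2, rhoend = 1e-8,
                                       iprint = 0))
    cand <- list(par = as.numeric(bb$par), objective = bb$fval,
                 convergence = if (bb$ierr == 0) 0L else 1L,
                 message = "bobyqa", iterations = bb$feval)
    if (is.null(opt) || cand$objective < opt$objective - 1e-9) opt <- cand
  }
  # gradient polish to stationarity: converged when either optimizer reports
  # success or a polish round can no longer improve the objective
  conv_ok <- FALSE
  for (r in 1:3) {
    qn <- run_opt(opt$par)
    delta <- opt$objective - qn$objective
    if (qn$objective < opt$objective) {
      qn$par <- pmax(qn$par, lower)
      opt <- qn
    }
    if (qn$convergence == 0 || delta < 1e-8 * (1 + abs(opt$objective))) {
      conv_ok <- TRUE
      break
    }
  }
  conv_ok <- conv_ok || opt$convergence == 0
  betaS <- opt$par[seq_len(p)]
  thetaH <- opt$par[p + seq_len(n_th)]
  LS <- theta_to_L(thetaH, q)
  psiS <- LS %*% t(LS)
  boundary <- any(thetaH[if (q == 1) 1 else c(1, 3)] <=
                    log(control$var_floor) + 1e-8)
  if (boundary) {
    warning("random-effect variance estimate at the lower floor (boundary fit)")
  }
  loglik <- -opt$objective

  # observed information for beta (psi held at its estimate), scaled space
  llbeta <- function(b) -negll(c(b, thetaH))
  H <- pracma::hessian(llbeta, betaS)
  vcovS <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, p, p))
  seS <- sqrt(pmax(diag(vcovS), 0))

  # back to original scale
  beta <- betaS / sx
  se <- seS / sx
  D <- diag(1 / sz, q)
  psi <- D %*% psiS %*% D
  md <- find_modes(betaS, psiS, desS, b_init = warm$b)
  bmat <- sweep(md$b, 2, sz, "/")
  rownames(bmat) <- as.character(des$subjects)
  colnames(bmat) <- colnames(des$Z)
  names(beta) <- names(se) <- colnames(des$X)
  dimnames(psi) <- list(colnames(des$Z), colnames(des$Z))

  k <- n_parameters(spec)
  n <- attr(panel, "n_obs")
  ic <- information_criteria(loglik, k, n)

  structure(list(beta = beta, se = se, psi = psi,
                 vcov_beta = diag(1 / sx, p) %*% vcovS %*% diag(1 / sx, p),
                 loglik = loglik, k = k,
                 n_obs = n, n_subjects = attr(panel, "n_subjects"),
                 aic = ic[["aic"]], aicc = ic[["aicc"]], bic = ic[["bic"]],
                 converged = conv_ok && is.finite(loglik),
                 boundary = boundary,
                 conditional_modes = bmat,
                 spec = spec, family = fam_str, panel = panel,
                 optimizer = list(message = opt$message,
                                  iterations = opt$iterations)),
            class = "gfpmm_fit")
}

#' Information criteria from a maximized log-likelihood
#'
#' AIC = -2 loglik + 2k; AICc = AIC + 2k(k+1)/(n-k-1) (small-sample
#' correction); BIC = -2 loglik + k log(n).  `n` is the total number of
#' observations (rows), not subjects.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations; must exceed k + 1 for AICc.
#' @return Named numeric vector `c(aic, aicc, bic)`.
#' @export
information_criteria <- function(loglik, k, n) {
  stopifnot(is.finite(loglik), k >= 0, n >= 1)
  if (n <= k + 1) stop("AICc undefined: need n > k + 1", call. = FALSE)
  aic <- -2 * loglik + 2 * k
  c(aic = aic,
    aicc = aic + 2 * k * (k + 1) / (n - k - 1),
    bic = -2 * loglik + k * log(n))
}

#' @export
print.gfpmm_fit <- function(x, ...) {
  cat(sprintf("GFPMM fit '%s' (%s family, Laplace ML)%s\n",
              x$spec$label, x$family,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  cat(sprintf("  %d obs, %d subjects; k = %d; logLik = %.3f\n",
              x$n_obs, x$n_subjects, x$k, x$loglik))
  cat(sprintf("  AIC %.3f  AICc %.3f  BIC %.3f\n", x$aic, x$aicc, x$bic))
  est <- cbind(Estimate = x$beta, `Std.Error` = x$se)
  print(round(est, 6))
  cat("Random effects covariance (Psi):\n")
  print(round(x$psi, 8))
  invisible(x)
}

#' @export
logLik.gfpmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.gfpmm_fit <- function(object, ...) object$beta

#' Predict from a fitted GFPMM
#'
#' @param object A `gfpmm_fit`.
#' @param newdata data.frame with a `time` column (and any covariates the
#'   model uses); for `mode = "subject"` also an `id` column of known
#'   subject identifiers.  Defaults to the training panel.
#' @param mode `"conditional"` (random effects at zero, g^{-1}(X beta)),
#'   `"subject"` (adds the subject's predicted random effects), or
#'   `"marginal"` (integrates the inverse link over the random-effect
#'   distribution by 31-node Gauss-Hermite quadrature).
#' @param nodes Quadrature nodes for `mode = "marginal"`.
#' @param ... Unused.
#' @return Numeric vector of response-scale predictions.
#' @export
predict.gfpmm_fit <- function(object, newdata = NULL,
                              mode = c("conditional", "subject", "marginal"),
                              nodes = 31L, ...) {
  mode <- match.arg(mode)
  spec <- object$spec
  if (is.null(newdata)) newdata <- as.data.frame(object$panel)
  if (!"time" %in% names(newdata)) stop("'newdata' needs a 'time' column",
                                        call. = FALSE)
  tt <- time_terms(spec, newdata$time)
  X <- cbind(1, tt)
  for (cv in spec$covariates) {
    if (!cv %in% names(newdata)) stop("covariate '", cv, "' missing from newdata",
                                      call. = FALSE)
    X <- cbind(X, newdata[[cv]])
  }
  for (cv in spec$interactions) X <- cbind(X, tt * newdata[[cv]])
  eta <- drop(X %*% object$beta)
  Z <- if (spec$random == "intercept") matrix(1, nrow(X), 1) else
    cbind(1, tt[, 1])
  ginv <- family_funs(object$family)$mu

  if (mode == "conditional") return(ginv(eta))

  if (mode == "subject") {
    if (!"id" %in% names(newdata)) stop("'newdata' needs an 'id' column for subject-conditional prediction",
                                        call. = FALSE)
    idx <- match(as.character(newdata$id), rownames(object$conditional_modes))
    if (anyNA(idx)) stop("unknown subject id(s): ",
                         paste(unique(newdata$id[is.na(idx)]), collapse = ", "),
                         call. = FALSE)
    b <- object$conditional_modes[idx, , drop = FALSE]
    return(ginv(eta + rowSums(Z * b)))
  }

  # marginal: for each row the random contribution z'b is scalar Gaussian
  s2 <- rowSums((Z %*% object$psi) * Z)
  if (max(s2) < 1e-14) return(ginv(eta))
  gh <- pracma::gaussHermite(nodes)
  vapply(seq_along(eta), function(i) {
    sum(gh$w * ginv(eta[i] + sqrt(2 * s2[i]) * gh$x)) / sqrt(pi)
  }, numeric(1))
}
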