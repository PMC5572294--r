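## Family helpers (canonical links only: binomial-logit, poisson-log).
## Dispersion is fixed at 1 for both, so the conditional log-density, mean and
## IRLS weight are simple functions of the linear predictor.

softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

family_funs <- function(family) {
  switch(family,
    binomial = list(
      ll = function(y, eta) y * eta - softplus(eta),
      mu = function(eta) stats::plogis(eta),
      w  = function(mu) mu * (1 - mu)
    ),
    poisson = list(
      ll = function(y, eta) y * eta - exp(eta) - lgamma(y + 1),
      mu = function(eta) exp(eta),
      w  = function(mu) mu
    ),
    stop("unsupported family: ", family, call. = FALSE))
}

## Fixed-effects-only GLM log-likelihood at beta (the Psi -> 0 limit).
glm_loglik <- function(beta, des) {
  fam <- family_funs(des$spec$family)
  eta <- drop(des$X %*% beta)
  sum(fam$ll(des$y, eta))
}

psi_is_null <- function(psi) max(diag(psi)) < 1e-12

## Conditional-mode search: thin wrapper over the compiled per-subject damped
## Newton (see src/laplace_modes.cpp).  Returns the modes, the per-subject
## joint log-density at the mode, and the curvature components Z'WZ needed
## for the Laplace correction.  Subjects must occupy contiguous row blocks,
## which build_design guarantees.
find_modes <- function(beta, psi, des, b_init = NULL,
                       tol = 1e-8, max_iter = 100L, Linv = NULL,
                       decr_tol = 1e-15) {
  q <- ncol(des$Z)
  J <- length(des$subjects)
  if (is.null(des$run_start)) {
    len <- tabulate(des$subject, nbins = J)
    start <- c(0L, cumsum(len)[-J])
  } else {
    start <- des$run_start
    len <- des$run_len
  }
  if (is.null(Linv)) {
    # invert via the Cholesky factor: exact triangular solves stay finite
    # even when a near +-1 correlation makes solve(psi) fail outright
    L <- tryCatch(t(chol(psi)), error = function(e)
      stop("'psi' is not positive definite", call. = FALSE))
    Linv <- forwardsolve(L, diag(q))
  }
  b0 <- if (is.null(b_init)) matrix(0, J, q) else b_init
  off <- drop(des$X %*% beta)
  fam <- if (des$spec$family == "binomial") 0L else 1L
  res <- cpp_find_modes(off, des$Z, des$y, as.integer(start), as.integer(len),
                        Linv, b0, fam, tol, decr_tol, as.integer(max_iter))
  list(b = res$b, joint = drop(res$joint), converged = res$converged,
       M11 = res$M11,
       M12 = if (q == 2) res$M12, M22 = if (q == 2) res$M22, q = q)
}

#' Laplace approximation to the marginal log-likelihood
#'
#' Evaluates the Laplace-approximated marginal log-likelihood of a GFPMM/GCPMM
#' at fixed parameter values: for each subject the joint log-density of
#' (response, random effects) is maximized over the random effects by damped
#' Newton iterations, and the Gaussian curvature correction
#' \eqn{-\frac12 \log\det(I + \Psi Z'WZ)} is added at the mode.  Summed over
#' subjects this approximates the log of the integrated (marginal) likelihood.
#'
#' @param beta Fixed-effect coefficient vector (order as in [build_design()]).
#' @param psi Random-effect covariance matrix (1x1 or 2x2, PSD).
#' @param panel A [long_panel()], or a prebuilt design list from
#'   [build_design()].
#' @param spec A [model_spec()] (ignored when `panel` is already a design).
#' @return The approximate marginal log-likelihood (scalar).  If `psi` is
#'   numerically zero the exact fixed-effects GLM log-likelihood is returned.
#' @export
laplace_loglik <- function(beta, psi, panel, spec = NULL) {
  des <- if (inherits(panel, "long_panel")) build_design(panel, spec) else panel
  psi <- as.matrix(psi)
  stopifnot(nrow(psi) == ncol(des$Z), length(beta) == ncol(des$X))
  if (psi_is_null(psi)) return(glm_loglik(beta, des))
  md <- find_modes(beta, psi, des)
  if (!md$converged) {
    warning("inner Newton iterations did not converge; returning -Inf")
    return(-Inf)
  }
  ld <- laplace_logdet(t(chol(psi)), md)
  sum(md$joint) - 0.5 * sum(ld)
}

## log det(I + Psi M_j) per subject, evaluated as log det(I + L'ML) with L
## the lower Cholesky factor of Psi: B = L'ML is PSD, so every term of
## 1 + tr(B) + det(B) is non-negative and the expression cannot suffer the
## catastrophic cancellation the raw 2x2 determinant shows when the
## intercept-slope correlation approaches +-1.  Stable as Psi -> 0.
laplace_logdet <- function(L, md) {
  if (md$q == 1) {
    log1p(L[1, 1]^2 * md$M11)
  } else {
    l11 <- L[1, 1]; l21 <- L[2, 1]; l22 <- L[2, 2]
    B11 <- l11^2 * md$M11 + 2 * l11 * l21 * md$M12 + l21^2 * md$M22
    B22 <- l22^2 * md$M22
    B12 <- l22 * (l11 * md$M12 + l21 * md$M22)
    log1p(B11 + B22 + pmax(0, B11 * B22 - B12^2))
  }
}

#' Adaptive Gauss-Hermite marginal log-likelihood
#'
#' High-accuracy reference evaluation of the marginal log-likelihood by
#' adaptive Gauss-Hermite quadrature: nodes are centered at each subject's
#' conditional mode and scaled by the curvature of the joint log-density
#' there.  With a single node it reduces exactly to the Laplace
#' approximation; accuracy increases with the node count.  Intended as a
#' verification reference for [laplace_loglik()]: the modes are located here
#' by a general-purpose optimizer, independent of the production Newton
#' solver, and the integral is evaluated by quadrature rather than a
#' curvature expansion.
#'
#' @inheritParams laplace_loglik
#' @param nodes Number of quadrature nodes per random-effect dimension
#'   (default 31).
#' @return Marginal log-likelihood (scalar).
#' @export
agq_loglik <- function(beta, psi, panel, spec = NULL, nodes = 31L) {
  des <- if (inherits(panel, "long_panel")) build_design(panel, spec) else panel
  psi <- as.matrix(psi)
  q <- ncol(des$Z)
  if (q > 2) stop("random-effect dimension > 2 is unsupported", call. = FALSE)
  if (nodes < 1) stop("'nodes' must be >= 1", call. = FALSE)
  if (psi_is_null(psi)) return(glm_loglik(beta, des))

  fam <- family_funs(des$spec$family)
  Omega <- chol2inv(chol(psi))
  if (q == 1) Omega <- matrix(Omega, 1, 1)
  off <- drop(des$X %*% beta)
  gh <- if (nodes == 1L) list(x = 0, w = sqrt(pi)) else pracma::gaussHermite(nodes)
  idx <- split(seq_along(des$y), des$subject)
  ldetPsi <- as.numeric(determinant(psi, logarithm = TRUE)$modulus)

  total <- 0
  for (j in seq_along(idx)) {
    rows <- idx[[j]]
    yj <- des$y[rows]
    oj <- off[rows]
    Zj <- des$Z[rows, , drop = FALSE]
    joint <- function(b) {
      eta <- oj + drop(Zj %*% b)
      sum(fam$ll(yj, eta)) - 0.5 * drop(t(b) %*% Omega %*% b)
    }
    # independent mode search: general-purpose optimizer (not the production
    # Newton path), then refinement to machine precision so the one-node
    # identity with the Laplace value holds exactly
    joint_grad <- function(b) {
      eta <- oj + drop(Zj %*% b)
      drop(crossprod(Zj, yj - fam$mu(eta))) - drop(Omega %*% b)
    }
    op <- stats::nlminb(rep(0, q), function(b) -joint(b),
                        gradient = function(b) -joint_grad(b))
    bhat <- op$par
    for (it in 1:30) {
      eta <- oj + drop(Zj %*% bhat)
      w <- fam$w(fam$mu(eta))
      H <- crossprod(Zj, Zj * w) + Omega
      g <- joint_grad(bhat)
      step <- solve(H, g)
      if (sum(step * g) < 1e-15) break
      bhat <- bhat + step
    }
    # negative joint Hessian at the mode (analytic for canonical links)
    eta <- oj + drop(Zj %*% bhat)
    w <- fam$w(fam$mu(eta))
    H <- crossprod(Zj, Zj * w) + Omega
    L <- t(chol(solve(H)))          # H^{-1} = L L'
    if (q == 1) {
      zk <- gh$x
      vals <- vapply(seq_along(zk),
                     function(k) joint(bhat + sqrt(2) * L[1, 1] * zk[k]) + zk[k]^2,
                     numeric(1))
      lw <- log(gh$w) + vals
      lint <- log(sqrt(2) * L[1, 1]) + logsumexp(lw)
    } else {
      grid <- expand.grid(k1 = seq_along(gh$x), k2 = seq_along(gh$x))
      vals <- vapply(seq_len(nrow(grid)), function(r) {
        z <- c(gh$x[grid$k1[r]], gh$x[grid$k2[r]])
        joint(bhat + sqrt(2) * drop(L %*% z)) + sum(z^2)
      }, numeric(1))
      lw <- log(gh$w[grid$k1]) + log(gh$w[grid$k2]) + vals
      lint <- log(2) + sum(log(diag(L))) + logsumexp(lw)
    }
    # prior normalizing constant: -q/2 log(2pi) - 1/2 log det Psi
    total <- total + lint - 0.5 * q * log(2 * pi) - 0.5 * ldetPsi
  }
  total
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
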