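#' Candidate model specification
#'
#' Describes one GFPMM/GCPMM candidate: family and link (binomial-logit or
#' poisson-log), the fixed time structure (FP powers or a conventional
#' polynomial degree), static covariates, optional covariate-by-time
#' interactions, and the random structure (random intercept, or correlated
#' random intercept + random slope on the first transformed time term).
#'
#' Exactly one of `powers` and `degree` must be given.  Conventional
#' specifications are always well-formulated: degree d implies all terms
#' t, t^2, ..., t^d.
#'
#' @param family `"binomial"` (logit link) or `"poisson"` (log link).
#' @param powers FP power vector (GFPMM class), or `NULL`.
#' @param degree Conventional polynomial degree (GCPMM class), or `NULL`.
#' @param random `"intercept"` or `"slope"`.
#' @param covariates Character vector of static covariate names.
#' @param interactions Character vector of covariate names to interact with
#'   every time term; must be a subset of `covariates` (well-formulated rule).
#' @param label Optional display label; a default is derived from the
#'   structure.
#' @param max_order Maximum FP order accepted (default 2).
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("binomial", "poisson"),
                       powers = NULL, degree = NULL,
                       random = c("intercept", "slope"),
                       covariates = character(0),
                       interactions = character(0),
                       label = NULL, max_order = 2L) {
  family <- match.arg(family)
  random <- match.arg(random)
  if (is.null(powers) == is.null(degree)) {
    stop("give exactly one of 'powers' (FP class) or 'degree' (conventional class)",
         call. = FALSE)
  }
  if (!is.null(powers)) {
    powers <- as.double(fp_powers(powers, max_order = max_order))
    class_type <- "fp"
  } else {
    if (!is.numeric(degree) || length(degree) != 1L || degree < 1 ||
        degree != as.integer(degree)) {
      stop("'degree' must be a single integer >= 1", call. = FALSE)
    }
    degree <- as.integer(degree)
    class_type <- "conventional"
  }
  if (length(interactions) && !all(interactions %in% covariates)) {
    stop("interaction covariates must also appear as main effects ",
         "(well-formulated model rule)", call. = FALSE)
  }
  if (is.null(label)) {
    stem <- if (class_type == "fp") {
      paste0("gfpm(", paste(format(powers), collapse = ","), ")")
    } else {
      paste0("gcpm.", degree)
    }
    label <- paste0(stem, if (random == "intercept") ".ri" else ".rs",
                    if (length(covariates)) paste0("+", paste(covariates, collapse = "+")) else "",
                    if (length(interactions)) paste0("x", paste(interactions, collapse = "x")) else "")
  }
  structure(list(family = family, class = class_type,
                 powers = powers, degree = degree,
                 random = random, covariates = covariates,
                 interactions = interactions, label = label),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  tt <- if (x$class == "fp") {
    paste0("FP powers (", paste(format(x$powers), collapse = ", "), ")")
  } else {
    paste0("conventional degree ", x$degree)
  }
  cat(sprintf("model_spec '%s': %s family, %s, random %s\n",
              x$label, x$family, tt, x$random))
  if (length(x$covariates)) cat("covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (length(x$interactions)) cat("interactions with time:", paste(x$interactions, collapse = ", "), "\n")
  invisible(x)
}

## Number of fixed-effect columns (incl. intercept) a spec produces.
n_fixed <- function(spec) {
  n_time <- if (spec$class == "fp") length(spec$powers) else spec$degree
  1L + n_time + length(spec$covariates) + length(spec$interactions) * n_time
}

## Free covariance parameters: 1 for random intercept, 3 for correlated
## intercept + slope.  Dispersion is fixed at 1 for both families.
n_covparm <- function(spec) if (spec$random == "intercept") 1L else 3L

#' Parameter count (degrees of freedom) of a candidate model
#'
#' Total number of estimated parameters: fixed coefficients (including the
#' intercept) plus free random-effect covariance parameters (1 for a random
#' intercept; 3 for a correlated random intercept and slope).  The dispersion
#' is fixed at 1 for the binomial and Poisson families and is not counted.
#'
#' @param spec A [model_spec()].
#' @return Integer parameter count.
#' @examples
#' n_parameters(model_spec("binomial", powers = 1, random = "intercept"))  # 3
#' n_parameters(model_spec("binomial", powers = 3, random = "slope"))      # 5
#' n_parameters(model_spec("binomial", degree = 2, random = "slope"))      # 6
#' @export
n_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  n_fixed(spec) + n_covparm(spec)
}

## Time-term matrix for a spec on a vector of times (no intercept).
time_terms <- function(spec, times) {
  if (spec$class == "fp") {
    fp_basis(times, spec$powers, max_order = max(2L, length(spec$powers)))
  } else {
    out <- vapply(seq_len(spec$degree), function(d) times^d, numeric(length(times)))
    out <- matrix(out, nrow = length(times))
    colnames(out) <- if (spec$degree == 1) "time" else
      c("time", paste0("time^", 2:spec$degree))
    out
  }
}

#' Build fixed- and random-effects design matrices
#'
#' Assembles the stacked design matrices for a panel under a candidate
#' specification.  Fixed columns are ordered (intercept, time terms, static
#' covariates, interactions); random columns are (intercept) or
#' (intercept, first transformed time term).
#'
#' @param panel A [long_panel()].
#' @param spec A [model_spec()].
#' @return List with elements `X` (n x p fixed design), `Z` (n x q random
#'   design), `y` (response), `subject` (integer subject index 1..J),
#'   `subjects` (the original ids in index order), and `spec`.
#' @export
build_design <- function(panel, spec) {
  stopifnot(inherits(panel, "long_panel"), inherits(spec, "model_spec"))
  if (spec$family != panel_family(panel)) {
    stop("spec family (", spec$family, ") does not match panel family (",
         panel_family(panel), ")", call. = FALSE)
  }
  absent <- setdiff(c(spec$covariates, spec$interactions), panel_covariates(panel))
  if (length(absent)) {
    stop("covariate(s) named in spec but absent from panel: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  tt <- time_terms(spec, panel$time)
  X <- cbind(`(Intercept)` = 1, tt)
  for (cv in spec$covariates) {
    X <- cbind(X, panel[[cv]])
    colnames(X)[ncol(X)] <- cv
  }
  for (cv in spec$interactions) {
    ints <- tt * panel[[cv]]
    colnames(ints) <- paste0(cv, ":", colnames(tt))
    X <- cbind(X, ints)
  }
  Z <- if (spec$random == "intercept") {
    matrix(1, nrow = nrow(X), ncol = 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cbind(`(Intercept)` = 1, tt[, 1, drop = FALSE])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effects design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  subj <- match(panel$id, unique(panel$id))
  len <- tabulate(subj, nbins = max(subj))
  list(X = X, Z = Z, y = panel$y, subject = subj,
       subjects = unique(panel$id), spec = spec,
       run_start = c(0L, cumsum(len)[-length(len)]), run_len = len)
}
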