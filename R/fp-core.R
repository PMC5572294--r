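#' Royston-Altman power set
#'
#' The discrete set of candidate exponents for a fractional polynomial (FP)
#' of a given order: \{-2, -1, -0.5, 0, 0.5, 1, 2, max(3, order)\}.  Power 0
#' denotes the natural-log transform.  The set always has eight members; only
#' the largest member depends on the order (it is 3 unless the order exceeds 3).
#'
#' @param order FP order m (positive integer).
#' @return Numeric vector of length 8, sorted increasingly.
#' @examples
#' fp_power_set(1)   # -2 -1 -0.5 0 0.5 1 2 3
#' fp_power_set(4)   # -2 -1 -0.5 0 0.5 1 2 4
#' @export
fp_power_set <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || is.na(order) ||
      order < 1 || order != as.integer(order)) {
    stop("'order' must be a single integer >= 1", call. = FALSE)
  }
  c(-2, -1, -0.5, 0, 0.5, 1, 2, max(3, order))
}

#' Box-Tidwell power transformation
#'
#' t^m for m != 0 and log(t) for m = 0, defined only for strictly positive t.
#' This is the elementary transform from which all FP basis columns are built.
#'
#' @param t Positive time value(s).
#' @param m Single finite exponent.
#' @return Transformed value(s), same length as `t`.
#' @examples
#' box_tidwell(2, 2)      # 4
#' box_tidwell(4, -0.5)   # 0.5
#' box_tidwell(1, 0)      # 0
#' @export
box_tidwell <- function(t, m) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m)) {
    stop("'m' must be a single finite exponent", call. = FALSE)
  }
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop("Box-Tidwell transforms require strictly positive time values ",
         "(t > 0); rescale time first, e.g. t -> (t - a)/c with a < min(t), ",
         "if your time axis includes zero or negative values.", call. = FALSE)
  }
  if (m == 0) log(t) else t^m
}

## Powers live on the half-integer grid of the Royston-Altman set; equality of
## adjacent powers (the repeated-power rule) must be exact, so compare 2*m as
## integers rather than doubles-with-tolerance.
power_key <- function(m) as.integer(round(2 * m))

#' Validate an ordered FP power vector
#'
#' Checks that powers are non-decreasing, drawn from the power set for the
#' given order, and that the order does not exceed `max_order`.
#'
#' @param powers Numeric vector of FP exponents m_1 <= ... <= m_p.
#' @param max_order Largest FP order accepted (default 2; orders above 3 are
#'   rarely useful in practice).
#' @return `powers`, invisibly normalized to double, with attribute
#'   `source_set` giving the power set used.
#' @export
fp_powers <- function(powers, max_order = 2L) {
  if (!is.numeric(powers) || length(powers) < 1L || any(!is.finite(powers))) {
    stop("'powers' must be a non-empty finite numeric vector", call. = FALSE)
  }
  p <- length(powers)
  if (p > max_order) {
    stop(sprintf("FP order %d exceeds the configured maximum (%d)", p, max_order),
         call. = FALSE)
  }
  if (is.unsorted(powers)) {
    stop("FP powers must be non-decreasing: m1 <= m2 <= ... <= mp", call. = FALSE)
  }
  set <- fp_power_set(p)
  if (!all(power_key(powers) %in% power_key(set))) {
    bad <- powers[!power_key(powers) %in% power_key(set)]
    stop("power(s) ", paste(bad, collapse = ", "),
         " not in the admissible set {", paste(set, collapse = ", "), "}",
         call. = FALSE)
  }
  out <- as.double(powers)
  attr(out, "source_set") <- set
  invisible(out)
}

#' Fractional polynomial basis
#'
#' Builds the FP design columns f_1(t), ..., f_p(t) for a vector of positive
#' times.  Column h is the Box-Tidwell transform t^(m_h) when m_h differs from
#' the preceding power, and the repeated-power rule f_h = f_{h-1} * log(t)
#' when m_h equals m_{h-1}; repetition applies recursively for higher orders.
#'
#' @param times Vector of strictly positive times.
#' @param powers FP power vector (validated via [fp_powers()]).
#' @param max_order Passed to [fp_powers()].
#' @return Matrix with `length(times)` rows and `length(powers)` columns;
#'   column names `fp(m)` (and `fp(m).log^k` for repeats).  Attributes
#'   `powers` and `times` carry the generators.
#' @examples
#' fp_basis(c(3, 8, 12, 17), 1)     # identity column
#' fp_basis(exp(1), c(2, 2))        # (e^2, e^2) since log(e) = 1
#' @export
fp_basis <- function(times, powers, max_order = length(powers)) {
  powers <- fp_powers(powers, max_order = max(max_order, 2L))
  if (!is.numeric(times) || length(times) < 1L) {
    stop("'times' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all time values must be strictly positive for FP transforms; ",
         "consider rescaling time t -> (t - a)/c with a < min(t).",
         call. = FALSE)
  }
  p <- length(powers)
  out <- matrix(NA_real_, nrow = length(times), ncol = p)
  nms <- character(p)
  logt <- log(times)
  rep_count <- 0L
  for (h in seq_len(p)) {
    if (h > 1L && power_key(powers[h]) == power_key(powers[h - 1L])) {
      out[, h] <- out[, h - 1L] * logt
      rep_count <- rep_count + 1L
      nms[h] <- sprintf("fp(%s).log%d", format(powers[h]), rep_count)
    } else {
      out[, h] <- if (powers[h] == 0) logt else times^powers[h]
      rep_count <- 0L
      nms[h] <- sprintf("fp(%s)", format(powers[h]))
    }
  }
  if (any(!is.finite(out))) {
    stop("non-finite value in FP basis (overflow in t^m?)", call. = FALSE)
  }
  colnames(out) <- nms
  attr(out, "powers") <- as.double(powers)
  attr(out, "times") <- times
  out
}

#' Enumerate candidate models over the FP power set
#'
#' Generates one [model_spec()] per admissible power combination and random
#' structure: 8 candidates per structure at order 1, and all 36 multisets of
#' two powers per structure at order 2.  Static covariates (and optionally
#' covariate-by-time interactions) are attached to every candidate.
#'
#' @param order FP order, 1 or 2.
#' @param family `"binomial"` or `"poisson"`.
#' @param random_structures Character subset of `c("intercept", "slope")`.
#' @param static_covariates Character vector of covariate names (may be empty).
#' @param include_interactions Add covariate-by-time interaction terms.
#' @return List of `model_spec` objects.
#' @export
enumerate_candidates <- function(order, family = c("binomial", "poisson"),
                                 random_structures = c("intercept", "slope"),
                                 static_covariates = character(0),
                                 include_interactions = FALSE) {
  family <- match.arg(family)
  if (!is.numeric(order) || length(order) != 1L || !order %in% c(1, 2)) {
    stop("'order' must be 1 or 2", call. = FALSE)
  }
  random_structures <- match.arg(random_structures, several.ok = TRUE)
  set <- fp_power_set(order)
  combos <- if (order == 1) {
    lapply(set, function(m) m)
  } else {
    out <- list()
    for (i in seq_along(set)) {
      for (j in i:length(set)) out[[length(out) + 1L]] <- c(set[i], set[j])
    }
    out
  }
  specs <- list()
  for (rs in random_structures) {
    for (pw in combos) {
      specs[[length(specs) + 1L]] <- model_spec(
        family = family, powers = pw, random = rs,
        covariates = static_covariates,
        interactions = if (include_interactions) static_covariates else character(0)
      )
    }
  }
  specs
}

#' Enumerate conventional polynomial candidates
#'
#' One [model_spec()] per degree (1..`max_degree`) per random structure, each
#' well-formulated (all lower-degree terms included).
#'
#' @inheritParams enumerate_candidates
#' @param max_degree Highest polynomial degree to include.
#' @return List of `model_spec` objects, ordered degree-within-structure.
#' @export
enumerate_conventional <- function(max_degree, family = c("binomial", "poisson"),
                                   random_structures = c("intercept", "slope"),
                                   static_covariates = character(0),
                                   include_interactions = FALSE) {
  family <- match.arg(family)
  random_structures <- match.arg(random_structures, several.ok = TRUE)
  if (max_degree < 1) stop("'max_degree' must be >= 1", call. = FALSE)
  specs <- list()
  for (rs in random_structures) {
    for (d in seq_len(max_degree)) {
      specs[[length(specs) + 1L]] <- model_spec(
        family = family, degree = d, random = rs,
        covariates = static_covariates,
        interactions = if (include_interactions) static_covariates else character(0)
      )
    }
  }
  specs
}
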