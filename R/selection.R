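#' Generalized likelihood ratio test for nested fits
#'
#' Compares two fits of the same panel and family where the reduced model is
#' structurally nested in the full model (its fixed terms a subset, its random
#' structure no richer).  The statistic is 2 * (loglik_full - loglik_reduced),
#' floored at zero, referred to a chi-square with df equal to the
#' parameter-count difference.  Non-nested pairs are refused: a likelihood
#' ratio between non-nested models has no chi-square reference distribution,
#' so cross-class comparisons must use the delta criteria instead.
#'
#' @param fit_reduced,fit_full `gfpmm_fit` objects.
#' @param alpha Significance level (default 0.05).
#' @return List with `chisq`, `df`, `p`, `significant`.
#' @export
glrt <- function(fit_reduced, fit_full, alpha = 0.05) {
  stopifnot(inherits(fit_reduced, "gfpmm_fit"), inherits(fit_full, "gfpmm_fit"))
  if (fit_reduced$family != fit_full$family ||
      fit_reduced$n_obs != fit_full$n_obs) {
    stop("GLRT requires fits of the same panel and family", call. = FALSE)
  }
  if (fit_full$k <= fit_reduced$k) {
    stop("full model must have more parameters than the reduced model",
         call. = FALSE)
  }
  if (!is_nested(fit_reduced$spec, fit_full$spec)) {
    stop("models are not nested; use the delta (AICc/BIC) criteria for ",
         "non-nested comparisons", call. = FALSE)
  }
  chisq <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  df <- fit_full$k - fit_reduced$k
  p <- stats::pchisq(chisq, df = df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p, significant = p < alpha)
}

## Structural nesting: reduced fixed columns a subset of full's, reduced
## random structure no richer, same covariate/interaction sets or subsets.
is_nested <- function(spec_red, spec_full) {
  if (spec_red$family != spec_full$family) return(FALSE)
  cols <- function(s) {
    tt <- colnames(time_terms(s, 2))  # names only; any positive time works
    c("(Intercept)", tt, s$covariates,
      unlist(lapply(s$interactions, function(cv) paste0(cv, ":", tt))))
  }
  if (!all(cols(spec_red) %in% cols(spec_full))) return(FALSE)
  if (spec_red$random == "slope") {
    if (spec_full$random != "slope") return(FALSE)
    # slope terms must coincide (slope sits on the first time term)
    t1 <- function(s) colnames(time_terms(s, 2))[1]
    if (t1(spec_red) != t1(spec_full)) return(FALSE)
  }
  TRUE
}

#' Delta support categories for a set of criterion values
#'
#' Subtracts the minimum from each value and assigns the Burnham-Anderson
#' support category: delta <= 2 substantial support; 4 <= delta <= 7
#' considerably less; delta > 10 essentially none.  The unnamed gaps
#' (2, 4) and (7, 10] are labeled "intermediate".
#'
#' @param values Named numeric vector of AICc or BIC values.
#' @return data.frame with columns `label`, `value`, `delta`, `support`.
#' @export
delta_table <- function(values) {
  if (length(values) < 1L || any(!is.finite(values))) {
    stop("'values' must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (is.null(names(values))) names(values) <- paste0("model", seq_along(values))
  delta <- values - min(values)
  data.frame(label = names(values), value = unname(values),
             delta = unname(delta), support = support_category(delta),
             stringsAsFactors = FALSE)
}

#' @rdname delta_table
#' @param delta Numeric vector of delta values.
#' @export
support_category <- function(delta) {
  out <- character(length(delta))
  out[delta <= 2] <- "substantial"
  out[delta > 2 & delta < 4] <- "intermediate"
  out[delta >= 4 & delta <= 7] <- "considerably less"
  out[delta > 7 & delta <= 10] <- "intermediate"
  out[delta > 10] <- "essentially none"
  out
}

## Build a comparison table from a list of fits.  GLRT cells are filled only
## for each model's most recent nested predecessor in the given order (the
## ladder convention of the staged procedure); others stay blank.
comparison_table <- function(fits, glrt_ladder = TRUE, alpha = 0.05) {
  stopifnot(length(fits) >= 1)
  labels <- vapply(fits, function(f) f$spec$label, character(1))
  k <- vapply(fits, `[[`, numeric(1), "k")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  gc <- gdf <- gp <- rep(NA_real_, length(fits))
  if (glrt_ladder && length(fits) > 1) {
    for (i in 2:length(fits)) {
      prev <- rev(which(vapply(seq_len(i - 1), function(j) {
        is_nested(fits[[j]]$spec, fits[[i]]$spec) && fits[[j]]$k < fits[[i]]$k
      }, logical(1))))
      if (length(prev)) {
        g <- glrt(fits[[prev[1]]], fits[[i]], alpha = alpha)
        gc[i] <- g$chisq; gdf[i] <- g$df; gp[i] <- g$p
      }
    }
  }
  tab <- data.frame(label = labels, k = as.integer(k), bic = bic, aicc = aicc,
                    glrt_chisq = gc, glrt_df = gdf, glrt_p = gp,
                    delta_bic = bic - min(bic), delta_aicc = aicc - min(aicc),
                    stringsAsFactors = FALSE)
  tab$support_bic <- support_category(tab$delta_bic)
  tab$support_aicc <- support_category(tab$delta_aicc)
  structure(tab, class = c("comparison_table", "data.frame"),
            best_bic_label = best_label(fits, "bic"),
            best_aicc_label = best_label(fits, "aicc"),
            candidate_set = labels[tab$delta_aicc <= 2])
}

## Parsimony-first tie-break: smallest criterion, then fewest parameters,
## then the conventional class.
best_label <- function(fits, criterion) {
  v <- vapply(fits, `[[`, numeric(1), criterion)
  k <- vapply(fits, `[[`, numeric(1), "k")
  is_fp <- vapply(fits, function(f) f$spec$class == "fp", logical(1))
  ord <- order(round(v, 10), k, is_fp)
  fits[[ord[1]]]$spec$label
}

#' @export
print.comparison_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$bic <- sprintf("%.3f", df$bic)
  df$aicc <- sprintf("%.3f", df$aicc)
  df$glrt <- ifelse(is.na(df$glrt_chisq), "",
                    sprintf("%.3f (%.3f)", df$glrt_chisq, df$glrt_p))
  df$delta_bic <- sprintf("%.3f", df$delta_bic)
  df$delta_aicc <- sprintf("%.3f", df$delta_aicc)
  print(df[, c("label", "k", "bic", "aicc", "glrt", "delta_bic",
               "delta_aicc", "support_aicc")], row.names = FALSE)
  cat(sprintf("best by BIC: %s | best by AICc: %s\n",
              attr(x, "best_bic_label"), attr(x, "best_aicc_label")))
  invisible(x)
}

#' Configuration for the staged selection procedure
#'
#' @param family `"binomial"` or `"poisson"`.
#' @param covariates Static covariates to test in the covariate stage.
#' @param fp_order FP order for the GFPMM stage (1, the default search, or 2).
#' @param random_structures Random structures to consider.
#' @param criterion Lead criterion for picking "best" models: `"aicc"`
#'   (the paper's primary delta) or `"bic"`.
#' @param alpha GLRT significance level.
#' @param gam Run the advisory GAM diagnostic first.
#' @param basis_size Basis size for the diagnostic.
#' @return List of settings for [run_selection()].
#' @export
selection_config <- function(family = c("binomial", "poisson"),
                             covariates = character(0),
                             fp_order = 1L,
                             random_structures = c("intercept", "slope"),
                             criterion = c("aicc", "bic"),
                             alpha = 0.05, gam = TRUE, basis_size = 10L) {
  family <- match.arg(family)
  criterion <- match.arg(criterion)
  stopifnot(fp_order %in% c(1L, 2L))
  random_structures <- match.arg(random_structures, several.ok = TRUE)
  list(family = family, covariates = covariates, fp_order = fp_order,
       random_structures = random_structures, criterion = criterion,
       alpha = alpha, gam = gam, basis_size = basis_size)
}

#' Staged model selection for longitudinal non-Gaussian panels
#'
#' Runs the full comparison-table workflow on a panel:
#' \enumerate{
#'   \item advisory GAM trend diagnostic (edf and shape hint; never a gate);
#'   \item conventional-polynomial mixed models (GCPMM): degrees up to
#'     (number of waves - 2) -- the saturation guard -- fitted with a random
#'     intercept then a random slope, compared by ladder GLRTs and deltas;
#'   \item fractional-polynomial mixed models (GFPMM): all first-order powers
#'     (or order-2 pairs) crossed with the random structures, compared by
#'     deltas over the full candidate set;
#'   \item covariate stage: static covariates tested by GLRT at `alpha` on the
#'     best model of each class, interactions tested only when the main
#'     effect is retained;
#'   \item cross-class comparison of the best GCPMM vs the best GFPMM by
#'     deltas (GLRT refused for non-nested pairs and logged).
#' }
#'
#' @param panel A [long_panel()].
#' @param config A [selection_config()].
#' @return A `gfpmm_selection` object: `gam`, `stages` (named list of
#'   comparison tables), `best` (list with `by_bic`, `by_aicc`,
#'   `candidate_set`, `fit`), `fits` (all converged fits, by label), and
#'   `log` (character vector of actions, including refused comparisons).
#' @export
run_selection <- function(panel, config = selection_config(panel_family(panel))) {
  stopifnot(inherits(panel, "long_panel"))
  if (config$family != panel_family(panel)) {
    stop("config family does not match panel family", call. = FALSE)
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  # stage 1: advisory GAM
  gam_fit <- NULL
  if (isTRUE(config$gam)) {
    gam_fit <- tryCatch(fit_trend_gam(panel, basis_size = config$basis_size),
                        error = function(e) {
                          note("GAM diagnostic declined: %s", conditionMessage(e))
                          NULL
                        })
    if (!is.null(gam_fit)) {
      note("GAM diagnostic: edf(smooth) = %.2f (%s)",
           gam_fit$edf_smooth, gam_fit$shape_hint)
    }
  }

  n_waves <- length(unique(panel$time))
  fit_all <- function(specs) {
    fits <- lapply(specs, function(s) {
      f <- tryCatch(fit_gfpmm(panel, s), error = function(e) {
        note("fit of '%s' failed: %s", s$label, conditionMessage(e)); NULL
      })
      if (!is.null(f) && !f$converged) {
        note("fit of '%s' did not converge; excluded", s$label)
        f <- NULL
      }
      if (!is.null(f)) {
        note("fitted '%s': k=%d logLik=%.3f", s$label, f$k, f$loglik)
      }
      f
    })
    fits[!vapply(fits, is.null, logical(1))]
  }

  # stage 2: conventional class, ladder RI degrees then RS degrees
  max_deg <- max(1L, n_waves - 2L)
  gcpmm_specs <- enumerate_conventional(max_deg, family = config$family,
                                        random_structures = config$random_structures)
  gcpmm_fits <- fit_all(gcpmm_specs)
  if (!length(gcpmm_fits)) stop("all conventional candidates failed; log:\n",
                                paste(log, collapse = "\n"), call. = FALSE)
  gcpmm_tab <- comparison_table(gcpmm_fits, alpha = config$alpha)

  # stage 3: FP class, deltas over the full displayed set
  gfpmm_specs <- enumerate_candidates(config$fp_order, family = config$family,
                                      random_structures = config$random_structures)
  gfpmm_fits <- fit_all(gfpmm_specs)
  if (!length(gfpmm_fits)) stop("all FP candidates failed; log:\n",
                                paste(log, collapse = "\n"), call. = FALSE)
  gfpmm_tab <- comparison_table(gfpmm_fits, glrt_ladder = FALSE)

  crit <- config$criterion
  pick <- function(fits) {
    labs <- vapply(fits, function(f) f$spec$label, character(1))
    fits[[match(best_label(fits, crit), labs)]]
  }
  best_gcpmm <- pick(gcpmm_fits)
  best_gfpmm <- pick(gfpmm_fits)

  # stage 4: covariates by GLRT on the best model of each class
  cov_tab <- NULL
  if (length(config$covariates)) {
    cov_stage <- function(base_fit) {
      fits <- list(base_fit)
      current <- base_fit
      for (cv in config$covariates) {
        s <- current$spec
        with_cov <- model_spec(family = s$family, powers = s$powers,
                               degree = s$degree, random = s$random,
                               covariates = c(s$covariates, cv),
                               interactions = s$interactions)
        f1 <- fit_gfpmm(panel, with_cov)
        fits <- c(fits, list(f1))
        g <- glrt(current, f1, alpha = config$alpha)
        if (g$significant) {
          note("covariate '%s' retained on '%s' (GLRT p=%.3f)", cv,
               current$spec$label, g$p)
          # interaction tested only when the main effect is retained
          with_int <- model_spec(family = s$family, powers = s$powers,
                                 degree = s$degree, random = s$random,
                                 covariates = c(s$covariates, cv),
                                 interactions = c(s$interactions, cv))
          f2 <- fit_gfpmm(panel, with_int)
          fits <- c(fits, list(f2))
          g2 <- glrt(f1, f2, alpha = config$alpha)
          if (g2$significant) {
            note("interaction '%s x time' retained (GLRT p=%.3f)", cv, g2$p)
            current <- f2
          } else {
            note("interaction '%s x time' dropped (GLRT p=%.3f)", cv, g2$p)
            current <- f1
          }
        } else {
          note("covariate '%s' dropped on '%s' (GLRT p=%.3f)", cv,
               current$spec$label, g$p)
        }
      }
      list(fits = fits, final = current)
    }
    cg <- cov_stage(best_gcpmm)
    cf <- cov_stage(best_gfpmm)
    best_gcpmm <- cg$final
    best_gfpmm <- cf$final
    cov_tab <- comparison_table(c(cg$fits, cf$fits), alpha = config$alpha)
  }

  # stage 5: cross-class by deltas only
  if (!is_nested(best_gcpmm$spec, best_gfpmm$spec) &&
      !is_nested(best_gfpmm$spec, best_gcpmm$spec)) {
    note("cross-class GLRT refused ('%s' vs '%s' not nested); deltas only",
         best_gcpmm$spec$label, best_gfpmm$spec$label)
  }
  cross_tab <- comparison_table(list(best_gfpmm, best_gcpmm), alpha = config$alpha)

  all_fits <- c(gcpmm_fits, gfpmm_fits,
                if (!is.null(cov_tab)) list(best_gcpmm, best_gfpmm))
  labs <- vapply(all_fits, function(f) f$spec$label, character(1))
  all_fits <- all_fits[!duplicated(labs)]
  names(all_fits) <- labs[!duplicated(labs)]

  final_pool <- list(best_gfpmm, best_gcpmm)
  best_fit <- pick(final_pool)
  crit_vals <- vapply(final_pool, `[[`, numeric(1), crit)
  cand <- vapply(final_pool, function(f) f$spec$label,
                 character(1))[crit_vals - min(crit_vals) <= 2]
  note("final recommendation (%s-led): %s; candidate set {%s}",
       toupper(crit), best_fit$spec$label, paste(cand, collapse = ", "))

  structure(list(gam = gam_fit,
                 stages = list(gcpmm = gcpmm_tab, gfpmm = gfpmm_tab,
                               covariates = cov_tab, cross_class = cross_tab),
                 best = list(by_bic = attr(cross_tab, "best_bic_label"),
                             by_aicc = attr(cross_tab, "best_aicc_label"),
                             candidate_set = cand, fit = best_fit),
                 fits = all_fits, config = config, log = log),
            class = "gfpmm_selection")
}

#' @export
print.gfpmm_selection <- function(x, ...) {
  cat("Staged model selection\n")
  if (!is.null(x$gam)) {
    cat(sprintf("GAM diagnostic: edf(smooth) = %.2f (%s)\n",
                x$gam$edf_smooth, x$gam$shape_hint))
  }
  for (nm in names(x$stages)) {
    if (is.null(x$stages[[nm]])) next
    cat("\n--", nm, "stage --\n")
    print(x$stages[[nm]])
  }
  cat(sprintf("\nRecommended: %s (best by BIC: %s; by AICc: %s)\n",
              x$best$fit$spec$label, x$best$by_bic, x$best$by_aicc))
  invisible(x)
}
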