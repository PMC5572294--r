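#' Read a long-format panel from CSV
#'
#' Reads a comma-delimited, headered file and validates it into a
#' [long_panel()].  Rows with a missing response are dropped with a message;
#' out-of-range responses (binary values outside \{0,1\}, non-integer or
#' negative counts) are errors naming the offending rows.
#'
#' @param path CSV file path.
#' @param family `"binomial"` or `"poisson"`.
#' @param id,time,response Column names in the file.
#' @param covariates Static covariate column names to carry along.
#' @return A [long_panel()].
#' @export
read_long_panel <- function(path, family = c("binomial", "poisson"),
                            id = "id", time = "time", response = "y",
                            covariates = character(0)) {
  family <- match.arg(family)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  long_panel(df, family = family, id = id, time = time, response = response,
             covariates = covariates)
}

#' Write a panel to CSV
#'
#' @param panel A [long_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_long_panel <- function(panel, path) {
  stopifnot(inherits(panel, "long_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Write a comparison table as CSV
#'
#' Emits the table in the conventional report layout: model label, parameter
#' count, BIC, AICc, the GLRT as "chisq (p)" with three decimals (blank where
#' no nested predecessor exists), the two deltas with three decimals, and the
#' support category.  [read_comparison_table()] round-trips the file at that
#' precision.
#'
#' @param table A `comparison_table` (from the selection stages).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(table, path) {
  stopifnot(inherits(table, "comparison_table"))
  df <- as.data.frame(table)
  out <- data.frame(
    Models = df$label,
    `Number of parameters` = df$k,
    BIC = sprintf("%.3f", df$bic),
    AICC = sprintf("%.3f", df$aicc),
    `GLRT Chisq (p-value)` = ifelse(is.na(df$glrt_chisq), "",
                                    sprintf("%.3f (%.3f)", df$glrt_chisq,
                                            df$glrt_p)),
    `Delta(BIC)` = sprintf("%.3f", df$delta_bic),
    `Delta(AICC)` = sprintf("%.3f", df$delta_aicc),
    Support = df$support_aicc,
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read back a comparison-table CSV
#'
#' @param path File written by [write_comparison_table()].
#' @return data.frame with numeric columns `k`, `bic`, `aicc`, `glrt_chisq`,
#'   `glrt_p`, `delta_bic`, `delta_aicc` (3-decimal precision) plus `label`
#'   and `support`.
#' @export
read_comparison_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  glrt <- df[["GLRT Chisq (p-value)"]]
  chisq <- p <- rep(NA_real_, length(glrt))
  has <- !is.na(glrt) & nzchar(glrt)
  chisq[has] <- as.numeric(sub(" \\(.*", "", glrt[has]))
  p[has] <- as.numeric(sub(".*\\((.*)\\)", "\\1", glrt[has]))
  data.frame(label = df$Models, k = df[["Number of parameters"]],
             bic = as.numeric(df$BIC), aicc = as.numeric(df$AICC),
             glrt_chisq = chisq, glrt_p = p,
             delta_bic = as.numeric(df[["Delta(BIC)"]]),
             delta_aicc = as.numeric(df[["Delta(AICC)"]]),
             support = df$Support, stringsAsFactors = FALSE)
}

#' Serialize a fitted model summary as JSON
#'
#' Writes estimates, standard errors, the random-effect covariance, the
#' maximized log-likelihood, parameter count, sample sizes, information
#' criteria and convergence diagnostics.
#'
#' @param fit A `gfpmm_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  stopifnot(inherits(fit, "gfpmm_fit"))
  obj <- list(
    label = fit$spec$label,
    family = fit$family,
    class = fit$spec$class,
    powers = fit$spec$powers,
    degree = fit$spec$degree,
    random = fit$spec$random,
    beta = as.list(fit$beta),
    se = as.list(fit$se),
    psi = unclass(fit$psi),
    loglik = fit$loglik,
    k = fit$k,
    n_obs = fit$n_obs,
    n_subjects = fit$n_subjects,
    aic = fit$aic, aicc = fit$aicc, bic = fit$bic,
    converged = fit$converged,
    boundary = fit$boundary)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
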