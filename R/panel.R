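#' Long-format longitudinal panel
#'
#' Construct and validate a long-format panel: one row per subject-time
#' observation with a subject identifier, a strictly positive time value, a
#' response (0/1 for the binomial family, a non-negative integer count for the
#' Poisson family), and optional static covariates.  Rows with a missing
#' response are dropped (with a message reporting the count); missing values
#' in any other modeled column are an error.
#'
#' @param data A data.frame in long format.
#' @param family `"binomial"` or `"poisson"`.
#' @param id,time,response Column names for subject id, time, and response.
#' @param covariates Character vector of static covariate column names.
#' @return A `long_panel`: the validated data.frame (columns renamed to
#'   `id`, `time`, `y`, covariates as-is), sorted by subject then time, with
#'   attributes `family`, `covariates`, `n_subjects`, `n_obs`, `n_dropped`.
#' @export
long_panel <- function(data, family = c("binomial", "poisson"),
                       id = "id", time = "time", response = "y",
                       covariates = character(0)) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data))
  needed <- c(id, time, response, covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(needed)) {
    stop("mapped columns must be distinct", call. = FALSE)
  }
  df <- data.frame(id = data[[id]], time = as.numeric(data[[time]]),
                   y = data[[response]], check.names = FALSE)
  for (cv in covariates) df[[cv]] <- data[[cv]]

  n_dropped <- sum(is.na(df$y))
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with missing response dropped")
    df <- df[!is.na(df$y), , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no usable rows after dropping missing responses",
                           call. = FALSE)
  if (anyNA(df$time) || any(!is.finite(df$time))) {
    stop("missing or non-finite time values", call. = FALSE)
  }
  if (any(df$time <= 0)) {
    stop("time values must be strictly positive (required for FP transforms); ",
         "rescale time before building the panel.", call. = FALSE)
  }
  for (cv in covariates) {
    if (anyNA(df[[cv]])) stop("missing values in covariate '", cv, "'",
                              call. = FALSE)
  }
  y <- df$y
  if (family == "binomial") {
    bad <- which(!(y %in% c(0, 1)))
    if (length(bad)) {
      stop("binary responses must be 0/1; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  } else {
    bad <- which(!is.finite(y) | y < 0 | y != round(y))
    if (length(bad)) {
      stop("count responses must be non-negative integers; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  df$y <- as.numeric(y)

  df <- df[order(df$id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  if (any(duplicated(df[c("id", "time")]))) {
    stop("times within subject must be strictly increasing (duplicates found)",
         call. = FALSE)
  }

  structure(df,
            class = c("long_panel", "data.frame"),
            family = family,
            covariates = covariates,
            n_subjects = length(unique(df$id)),
            n_obs = nrow(df),
            n_dropped = n_dropped)
}

#' @export
print.long_panel <- function(x, ...) {
  cat(sprintf("long_panel: %d observations on %d subjects (%s family)\n",
              attr(x, "n_obs"), attr(x, "n_subjects"), attr(x, "family")))
  cv <- attr(x, "covariates")
  if (length(cv)) cat("covariates:", paste(cv, collapse = ", "), "\n")
  cat("waves:", paste(sort(unique(x$time)), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

panel_family <- function(panel) attr(panel, "family")
panel_covariates <- function(panel) attr(panel, "covariates")

#' Per-wave summary of a panel
#'
#' Mean response (proportion at-risk for binary panels, mean count for count
#' panels) and observation count at each time value.
#'
#' @param panel A [long_panel()].
#' @return data.frame with columns `time`, `n`, `mean`.
#' @export
panel_wave_summary <- function(panel) {
  stopifnot(inherits(panel, "long_panel"))
  agg <- stats::aggregate(panel$y, by = list(time = panel$time),
                          FUN = function(v) c(n = length(v), mean = mean(v)))
  data.frame(time = agg$time, n = agg$x[, "n"], mean = agg$x[, "mean"])
}
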