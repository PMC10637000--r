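#' Estimate TE subfamily cis-regulatory activities by least squares
#'
#' Fits, with an intercept, the linear model in which the stacked per-pair
#' differences in doubly centered log2 TPM expression are a linear
#' combination of the gene-by-subfamily regulatory susceptibilities. Each
#' subfamily coefficient is the difference in cis-regulatory activity
#' (log2 expression units per integrant) between treatment and control;
#' coefficients are t-tested against zero, adjusted with Benjamini-Hochberg
#' across subfamilies (intercept excluded), and the overall regression
#' F-test and adjusted R-squared are reported.
#'
#' @param delta Stacked delta-expression tibble ([build_delta()]); the
#'   susceptibility matrix is expanded row-wise to match via `gene_id`.
#' @param N A `susceptibility_matrix` whose rows cover the genes in `delta`.
#' @return An object of class `te_activity_fit`; see [tidy.te_activity_fit()]
#'   and [glance.te_activity_fit()].
#' @export
fit_activities <- function(delta, N) {
  stopifnot(inherits(N, "susceptibility_matrix"))
  idx <- match(delta$gene_id, rownames(N$values))
  if (anyNA(idx)) {
    bad <- delta$gene_id[which(is.na(idx))[1]]
    te_abort(sprintf("gene '%s' in delta is absent from the susceptibility matrix",
                     bad), "te_validation_error")
  }
  X <- N$values[idx, , drop = FALSE]
  y <- delta$delta
  n_obs <- length(y)
  p <- ncol(X) + 1L
  if (n_obs <= p) {
    te_abort(sprintf("%d observations cannot identify %d parameters", n_obs, p),
             "te_validation_error")
  }
  subfams <- colnames(X)
  safe <- make.names(subfams, unique = TRUE)
  df <- as.data.frame(X)
  names(df) <- safe
  df$.delta <- y
  fit <- stats::lm(.delta ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    aliased <- subfams[match(names(stats::coef(fit))[is.na(stats::coef(fit))], safe)]
    te_abort(paste0("design is rank-deficient; collinear column(s): ",
                    paste(aliased, collapse = ", ")),
             "te_rank_error")
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  tab <- tibble::tibble(
    subfamily = subfams,
    estimate = unname(ct[-1, "Estimate"]),
    std_error = unname(ct[-1, "Std. Error"]),
    t_value = unname(ct[-1, "t value"]),
    p_value = unname(ct[-1, "Pr(>|t|)"])
  )
  tab$adj_p_value <- bh_adjust(tab$p_value)
  fstat <- sm$fstatistic
  structure(
    list(
      table = tab,
      intercept = unname(ct[1, "Estimate"]),
      intercept_se = unname(ct[1, "Std. Error"]),
      coefficients = stats::setNames(ct[-1, "Estimate"], subfams),
      f_statistic = unname(fstat[1]),
      f_p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                   lower.tail = FALSE)),
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      sigma = sm$sigma,
      n_obs = n_obs,
      residual_df = fit$df.residual,
      mode = N$mode
    ),
    class = "te_activity_fit"
  )
}

#' @export
print.te_activity_fit <- function(x, ...) {
  cat(sprintf(
    "<te_activity_fit> %d subfamilies, %d observations (residual df %d)\n",
    nrow(x$table), x$n_obs, x$residual_df))
  cat(sprintf("  F-test p = %.3g, adj. R^2 = %.3f, %d subfamil%s with adj. p <= 0.05\n",
              x$f_p_value, x$adj_r_squared,
              sum(x$table$adj_p_value <= 0.05),
              if (sum(x$table$adj_p_value <= 0.05) == 1) "y" else "ies"))
  invisible(x)
}

#' Tidy per-subfamily activity estimates
#'
#' @param x A `te_activity_fit`.
#' @param ... Unused.
#' @return A tibble with one row per subfamily: `subfamily`, `estimate`
#'   (difference in cis-regulatory activity, log2 units per integrant),
#'   `std_error`, `t_value`, `p_value`, `adj_p_value` (Benjamini-Hochberg).
#' @exportS3Method generics::tidy
tidy.te_activity_fit <- function(x, ...) {
  x$table
}

#' One-row model-level summary of an activity fit
#'
#' @inheritParams tidy.te_activity_fit
#' @return A one-row tibble: intercept, F statistic and p-value, R-squared,
#'   adjusted R-squared, residual sigma, observation count, residual df.
#' @exportS3Method generics::glance
glance.te_activity_fit <- function(x, ...) {
  tibble::tibble(
    intercept = x$intercept,
    statistic = x$f_statistic,
    p_value = x$f_p_value,
    r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared,
    sigma = x$sigma,
    n_obs = x$n_obs,
    df_residual = x$residual_df
  )
}

#' Predict stacked deltas from a fitted activity model
#'
#' @param object A `te_activity_fit`.
#' @param delta A delta tibble whose `gene_id` rows to predict.
#' @param N The `susceptibility_matrix` supplying predictor rows.
#' @param ... Unused.
#' @return Numeric vector of predicted delta values.
#' @export
predict.te_activity_fit <- function(object, delta, N, ...) {
  X <- N$values[match(delta$gene_id, rownames(N$values)),
                names(object$coefficients), drop = FALSE]
  drop(object$intercept + X %*% object$coefficients)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order. A thin
#' validating wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    te_abort("p-values must lie in [0, 1]", "te_validation_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Fold-change confidence interval for an activity estimate
#'
#' Converts a log2 activity estimate and its standard error into the
#' per-integrant expression fold-change interval
#' `2^(estimate -/+ z * se)`. With the default normal quantile and
#' `level = 0.95`, `z = 1.96`. Set `quantile = "t"` (with `df`) for a
#' t-based interval.
#'
#' @param estimate Log2 activity estimate(s).
#' @param se Standard error(s), `>= 0`.
#' @param level Confidence level in `(0, 1)`, default 0.95.
#' @param quantile `"normal"` (default) or `"t"`.
#' @param df Residual degrees of freedom, required for `quantile = "t"`.
#' @return A tibble with columns `low` and `high` (fold-change scale).
#' @export
#' @examples
#' fold_change_interval(-0.133, 0.0095) # about [0.90, 0.92]
fold_change_interval <- function(estimate, se, level = 0.95,
                                 quantile = c("normal", "t"), df = NULL) {
  quantile <- match.arg(quantile)
  if (any(se < 0)) te_abort("se must be >= 0", "te_validation_error")
  if (level <= 0 || level >= 1) {
    te_abort("level must be in (0, 1)", "te_validation_error")
  }
  z <- if (quantile == "normal") {
    stats::qnorm(1 - (1 - level) / 2)
  } else {
    if (is.null(df)) te_abort("t-based interval needs df", "te_validation_error")
    stats::qt(1 - (1 - level) / 2, df)
  }
  tibble::tibble(low = 2^(estimate - z * se), high = 2^(estimate + z * se))
}
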