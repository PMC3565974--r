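# Cohort statistics: group comparisons and the MRI -> mechanics regressions.

#' One-way ANOVA across groups
#'
#' Classical between/within decomposition via [stats::lm()]/[stats::anova()].
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 observations each.
#' @return list with `f`, `p`, `df` (c(between, within)).
#' @examples
#' one_way_anova(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  keep <- is.finite(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  if (stats::var(values) == 0)
    return(list(f = 0, p = 1,
                df = c(nlevels(groups) - 1, length(values) - nlevels(groups))))
  a <- stats::anova(stats::lm(values ~ groups))
  list(f = a$`F value`[1], p = a$`Pr(>F)`[1], df = a$Df)
}

#' Pairwise comparisons with the Dunn-Sidak adjustment
#'
#' Pooled-variance two-sample t tests for every group pair, adjusted as
#' \eqn{p' = 1 - (1 - p)^m} over the m = k(k-1)/2 comparisons.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level carried through to the `significant`
#'   column.
#' @return data.frame with group1, group2, p_raw, p_adjusted, significant.
#' @export
dunn_sidak_pairwise <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  keep <- is.finite(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  lv <- levels(groups)
  n <- table(groups)
  # pooled within-group variance (the ANOVA error mean square)
  ss_w <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df_w <- length(values) - k
  s2 <- ss_w / df_w
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    p_raw = NA_real_, p_adjusted = NA_real_)
  for (j in seq_len(m)) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt(s2 * (1 / n[[g1]] + 1 / n[[g2]]))
    tstat <- (mean(values[groups == g1]) - mean(values[groups == g2])) / se
    p <- 2 * stats::pt(-abs(tstat), df_w)
    out$p_raw[j] <- p
    out$p_adjusted[j] <- min(max(1 - (1 - p)^m, 0), 1)
  }
  out$significant <- out$p_adjusted <= alpha
  out
}

#' Multiple linear regression of a mechanical property on the MRI parameters
#'
#' Ordinary least squares `MP = a0 + a1 T1 + a2 T2 + a3 MTR + a4 ADC + a5 FA`
#' with the coefficient of determination, the standard error of estimate
#' SEE = sqrt(SSE / (n - p - 1)), the power of the overall F test at alpha =
#' 0.05 ([regression_power()]) and per-predictor variance inflation factors.
#'
#' @param cohort data.frame containing `response` and the predictor columns.
#' @param response Name of the response column (e.g. `"E"`).
#' @param predictors Character vector of predictor columns.
#' @param alpha Significance level for the power computation.
#' @param ncp_convention Noncentrality convention, see [regression_power()].
#' @return An object of class `regression_result`: list with `coefficients`
#'   (a0..a5), `r2`, `see`, `power`, `vif`, `n`, `response`, `predictors`.
#' @export
fit_multilinear <- function(cohort, response,
                            predictors = c("T1", "T2", "MTR", "ADC", "FA"),
                            alpha = 0.05, ncp_convention = c("n", "residual")) {
  ncp_convention <- match.arg(ncp_convention)
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  d <- cohort[stats::complete.cases(cohort[cols]), cols]
  n <- nrow(d); p <- length(predictors)
  if (n <= p + 1) stop("need more than p + 1 complete rows")
  X <- as.matrix(d[predictors])
  if (qr(cbind(1, X))$rank < p + 1)
    stop("rank-deficient design: predictors are collinear")
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((d[[response]] - mean(d[[response]]))^2)
  r2 <- if (sst == 0) 0 else 1 - sse / sst
  see <- sqrt(sse / (n - p - 1))
  structure(list(
    coefficients = stats::setNames(stats::coef(fit), c("a0", paste0("a", seq_len(p)))),
    r2 = r2, see = see,
    power = regression_power(r2, n, p, alpha, ncp_convention),
    vif = if (p >= 2) compute_vif(X) else NULL,
    n = n, response = response, predictors = predictors,
    ncp_convention = ncp_convention
  ), class = "regression_result")
}

#' Power of the overall regression F test
#'
#' Power of rejecting `a1 = ... = ap = 0` at level alpha via the noncentral
#' F distribution with (p, n - p - 1) degrees of freedom and noncentrality
#' `lambda = n * r2 / (1 - r2)` (convention `"n"`, the default) or
#' `lambda = (n - p - 1) * r2 / (1 - r2)` (convention `"residual"`).
#'
#' @param r2 Observed coefficient of determination in \[0, 1).
#' @param n Sample size.
#' @param n_predictors Number of predictors p.
#' @param alpha Test level.
#' @param ncp_convention `"n"` or `"residual"`.
#' @return Power in \[alpha, 1\]. `r2 = 1` returns 1 (flagged by warning).
#' @examples
#' regression_power(0.70, 15, 5)
#' @export
regression_power <- function(r2, n, n_predictors, alpha = 0.05,
                             ncp_convention = c("n", "residual")) {
  ncp_convention <- match.arg(ncp_convention)
  if (r2 < 0 || r2 > 1) stop("r2 must lie in [0, 1]")
  p <- n_predictors
  if (n <= p + 1) stop("need n > n_predictors + 1")
  if (r2 == 1) {
    warning("r2 = 1: power is 1 by convention")
    return(1)
  }
  mult <- if (ncp_convention == "n") n else n - p - 1
  lambda <- mult * r2 / (1 - r2)
  fcrit <- stats::qf(1 - alpha, p, n - p - 1)
  1 - stats::pf(fcrit, p, n - p - 1, ncp = lambda)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R_j^2)`, with `R_j^2` from regressing predictor j on
#' the remaining predictors (with intercept). Perfect collinearity yields
#' `Inf` with a warning.
#'
#' @param X Numeric matrix or data.frame of predictors (>= 2 columns, more
#'   rows than columns).
#' @return Named numeric vector of VIFs.
#' @examples
#' compute_vif(cbind(a = rnorm(20), b = rnorm(20)))
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stop("need at least 2 predictors")
  if (nrow(X) <= p) stop("need more observations than predictors")
  vif <- stats::setNames(numeric(p), colnames(X))
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    sse <- sum(fit$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    r2j <- if (sst == 0) 1 else 1 - sse / sst
    vif[j] <- if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
  }
  if (any(is.infinite(vif)))
    warning("perfect collinearity: infinite VIF for ",
            paste(names(vif)[is.infinite(vif)], collapse = ", "))
  vif
}

#' Backward elimination of high-VIF predictors
#'
#' Repeatedly removes the predictor with the highest VIF while the maximum
#' VIF exceeds `threshold`, refitting the regression at each step and
#' recording the change in R-squared.
#'
#' @inheritParams fit_multilinear
#' @param threshold VIF threshold (default 10); `Inf` disables elimination.
#' @return list with `result` (final `regression_result`), `trace`
#'   (data.frame: step, removed, max_vif, r2, delta_r2).
#' @export
vif_eliminate <- function(cohort, response,
                          predictors = c("T1", "T2", "MTR", "ADC", "FA"),
                          threshold = 10, alpha = 0.05) {
  preds <- predictors
  res <- fit_multilinear(cohort, response, preds, alpha)
  trace <- data.frame(step = 0L, removed = NA_character_,
                      max_vif = max(res$vif), r2 = res$r2, delta_r2 = 0)
  step <- 0L
  while (length(preds) > 2 && max(res$vif) > threshold) {
    step <- step + 1L
    worst <- names(res$vif)[which.max(res$vif)]
    preds <- setdiff(preds, worst)
    new_res <- fit_multilinear(cohort, response, preds, alpha)
    trace <- rbind(trace, data.frame(
      step = step, removed = worst,
      max_vif = if (length(preds) >= 2) max(new_res$vif) else NA_real_,
      r2 = new_res$r2, delta_r2 = new_res$r2 - res$r2))
    res <- new_res
  }
  list(result = res, trace = trace)
}
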