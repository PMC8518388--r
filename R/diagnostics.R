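# Model evaluation: classification metrics, ROC AUC, and covariate-pattern
# goodness of fit and influence diagnostics.

# Rank-based AUC (probability a random case outranks a random control, ties
# counted half) with the Hanley-McNeil standard error.
.auc_hanley_mcneil <- function(y, p, conf_level = 0.95) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both outcome classes", call. = FALSE)
  r <- rank(p)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = auc, se = se,
       ci = pmin(pmax(auc + c(-1, 1) * z * se, 0), 1))
}

#' Covariate-pattern diagnostics for a logistic fit
#'
#' Evaluates the model the way epidemiological logistic regressions are
#' audited: sensitivity, specificity and percent correctly classified at a
#' fitted-probability cut-off; ROC area by rank concordance with a
#' Hanley-McNeil confidence interval; and, aggregated over covariate
#' patterns (unique predictor combinations), the Pearson goodness-of-fit
#' chi-square with per-pattern Pearson residuals, leverages from the
#' weighted hat matrix, and standardised delta-betas (the scaled change in
#' the coefficient vector on deleting the pattern).
#'
#' @param fit A [fit_logistic()] result.
#' @param cutoff Classification cut-off on the fitted probability
#'   (default 0.5).
#' @param conf_level Confidence level for the AUC interval.
#' @return An object of class `diagnostics_block`: classification metrics,
#'   `auc`, `auc_ci`, `gof_chisq`/`gof_df`/`gof_p` (NA when there are no
#'   more patterns than parameters), and a `patterns` tibble with `m`
#'   (pattern size), `y` (observed events), `p_hat`, `pearson_residual`,
#'   `leverage` and `delta_beta`.
#' @export
diagnostics <- function(fit, cutoff = 0.5, conf_level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  model <- fit$model
  y <- model$y
  p <- stats::fitted(model)
  pred <- as.integer(p >= cutoff)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  pct <- (tp + tn) / length(y)
  roc <- .auc_hanley_mcneil(y, p, conf_level)

  X <- stats::model.matrix(model)
  key <- apply(X, 1, paste, collapse = "\r")
  # patterns keyed by sorted design rows, so results are invariant to the
  # row order of the input cohort
  grp <- factor(key, levels = sort(unique(key)))
  m <- as.vector(table(grp))
  yj <- as.vector(tapply(y, grp, sum))
  pj <- as.vector(tapply(p, grp, mean))
  Xj <- X[match(levels(grp), key), , drop = FALSE]
  vj <- m * pj * (1 - pj)
  rj <- (yj - m * pj) / sqrt(vj)
  XtVX_inv <- solve(t(Xj) %*% (Xj * vj))
  hj <- unname(vj * rowSums((Xj %*% XtVX_inv) * Xj))
  delta_beta <- rj^2 * hj / (1 - hj)^2
  k <- ncol(X)
  J <- length(m)
  if (J > k) {
    gof_chisq <- sum(rj^2)
    gof_df <- J - k
    gof_p <- stats::pchisq(gof_chisq, gof_df, lower.tail = FALSE)
  } else {
    gof_chisq <- NA_real_; gof_df <- NA_integer_; gof_p <- NA_real_
  }
  patterns <- tibble::tibble(
    pattern = seq_len(J), m = m, y = yj, p_hat = pj,
    pearson_residual = rj, leverage = hj, delta_beta = delta_beta)
  structure(list(
    sensitivity = sens, specificity = spec, percent_correct = pct,
    cutoff = cutoff, confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    auc = roc$auc, auc_se = roc$se, auc_ci = roc$ci,
    gof_chisq = gof_chisq, gof_df = gof_df, gof_p = gof_p,
    n_patterns = J, n = length(y), patterns = patterns
  ), class = "diagnostics_block")
}

#' @export
print.diagnostics_block <- function(x, ...) {
  cat(sprintf("Classification at cut-off %.2f: sensitivity %.0f%%, specificity %.0f%%, %.0f%% correct\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$percent_correct))
  cat(sprintf("ROC AUC %.0f%% (CI %.0f%%-%.0f%%)\n", 100 * x$auc,
              100 * x$auc_ci[1], 100 * x$auc_ci[2]))
  if (!is.na(x$gof_chisq)) {
    cat(sprintf("Pearson GOF chi-square %.2f on %d covariate-pattern df, p = %.2g\n",
                x$gof_chisq, x$gof_df, x$gof_p))
  } else {
    cat("Pearson GOF not computable (no more patterns than parameters)\n")
  }
  invisible(x)
}
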