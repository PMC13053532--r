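#' Multivariable logistic model with odds ratios
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()], convergence tolerance `1e-8`). Continuous
#' predictors are standardized per 1 SD by default, so each odds ratio is
#' per-SD; factor/logical predictors are coded by `model.matrix` against
#' their reference level. Reported per predictor: the odds ratio, Wald 95%
#' CI on the log-odds scale, and Wald p-value. Reported for the model: the
#' likelihood-ratio chi-square against the intercept-only model with its
#' degrees of freedom and p-value, and the in-sample AUC of the fitted
#' probabilities. Quasi-complete separation (diverging coefficients or
#' non-convergence) is flagged rather than silently reported.
#'
#' @param predictors data frame of predictors (numeric, logical or factor
#'   columns).
#' @param labels logical (or 0/1) outcome.
#' @param standardize standardize continuous predictors per 1 SD.
#' @param conf_level Wald CI level.
#' @return An object of class `logistic_result`: `coefficients` data frame
#'   (term, estimate, odds_ratio, ci_low, ci_high, p_value), `lr_chi2`,
#'   `df`, `lr_p`, `in_sample_auc`, `separation`, `converged`, `coding`
#'   notes.
#' @export
logistic_model <- function(predictors, labels, standardize = TRUE,
                           conf_level = 0.95) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("missing labels", call. = FALSE)
  predictors <- as.data.frame(predictors)
  n <- length(labels)
  if (nrow(predictors) > 0 && nrow(predictors) != n)
    stop("'predictors' and 'labels' sizes disagree", call. = FALSE)

  coding <- character(0)
  for (nm in names(predictors)) {
    col <- predictors[[nm]]
    if (is.character(col)) col <- factor(col)
    if (is.factor(col)) {
      coding <- c(coding, sprintf("%s: reference level '%s'", nm, levels(col)[1]))
      predictors[[nm]] <- col
    } else if (is.logical(col)) {
      coding <- c(coding, sprintf("%s: FALSE = reference", nm))
    } else if (standardize) {
      s <- stats::sd(col)
      if (is.na(s) || s == 0)
        stop("predictor '", nm, "' is constant", call. = FALSE)
      predictors[[nm]] <- (col - mean(col)) / s
      coding <- c(coding, sprintf("%s: standardized per 1 SD (%.4g)", nm, s))
    }
  }

  dat <- cbind(predictors, .y = labels)
  form <- if (ncol(predictors) == 0) .y ~ 1 else
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`", names(predictors)),
                                          collapse = " + ")))
  mm <- stats::model.matrix(stats::delete.response(stats::terms(form)), dat)
  if (n <= ncol(mm))
    stop("need more observations than coefficients", call. = FALSE)
  if (qr(mm)$rank < ncol(mm))
    stop("design matrix is rank deficient after coding", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))

  sm <- summary(fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms_keep <- rownames(sm) != "(Intercept)"
  est <- sm[terms_keep, 1]; se <- sm[terms_keep, 2]; pv <- sm[terms_keep, 4]
  coefs <- data.frame(term = rownames(sm)[terms_keep],
                      estimate = unname(est),
                      odds_ratio = exp(unname(est)),
                      ci_low = exp(unname(est - zq * se)),
                      ci_high = exp(unname(est + zq * se)),
                      p_value = unname(pv),
                      stringsAsFactors = FALSE, row.names = NULL)

  null_fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = dat)
  lr_chi2 <- as.numeric(null_fit$deviance - fit$deviance)
  df <- null_fit$df.residual - fit$df.residual
  lr_p <- if (df > 0) stats::pchisq(lr_chi2, df, lower.tail = FALSE) else NA_real_
  probs <- stats::fitted(fit)
  in_auc <- if (df > 0) roc_with_youden(probs, labels)$auc else 0.5
  separation <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15)

  structure(list(coefficients = coefs, lr_chi2 = lr_chi2, df = df,
                 lr_p = lr_p, in_sample_auc = in_auc,
                 separation = separation, converged = fit$converged,
                 coding = coding, n = n, fit = fit),
            class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("<logistic_result> n = %d, LR chi2(%d) = %.3f, p = %.4g, in-sample AUC = %.3f%s\n",
              x$n, x$df, x$lr_chi2, x$lr_p, x$in_sample_auc,
              if (x$separation) "  [separation flagged]" else ""))
  if (nrow(x$coefficients)) {
    df <- x$coefficients
    cat(sprintf("  %-28s OR %8.3f  [%.3f, %.3f]  p = %.4g\n",
                df$term, df$odds_ratio, df$ci_low, df$ci_high, df$p_value),
        sep = "")
  }
  invisible(x)
}
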