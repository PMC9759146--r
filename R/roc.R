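#' Single-predictor binary logistic regression
#'
#' Maximum-likelihood logistic model of a binary outcome (e.g. membership of
#' the cognitively impaired group) on one predictor, with Wald 95% CI and
#' p-value for the slope. Under complete separation the ML estimate
#' diverges; a small ridge penalty is then applied via penalized IRLS and a
#' warning is issued (the Wald p is reported as `NA` in that case).
#'
#' @param predictor Numeric vector.
#' @param labels Binary outcome: logical, 0/1, or a two-level factor (the
#'   second level is the positive class).
#' @param ridge Penalty used by the separation fallback (default 1e-2).
#' @return An object of class `meg_logistic` with fields `coef`,
#'   `intercept`, `ci95`, `p`, `separated`, `n`; see [tidy.meg_logistic()].
#' @export
logistic_fit <- function(predictor, labels, ridge = 1e-2) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) abort("Both outcome classes must be present")
  if (length(y) != length(predictor)) abort("predictor and labels must be paired")
  if (length(y) < 10) abort("Need at least 10 observations")
  fit <- suppressWarnings(glm(y ~ predictor, family = stats::binomial()))
  eta <- abs(predict(fit))
  separated <- any(eta > 15) && fit$deviance < 1e-6
  if (!separated) {
    sm <- summary(fit)$coefficients
    est <- sm["predictor", "Estimate"]
    se <- sm["predictor", "Std. Error"]
    out <- list(
      coef = est, intercept = sm["(Intercept)", "Estimate"],
      ci95 = est + c(-1, 1) * 1.96 * se,
      p = sm["predictor", "Pr(>|z|)"], separated = FALSE, n = length(y)
    )
  } else {
    warn("Complete separation detected; returning ridge-penalized estimates (Wald p unavailable)")
    beta <- ridge_logistic_irls(cbind(1, predictor), y, ridge)
    out <- list(
      coef = beta[2], intercept = beta[1], ci95 = c(NA_real_, NA_real_),
      p = NA_real_, separated = TRUE, n = length(y)
    )
  }
  structure(out, class = "meg_logistic")
}

# Minimal ridge-penalized IRLS for the separation fallback (intercept
# unpenalized).
ridge_logistic_irls <- function(X, y, lambda, max_iter = 100, tol = 1e-8) {
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1)))
  for (i in seq_len(max_iter)) {
    mu <- plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    score <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' @export
print.meg_logistic <- function(x, ...) {
  cat(sprintf(
    "<meg_logistic> coef %.4g (95%% CI %.4g..%.4g), intercept %.4g, p %.4g%s\n",
    x$coef, x$ci95[1], x$ci95[2], x$intercept, x$p,
    if (x$separated) " [ridge fallback: separation]" else ""
  ))
  invisible(x)
}

#' @describeIn logistic_fit Tidy the model coefficients into a tibble.
#' @param x A `meg_logistic`.
#' @param ... Unused.
#' @export
tidy.meg_logistic <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "predictor"),
    estimate = c(x$intercept, x$coef),
    conf.low = c(NA_real_, x$ci95[1]),
    conf.high = c(NA_real_, x$ci95[2]),
    p.value = c(NA_real_, x$p)
  )
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    as.integer(labels == levels(labels)[2])
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else {
    v <- as.numeric(labels)
    if (!all(v %in% c(0, 1))) abort("Numeric labels must be 0/1")
    as.integer(v)
  }
}

#' ROC analysis of a diagnostic predictor
#'
#' AUC via the Mann-Whitney pair-counting identity (probability a random
#' positive outranks a random negative, ties counting one half), oriented so
#' AUC >= 0.5. Sensitivity, specificity and accuracy (in percent) are
#' reported at the Youden-optimal cutoff (maximizing sensitivity +
#' specificity - 1); the cutoff is the midpoint between adjacent observed
#' values.
#'
#' @param predictor Numeric scores.
#' @param labels Binary outcome (positive = second factor level / 1 / TRUE).
#' @param name Optional predictor name carried into the output.
#' @return An object of class `meg_roc`: `name`, `auc`, `sensitivity`,
#'   `specificity`, `accuracy` (percent), `cutoff`, `direction` (`">"` when
#'   high scores indicate the positive class), and `curve`, a tibble of ROC
#'   points.
#' @examples
#' roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc # 0.75
#' @export
roc_analysis <- function(predictor, labels, name = "predictor") {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) abort("Both outcome classes must be present")
  pos <- predictor[y == 1]
  neg <- predictor[y == 0]
  auc_raw <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  direction <- if (auc_raw >= 0.5) ">" else "<"
  score <- if (direction == ">") predictor else -predictor
  auc <- max(auc_raw, 1 - auc_raw)
  v <- sort(unique(score))
  cuts <- c(-Inf, if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2, Inf)
  curve <- purrr::map_dfr(cuts, function(ct) {
    pred_pos <- score > ct
    tibble::tibble(
      cutoff = ct,
      sensitivity = mean(pred_pos[y == 1]),
      specificity = mean(!pred_pos[y == 0])
    )
  })
  j <- curve$sensitivity + curve$specificity - 1
  best <- which.max(j)
  cut_star <- curve$cutoff[best]
  acc <- mean((score > cut_star) == (y == 1))
  structure(
    list(
      name = name, auc = auc,
      sensitivity = 100 * curve$sensitivity[best],
      specificity = 100 * curve$specificity[best],
      accuracy = 100 * acc,
      cutoff = if (direction == ">") cut_star else -cut_star,
      direction = direction,
      curve = curve
    ),
    class = "meg_roc"
  )
}

#' @export
print.meg_roc <- function(x, ...) {
  cat(sprintf(
    "<meg_roc> %s: AUC %.3f, sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%% at cutoff %.4g (%s)\n",
    x$name, x$auc, x$sensitivity, x$specificity, x$accuracy, x$cutoff, x$direction
  ))
  invisible(x)
}

#' @describeIn roc_analysis One-row tibble of the headline ROC metrics.
#' @param x A `meg_roc`.
#' @param ... Unused.
#' @export
glance.meg_roc <- function(x, ...) {
  tibble::tibble(
    indicator = x$name, auc = x$auc, sensitivity = x$sensitivity,
    specificity = x$specificity, accuracy = x$accuracy, cutoff = x$cutoff
  )
}

#' @describeIn roc_analysis The ROC curve points as a tibble.
#' @export
tidy.meg_roc <- function(x, ...) x$curve
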