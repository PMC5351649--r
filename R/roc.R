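#' Empirical ROC curve with AUC and confidence interval
#'
#' Builds the empirical ROC of the rule "value > threshold => case" over all
#' distinct observed values. The trapezoidal AUC equals the Mann-Whitney
#' pair-counting probability (concordant pairs plus half ties over
#' `n_case * n_control`). The 95% CI uses the Hanley-McNeil variance by
#' default; DeLong's placement-value variance is available as an option.
#'
#' @param values Numeric marker values (higher assumed more case-like; an
#'   AUC below 0.5 simply reports an inversely oriented marker).
#' @param labels `case`/`control` label per value.
#' @param positive Label treated as the positive class.
#' @param ci_method `"hanley"` (default) or `"delong"`.
#' @param conf_level Confidence level for the AUC interval.
#' @return Object of class `roc_result`: `thresholds` (increasing; first is
#'   `-Inf`), `sensitivity`, `specificity`, `auc`, `ci_low`, `ci_high`,
#'   `n_case`, `n_control`, `values` (sorted distinct marker values).
#' @export
roc_curve <- function(values, labels, positive = "case",
                      ci_method = c("hanley", "delong"),
                      conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.character(labels)[keep]
  check_both_groups(labels, positive)

  cases <- values[labels == positive]
  controls <- values[labels != positive]
  n1 <- length(cases)
  n0 <- length(controls)

  v <- sort(unique(values))
  thresholds <- c(-Inf, v)
  sens <- vapply(thresholds, function(t) mean(cases > t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(controls <= t), numeric(1))

  # trapezoid over the staircase; ties produce diagonal segments (half credit)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (head(sens[ord], -1) + tail(sens[ord], -1)) / 2)
  auc <- abs(auc)

  se <- switch(ci_method,
    hanley = auc_se_hanley(auc, n1, n0),
    delong = auc_se_delong(cases, controls)
  )
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      thresholds = thresholds,
      sensitivity = sens,
      specificity = spec,
      auc = auc,
      ci_low = max(0, auc - z * se),
      ci_high = min(1, auc + z * se),
      se = se,
      ci_method = ci_method,
      n_case = n1,
      n_control = n0,
      values = v
    ),
    class = "roc_result"
  )
}

auc_se_hanley <- function(auc, n1, n0) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
    (n1 * n0)
  sqrt(max(0, v))
}

auc_se_delong <- function(cases, controls) {
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(cases, function(x) mean(psi(x, controls)), numeric(1))
  v01 <- vapply(controls, function(y) mean(psi(cases, y)), numeric(1))
  sqrt(var(v10) / length(cases) + var(v01) / length(controls))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f (95%% CI %.3f-%.3f, %s), %d cases vs %d controls\n",
    x$auc, x$ci_low, x$ci_high, x$ci_method, x$n_case, x$n_control
  ))
  invisible(x)
}

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(
    threshold = x$thresholds,
    sensitivity = x$sensitivity,
    specificity = x$specificity
  )
}

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
    n_case = x$n_case, n_control = x$n_control, ci_method = x$ci_method
  )
}

#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tidy(object)
  df <- df[order(1 - df$specificity, df$sensitivity), ]
  ggplot2::ggplot(df, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf(
        "AUC = %.2f (95%% CI %.2f-%.2f)",
        object$auc, object$ci_low, object$ci_high
      )
    )
}

#' Optimal threshold by Youden's J
#'
#' Scans every threshold of an empirical ROC for the maximum of
#' `J = sensitivity + specificity - 1`. Ties are broken toward higher
#' specificity, then toward the lower threshold. The returned cutoff is the
#' midpoint between the selected threshold value and the next distinct
#' observed value (any cutoff in that open interval classifies identically).
#'
#' @param roc A [roc_curve()] result.
#' @return List of class `youden_cutoff`: `cutoff`, `j`, `sensitivity`,
#'   `specificity`, `degenerate` (TRUE when J = 0 everywhere, e.g. all
#'   values identical).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  best_j <- max(j)
  cand <- which(j >= best_j - 1e-12)
  if (length(cand) > 1) {
    cand <- cand[roc$specificity[cand] >= max(roc$specificity[cand]) - 1e-12]
  }
  i <- cand[1] # thresholds increase, so first candidate = lowest cutoff
  thr <- roc$thresholds[i]
  v <- roc$values
  cutoff <- if (is.infinite(thr)) {
    v[1] - 1 # everything scores positive; place cutoff below the data
  } else {
    k <- match(thr, v)
    if (k < length(v)) (v[k] + v[k + 1]) / 2 else v[k]
  }
  structure(
    list(
      cutoff = cutoff,
      j = best_j,
      sensitivity = roc$sensitivity[i],
      specificity = roc$specificity[i],
      degenerate = best_j <= 1e-12
    ),
    class = "youden_cutoff"
  )
}

#' @export
print.youden_cutoff <- function(x, ...) {
  cat(sprintf(
    "Youden cutoff %.4g (J = %.3f; sens %.2f, spec %.2f)%s\n",
    x$cutoff, x$j, x$sensitivity, x$specificity,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}
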