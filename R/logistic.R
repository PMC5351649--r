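#' Univariate logistic regression for risk-score weights
#'
#' Maximum-likelihood fit of `logit P(case) = b0 + b1 * value` by
#' Newton-Raphson with step-halving, converging when the log-likelihood
#' changes by less than `tol` (default 1e-10) within `max_iter` iterations.
#' The slope `b1` is the panel weight W for the marker. Under complete
#' separation the MLE diverges; the slope is then capped at `cap` in
#' absolute value (with a warning) and the intercept re-maximized at the
#' capped slope.
#'
#' @param values Numeric predictor (a concentration, or a 0/1 dichotomized
#'   score).
#' @param labels `case`/`control` per value.
#' @param positive Label coded as 1.
#' @param cap Bound on `|b1|` applied under separation.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `uni_logistic`: `intercept`, `weight` (the
#'   slope), `log_likelihood`, `converged`, `separated`, `iterations`, `n`.
#' @export
fit_univariate_logistic <- function(values, labels, positive = "case",
                                    cap = 10, tol = 1e-10, max_iter = 100) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.character(labels)[keep]
  check_both_groups(labels, positive)
  y <- as.integer(labels == positive)
  x <- as.numeric(values)
  n <- length(y)

  loglik <- function(beta) {
    eta <- beta[1] + beta[2] * x
    soft <- ifelse(eta > 30, eta, log1p(exp(eta))) # stable log(1 + e^eta)
    sum(y * eta - soft)
  }

  p_bar <- mean(y)
  beta <- c(log(p_bar / (1 - p_bar)), 0)
  ll <- loglik(beta)
  converged <- FALSE
  separated <- FALSE
  iter <- 0

  while (iter < max_iter) {
    iter <- iter + 1
    eta <- beta[1] + beta[2] * x
    p <- plogis(eta)
    w <- p * (1 - p)
    g <- c(sum(y - p), sum((y - p) * x))
    h11 <- sum(w)
    h12 <- sum(w * x)
    h22 <- sum(w * x^2)
    det <- h11 * h22 - h12^2
    if (!is.finite(det) || det < 1e-12 * max(1, h11 * h22)) {
      separated <- TRUE
      break
    }
    step <- c(h22 * g[1] - h12 * g[2], h11 * g[2] - h12 * g[1]) / det
    # step-halve until the likelihood does not decrease
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) {
        cand <- beta
        ll_new <- ll
        break
      }
    }
    delta <- ll_new - ll
    beta <- cand
    ll <- ll_new
    if (abs(beta[2]) > cap) {
      separated <- TRUE
      break
    }
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }

  if (separated) {
    warn(paste0(
      "fit_univariate_logistic: (near-)complete separation; slope capped at |",
      cap, "|"
    ))
    beta[2] <- sign(beta[2]) * cap
    beta[1] <- profile_intercept(y, x, beta[2])
    ll <- loglik(beta)
    converged <- TRUE
  }
  if (!converged) {
    abort(paste0(
      "fit_univariate_logistic did not converge in ", max_iter, " iterations"
    ))
  }

  structure(
    list(
      intercept = beta[1], weight = beta[2], log_likelihood = ll,
      converged = converged, separated = separated, iterations = iter, n = n
    ),
    class = "uni_logistic"
  )
}

# 1-D Newton for the intercept at a fixed slope
profile_intercept <- function(y, x, b1) {
  b0 <- 0
  for (i in 1:100) {
    p <- plogis(b0 + b1 * x)
    g <- sum(y - p)
    h <- sum(p * (1 - p))
    if (h < 1e-12) break
    step <- g / h
    b0 <- b0 + step
    if (abs(step) < 1e-12) break
  }
  b0
}

#' @export
print.uni_logistic <- function(x, ...) {
  cat(sprintf(
    "Univariate logistic: weight = %.4f, intercept = %.4f, logLik = %.4f (n = %d%s)\n",
    x$weight, x$intercept, x$log_likelihood, x$n,
    if (x$separated) ", separated" else ""
  ))
  invisible(x)
}

#' @method tidy uni_logistic
#' @export
tidy.uni_logistic <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "value"),
    estimate = c(x$intercept, x$weight)
  )
}

#' @method glance uni_logistic
#' @export
glance.uni_logistic <- function(x, ...) {
  tibble::tibble(
    weight = x$weight, intercept = x$intercept,
    log_likelihood = x$log_likelihood, separated = x$separated,
    iterations = x$iterations, n = x$n
  )
}
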