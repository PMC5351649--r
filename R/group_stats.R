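#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling. The U statistic reported is the
#' number of (a, b) pairs with `a > b`, counting ties as 1/2, for the first
#' argument. For `n_a + n_b <= 12` the two-sided p-value is computed by
#' exhaustive enumeration of all group assignments (valid with ties); above
#' that, a normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param values_a,values_b Numeric vectors, both nonempty.
#' @param exact_max Total sample size up to which the exact enumeration is
#'   used.
#' @return List of class `mw_test`: `u`, `p_value`, `n_a`, `n_b`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(values_a, values_b, exact_max = 12) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (n_a == 0 || n_b == 0) {
    abort("both groups must be nonempty")
  }
  pooled <- c(values_a, values_b)
  u_obs <- u_statistic(values_a, values_b)
  mu <- n_a * n_b / 2

  if (n_a + n_b <= exact_max) {
    n <- n_a + n_b
    idx <- combn(n, n_a)
    dev_obs <- abs(u_obs - mu) - 1e-9
    count <- sum(apply(idx, 2, function(i) {
      abs(u_statistic(pooled[i], pooled[-i]) - mu) >= dev_obs
    }))
    p <- count / ncol(idx)
    method <- "exact"
  } else {
    n <- n_a + n_b
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu - 0.5 * sign(u_obs - mu)) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  structure(
    list(u = u_obs, p_value = p, n_a = n_a, n_b = n_b, method = method),
    class = "mw_test"
  )
}

# pairs (a, b) with a > b, ties 1/2 -- equals R_a - n_a(n_a+1)/2 on midranks
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney: U = %.1f (n = %d vs %d), two-sided p = %.4g [%s]\n",
    x$u, x$n_a, x$n_b, x$p_value, x$method
  ))
  invisible(x)
}

#' @method tidy mw_test
#' @export
tidy.mw_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$u, p_value = x$p_value,
    n_a = x$n_a, n_b = x$n_b, method = x$method
  )
}

#' Paired t-test
#'
#' Classical paired t on within-subject differences with `n - 1` degrees of
#' freedom (used for arterial vs peripheral plasma pairs). A zero-variance
#' difference vector is flagged degenerate rather than producing an
#' undefined statistic.
#'
#' @param values_a,values_b Equal-length numeric vectors paired by subject.
#' @return List of class `paired_t_test`: `t`, `df`, `p_value`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    abort("paired samples must have equal length")
  }
  keep <- !is.na(values_a) & !is.na(values_b)
  d <- values_a[keep] - values_b[keep]
  n <- length(d)
  if (n < 2) {
    abort("need at least 2 complete pairs")
  }
  if (var(d) == 0) {
    warn("paired_t: zero variance of differences; test is degenerate")
    return(structure(
      list(
        t = NA_real_, df = n - 1, p_value = NA_real_,
        mean_diff = mean(d), degenerate = TRUE, n = n
      ),
      class = "paired_t_test"
    ))
  }
  tt <- stats::t.test(values_a[keep], values_b[keep], paired = TRUE)
  structure(
    list(
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, mean_diff = mean(d), degenerate = FALSE, n = n
    ),
    class = "paired_t_test"
  )
}

#' @export
print.paired_t_test <- function(x, ...) {
  if (x$degenerate) {
    cat("Paired t-test: degenerate (zero difference variance), n =", x$n, "\n")
  } else {
    cat(sprintf(
      "Paired t-test: t = %.3f (df = %d), two-sided p = %.4g, mean diff = %.4g\n",
      x$t, x$df, x$p_value, x$mean_diff
    ))
  }
  invisible(x)
}

#' @method tidy paired_t_test
#' @export
tidy.paired_t_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$t, df = x$df, p_value = x$p_value,
    mean_diff = x$mean_diff, degenerate = x$degenerate, n = x$n
  )
}

#' Fold change between group means
#'
#' `FC = mean(case) / mean(control)` by default. When per-cohort means and
#' sizes are supplied (vectors of matching length), the groups are pooled
#' first with sample-size weights, exactly as combining the raw samples
#' would. Set `direction = "control_over_case"` for tables reported with the
#' inverse convention.
#'
#' @param mean_case,mean_control Group means (scalars, or per-cohort
#'   vectors to pool).
#' @param n_case,n_control Group sizes; required when pooling.
#' @param direction Which ratio to report.
#' @return A single fold-change value (unitless).
#' @examples
#' fold_change(592, 331) # 1.79 after rounding to 2 dp
#' fold_change(c(1338, 1103), c(632, 570),
#'   n_case = c(42, 66), n_control = c(32, 62)
#' ) # 2.02
#' @export
fold_change <- function(mean_case, mean_control, n_case = NULL,
                        n_control = NULL,
                        direction = c("case_over_control", "control_over_case")) {
  direction <- match.arg(direction)
  if (any(mean_case < 0) || any(mean_control < 0)) {
    abort("group means must be nonnegative")
  }
  pool <- function(m, n) {
    if (length(m) == 1) {
      return(m)
    }
    if (is.null(n) || length(n) != length(m) || any(n < 1)) {
      abort("pooling requires a group size (n >= 1) per cohort mean")
    }
    sum(n * m) / sum(n)
  }
  mc <- pool(mean_case, n_case)
  m0 <- pool(mean_control, n_control)
  num <- if (direction == "case_over_control") mc else m0
  den <- if (direction == "case_over_control") m0 else mc
  if (den == 0) {
    abort("denominator group mean is zero; fold change undefined")
  }
  num / den
}

#' Group comparison table for a cohort
#'
#' Per-miRNA group means, SDs, fold change and a two-sided p-value, shaped
#' like the per-stage columns of a validation summary table.
#'
#' @param data Concentration (or relative-expression) tibble: metadata
#'   columns plus one numeric column per miRNA.
#' @param mirnas miRNA columns to compare; defaults to all non-metadata
#'   columns.
#' @param group_col Column holding the `case`/`control` labels.
#' @param test `"mann_whitney"` for independent groups or `"paired_t"` for
#'   subject-paired designs (rows must then be aligned between groups).
#' @return Tibble with one row per miRNA: group sizes, means, SDs,
#'   `fold_change`, `p_value`, `test`.
#' @export
compare_groups <- function(data, mirnas = NULL, group_col = "group",
                           test = c("mann_whitney", "paired_t")) {
  test <- match.arg(test)
  check_group_column(data, group_col)
  mirnas <- measure_cols(data, mirnas)
  is_case <- data[[group_col]] == "case"
  purrr::map_dfr(mirnas, function(m) {
    a <- data[[m]][is_case]
    b <- data[[m]][!is_case]
    res <- if (test == "mann_whitney") {
      mann_whitney(a, b)
    } else {
      paired_t(a, b)
    }
    mc <- mean(a, na.rm = TRUE)
    m0 <- mean(b, na.rm = TRUE)
    tibble::tibble(
      mirna = m,
      n_case = sum(!is.na(a)),
      n_control = sum(!is.na(b)),
      mean_case = mc,
      sd_case = sd(a, na.rm = TRUE),
      mean_control = m0,
      sd_control = sd(b, na.rm = TRUE),
      fold_change = fold_change(mc, m0),
      p_value = res$p_value,
      test = test
    )
  })
}
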