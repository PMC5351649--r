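#' Build a dichotomized risk-score panel on a training cohort
#'
#' For each panel miRNA the training concentrations are scanned with an ROC
#' curve and the optimal cutoff is placed by Youden's J (ties toward higher
#' specificity, midpoint between adjacent distinct values). The per-subject
#' score `S` is 1 when the value exceeds the cutoff for an up-regulated
#' marker (is below it for a down-regulated one), else 0, and the panel
#' weight `W` is the slope of a univariate logistic regression of case
#' status on the score. The risk score function is `RSF_i = sum_j W_j *
#' S_ij`, and its own operating cutoff is placed by Youden's J on the
#' training RSF values and frozen for later cohorts.
#'
#' @param data Concentration tibble: `sample_id`, `group`, one numeric
#'   column per miRNA.
#' @param mirnas Panel miRNA columns; defaults to all non-metadata columns.
#' @param group_col Column holding `case`/`control` labels.
#' @param positive Label treated as diseased.
#' @param weight_on `"score"` (default) weights the dichotomized score, the
#'   quantity the RSF sums; `"value"` uses the continuous concentration.
#' @param cap Separation cap passed to [fit_univariate_logistic()].
#' @return Object of class `mirna_panel`: `components` tibble (`mirna`,
#'   `cutoff`, `direction`, `weight`, `auc`), `rsf_cutoff`, and `training`
#'   (a one-row tibble of training-set performance).
#' @export
build_panel <- function(data, mirnas = NULL, group_col = "group",
                        positive = "case",
                        weight_on = c("score", "value"), cap = 10) {
  weight_on <- match.arg(weight_on)
  check_group_column(data, group_col)
  mirnas <- measure_cols(data, mirnas)
  if (length(mirnas) == 0) {
    abort("no panel miRNAs to fit")
  }
  if (anyDuplicated(mirnas)) {
    abort("panel miRNAs must be unique")
  }
  labels <- as.character(data[[group_col]])
  check_both_groups(labels, positive)

  components <- purrr::map_dfr(mirnas, function(m) {
    v <- data[[m]]
    roc_raw <- roc_curve(v, labels, positive = positive)
    direction <- if (roc_raw$auc >= 0.5) "up" else "down"
    oriented <- if (direction == "up") v else -v
    cut_obj <- optimal_cutoff(roc_curve(oriented, labels, positive = positive))
    cutoff <- if (direction == "up") cut_obj$cutoff else -cut_obj$cutoff
    s <- dichotomize(v, cutoff, direction)
    predictor <- if (weight_on == "score") s else v
    w <- fit_univariate_logistic(predictor, labels,
      positive = positive, cap = cap
    )
    tibble::tibble(
      mirna = m, cutoff = cutoff, direction = direction,
      weight = w$weight, auc = roc_raw$auc
    )
  })

  panel <- structure(
    list(components = components, rsf_cutoff = NA_real_, training = NULL),
    class = "mirna_panel"
  )
  rsf <- score_subjects(data, panel)$rsf
  rsf_roc <- roc_curve(rsf, labels, positive = positive)
  rsf_cut <- optimal_cutoff(rsf_roc)
  panel$rsf_cutoff <- rsf_cut$cutoff
  panel$training <- tibble::tibble(
    auc = rsf_roc$auc, ci_low = rsf_roc$ci_low, ci_high = rsf_roc$ci_high,
    sensitivity = rsf_cut$sensitivity, specificity = rsf_cut$specificity,
    n_case = rsf_roc$n_case, n_control = rsf_roc$n_control
  )
  panel
}

dichotomize <- function(values, cutoff, direction) {
  if (direction == "up") {
    as.integer(values > cutoff)
  } else {
    as.integer(values < cutoff)
  }
}

#' @export
print.mirna_panel <- function(x, ...) {
  cat(
    "<mirna_panel> with", nrow(x$components), "miRNAs, RSF cutoff",
    format(x$rsf_cutoff, digits = 4), "\n"
  )
  print(x$components)
  if (!is.null(x$training)) {
    cat(sprintf(
      "training: AUC %.3f (%.3f-%.3f), sens %.2f / spec %.2f\n",
      x$training$auc, x$training$ci_low, x$training$ci_high,
      x$training$sensitivity, x$training$specificity
    ))
  }
  invisible(x)
}

#' @method tidy mirna_panel
#' @export
tidy.mirna_panel <- function(x, ...) x$components

#' @method glance mirna_panel
#' @export
glance.mirna_panel <- function(x, ...) {
  out <- tibble::tibble(
    n_mirnas = nrow(x$components), rsf_cutoff = x$rsf_cutoff
  )
  if (!is.null(x$training)) out <- dplyr::bind_cols(out, x$training)
  out
}

#' Risk score function values for a cohort
#'
#' Applies a built panel's stored cutoffs and weights to a new table:
#' `RSF_i = sum_j W_j * S_ij`, with `S_ij = 1` when subject i's value for
#' miRNA j lies beyond the cutoff in the stored direction. No cutoff or
#' weight is re-estimated.
#'
#' @param data Concentration tibble containing every panel miRNA column.
#' @param panel A [build_panel()] object.
#' @return The metadata columns of `data` plus `rsf` and `rsf_positive`
#'   (whether `rsf > rsf_cutoff`).
#' @export
score_subjects <- function(data, panel) {
  stopifnot(inherits(panel, "mirna_panel"))
  comp <- panel$components
  missing <- setdiff(comp$mirna, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "panel miRNA(s) missing from data: ", paste(missing, collapse = ", ")
    ))
  }
  scores <- purrr::pmap(
    list(comp$mirna, comp$cutoff, comp$direction, comp$weight),
    function(m, cutoff, direction, weight) {
      weight * dichotomize(data[[m]], cutoff, direction)
    }
  )
  rsf <- Reduce(`+`, scores)
  meta <- intersect(.meta_cols, names(data))
  out <- tibble::as_tibble(data[meta])
  out$rsf <- rsf
  out$rsf_positive <- rsf > panel$rsf_cutoff
  out
}

#' Evaluate a frozen panel on a new cohort
#'
#' Computes the ROC of the panel RSF on an evaluation cohort and the
#' sensitivity/specificity at the panel's stored `rsf_cutoff`. The panel is
#' used as-is: this is the fixed-cutoff transfer the validation stages
#' perform, so nothing is re-fit and the panel object is not modified.
#'
#' @inheritParams score_subjects
#' @param group_col,positive Group labelling, as in [build_panel()].
#' @return Object of class `panel_evaluation`: `roc` (a [roc_curve()]
#'   result), `auc`, `ci_low`, `ci_high`, `sensitivity`, `specificity`
#'   (at the frozen cutoff), `rsf_cutoff`, `n_case`, `n_control`.
#' @export
evaluate_fixed <- function(data, panel, group_col = "group",
                           positive = "case") {
  stopifnot(inherits(panel, "mirna_panel"))
  check_group_column(data, group_col)
  labels <- as.character(data[[group_col]])
  check_both_groups(labels, positive)
  scored <- score_subjects(data, panel)
  roc <- roc_curve(scored$rsf, labels, positive = positive)
  is_case <- labels == positive
  structure(
    list(
      roc = roc,
      auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
      sensitivity = mean(scored$rsf[is_case] > panel$rsf_cutoff),
      specificity = mean(scored$rsf[!is_case] <= panel$rsf_cutoff),
      rsf_cutoff = panel$rsf_cutoff,
      n_case = sum(is_case), n_control = sum(!is_case)
    ),
    class = "panel_evaluation"
  )
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf(
    "Panel evaluation: AUC %.3f (95%% CI %.3f-%.3f); sens %.2f / spec %.2f at RSF cutoff %.3f (%d vs %d)\n",
    x$auc, x$ci_low, x$ci_high, x$sensitivity, x$specificity,
    x$rsf_cutoff, x$n_case, x$n_control
  ))
  invisible(x)
}

#' @method glance panel_evaluation
#' @export
glance.panel_evaluation <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
    sensitivity = x$sensitivity, specificity = x$specificity,
    rsf_cutoff = x$rsf_cutoff, n_case = x$n_case, n_control = x$n_control
  )
}

#' @method autoplot panel_evaluation
#' @export
autoplot.panel_evaluation <- function(object, ...) {
  autoplot(object$roc) +
    ggplot2::geom_point(
      data = data.frame(x = 1 - object$specificity, y = object$sensitivity),
      ggplot2::aes(.data$x, .data$y),
      shape = 4, size = 3
    )
}

#' Association of a marker or risk score with clinical covariates
#'
#' For each covariate: a chi-squared test when the value is dichotomous
#' (0/1 score or RSF positivity), otherwise a one-way ANOVA F-test of the
#' value across covariate levels. Covariate levels with no observations are
#' dropped with a warning.
#'
#' @param data Tibble holding the value column and the covariates.
#' @param value Name of the value column (e.g. `"rsf"` or a miRNA).
#' @param covariates Character vector of categorical covariate columns
#'   (e.g. gender, age group, smoking, TNM stage).
#' @param method `"auto"` picks chi-squared for values with at most 2
#'   distinct levels, ANOVA otherwise; or force `"chisq"` / `"anova"`.
#' @return Tibble: `covariate`, `test`, `statistic`, `df`, `p_value`, `n`.
#' @export
association_tests <- function(data, value, covariates,
                              method = c("auto", "chisq", "anova")) {
  method <- match.arg(method)
  if (!value %in% names(data)) {
    abort(paste0("value column '", value, "' not present"))
  }
  v_all <- data[[value]]
  purrr::map_dfr(covariates, function(cv) {
    if (!cv %in% names(data)) {
      abort(paste0("covariate '", cv, "' not present"))
    }
    keep <- !is.na(v_all) & !is.na(data[[cv]])
    v <- v_all[keep]
    col <- data[[cv]]
    g <- if (is.factor(col)) col[keep] else factor(as.character(col)[keep])
    empty <- setdiff(levels(g), unique(as.character(g)))
    if (length(empty) > 0) {
      warn(paste0("dropping empty level(s) of ", cv, ": ", paste(empty, collapse = ", ")))
      g <- droplevels(g)
    }
    if (nlevels(g) < 2) {
      abort(paste0("covariate '", cv, "' needs at least 2 observed levels"))
    }
    use <- if (method == "auto") {
      if (length(unique(v)) <= 2) "chisq" else "anova"
    } else {
      method
    }
    if (use == "chisq") {
      tab <- table(factor(v), g)
      res <- suppressWarnings(chisq.test(tab))
      tibble::tibble(
        covariate = cv, test = "chisq",
        statistic = unname(res$statistic), df = unname(res$parameter),
        p_value = res$p.value, n = length(v)
      )
    } else {
      fit <- aov(v ~ g)
      s <- summary(fit)[[1]]
      tibble::tibble(
        covariate = cv, test = "anova",
        statistic = s[["F value"]][1], df = s[["Df"]][1],
        p_value = s[["Pr(>F)"]][1], n = length(v)
      )
    }
  })
}

#' Write / read a panel as JSON
#'
#' The serialization holds each component's `mirna`, `cutoff`, `direction`
#' and `weight`, plus the frozen `rsf_cutoff` — everything needed to apply
#' the panel to a new cohort.
#'
#' @param panel A [build_panel()] object.
#' @param path File path for the JSON document.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns the
#'   reconstructed `mirna_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "mirna_panel"))
  obj <- list(
    components = panel$components[c("mirna", "cutoff", "direction", "weight")],
    rsf_cutoff = panel$rsf_cutoff
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- tibble::as_tibble(obj$components)
  required <- c("mirna", "cutoff", "direction", "weight")
  if (!all(required %in% names(comp)) || nrow(comp) == 0) {
    abort("panel JSON must contain nonempty components with mirna/cutoff/direction/weight")
  }
  if (anyDuplicated(comp$mirna)) {
    abort("panel JSON has duplicate miRNAs")
  }
  if (!"auc" %in% names(comp)) comp$auc <- NA_real_
  structure(
    list(
      components = comp[c("mirna", "cutoff", "direction", "weight", "auc")],
      rsf_cutoff = obj$rsf_cutoff,
      training = NULL
    ),
    class = "mirna_panel"
  )
}
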