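make_cohort <- function(seed = 30, n1 = 40, n0 = 40, effects = c(a = 2, b = 3, c = 1)) {
  withr::with_seed(seed, {
    out <- tibble::tibble(
      sample_id = paste0("s", 1:(n1 + n0)),
      group = rep(c("case", "control"), c(n1, n0))
    )
    for (m in names(effects)) {
      out[[m]] <- exp(rnorm(n1 + n0, 0, 0.5)) *
        rep(c(effects[[m]], 1), c(n1, n0))
    }
    out
  })
}

test_that("panel recovers planted cutoffs inside the separating gaps", {
  # perfectly separated markers with known gaps
  data <- tibble::tibble(
    sample_id = paste0("s", 1:20),
    group = rep(c("case", "control"), each = 10),
    up = c(11:20, 1:10), # gap (10, 11)
    down = c(1:10, 21:30) # cases low: gap (10, 21)
  )
  panel <- suppressWarnings(build_panel(data))
  comp <- panel$components
  expect_equal(comp$direction, c("up", "down"))
  expect_gt(comp$cutoff[1], 10)
  expect_lt(comp$cutoff[1], 11)
  expect_gt(comp$cutoff[2], 10)
  expect_lt(comp$cutoff[2], 21)
  expect_equal(comp$auc, c(1, 0))
  # separated markers carry the capped weight
  expect_equal(comp$weight, c(10, 10))
})

test_that("single-miRNA panel ranks subjects like its dichotomized marker", {
  data <- make_cohort(31, effects = c(a = 2.5))
  panel <- build_panel(data, mirnas = "a")
  rsf <- score_subjects(data, panel)$rsf
  s <- as.integer(data$a > panel$components$cutoff)
  expect_equal(order(rsf), order(s))
  expect_equal(rsf, panel$components$weight * s)
})

test_that("risk scores equal a brute-force per-subject recomputation", {
  data <- make_cohort(32, n1 = 10, n0 = 10)
  panel <- suppressWarnings(build_panel(data)) # small n can separate
  scored <- score_subjects(data, panel)
  expect_equal(scored$rsf, brute_rsf(data, panel$components), tolerance = 1e-12)

  # hand-built panel: all values above cutoffs sum the weights
  toy <- structure(
    list(
      components = tibble::tibble(
        mirna = c("a", "b"), cutoff = c(0.5, 0.5),
        direction = c("up", "up"), weight = c(0.5, 1.2), auc = NA_real_
      ),
      rsf_cutoff = 1.0, training = NULL
    ),
    class = "mirna_panel"
  )
  high <- tibble::tibble(sample_id = "x", group = "case", a = 1, b = 1)
  low <- tibble::tibble(sample_id = "y", group = "control", a = 0.1, b = 0.2)
  expect_equal(score_subjects(high, toy)$rsf, 1.7)
  expect_equal(score_subjects(low, toy)$rsf, 0)
  expect_error(score_subjects(high[, 1:3], toy), "b")
})

test_that("RSF is invariant under strictly monotone marker transforms", {
  data <- make_cohort(33)
  panel <- build_panel(data)
  transformed <- data
  transformed$a <- log(data$a)
  tpanel <- panel
  tpanel$components$cutoff[tpanel$components$mirna == "a"] <-
    log(panel$components$cutoff[panel$components$mirna == "a"])
  expect_equal(
    score_subjects(transformed, tpanel)$rsf,
    score_subjects(data, panel)$rsf
  )
})

test_that("fixed evaluation freezes the panel and reproduces training metrics", {
  data <- make_cohort(34)
  panel <- build_panel(data)
  before <- panel
  ev <- evaluate_fixed(data, panel)
  expect_identical(panel, before) # frozen-cutoff contract
  expect_equal(ev$auc, panel$training$auc)
  expect_equal(ev$sensitivity, panel$training$sensitivity)
  expect_equal(ev$specificity, panel$training$specificity)

  # permuted labels: no signal left
  set.seed(99)
  aucs <- replicate(60, {
    null <- data
    null$group <- sample(null$group)
    evaluate_fixed(null, panel)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(60))

  one_class <- data[data$group == "case", ]
  expect_error(evaluate_fixed(one_class, panel), "case and control")
})

test_that("a fresh cohort from the training distribution scores close to training", {
  data <- make_cohort(35, n1 = 100, n0 = 100)
  panel <- build_panel(data)
  new <- make_cohort(36, n1 = 200, n0 = 200)
  ev <- evaluate_fixed(new, panel)
  se <- panel$training$ci_high - panel$training$auc # ~1.96 SE
  expect_lt(abs(ev$auc - panel$training$auc), 3 * se)
})

test_that("association tests detect association and respect test choice", {
  # perfect 2x2 table
  score <- rep(c(1, 0), each = 10)
  grp <- rep(c("mut", "wild"), each = 10)
  res <- association_tests(
    tibble::tibble(s = score, egfr = grp), "s", "egfr"
  )
  expect_equal(res$test, "chisq")
  expect_lt(res$p_value, 0.001)

  # continuous value goes through one-way ANOVA
  set.seed(40)
  d <- tibble::tibble(
    v = rnorm(90),
    stage = rep(c("I", "II", "III"), each = 30)
  )
  res2 <- association_tests(d, "v", "stage")
  expect_equal(res2$test, "anova")
  a <- anova(aov(v ~ factor(stage), data = d))
  expect_equal(res2$statistic, a$`F value`[1], tolerance = 1e-12)
  expect_equal(res2$p_value, a$`Pr(>F)`[1], tolerance = 1e-12)

  # empty level dropped with warning
  d$stage <- factor(d$stage, levels = c("I", "II", "III", "IV"))
  expect_warning(association_tests(d, "v", "stage"), "IV")
})

test_that("panel JSON round-trips and validates", {
  data <- make_cohort(41)
  panel <- build_panel(data)
  path <- withr::local_tempfile(fileext = ".json")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(back$components$mirna, panel$components$mirna)
  expect_equal(back$components$cutoff, panel$components$cutoff)
  expect_equal(back$components$weight, panel$components$weight)
  expect_equal(back$rsf_cutoff, panel$rsf_cutoff)
  # applying the reloaded panel gives identical scores
  expect_equal(
    score_subjects(data, back)$rsf,
    score_subjects(data, panel)$rsf
  )

  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(components = list()), bad, auto_unbox = TRUE)
  expect_error(read_panel(bad), "nonempty")
})
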