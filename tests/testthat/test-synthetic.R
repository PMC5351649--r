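test_that("lognormal moment matching is exact in closed form", {
  # analytic round trip: (mu, sigma) -> (mean, sd) -> (mu, sigma)
  mu <- 1.7
  sigma <- 0.8
  m <- exp(mu + sigma^2 / 2)
  s <- m * sqrt(exp(sigma^2) - 1)
  p <- lognormal_from_moments(m, s)
  expect_equal(p$meanlog, mu, tolerance = 1e-12)
  expect_equal(p$sdlog, sigma, tolerance = 1e-12)

  # degenerate limit: sd -> 0 collapses to a point mass at the mean
  tiny <- lognormal_from_moments(1, 1e-8)
  expect_equal(tiny$meanlog, 0, tolerance = 1e-8)
  expect_equal(tiny$sdlog, 0, tolerance = 1e-4)

  expect_error(lognormal_from_moments(-1, 1), "> 0")
  expect_error(lognormal_from_moments(1, 0), "> 0")
})

test_that("generated samples reproduce the target moments", {
  p <- lognormal_from_moments(592, 458)
  set.seed(50)
  x <- exp(rnorm(2e5, p$meanlog, p$sdlog))
  expect_equal(mean(x), 592, tolerance = 0.02)
  expect_equal(sd(x), 458, tolerance = 0.05)
})

test_that("cohort generation is reproducible and correctly labelled", {
  cfg <- synthetic_config(seed = 51)
  a <- generate_cohort(cfg, "training")
  b <- generate_cohort(cfg, "training")
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cfg, "training", seed = 52)))

  expect_equal(sum(a$group == "case"), 42)
  expect_equal(sum(a$group == "control"), 32)
  expect_equal(unique(a$cohort), "training")
  expect_equal(anyDuplicated(a$sample_id), 0L)
  expect_setequal(
    setdiff(names(a), c("sample_id", "group", "cohort")),
    default_plasma_params()$mirna
  )
  expect_true(all(as.matrix(a[default_plasma_params()$mirna]) > 0))

  te <- generate_cohort(cfg, "testing")
  expect_equal(nrow(te), 66 + 62)
})

test_that("the copula hits the configured between-miRNA rank correlation", {
  cfg <- synthetic_config(correlation = 0.5, seed = 53)
  big <- generate_cohort(cfg, "training", n_case = 4000, n_control = 10)
  cases <- big[big$group == "case", default_plasma_params()$mirna]
  rho <- cor(as.matrix(cases), method = "spearman")
  off <- rho[upper.tri(rho)]
  expect_equal(mean(off), 0.5, tolerance = 0.05)
})

test_that("null configurations pass verification only at the nominal rate", {
  params <- default_plasma_params()
  null_params <- params
  null_params$case_mean <- null_params$control_mean
  null_params$case_sd <- null_params$control_sd
  cfg <- synthetic_config(params = null_params, correlation = 0)
  set.seed(54)
  res <- purrr::map_dfr(1:30, function(i) {
    verify_candidates(generate_cohort(cfg, "training", seed = 54 + i))
  })
  # the FC gate on top of the p gate keeps the pass rate below alpha
  expect_lt(mean(res$pass), 0.05)
})

test_that("Ct simulation inverts exactly without noise and censors below range", {
  cfg <- synthetic_config(seed = 55)
  conc <- generate_cohort(cfg, "training")
  curve <- default_standard_curve()
  ct <- generate_ct_matrix(conc[c("sample_id", default_plasma_params()$mirna)],
    curve,
    noise_sd = 0, spike_offset_sd = 0, seed = 55
  )
  expect_true(all(c("cel_mir_39", "negative_control") %in% names(ct)))
  for (m in default_plasma_params()$mirna) {
    expect_equal(ct_to_concentration(ct[[m]], curve), conc[[m]], tolerance = 1e-9)
  }

  # spike offsets are removed exactly by spike-in normalization
  noisy <- generate_ct_matrix(conc[c("sample_id", default_plasma_params()$mirna)],
    curve,
    noise_sd = 0, spike_offset_sd = 1, seed = 56
  )
  expect_gt(var(noisy$cel_mir_39), 0)
  norm <- spike_in_normalize(noisy, reference_ct = 22)
  expect_equal(var(norm$cel_mir_39), 0)
  for (m in default_plasma_params()$mirna) {
    expect_equal(ct_to_concentration(norm[[m]], curve), conc[[m]], tolerance = 1e-9)
  }

  # concentrations below the curve range come back undetected
  low <- tibble::tibble(sample_id = "s1", weak = 1e-4)
  ct_low <- generate_ct_matrix(low, curve, noise_sd = 0, spike_offset_sd = 0)
  expect_true(is.na(ct_low$weak))

  expect_error(
    generate_ct_matrix(conc[c("sample_id", "miR-21-5p")], list(x = curve)),
    "miR-21-5p"
  )
})

test_that("paired designs carry the planted condition effects", {
  tis <- generate_paired("tissue", seed = 57)
  expect_equal(nrow(tis), 38)
  expect_setequal(unique(tis$condition), c("normal", "tumor"))
  tumor <- tis[tis$condition == "tumor", ]
  normal <- tis[tis$condition == "normal", ]
  expect_equal(tumor$subject_id, normal$subject_id)
  # planted 2x up-regulation detectable in most panel miRNAs
  p_up <- paired_t(log2(tumor$`miR-21-5p`), log2(normal$`miR-21-5p`))
  expect_lt(p_up$p_value, 0.05)

  # no condition effect: paired t is null or degenerate
  flat <- generate_paired("tissue",
    params = tibble::tibble(mirna = "m", log2_effect = 0),
    seed = 58
  )
  res <- paired_t(
    flat$m[flat$condition == "tumor"],
    flat$m[flat$condition == "normal"]
  )
  expect_true(res$degenerate || res$p_value > 0.01)

  art <- generate_paired("arterial", seed = 59)
  expect_equal(nrow(art), 10)
  expect_setequal(unique(art$condition), c("peripheral", "arterial"))

  exo <- generate_paired("exosome", seed = 60)
  expect_equal(table(exo$group)[["case"]], 18)
  expect_equal(table(exo$group)[["control"]], 14)
})

test_that("exosome draws land near the configured group means", {
  set.seed(61)
  reps <- purrr::map_dfr(1:40, function(i) {
    exo <- generate_paired("exosome", seed = 61 + i)
    compare_groups(exo[c("sample_id", "group", "miR-221-3p")])
  })
  target <- default_exosome_params()
  row <- target[target$mirna == "miR-221-3p", ]
  expect_equal(mean(reps$mean_case), row$case_mean, tolerance = 0.1)
  expect_equal(mean(reps$mean_control), row$control_mean, tolerance = 0.1)
})

test_that("screening-phase generator is reproducible with coherent ground truth", {
  a <- generate_screening_phase(seed = 62, n_assays = 50, n_undetected = 4)
  b <- generate_screening_phase(seed = 62, n_assays = 50, n_undetected = 4)
  expect_identical(a, b)
  expect_equal(nrow(a$planted), 14)
  expect_equal(ncol(a$samples) - 3, 50)
  expect_equal(nrow(a$pools$pools), 4)
  # planted effects are present in the per-sample concentrations
  up1 <- a$planted$mirna[a$planted$direction == "up"][1]
  fc <- mean(a$samples[[up1]][a$samples$group == "case"]) /
    mean(a$samples[[up1]][a$samples$group == "control"])
  expect_gt(fc, 2)
})

test_that("simulate_study feeds the full pipeline and recovers the truth", {
  st <- simulate_study(seed = 63)
  run <- suppressWarnings(run_pipeline(st$config))
  expect_setequal(run$panel$components$mirna, st$screening$planted$mirna)
  run2 <- suppressWarnings(run_pipeline(st$config))
  expect_equal(run$panel$components, run2$panel$components)
  expect_equal(run$evaluations$external$auc, run2$evaluations$external$auc)

  broken <- st$config
  broken$training <- NULL
  expect_error(run_pipeline(broken), "training")
})
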