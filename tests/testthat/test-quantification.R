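test_that("standard curve recovers slope/efficiency of a perfect doubling series", {
  ds <- data.frame(concentration = c(1e4, 1e3, 1e2), ct = c(20, 23.3219, 26.6439))
  sc <- fit_standard_curve(ds, "miR-21-5p")
  expect_equal(sc$slope, -3.3219, tolerance = 1e-3)
  expect_equal(sc$efficiency, 1.0, tolerance = 1e-4)
  expect_equal(sc$r_squared, 1.0, tolerance = 1e-9)
  expect_lt(sc$slope, 0)

  # exact 2-fold-per-cycle series: efficiency is 1 to numerical precision
  exact <- data.frame(
    concentration = 10^(6:1),
    ct = 10 + (6 - (6:1)) * log2(10)
  )
  expect_equal(fit_standard_curve(exact)$efficiency, 1.0, tolerance = 1e-6)
})

test_that("standard curve matches closed-form least squares on a noisy series", {
  set.seed(101)
  conc <- 10^(6:1)
  ct <- 38 - 3.4 * log10(conc) + rnorm(6, 0, 0.2)
  sc <- fit_standard_curve(data.frame(concentration = conc, ct = ct))
  # normal equations computed directly
  x <- log10(conc)
  slope <- sum((x - mean(x)) * (ct - mean(ct))) / sum((x - mean(x))^2)
  intercept <- mean(ct) - slope * mean(x)
  expect_equal(sc$slope, slope, tolerance = 1e-9)
  expect_equal(sc$intercept, intercept, tolerance = 1e-9)
})

test_that("standard curve rejects degenerate and invalid dilution series", {
  expect_error(
    fit_standard_curve(data.frame(concentration = c(100, 100), ct = c(25, 25))),
    "distinct"
  )
  expect_error(
    fit_standard_curve(data.frame(concentration = c(100, -1), ct = c(25, 30))),
    "> 0"
  )
  expect_error(
    fit_standard_curve(data.frame(concentration = c(100, 10), ct = c(25, NA))),
    "finite"
  )
})

test_that("ct_to_concentration inverts the curve", {
  curve <- default_standard_curve(slope = -3.3219, intercept = 33.3219)
  expect_equal(ct_to_concentration(curve$intercept, curve), 1.0)
  # hand evaluation of 10^((20 - 33.3219) / -3.3219)
  expect_equal(ct_to_concentration(20, curve), 10^((20 - 33.3219) / -3.3219))
  expect_equal(ct_to_concentration(20, curve), 1e4, tolerance = 0.05)
  expect_true(is.na(ct_to_concentration(NA_real_, curve)))

  # round trip over the working range
  conc <- 10^seq(-2, 6, by = 0.5)
  back <- ct_to_concentration(predict_ct(curve, conc), curve)
  expect_equal(back, conc, tolerance = 1e-9)

  up <- default_standard_curve(slope = 3.3, intercept = 10)
  expect_error(ct_to_concentration(25, up), "negative")
})

test_that("spike-in normalization aligns samples on the spike assay", {
  ctm <- toy_ct_matrix()

  # all spikes already at reference: identity
  flat <- ctm
  flat$cel_mir_39 <- rep(22, 4)
  expect_equal(spike_in_normalize(flat, reference_ct = 22), flat)

  # one sample offset by +1: every assay in it shifts down by 1
  shifted <- flat
  shifted$cel_mir_39[2] <- 23
  out <- spike_in_normalize(shifted, reference_ct = 22)
  expect_equal(out$target[2], flat$target[2] - 1)
  expect_equal(out$ref1[2], flat$ref1[2] - 1)
  expect_equal(out$target[-2], flat$target[-2])

  # random offsets: spike column becomes constant with zero variance
  out2 <- spike_in_normalize(ctm, reference_ct = 22)
  expect_equal(var(out2$cel_mir_39), 0)
  expect_equal(unique(out2$cel_mir_39), 22)

  # idempotent
  expect_equal(spike_in_normalize(out2, reference_ct = 22), out2)
  expect_equal(spike_in_normalize(spike_in_normalize(ctm)), spike_in_normalize(ctm))

  # undetected spike names the sample
  bad <- ctm
  bad$cel_mir_39[3] <- NA
  expect_error(spike_in_normalize(bad), "s3")
})

test_that("2^-ddCt relative expression matches a hand-computed table", {
  ctm <- toy_ct_matrix()
  res <- delta_delta_ct(
    ctm, "target", c("ref1", "ref2"),
    case_ids = c("s1", "s2"), control_ids = c("s3", "s4")
  )
  # spreadsheet arithmetic: dCt = target - (ref1+ref2)/2
  dct <- c(24 - 21, 25 - 21.5, 26 - 22, 27 - 22.5)
  calib <- mean(dct[3:4])
  expect_equal(res$value, 2^(-(dct - calib)), tolerance = 1e-12)
  # control geometric mean is exactly 1
  expect_equal(exp(mean(log(res$value[res$group == "control"]))), 1, tolerance = 1e-12)
})

test_that("ddCt trivial identities hold", {
  ctm <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    t = c(20, 21, 22, 23),
    r = c(20, 21, 22, 23)
  )
  res <- delta_delta_ct(ctm, "t", "r", c("s1", "s2"), c("s3", "s4"))
  expect_equal(res$value, rep(1, 4))

  # case dCt exactly one cycle below the control mean dCt: value 2.0
  ctm2 <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    t = c(24, 24, 25, 25),
    r = rep(20, 4)
  )
  res2 <- delta_delta_ct(ctm2, "t", "r", c("s1", "s2"), c("s3", "s4"))
  expect_equal(res2$value[res2$group == "case"], c(2, 2))
})

test_that("ddCt is invariant to a per-sample global Ct shift", {
  ctm <- toy_ct_matrix()
  base <- delta_delta_ct(ctm, "target", c("ref1", "ref2"), c("s1", "s2"), c("s3", "s4"))
  shift <- c(1.3, -0.7, 0.2, 2.5)
  shifted <- ctm
  for (a in c("target", "ref1", "ref2")) shifted[[a]] <- shifted[[a]] + shift
  again <- delta_delta_ct(shifted, "target", c("ref1", "ref2"), c("s1", "s2"), c("s3", "s4"))
  expect_equal(again$value, base$value, tolerance = 1e-12)
})

test_that("ddCt rejects empty references and drops undetected samples with a warning", {
  ctm <- toy_ct_matrix()
  expect_error(
    delta_delta_ct(ctm, "target", character(0), c("s1", "s2"), c("s3", "s4")),
    "reference"
  )
  bad <- ctm
  bad$target[1] <- NA
  expect_warning(
    res <- delta_delta_ct(bad, "target", "ref1", c("s1", "s2"), c("s3", "s4")),
    "s1"
  )
  expect_equal(nrow(res), 3)
})

test_that("censor_undetected flags late wells and reports the count", {
  ctm <- toy_ct_matrix()
  ctm$target[1] <- 41
  ctm$ref1[2] <- 40
  expect_message(out <- censor_undetected(ctm), "2 cell")
  expect_true(is.na(out$target[1]))
  expect_true(is.na(out$ref1[2]))
})
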