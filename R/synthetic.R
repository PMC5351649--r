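#' Log-scale parameters of a lognormal from its mean and SD
#'
#' Moment matching: `mu = ln(mean^2 / sqrt(mean^2 + sd^2))`,
#' `sigma = sqrt(ln(1 + sd^2/mean^2))`. The implied lognormal has exactly
#' the requested first two moments. Circulating-miRNA concentration tables
#' report SDs on the order of the means, implying strong right skew on a
#' nonnegative scale — which this family captures.
#'
#' @param mean,sd Target mean and SD (> 0), vectorized.
#' @return Tibble with `meanlog` and `sdlog`.
#' @export
lognormal_from_moments <- function(mean, sd) {
  if (any(mean <= 0) || any(sd <= 0)) {
    abort("mean and sd must be > 0")
  }
  tibble::tibble(
    meanlog = log(mean^2 / sqrt(mean^2 + sd^2)),
    sdlog = sqrt(log(1 + sd^2 / mean^2))
  )
}

#' Closed-form AUC of one lognormal marker
#'
#' For lognormal case/control distributions the optimal single-marker AUC
#' is binormal on the log scale:
#' `Phi((mu_case - mu_control) / sqrt(sigma_case^2 + sigma_control^2))`.
#' Used as the analytic reference for simulation checks.
#'
#' @param case_mean,case_sd,control_mean,control_sd Group moments (fmol/L).
#' @return AUC in (0, 1).
#' @export
expected_auc_lognormal <- function(case_mean, case_sd, control_mean,
                                   control_sd) {
  ca <- lognormal_from_moments(case_mean, case_sd)
  co <- lognormal_from_moments(control_mean, control_sd)
  pnorm((ca$meanlog - co$meanlog) / sqrt(ca$sdlog^2 + co$sdlog^2))
}

#' Default per-miRNA plasma distribution parameters
#'
#' Group means and SDs (fmol/L) of the six panel miRNAs in the training or
#' testing stage of the study the package models.
#'
#' @param stage `"training"` or `"testing"`.
#' @return Tibble: `mirna`, `case_mean`, `case_sd`, `control_mean`,
#'   `control_sd`.
#' @export
default_plasma_params <- function(stage = c("training", "testing")) {
  stage <- match.arg(stage)
  if (stage == "training") {
    tibble::tribble(
      ~mirna, ~case_mean, ~case_sd, ~control_mean, ~control_sd,
      "miR-19b-3p", 592, 458, 331, 222,
      "miR-21-5p", 1338, 1567, 632, 709,
      "miR-221-3p", 127, 136, 51, 56,
      "miR-409-3p", 14, 17, 3.3, 5.5,
      "miR-425-5p", 262, 195, 152, 69,
      "miR-584-5p", 330, 458, 161, 197
    )
  } else {
    tibble::tribble(
      ~mirna, ~case_mean, ~case_sd, ~control_mean, ~control_sd,
      "miR-19b-3p", 517, 447, 313, 280,
      "miR-21-5p", 1103, 990, 570, 546,
      "miR-221-3p", 132, 194, 59, 81,
      "miR-409-3p", 12.3, 16, 2.8, 2.4,
      "miR-425-5p", 201, 166, 128, 64,
      "miR-584-5p", 353, 425, 145, 164
    )
  }
}

#' Default exosomal relative-expression parameters
#'
#' Group means and SDs on the 2^-ddCt scale for exosomal miRNA from
#' peripheral plasma (cases run below the control calibrator here).
#'
#' @return Tibble as in [default_plasma_params()].
#' @export
default_exosome_params <- function() {
  tibble::tribble(
    ~mirna, ~case_mean, ~case_sd, ~control_mean, ~control_sd,
    "miR-19b-3p", 0.79, 0.85, 1.05, 0.32,
    "miR-21-5p", 0.49, 0.73, 1.20, 0.82,
    "miR-221-3p", 0.39, 0.24, 1.17, 0.65,
    "miR-409-3p", 0.81, 1.44, 1.29, 1.61,
    "miR-425-5p", 0.98, 1.05, 1.37, 1.25,
    "miR-584-5p", 0.62, 0.69, 1.06, 0.62
  )
}

#' Default cohort sizes per study stage
#'
#' @return Tibble: `stage`, `n_case`, `n_control` (30/10, 42/32, 66/62,
#'   33/30 for screening, training, testing, external).
#' @export
default_cohort_sizes <- function() {
  tibble::tribble(
    ~stage, ~n_case, ~n_control,
    "screening", 30L, 10L,
    "training", 42L, 32L,
    "testing", 66L, 62L,
    "external", 33L, 30L
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param params Per-miRNA distribution moments: either a single tibble
#'   (shaped like [default_plasma_params()]) used for every stage, or a
#'   named list of such tibbles keyed by stage. The default uses the
#'   training-stage moments everywhere except the testing stage, which gets
#'   its own printed moments.
#' @param cohorts Tibble of per-stage sizes ([default_cohort_sizes()]).
#' @param correlation Between-miRNA Spearman rank correlation in `[0, 1)`,
#'   applied through a Gaussian copula; co-regulated circulating miRNAs
#'   motivate the default 0.3.
#' @param family `"lognormal"` (moment-matched; default) or `"truncnorm"`
#'   (normal truncated at zero, same location/scale before truncation).
#' @param seed Default seed for generators using this config.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(params = NULL, cohorts = default_cohort_sizes(),
                             correlation = 0.3,
                             family = c("lognormal", "truncnorm"),
                             seed = NULL) {
  family <- match.arg(family)
  params <- params %||% list(
    training = default_plasma_params("training"),
    testing = default_plasma_params("testing")
  )
  check_params <- function(p) {
    need <- c("mirna", "case_mean", "case_sd", "control_mean", "control_sd")
    if (!all(need %in% names(p))) {
      abort(paste0("params need columns: ", paste(need, collapse = ", ")))
    }
    if (any(p$case_mean <= 0 | p$case_sd <= 0 |
      p$control_mean <= 0 | p$control_sd <= 0)) {
      abort("all distribution means/SDs must be > 0")
    }
    invisible(p)
  }
  if (is.data.frame(params)) check_params(params) else purrr::walk(params, check_params)
  if (correlation < 0 || correlation >= 1) {
    abort("correlation must be in [0, 1)")
  }
  structure(
    list(
      params = params, cohorts = cohorts, correlation = correlation,
      family = family, seed = seed
    ),
    class = "synthetic_config"
  )
}

stage_params <- function(config, stage) {
  p <- config$params
  if (is.data.frame(p)) {
    return(p)
  }
  p[[stage]] %||% p[["training"]] %||% p[[1]]
}

# Correlated draws with lognormal (or zero-truncated normal) marginals via a
# Gaussian copula; `correlation` is the target Spearman rank correlation.
draw_group <- function(n, params, mean_col, sd_col, correlation, family) {
  p <- nrow(params)
  rho_z <- 2 * sin(pi * correlation / 6) # Pearson on the latent normals
  sigma_z <- matrix(rho_z, p, p)
  diag(sigma_z) <- 1
  z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma_z)
  z <- matrix(z, nrow = n)
  out <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    m <- params[[mean_col]][j]
    s <- params[[sd_col]][j]
    if (family == "lognormal") {
      lp <- lognormal_from_moments(m, s)
      out[, j] <- exp(lp$meanlog + lp$sdlog * z[, j])
    } else {
      u <- pnorm(z[, j])
      lo <- pnorm(0, m, s) # truncate at zero, keep location/scale
      out[, j] <- stats::qnorm(lo + u * (1 - lo), m, s)
    }
  }
  colnames(out) <- params$mirna
  out
}

#' Generate a synthetic case/control cohort
#'
#' Draws per-group, per-miRNA concentrations (fmol/L) from the configured
#' family, rank-correlated across miRNAs through a Gaussian copula, and
#' labels rows with group and cohort stage. Bit-reproducible for a given
#' `(config, stage, seed)`.
#'
#' @param config A [synthetic_config()].
#' @param stage Study stage; sets the cohort sizes and (where configured)
#'   the stage-specific moments.
#' @param seed Overrides `config$seed`.
#' @param n_case,n_control Override the configured cohort sizes.
#' @return Concentration tibble: `sample_id`, `group`, `cohort`, one column
#'   per miRNA.
#' @export
generate_cohort <- function(config = synthetic_config(),
                            stage = c("training", "testing", "external", "screening"),
                            seed = NULL, n_case = NULL, n_control = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  stage <- match.arg(stage)
  seed <- seed %||% config$seed
  sizes <- config$cohorts[config$cohorts$stage == stage, ]
  if (nrow(sizes) != 1 && (is.null(n_case) || is.null(n_control))) {
    abort(paste0("no cohort sizes configured for stage '", stage, "'"))
  }
  n_case <- n_case %||% sizes$n_case
  n_control <- n_control %||% sizes$n_control
  params <- stage_params(config, stage)

  draws <- with_seed_if(seed, {
    list(
      case = draw_group(
        n_case, params, "case_mean", "case_sd",
        config$correlation, config$family
      ),
      control = draw_group(
        n_control, params, "control_mean", "control_sd",
        config$correlation, config$family
      )
    )
  })
  tag <- toupper(substr(stage, 1, 2))
  meta <- tibble::tibble(
    sample_id = c(
      sprintf("%s_case_%03d", tag, seq_len(n_case)),
      sprintf("%s_control_%03d", tag, seq_len(n_control))
    ),
    group = c(rep("case", n_case), rep("control", n_control)),
    cohort = stage
  )
  dplyr::bind_cols(meta, tibble::as_tibble(rbind(draws$case, draws$control)))
}

#' Build a standard curve without a dilution series
#'
#' Constructs the calibration line directly from a slope and intercept
#' (defaults: slope -3.32 cycles per decade, i.e. ~100% efficiency, with
#' the intercept placing typical plasma concentrations in the Ct 20-35
#' window).
#'
#' @param mirna Assay identifier.
#' @param slope,intercept Line parameters (cycles per log10 fmol/L; cycles).
#' @return A `standard_curve` object.
#' @export
default_standard_curve <- function(mirna = NULL, slope = -3.32,
                                   intercept = 35) {
  structure(
    list(
      mirna = mirna, slope = slope, intercept = intercept,
      r_squared = 1, efficiency = 10^(-1 / slope) - 1, n = 0L
    ),
    class = "standard_curve"
  )
}

#' Simulate a Ct matrix from known concentrations
#'
#' The inverse of the quantification path, for end-to-end tests: each
#' assay's Ct is the standard-curve prediction plus Gaussian measurement
#' noise plus a shared per-sample offset (extraction/RT yield). A spike-in
#' assay (`cel_mir_39`) carrying only the per-sample offset and a constant
#' no-template `negative_control` well are appended. Predicted Cts at or
#' beyond `max_ct` are censored to undetected.
#'
#' @param conc Concentration tibble (`sample_id` + miRNA columns).
#' @param curves Named list of `standard_curve` objects, one per miRNA
#'   column (a single curve is recycled to all assays).
#' @param noise_sd Measurement noise SD in cycles.
#' @param spike_offset_sd SD of the per-sample offset in cycles.
#' @param spike_reference_ct Nominal spike-in Ct.
#' @param nc_ct Negative-control Ct (NA for a clean no-template well).
#' @param max_ct Censoring bound in cycles.
#' @param seed RNG seed.
#' @return Wide Ct tibble: `sample_id`, assay columns, `cel_mir_39`,
#'   `negative_control`.
#' @export
generate_ct_matrix <- function(conc, curves, noise_sd = 0.2,
                               spike_offset_sd = 0.5,
                               spike_reference_ct = 22, nc_ct = 40,
                               max_ct = 40, seed = NULL) {
  mirnas <- measure_cols(conc)
  if (inherits(curves, "standard_curve")) {
    curves <- setNames(rep(list(curves), length(mirnas)), mirnas)
  }
  missing <- setdiff(mirnas, names(curves))
  if (length(missing) > 0) {
    abort(paste0(
      "no standard curve for assay(s): ", paste(missing, collapse = ", ")
    ))
  }
  n <- nrow(conc)
  with_seed_if(seed, {
    offset <- rnorm(n, 0, spike_offset_sd)
    out <- tibble::tibble(sample_id = conc$sample_id)
    for (m in mirnas) {
      ct <- predict_ct(curves[[m]], conc[[m]]) + offset + rnorm(n, 0, noise_sd)
      ct[ct >= max_ct] <- NA_real_
      out[[m]] <- ct
    }
    out$cel_mir_39 <- spike_reference_ct + offset + rnorm(n, 0, noise_sd)
    out$negative_control <- rep(nc_ct, n)
    out
  })
}

#' Generate paired or two-group ancillary designs
#'
#' Emulates the study's ancillary comparisons: `"tissue"` (paired
#' tumor/normal relative expression, 2^-ddCt scale, default 19 pairs),
#' `"arterial"` (paired arterial/peripheral plasma, fmol/L, default 5
#' pairs), and `"exosome"` (two independent groups on the 2^-ddCt scale,
#' default 18 cases vs 14 controls, moments from
#' [default_exosome_params()]). Paired designs share a subject-level random
#' effect within each pair, on top of which the condition effect acts.
#'
#' @param design One of `"tissue"`, `"arterial"`, `"exosome"`.
#' @param params Optional parameter tibble. For `tissue`/`arterial`:
#'   `mirna`, `log2_effect` (condition effect), plus for arterial the
#'   baseline moments (`case_mean`, `case_sd`). For `exosome`: as
#'   [default_exosome_params()].
#' @param n Number of pairs (tissue/arterial); ignored for exosome, whose
#'   group sizes come from `n_case`/`n_control`.
#' @param n_case,n_control Exosome group sizes.
#' @param subject_sd,residual_sd Log2-scale SDs of the shared subject
#'   effect and the residual noise.
#' @param seed RNG seed.
#' @return Tissue/arterial: tibble with `subject_id`, `condition` and one
#'   column per miRNA (two rows per subject). Exosome: tibble with
#'   `sample_id`, `group`, miRNA columns.
#' @export
generate_paired <- function(design = c("tissue", "arterial", "exosome"),
                            params = NULL, n = NULL, n_case = 18,
                            n_control = 14, subject_sd = 0.5,
                            residual_sd = 0.5, seed = NULL) {
  design <- match.arg(design)

  if (design == "exosome") {
    params <- params %||% default_exosome_params()
    cfg <- synthetic_config(
      params = params,
      cohorts = tibble::tibble(
        stage = "external", n_case = n_case, n_control = n_control
      ),
      correlation = 0, seed = seed
    )
    out <- generate_cohort(cfg, "external", seed = seed)
    out$sample_id <- sub("^EX", "EXO", out$sample_id)
    out$cohort <- NULL
    return(out)
  }

  if (design == "tissue") {
    n <- n %||% 19L
    params <- params %||% tibble::tibble(
      mirna = default_plasma_params()$mirna,
      log2_effect = c(1, 1, 1, 1, 1, 0) # miR-584-5p flat in tissue
    )
    conditions <- c("normal", "tumor")
  } else {
    n <- n %||% 5L
    base <- default_plasma_params("training")
    params <- params %||% tibble::tibble(
      mirna = base$mirna,
      log2_effect = c(0.4, 0.4, 0.4, 0.4, 0.4, 0),
      case_mean = base$case_mean,
      case_sd = base$case_sd
    )
    conditions <- c("peripheral", "arterial")
  }
  if (n < 2) {
    abort("need at least 2 pairs")
  }

  with_seed_if(seed, {
    p <- nrow(params)
    subj <- matrix(rnorm(n * p, 0, subject_sd), n, p)
    eff <- matrix(params$log2_effect, n, p, byrow = TRUE)
    val <- function(is_treated) {
      log2v <- subj + if (is_treated) eff else 0
      log2v <- log2v + matrix(rnorm(n * p, 0, residual_sd), n, p)
      if (design == "arterial") {
        lp <- lognormal_from_moments(params$case_mean, params$case_sd)
        sweep(2^log2v, 2, exp(lp$meanlog), `*`)
      } else {
        2^log2v
      }
    }
    ref <- val(FALSE)
    trt <- val(TRUE)
    assemble <- function(mat, cond) {
      out <- tibble::tibble(
        subject_id = sprintf("%s_%02d", toupper(substr(design, 1, 3)), seq_len(n)),
        condition = cond
      )
      colnames(mat) <- params$mirna
      dplyr::bind_cols(out, tibble::as_tibble(mat))
    }
    dplyr::arrange(
      dplyr::bind_rows(assemble(ref, conditions[1]), assemble(trt, conditions[2])),
      .data$subject_id, .data$condition
    )
  })
}

#' Generate a complete synthetic screening phase
#'
#' Builds the phase-1 material with known ground truth: `n_assays` panel
#' assays measured on individual screening-phase samples, a planted subset
#' with a true case/control concentration ratio (up and/or down), a few
#' assays below the detection range, randomized pooling of the samples,
#' and the pool-level Ct matrix (with spike-in and negative-control wells)
#' the screen runs on.
#'
#' @param seed RNG seed (drives every draw).
#' @param n_assays Panel size.
#' @param planted_up,planted_down Numbers of planted up-/down-regulated
#'   assays.
#' @param effect_up,effect_down True case/control concentration ratios of
#'   the planted assays. The defaults (4 and 1/4) clear the two-fold pool
#'   gate with several standard deviations of margin over pool-level
#'   sampling noise, so a planted effect is one that passes every gate by
#'   construction.
#' @param n_case,n_control Screening-phase sample counts.
#' @param pool_size Samples per pool.
#' @param sigma_log Log-scale SD of the per-sample concentrations.
#' @param n_undetected Assays planted below the quantifiable range (these
#'   must fail the detection gate).
#' @param noise_sd,spike_offset_sd Ct-simulation parameters.
#' @return List: `samples` (per-sample concentration tibble), `pools`
#'   (from [make_pools()]), `ct_pools` (pool-level Ct matrix), `planted`
#'   (tibble `mirna`, `direction`), `undetectable` (assay names), `curve`.
#' @export
generate_screening_phase <- function(seed = NULL, n_assays = 168,
                                     planted_up = 13, planted_down = 1,
                                     effect_up = 4, effect_down = 1 / 4,
                                     n_case = 30, n_control = 10,
                                     pool_size = 10, sigma_log = 0.3,
                                     n_undetected = 10, noise_sd = 0.1,
                                     spike_offset_sd = 0.5) {
  assays <- sprintf("miR-sim-%03d", seq_len(n_assays))
  curve <- default_standard_curve(slope = -3.32, intercept = 35)

  with_seed_if(seed, {
    picked <- sample(assays, planted_up + planted_down + n_undetected)
    up <- picked[seq_len(planted_up)]
    down <- picked[planted_up + seq_len(planted_down)]
    undetectable <- picked[planted_up + planted_down + seq_len(n_undetected)]

    base <- 10^stats::runif(n_assays, 1, 3) # 10-1000 fmol/L
    names(base) <- assays
    base[undetectable] <- 1e-3 # below the curve range -> Ct past 40

    effect <- setNames(rep(1, n_assays), assays)
    effect[up] <- effect_up
    effect[down] <- effect_down

    n <- n_case + n_control
    group <- c(rep("case", n_case), rep("control", n_control))
    conc <- tibble::tibble(
      sample_id = sprintf("SC_%s_%03d", group, c(seq_len(n_case), seq_len(n_control))),
      group = group,
      cohort = "screening"
    )
    for (a in assays) {
      mu <- log(base[[a]]) - sigma_log^2 / 2
      v <- exp(mu + sigma_log * rnorm(n))
      v[group == "case"] <- v[group == "case"] * effect[[a]]
      conc[[a]] <- v
    }

    pools <- make_pools(conc, pool_size = pool_size, seed = sample.int(1e6, 1))
    pooled <- pools$pooled
    pooled_conc <- dplyr::rename(pooled, sample_id = "pool_id")
    ct_pools <- generate_ct_matrix(
      pooled_conc[c("sample_id", assays)],
      curves = curve, noise_sd = noise_sd,
      spike_offset_sd = spike_offset_sd, seed = sample.int(1e6, 1)
    )

    list(
      samples = conc,
      pools = pools,
      ct_pools = ct_pools,
      planted = tibble::tibble(
        mirna = c(up, down),
        direction = c(rep("up", planted_up), rep("down", planted_down))
      ),
      undetectable = undetectable,
      assay_info = tibble::tibble(
        mirna = assays,
        base_mean = unname(base),
        effect = unname(effect)
      ),
      curve = curve
    )
  })
}

#' Simulate a coherent four-phase study
#'
#' Wires the synthetic modules into one consistent study: a planted
#' screening phase, plus training/testing/external cohorts in which the
#' planted assays keep their true case/control concentration ratios (group
#' SDs matching the screening-phase log-scale spread). The result feeds
#' [run_pipeline()] directly.
#'
#' @param seed RNG seed; per-stage seeds are derived from it.
#' @param correlation Between-miRNA rank correlation of the validation
#'   cohorts.
#' @param ... Passed to [generate_screening_phase()].
#' @return List: `screening` (as [generate_screening_phase()]), `params`
#'   (validation-cohort moments of the planted assays), `training`,
#'   `testing`, `external` (concentration tibbles), `config` (a ready
#'   [run_pipeline()] config).
#' @export
simulate_study <- function(seed = 1, correlation = 0.3, ...) {
  scr <- generate_screening_phase(seed = seed, ...)
  info <- scr$assay_info[scr$assay_info$mirna %in% scr$planted$mirna, ]
  cv <- sqrt(exp(0.3^2) - 1) # matches the screening-phase log-scale spread
  params <- tibble::tibble(
    mirna = info$mirna,
    case_mean = info$base_mean * info$effect,
    case_sd = info$base_mean * info$effect * cv,
    control_mean = info$base_mean,
    control_sd = info$base_mean * cv
  )
  cfg <- synthetic_config(params = params, correlation = correlation)
  cohorts <- list(
    training = generate_cohort(cfg, "training", seed = seed + 1),
    testing = generate_cohort(cfg, "testing", seed = seed + 2),
    external = generate_cohort(cfg, "external", seed = seed + 3)
  )
  case_pools <- scr$pools$pools$pool_id[scr$pools$pools$group == "case"]
  control_pool <- scr$pools$pools$pool_id[scr$pools$pools$group == "control"]
  list(
    screening = scr,
    params = params,
    training = cohorts$training,
    testing = cohorts$testing,
    external = cohorts$external,
    config = list(
      seed = seed,
      screening = list(
        ct_pools = scr$ct_pools,
        case_pools = case_pools,
        control_pool = control_pool
      ),
      verification = list(data = scr$samples),
      training = cohorts$training,
      testing = cohorts$testing,
      external = cohorts$external
    )
  )
}
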