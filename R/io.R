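#' Read a Ct matrix from CSV/TSV
#'
#' First column `sample_id`, remaining columns assay Cts; an empty cell or
#' `NA` is the undetected sentinel. The loaded table is validated (unique
#' IDs, numeric positive Cts) and the undetected-cell count reported.
#'
#' @param path CSV or TSV file (dialect chosen by extension).
#' @return Wide Ct tibble.
#' @export
read_ct_matrix <- function(path) {
  data <- read_delim_auto(path)
  if (names(data)[1] != "sample_id") {
    names(data)[1] <- "sample_id"
  }
  data$sample_id <- as.character(data$sample_id)
  for (a in setdiff(names(data), "sample_id")) {
    v <- data[[a]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(coerced))
      if (length(bad) > 0) {
        abort(paste0(
          "non-numeric Ct in assay '", a, "', sample(s): ",
          paste(data$sample_id[bad], collapse = ", ")
        ))
      }
      v <- coerced
    }
    data[[a]] <- v
  }
  validate_ct_matrix(data, basename(path))
  n_na <- sum(is.na(data[setdiff(names(data), "sample_id")]))
  if (n_na > 0) {
    inform(paste0(basename(path), ": ", n_na, " undetected cell(s)"))
  }
  data
}

#' @rdname read_ct_matrix
#' @param ct_matrix Wide Ct tibble to write.
#' @export
write_ct_matrix <- function(ct_matrix, path) {
  validate_ct_matrix(ct_matrix)
  write_delim_auto(ct_matrix, path)
}

#' Read a sample sheet
#'
#' Requires `sample_id`, `group` (`case`/`control`) and `cohort`
#' (`screening`/`training`/`testing`/`external`); clinical columns (age,
#' gender, smoking, tnm_stage, egfr) are optional.
#'
#' @param path CSV file.
#' @return Validated tibble.
#' @export
read_sample_sheet <- function(path) {
  data <- read_delim_auto(path)
  required <- c("sample_id", "group", "cohort")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      basename(path), ": missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  data$sample_id <- as.character(data$sample_id)
  dup <- unique(data$sample_id[duplicated(data$sample_id)])
  if (length(dup) > 0) {
    abort(paste0(
      basename(path), ": duplicate sample_id(s): ", paste(dup, collapse = ", ")
    ))
  }
  check_group_column(data, "group")
  check_group_column(
    data, "cohort",
    levels = c("screening", "training", "testing", "external")
  )
  data
}

#' Read standard-curve dilution series and fit all curves
#'
#' Expects columns `mirna`, `concentration_fmol_per_l`, `ct`; one curve is
#' fitted per miRNA.
#'
#' @param path CSV file.
#' @return Named list of `standard_curve` objects.
#' @export
read_standard_curves <- function(path) {
  data <- read_delim_auto(path)
  need <- c("mirna", "concentration_fmol_per_l", "ct")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      basename(path), ": missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  series <- split(data, data$mirna)
  purrr::imap(series, function(d, m) fit_standard_curve(d, m))
}

#' Read / write a concentration table
#'
#' Columns `sample_id`, `group`, `cohort`, then one numeric column per
#' miRNA (fmol/L; blank/`NA` = undetected).
#'
#' @param path CSV file.
#' @return Validated concentration tibble.
#' @export
read_concentration_table <- function(path) {
  data <- read_delim_auto(path)
  need <- c("sample_id", "group", "cohort")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      basename(path), ": missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) {
    abort(paste0(basename(path), ": duplicate sample_id(s)"))
  }
  check_group_column(data, "group")
  for (m in measure_cols(data)) {
    if (!is.numeric(data[[m]])) {
      abort(paste0(basename(path), ": non-numeric concentration column '", m, "'"))
    }
    if (any(data[[m]] < 0, na.rm = TRUE)) {
      abort(paste0(basename(path), ": negative concentration in '", m, "'"))
    }
  }
  data
}

#' @rdname read_concentration_table
#' @param data Concentration tibble to write.
#' @export
write_concentration_table <- function(data, path) {
  write_delim_auto(data, path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

write_delim_auto <- function(data, path) {
  # list-columns (e.g. pooled fold changes) are not part of the CSV surface
  data <- data[!vapply(data, is.list, logical(1))]
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(data, path, progress = FALSE)
  } else {
    readr::write_csv(data, path, progress = FALSE)
  }
  invisible(path)
}

#' Run the four-phase discovery/validation pipeline
#'
#' Executes, in order: the pooled screen (detection gate + pool fold-change
#' gate), qRT-PCR verification on the screening-phase samples, panel
#' training, and fixed-cutoff evaluation on the testing and (optionally)
#' external cohorts. Inputs are data frames or file paths; every phase's
#' inputs are checked up front so a missing dependency fails before any
#' computation.
#'
#' @param config Named list:
#'   \describe{
#'     \item{screening}{list with `ct_pools` (Ct matrix or path),
#'       `case_pools`, `control_pool`, and optionally `normalizer_assays`,
#'       `max_ct`, `nc_margin`, `fc_threshold`.}
#'     \item{verification}{list with `data` (concentration/relative table
#'       or path) and optionally `fc_up`, `fc_down`, `alpha`. Candidates
#'       default to the screen's passing miRNAs.}
#'     \item{training, testing, external}{concentration tables or paths
#'       (`external` optional).}
#'     \item{mirnas}{optional: panel miRNAs, overriding the verified set.}
#'     \item{seed}{recorded in the run log.}
#'   }
#' @param out_dir Optional directory; when given, writes the comparison
#'   table (`comparison.csv`), panel (`panel.json`), per-stage ROC
#'   summaries (`roc_summary.csv`) and a run log (`run_log.json`).
#' @return List of class `mirpanel_run`: `screen`, `verification`,
#'   `panel`, `evaluations` (per stage), `comparison`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  need_phase <- function(name) {
    if (is.null(config[[name]])) {
      abort(paste0("pipeline config is missing the '", name, "' phase"))
    }
    config[[name]]
  }
  scr <- need_phase("screening")
  ver <- need_phase("verification")
  load_tbl <- function(x) {
    if (is.character(x)) read_concentration_table(x) else tibble::as_tibble(x)
  }
  training <- load_tbl(need_phase("training"))
  testing <- load_tbl(need_phase("testing"))
  external <- if (!is.null(config$external)) load_tbl(config$external)

  ct_pools <- if (is.character(scr$ct_pools)) {
    read_ct_matrix(scr$ct_pools)
  } else {
    tibble::as_tibble(scr$ct_pools)
  }
  screen <- screen_panel(
    ct_pools,
    case_pools = scr$case_pools, control_pool = scr$control_pool,
    normalizer_assays = scr$normalizer_assays,
    max_ct = scr$max_ct %||% 37, nc_margin = scr$nc_margin %||% 5,
    fc_threshold = scr$fc_threshold %||% 2
  )
  candidates <- screen$mirna[screen$pass]
  if (length(candidates) == 0) {
    abort("screening phase passed no candidates")
  }

  ver_data <- load_tbl(ver$data)
  verification <- verify_candidates(
    ver_data,
    candidates = intersect(candidates, names(ver_data)),
    fc_up = ver$fc_up %||% 1.5, fc_down = ver$fc_down %||% 0.66,
    alpha = ver$alpha %||% 0.05
  )
  verified <- verification$mirna[verification$pass]
  mirnas <- config$mirnas %||% verified
  if (length(mirnas) == 0) {
    abort("verification passed no candidates and config$mirnas is empty")
  }

  panel_mirnas <- intersect(mirnas, names(training))
  if (length(panel_mirnas) == 0) {
    abort("training cohort measures none of the candidate miRNAs")
  }
  panel <- build_panel(training, mirnas = panel_mirnas)
  evaluations <- list(
    training = evaluate_fixed(training, panel),
    testing = evaluate_fixed(testing, panel)
  )
  if (!is.null(external)) {
    evaluations$external <- evaluate_fixed(external, panel)
  }

  comparison <- dplyr::bind_rows(
    dplyr::mutate(compare_groups(training, mirnas = panel$components$mirna),
      cohort = "training", .before = 1
    ),
    dplyr::mutate(compare_groups(testing, mirnas = panel$components$mirna),
      cohort = "testing", .before = 1
    )
  )

  log <- list(
    seed = config$seed,
    mirnas = panel$components$mirna,
    n_candidates_screen = length(candidates),
    n_candidates_verified = length(verified),
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("mirpanel")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )

  run <- structure(
    list(
      screen = screen, verification = verification, panel = panel,
      evaluations = evaluations, comparison = comparison, log = log
    ),
    class = "mirpanel_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_delim_auto(comparison, file.path(out_dir, "comparison.csv"))
    write_panel(panel, file.path(out_dir, "panel.json"))
    roc_summary <- purrr::imap_dfr(
      evaluations,
      function(e, stage) dplyr::mutate(glance(e), stage = stage, .before = 1)
    )
    write_delim_auto(roc_summary, file.path(out_dir, "roc_summary.csv"))
    jsonlite::write_json(
      log, file.path(out_dir, "run_log.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  run
}

#' @export
print.mirpanel_run <- function(x, ...) {
  cat("<mirpanel_run>\n")
  cat(
    " screen:", sum(x$screen$pass), "of", nrow(x$screen),
    "assays passed the pooled screen\n"
  )
  cat(
    " verification:", sum(x$verification$pass), "of", nrow(x$verification),
    "candidates verified\n"
  )
  cat(" panel:", nrow(x$panel$components), "miRNAs\n")
  for (stage in names(x$evaluations)) {
    e <- x$evaluations[[stage]]
    cat(sprintf(
      "  %s: AUC %.3f (sens %.2f / spec %.2f)\n",
      stage, e$auc, e$sensitivity, e$specificity
    ))
  }
  invisible(x)
}
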