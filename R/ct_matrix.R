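# A Ct matrix is an ordinary wide tibble: a `sample_id` column followed by
# one numeric column per assay, in PCR cycles. NA marks an undetected well.
# Special assay columns used by the workflow: "negative_control" (no-template
# panel well), "cel_mir_39" (the C. elegans spike-in), plus any endogenous
# reference assays (e.g. "miR-16", "U6").

validate_ct_matrix <- function(data, call_name = "ct matrix") {
  if (!"sample_id" %in% names(data)) {
    abort(paste0(call_name, ": first column must be 'sample_id'"))
  }
  dup <- data$sample_id[duplicated(data$sample_id)]
  if (length(dup) > 0) {
    abort(paste0(
      call_name, ": duplicate sample_id(s): ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  assays <- setdiff(names(data), "sample_id")
  if (anyDuplicated(assays)) {
    abort(paste0(call_name, ": duplicate assay columns"))
  }
  for (a in assays) {
    v <- data[[a]]
    if (!is.numeric(v)) {
      abort(paste0(call_name, ": assay '", a, "' is not numeric"))
    }
    bad <- which(is.finite(v) & v <= 0)
    if (length(bad) > 0) {
      abort(paste0(
        call_name, ": assay '", a, "' has non-positive Ct in sample(s) ",
        paste(data$sample_id[bad], collapse = ", ")
      ))
    }
  }
  invisible(data)
}

#' Mark late or undetermined wells as undetected
#'
#' Cells with `Ct >= max_ct` (or non-finite values) are set to `NA`, the
#' undetected sentinel used throughout the package; the number of newly
#' censored cells is reported.
#'
#' @param ct_matrix Wide Ct tibble (`sample_id` + assay columns).
#' @param max_ct Censoring bound in cycles; the qPCR protocol runs 40 cycles,
#'   so 40 by default.
#' @param exclude Assay columns left untouched. The no-template negative
#'   control legitimately runs late and must keep its Ct: censoring it to
#'   `NA` would lift the detection-gate margin.
#' @return The Ct matrix with censored cells set to `NA`.
#' @export
censor_undetected <- function(ct_matrix, max_ct = 40,
                              exclude = "negative_control") {
  validate_ct_matrix(ct_matrix)
  assays <- setdiff(names(ct_matrix), c("sample_id", exclude))
  n_new <- 0L
  for (a in assays) {
    v <- ct_matrix[[a]]
    censor <- !is.na(v) & (!is.finite(v) | v >= max_ct)
    n_new <- n_new + sum(censor)
    v[censor] <- NA_real_
    ct_matrix[[a]] <- v
  }
  if (n_new > 0) {
    inform(paste0("censor_undetected: ", n_new, " cell(s) set to undetected (Ct >= ", max_ct, ")"))
  }
  ct_matrix
}

#' Spike-in normalization of a Ct matrix
#'
#' Removes per-sample technical variation (extraction and RT yield) using an
#' exogenous spike-in assay (cel-miR-39 added at a fixed amount per sample).
#' For each sample the offset `delta_s = Ct(spike) - reference_ct` is
#' subtracted from every assay, so the spike-in column becomes exactly
#' `reference_ct` everywhere.
#'
#' @param ct_matrix Wide Ct tibble.
#' @param spike_assay Name of the spike-in assay column.
#' @param reference_ct Target Ct for the spike-in; defaults to the mean
#'   observed spike-in Ct (which makes the operation idempotent).
#' @param exclude Assay columns left untouched (the no-template negative
#'   control is not a sample-borne signal).
#' @return Normalized Ct matrix of the same shape.
#' @export
spike_in_normalize <- function(ct_matrix, spike_assay = "cel_mir_39",
                               reference_ct = NULL,
                               exclude = "negative_control") {
  validate_ct_matrix(ct_matrix)
  if (!spike_assay %in% names(ct_matrix)) {
    abort(paste0("spike assay '", spike_assay, "' not present"))
  }
  spike <- ct_matrix[[spike_assay]]
  if (anyNA(spike)) {
    abort(paste0(
      "spike-in undetected in sample(s): ",
      paste(ct_matrix$sample_id[is.na(spike)], collapse = ", ")
    ))
  }
  reference_ct <- reference_ct %||% mean(spike)
  offset <- spike - reference_ct
  assays <- setdiff(names(ct_matrix), c("sample_id", exclude))
  for (a in assays) {
    ct_matrix[[a]] <- ct_matrix[[a]] - offset
  }
  # exact by construction, guard against float drift
  ct_matrix[[spike_assay]] <- rep(reference_ct, nrow(ct_matrix))
  ct_matrix
}

#' Relative expression by the 2^-ddCt method
#'
#' Per-sample `dCt = Ct(target) - mean Ct(reference assays)`; the calibrator
#' is the control-group mean dCt, so `ddCt = dCt - mean(dCt | control)` and
#' the reported value is `2^-ddCt`. With this calibrator the geometric mean
#' of the control group is exactly 1. Multiple reference assays (e.g.
#' cel-miR-39 combined with miR-16) enter as the arithmetic mean of their
#' Cts, i.e. the geometric mean of the linear quantities.
#'
#' @param ct_matrix Wide Ct tibble.
#' @param target Target assay name.
#' @param reference_assays Character vector of reference assay names
#'   (nonempty).
#' @param case_ids,control_ids Sample IDs of the two groups.
#' @return Tibble with `sample_id`, `group`, `delta_ct`, `delta_delta_ct`
#'   and `value` (= 2^-ddCt), one row per usable sample. Samples with any
#'   required Ct undetected are dropped with a warning. Attributes
#'   `reference_assays` and `calibrator` record the normalization.
#' @export
delta_delta_ct <- function(ct_matrix, target, reference_assays,
                           case_ids, control_ids) {
  validate_ct_matrix(ct_matrix)
  if (length(reference_assays) == 0) {
    abort("at least one reference assay is required")
  }
  needed <- c(target, reference_assays)
  missing_cols <- setdiff(needed, names(ct_matrix))
  if (length(missing_cols) > 0) {
    abort(paste0("assay(s) not present: ", paste(missing_cols, collapse = ", ")))
  }
  ids <- c(case_ids, control_ids)
  missing_ids <- setdiff(ids, ct_matrix$sample_id)
  if (length(missing_ids) > 0) {
    abort(paste0("sample(s) not present: ", paste(missing_ids, collapse = ", ")))
  }

  sub <- ct_matrix[match(ids, ct_matrix$sample_id), , drop = FALSE]
  ref_ct <- rowMeans(as.data.frame(sub[reference_assays]))
  dct <- sub[[target]] - ref_ct
  group <- c(rep("case", length(case_ids)), rep("control", length(control_ids)))

  usable <- !is.na(dct)
  if (any(!usable)) {
    warn(paste0(
      "delta_delta_ct: dropping ", sum(!usable),
      " sample(s) with undetected Ct: ",
      paste(sub$sample_id[!usable], collapse = ", ")
    ))
  }
  dct <- dct[usable]
  group <- group[usable]
  if (!any(group == "control")) {
    abort("no usable control samples to define the calibrator")
  }
  calibrator <- mean(dct[group == "control"])
  ddct <- dct - calibrator

  out <- tibble::tibble(
    sample_id = sub$sample_id[usable],
    group = group,
    delta_ct = dct,
    delta_delta_ct = ddct,
    value = 2^(-ddct)
  )
  attr(out, "reference_assays") <- reference_assays
  attr(out, "calibrator") <- "control-group mean delta-Ct"
  out
}
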