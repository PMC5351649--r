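# Internal helpers shared across the package.

# Columns of `data` treated as assay/miRNA measurements: everything that is
# not a reserved metadata column.
.meta_cols <- c(
  "sample_id", "pool_id", "group", "cohort", "subject_id", "condition",
  "age", "age_group", "gender", "smoking", "tnm_stage", "egfr"
)

measure_cols <- function(data, mirnas = NULL) {
  if (!is.null(mirnas)) {
    missing <- setdiff(mirnas, names(data))
    if (length(missing) > 0) {
      abort(paste0(
        "miRNA column(s) not present: ", paste(missing, collapse = ", ")
      ))
    }
    return(mirnas)
  }
  setdiff(names(data), .meta_cols)
}

check_group_column <- function(data, group_col = "group",
                               levels = c("case", "control")) {
  if (!group_col %in% names(data)) {
    abort(paste0("column '", group_col, "' is required"))
  }
  bad <- setdiff(unique(as.character(data[[group_col]])), levels)
  if (length(bad) > 0) {
    abort(paste0(
      "unknown ", group_col, " label(s): ", paste(bad, collapse = ", "),
      " (expected ", paste(levels, collapse = "/"), ")"
    ))
  }
  invisible(data)
}

check_both_groups <- function(labels, positive = "case") {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2 || !positive %in% labels) {
    abort("both case and control observations are required")
  }
  invisible(labels)
}

# Seeded evaluation that does not disturb the caller's RNG state.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

is_undetected <- function(ct) is.na(ct)
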