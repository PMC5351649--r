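#' Panel detection gate
#'
#' A panel well counts as detected when its Ct is below `max_ct` (37 by
#' default) and at least `nc_margin` cycles (5, inclusive) below the
#' no-template negative control. An undetected negative control imposes no
#' margin; an undetected sample well always fails.
#'
#' @param ct Ct value(s) in cycles, `NA` = undetected.
#' @param negative_control_ct Negative-control Ct (scalar or per-element),
#'   `NA` = undetected.
#' @param max_ct Upper Ct bound (exclusive).
#' @param nc_margin Required margin below the negative control (inclusive).
#' @return Logical vector.
#' @export
detection_gate <- function(ct, negative_control_ct, max_ct = 37,
                           nc_margin = 5) {
  nc <- rep_len(negative_control_ct, length(ct))
  ok_ct <- !is.na(ct) & ct < max_ct
  ok_nc <- is.na(nc) | (nc - ct >= nc_margin)
  ok_ct & ok_nc
}

#' Pool samples for the screening phase
#'
#' Randomly partitions each group's samples into pools of `pool_size`
#' (emulating equal-volume plasma pooling: the pooled concentration is the
#' arithmetic mean of the member concentrations). A final partial pool is
#' kept with a warning.
#'
#' @param data Concentration tibble (`sample_id`, `group`, miRNA columns).
#' @param pool_size Samples per pool.
#' @param mirnas Columns to pool; default all non-metadata columns.
#' @param group_col Column with `case`/`control` labels.
#' @param seed Seed making the random assignment reproducible.
#' @return List with `pools` (tibble: `pool_id`, `group`, `member_ids`
#'   list-column) and `pooled` (tibble: `pool_id`, `group`, pooled value per
#'   miRNA).
#' @export
make_pools <- function(data, pool_size = 10, mirnas = NULL,
                       group_col = "group", seed = NULL) {
  if (nrow(data) == 0) {
    abort("cannot pool an empty table")
  }
  check_group_column(data, group_col)
  mirnas <- measure_cols(data, mirnas)

  groups <- split(data$sample_id, as.character(data[[group_col]]))
  pools <- purrr::imap_dfr(groups, function(ids, grp) {
    shuffled <- with_seed_if(
      if (is.null(seed)) NULL else seed + match(grp, sort(names(groups))),
      sample(ids)
    )
    members <- split(shuffled, ceiling(seq_along(shuffled) / pool_size))
    if (length(shuffled) %% pool_size != 0) {
      warn(paste0(
        "make_pools: final ", grp, " pool has only ",
        length(shuffled) %% pool_size, " sample(s)"
      ))
    }
    tibble::tibble(
      pool_id = paste0(grp, "_pool_", seq_along(members)),
      group = grp,
      member_ids = unname(members)
    )
  })

  pooled <- purrr::pmap_dfr(
    pools,
    function(pool_id, group, member_ids) {
      rows <- data[match(member_ids, data$sample_id), mirnas, drop = FALSE]
      out <- tibble::tibble(pool_id = pool_id, group = group)
      dplyr::bind_cols(out, tibble::as_tibble(as.list(colMeans(rows))))
    }
  )
  list(pools = pools, pooled = pooled)
}

#' Pool-level fold-change screen
#'
#' Compares each case pool to the single control pool per miRNA. A miRNA
#' passes only when every case pool is more than `fc_threshold`-fold up
#' (all ratios > threshold) or down (all ratios < 1/threshold); mixed
#' directions are inconsistent and fail.
#'
#' @param pooled Pool-level expression tibble (`pool_id`, miRNA columns),
#'   e.g. `make_pools()$pooled` or panel-normalized pool expression.
#' @param case_pools Identifiers of the case pools (>= 1).
#' @param control_pool Identifier of the single control pool.
#' @param fc_threshold Fold-change gate (2 by default).
#' @param mirnas Columns to screen; default all non-metadata columns.
#' @param detected Optional named logical vector (by miRNA) from the
#'   detection gate; undetected miRNAs fail with `detected = FALSE`.
#' @return Tibble: `mirna`, `detected`, `fold_changes` (list-column, one
#'   ratio per case pool), `direction` (`up`/`down`/`inconsistent`), `pass`.
#' @export
pool_screen <- function(pooled, case_pools, control_pool, fc_threshold = 2,
                        mirnas = NULL, detected = NULL) {
  if (length(case_pools) < 1 || length(control_pool) != 1) {
    abort("need >= 1 case pool and exactly 1 control pool")
  }
  missing <- setdiff(c(case_pools, control_pool), pooled$pool_id)
  if (length(missing) > 0) {
    abort(paste0("pool(s) not present: ", paste(missing, collapse = ", ")))
  }
  mirnas <- measure_cols(pooled, mirnas)
  case_rows <- match(case_pools, pooled$pool_id)
  ctrl_row <- match(control_pool, pooled$pool_id)

  purrr::map_dfr(mirnas, function(m) {
    det <- if (is.null(detected)) TRUE else isTRUE(detected[[m]])
    if (!det) {
      return(tibble::tibble(
        mirna = m, detected = FALSE, fold_changes = list(numeric(0)),
        direction = "inconsistent", pass = FALSE
      ))
    }
    ctrl <- pooled[[m]][ctrl_row]
    if (is.na(ctrl) || ctrl == 0) {
      abort(paste0("control pool expression is zero/undetected for ", m))
    }
    fc <- pooled[[m]][case_rows] / ctrl
    direction <- if (all(!is.na(fc)) && all(fc > fc_threshold)) {
      "up"
    } else if (all(!is.na(fc)) && all(fc < 1 / fc_threshold)) {
      "down"
    } else {
      "inconsistent"
    }
    tibble::tibble(
      mirna = m, detected = TRUE, fold_changes = list(fc),
      direction = direction, pass = direction != "inconsistent"
    )
  })
}

#' qRT-PCR verification of screening candidates
#'
#' The phase-2 filter: per candidate miRNA, the group fold change
#' `mean(case)/mean(control)` and a two-sided Mann-Whitney p-value. A
#' candidate passes when `FC > fc_up` or `FC < fc_down`, and `p < alpha`.
#'
#' @param data Concentration or relative-expression tibble with `group` and
#'   one numeric column per miRNA.
#' @param candidates miRNA columns to verify; default all non-metadata
#'   columns.
#' @param fc_up,fc_down Fold-change gates (1.5 and 0.66).
#' @param alpha Significance gate (0.05).
#' @param group_col Column with `case`/`control` labels.
#' @return Tibble: `mirna`, `mean_case`, `mean_control`, `fold_change`,
#'   `p_value`, `pass`.
#' @export
verify_candidates <- function(data, candidates = NULL, fc_up = 1.5,
                              fc_down = 0.66, alpha = 0.05,
                              group_col = "group") {
  check_group_column(data, group_col)
  candidates <- measure_cols(data, candidates)
  is_case <- data[[group_col]] == "case"
  if (!any(is_case) || all(is_case)) {
    abort("both case and control samples are required")
  }
  purrr::map_dfr(candidates, function(m) {
    a <- data[[m]][is_case]
    b <- data[[m]][!is_case]
    m0 <- mean(b, na.rm = TRUE)
    if (is.na(m0) || m0 == 0) {
      abort(paste0("control mean is zero for ", m, "; fold change undefined"))
    }
    fc <- mean(a, na.rm = TRUE) / m0
    p <- mann_whitney(a, b)$p_value
    tibble::tibble(
      mirna = m,
      mean_case = mean(a, na.rm = TRUE),
      mean_control = m0,
      fold_change = fc,
      p_value = p,
      pass = (fc > fc_up || fc < fc_down) && p < alpha
    )
  })
}

#' Full phase-1 screen from a pool-level Ct matrix
#'
#' Chains the panel workflow on pooled samples: detection gate against the
#' negative-control well, global-mean relative quantification
#' (`dCt = Ct - mean Ct of the normalizer assays` per pool, expression
#' `2^-dCt`), then the pool fold-change gate.
#'
#' @param ct_pools Wide Ct tibble with `sample_id` = pool identifiers,
#'   assay columns including `negative_control`.
#' @param case_pools,control_pool Pool identifiers.
#' @param normalizer_assays Assays averaged into the per-pool normalizer Ct;
#'   `NULL` (default) uses the global mean of all detected panel assays.
#' @param max_ct,nc_margin Detection-gate parameters.
#' @param fc_threshold Pool fold-change gate.
#' @param exclude_assays Columns that are not panel miRNAs (spike-in,
#'   negative control).
#' @return As [pool_screen()], with `detected` reflecting the gate in all
#'   pools.
#' @export
screen_panel <- function(ct_pools, case_pools, control_pool,
                         normalizer_assays = NULL, max_ct = 37,
                         nc_margin = 5, fc_threshold = 2,
                         exclude_assays = c("negative_control", "cel_mir_39")) {
  validate_ct_matrix(ct_pools, "pool Ct matrix")
  if (!"negative_control" %in% names(ct_pools)) {
    abort("pool Ct matrix must contain a 'negative_control' assay")
  }
  rows <- match(c(case_pools, control_pool), ct_pools$sample_id)
  if (anyNA(rows)) {
    abort("case/control pool(s) missing from the Ct matrix")
  }
  sub <- ct_pools[rows, , drop = FALSE]
  assays <- setdiff(names(sub), c("sample_id", exclude_assays))
  nc <- sub$negative_control

  detected <- vapply(
    assays,
    function(a) all(detection_gate(sub[[a]], nc, max_ct, nc_margin)),
    logical(1)
  )

  norm_assays <- normalizer_assays %||% names(detected)[detected]
  if (length(norm_assays) == 0) {
    abort("no detected assays available as normalizers")
  }
  norm_ct <- rowMeans(as.data.frame(sub[norm_assays]))
  expr <- tibble::tibble(pool_id = sub$sample_id)
  for (a in assays) {
    expr[[a]] <- 2^(-(sub[[a]] - norm_ct))
  }
  pool_screen(
    expr, case_pools, control_pool,
    fc_threshold = fc_threshold, mirnas = assays, detected = as.list(detected)
  )
}
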