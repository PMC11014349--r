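#' Comparative 2^-ddCt expression ratio
#'
#' The comparative Ct method: `dCt = Ct(target) - Ct(reference)` within each
#' sample, and the expression ratio of treatment over control is
#' `2^-(dCt_treatment - dCt_control)`.
#'
#' @param ct_target_treat,ct_ref_treat Target/reference-gene Ct in the
#'   treated sample.
#' @param ct_target_ctrl,ct_ref_ctrl Target/reference-gene Ct in the control
#'   sample.
#' @return Expression ratio (control = 1).
#' @examples
#' ddct_ratio(22, 20, 20, 20) # 0.25
#' @export
ddct_ratio <- function(ct_target_treat, ct_ref_treat, ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_treat, ct_ref_treat, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("All Ct values must be finite and positive.", class = "mirmimic_value_error")
  }
  2^-((ct_target_treat - ct_ref_treat) - (ct_target_ctrl - ct_ref_ctrl))
}

#' Summarise qPCR knockdown from a Ct table
#'
#' Per biological replicate, technical replicates are first averaged at the
#' Ct level; dCt is then computed per gene against the reference gene of the
#' same (condition, replicate); ddCt is taken against the mean control-
#' condition dCt; and the per-replicate ratios `2^-ddCt` are averaged per
#' (gene, condition). The control condition's mean ratio is 1 by construction
#' for noise-free data.
#'
#' @param ct_table Data frame with columns `condition`, `gene`, `ct`,
#'   `replicate` (and optionally `sample`); one or more rows per
#'   (condition, gene, replicate) — extra rows are technical replicates.
#' @param ref_gene Reference (housekeeping) gene name, e.g. `"HPRT1"`.
#' @param control_condition Name of the control condition (baseline = 1).
#' @return A tibble `gene`, `condition`, `ratio_mean`, `ratio_sd`, `n`, of
#'   class `mimic_fold_change`.
#' @export
summarize_knockdown <- function(ct_table, ref_gene, control_condition) {
  ct_table <- as_tibble(ct_table)
  stopifnot(all(c("condition", "gene", "ct", "replicate") %in% names(ct_table)))
  if (!control_condition %in% ct_table$condition) {
    abort(sprintf("Control condition '%s' absent from the Ct table.", control_condition),
          class = "mirmimic_pairing_error")
  }
  if (!ref_gene %in% ct_table$gene) {
    abort(sprintf("Reference gene '%s' absent from the Ct table.", ref_gene),
          class = "mirmimic_pairing_error")
  }
  # technical replicates -> one Ct per (condition, gene, biological replicate)
  ct <- dplyr::summarise(
    dplyr::group_by(ct_table, .data$condition, .data$gene, .data$replicate),
    ct = mean(.data$ct), .groups = "drop"
  )
  refs <- ct[ct$gene == ref_gene, c("condition", "replicate", "ct")]
  names(refs)[names(refs) == "ct"] <- "ct_ref"
  dat <- dplyr::left_join(ct[ct$gene != ref_gene, ], refs,
                          by = c("condition", "replicate"))
  if (anyNA(dat$ct_ref)) {
    bad <- dat[is.na(dat$ct_ref), c("condition", "replicate")]
    abort(sprintf("Missing reference-gene record for condition '%s', replicate %s.",
                  bad$condition[1], bad$replicate[1]),
          class = "mirmimic_pairing_error")
  }
  dat$dct <- dat$ct - dat$ct_ref
  ctrl <- dplyr::summarise(
    dplyr::group_by(dat[dat$condition == control_condition, ], .data$gene),
    dct_ctrl = mean(.data$dct), .groups = "drop"
  )
  dat <- dplyr::left_join(dat, ctrl, by = "gene")
  if (anyNA(dat$dct_ctrl)) {
    abort("A gene lacks control-condition records.", class = "mirmimic_pairing_error")
  }
  dat$ratio <- 2^-(dat$dct - dat$dct_ctrl)
  out <- dplyr::summarise(
    dplyr::group_by(dat, .data$gene, .data$condition),
    ratio_mean = mean(.data$ratio),
    ratio_sd = stats::sd(.data$ratio),
    n = dplyr::n(),
    .groups = "drop"
  )
  structure(out, class = c("mimic_fold_change", class(out)),
            ref_gene = ref_gene, control_condition = control_condition)
}

#' Filter a differential-expression table
#'
#' Keeps genes passing the fold-change and FDR thresholds. Conventions are
#' fixed: the fold-change boundary is inclusive (`|log2fc| >= l2fc_cut`), the
#' FDR boundary strict (`fdr < fdr_cut`).
#'
#' @param degs Data frame `gene`, `log2fc`, `fdr`.
#' @param l2fc_cut Absolute log2-fold-change threshold (default 1.3).
#' @param fdr_cut False-discovery-rate threshold (default 0.05).
#' @param direction `"DOWN"` (log2fc <= -cut), `"UP"` (>= +cut) or `"BOTH"`.
#' @return The filtered tibble.
#' @examples
#' degs <- tibble::tibble(gene = c("a", "b"), log2fc = c(-2, -1), fdr = 0.01)
#' filter_degs(degs, direction = "DOWN")
#' @export
filter_degs <- function(degs, l2fc_cut = 1.3, fdr_cut = 0.05,
                        direction = c("BOTH", "DOWN", "UP")) {
  direction <- match.arg(direction)
  degs <- as_tibble(degs)
  stopifnot(all(c("gene", "log2fc", "fdr") %in% names(degs)))
  if (nrow(degs) && (any(degs$fdr < 0, na.rm = TRUE) || any(degs$fdr > 1, na.rm = TRUE))) {
    abort("FDR values must lie in [0, 1].", class = "mirmimic_value_error")
  }
  keep <- switch(direction,
    DOWN = degs$log2fc <= -l2fc_cut,
    UP   = degs$log2fc >= l2fc_cut,
    BOTH = abs(degs$log2fc) >= l2fc_cut
  ) & degs$fdr < fdr_cut
  degs[which(keep), ]
}

#' Dual-luciferase percent relative activity
#'
#' Per well, the Renilla signal is normalised to the firefly signal of the
#' same well (correcting for plasmid loading and cell count); activity is
#' expressed as a percentage of the mean normalised ratio across negative-
#' control wells, so the negative-control baseline is 100%.
#'
#' @param luc_table Data frame `well`, `group`, `fluc`, `rluc`; `group` must
#'   include at least one `"NEG_CONTROL"` row.
#' @return The input with `ratio` and `percent_activity` columns.
#' @examples
#' tbl <- tibble::tibble(well = c("A1", "A2", "B1"),
#'                       group = c("NEG_CONTROL", "NEG_CONTROL", "TREATED"),
#'                       fluc = c(100, 100, 100), rluc = c(200, 200, 100))
#' luciferase_percent(tbl)
#' @export
luciferase_percent <- function(luc_table) {
  luc_table <- as_tibble(luc_table)
  stopifnot(all(c("well", "group", "fluc", "rluc") %in% names(luc_table)))
  if (any(!is.finite(luc_table$fluc)) || any(luc_table$fluc <= 0)) {
    abort("F-Luc signals must be finite and positive.", class = "mirmimic_value_error")
  }
  if (!any(luc_table$group == "NEG_CONTROL")) {
    abort("At least one NEG_CONTROL well is required.",
          class = "mirmimic_configuration_error")
  }
  luc_table$ratio <- luc_table$rluc / luc_table$fluc
  baseline <- mean(luc_table$ratio[luc_table$group == "NEG_CONTROL"])
  luc_table$percent_activity <- 100 * luc_table$ratio / baseline
  luc_table
}
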