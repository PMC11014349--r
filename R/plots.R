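#' @importFrom ggplot2 ggplot aes geom_tile geom_text geom_col geom_errorbar
#'   geom_hline geom_point facet_wrap labs scale_fill_brewer theme_minimal
#'   position_dodge
NULL

#' Modification map of a duplex
#'
#' Tile plot of both strands aligned on guide coordinates: each residue is
#' coloured by its sugar chemistry, phosphorothioate linkages are marked with
#' an asterisk, and mismatch/deletion positions are outlined by the pairing
#' state shown on the guide row.
#'
#' @param object A `mimic_duplex`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mimic_duplex <- function(object, ...) {
  g <- tidy(object$guide)
  g$x <- g$position
  g$strand <- "guide (5'->3')"
  segs <- purrr::map_dfr(seq_along(object$passenger_segments), function(i) {
    d <- tidy(object$passenger_segments[[i]])
    fac <- object$passenger_segments[[i]]$facing
    d$x <- if (!is.null(fac)) fac else strand_length(object$guide) - d$position + 1L
    # residues beyond the duplex region (overhang/loop) trail off to the left
    miss <- which(is.na(d$x))
    if (length(miss)) d$x[miss] <- -seq_along(miss) + 1L
    d$strand <- paste0("passenger ", i, " (3'<-5')")
    d
  })
  dat <- rbind(g, segs)
  dat$ps <- !is.na(dat$linkage3) & dat$linkage3 == "PS"
  ggplot(dat, aes(x = .data$x, y = .data$strand, fill = .data$sugar)) +
    geom_tile(colour = "grey30", linewidth = 0.2) +
    geom_text(aes(label = .data$base), size = 2.6) +
    geom_text(data = dat[dat$ps, ], aes(label = "*"), nudge_y = 0.38, size = 3) +
    scale_fill_brewer(palette = "Pastel1") +
    labs(x = "guide coordinate", y = NULL, fill = "2' sugar",
         title = if (!is.na(object$mimic_id)) object$mimic_id else NULL,
         subtitle = "* = phosphorothioate linkage") +
    theme_minimal()
}

#' Knockdown bar plot
#'
#' Mean expression ratio (control = 1) per gene and condition with standard-
#' deviation error bars.
#'
#' @param fold_changes Output of [summarize_knockdown()].
#' @return A ggplot.
#' @export
plot_knockdown <- function(fold_changes) {
  stopifnot(all(c("gene", "condition", "ratio_mean") %in% names(fold_changes)))
  ggplot(fold_changes,
         aes(x = .data$condition, y = .data$ratio_mean, fill = .data$gene)) +
    geom_col(position = position_dodge(width = 0.85), width = 0.8) +
    geom_errorbar(aes(ymin = .data$ratio_mean - .data$ratio_sd,
                      ymax = .data$ratio_mean + .data$ratio_sd),
                  position = position_dodge(width = 0.85), width = 0.25) +
    geom_hline(yintercept = 1, linetype = 2) +
    labs(x = NULL, y = "expression ratio (2^-ddCt, control = 1)") +
    theme_minimal()
}

#' @describeIn summarize_deg_matches Bar plot of downregulated DEGs carrying
#'   at least one antisense- or sense-seed site.
#' @param object A `mimic_match_summary`.
#' @param ... Unused.
#' @export
autoplot.mimic_match_summary <- function(object, ...) {
  dat <- tidy(object)
  ggplot(dat, aes(x = .data$origin, y = .data$n_genes_with_site, fill = .data$origin)) +
    geom_col(width = 0.6, show.legend = FALSE) +
    labs(x = "seed origin", y = "downregulated DEGs with >= 1 site") +
    theme_minimal()
}

#' Luciferase percent-activity plot
#'
#' Per-well percent relative R-Luc activity with the 100% negative-control
#' baseline.
#'
#' @param luc Output of [luciferase_percent()].
#' @return A ggplot.
#' @export
plot_luciferase <- function(luc) {
  stopifnot("percent_activity" %in% names(luc))
  ggplot(luc, aes(x = .data$group, y = .data$percent_activity)) +
    geom_hline(yintercept = 100, linetype = 2, colour = "grey50") +
    geom_point(position = ggplot2::position_jitter(width = 0.08, height = 0), size = 2) +
    labs(x = NULL, y = "% relative R-Luc activity (F-Luc normalised)") +
    theme_minimal()
}
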