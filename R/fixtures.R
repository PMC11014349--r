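mirmimic_local_seed <- function(seed, code) {
  # Fixture contract: R's Mersenne-Twister with inversion normals, seeded per
  # call, caller's RNG state untouched.
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate a 3'UTR sequence set with planted seed sites
#'
#' Produces one synthetic DNA sequence per gene whose background is free of
#' every scanned site (rejection sampling: windows containing an accidental
#' occurrence are regenerated), then inserts the requested number of sites at
#' non-overlapping positions. Planted counts are therefore exact by
#' construction, so scan results can be asserted against the emitted truth.
#'
#' @param planted Data frame `gene`, `origin`, `n_sites` — sites to plant per
#'   gene and strand origin. Genes may repeat across origins; genes absent
#'   from `planted` but listed in `genes` get zero sites.
#' @param seeds Seed table (`origin`, `heptamer`); defaults to the miR-200c
#'   guide and passenger seeds.
#' @param genes Character vector of gene ids; defaults to the genes in
#'   `planted`.
#' @param length Background sequence length per gene (default 500 nt).
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @return List with `utrs` (tibble `id`, `sequence`), `truth` (tibble
#'   `gene`, `origin`, `site`, `n_sites`) and `seed`.
#' @export
gen_utr_set <- function(planted, seeds = default_seeds(), genes = NULL,
                        length = 500L, seed = 1L) {
  planted <- as_tibble(planted)
  stopifnot(all(c("gene", "origin", "n_sites") %in% names(planted)))
  genes <- genes %||% unique(planted$gene)
  sites <- stats::setNames(target_site(seeds$heptamer), seeds$origin)
  site_len <- nchar(sites)
  max_planted <- if (nrow(planted)) max(planted$n_sites) else 0L
  if (length < max(site_len) * max(1L, max_planted)) {
    abort("Sequence length too short to pack the planted sites.",
          class = "mirmimic_capacity_error")
  }
  mirmimic_local_seed(seed, {
    utrs <- purrr::map_dfr(genes, function(g) {
      want <- planted[planted$gene == g, ]
      tibble(id = g, sequence = plant_one(want, sites, length))
    })
    truth <- tidyr::expand_grid(gene = genes, origin = names(sites))
    truth$site <- unname(sites[truth$origin])
    truth <- dplyr::left_join(truth, planted, by = c("gene", "origin"))
    truth$n_sites[is.na(truth$n_sites)] <- 0L
    list(utrs = utrs, truth = truth[, c("gene", "origin", "site", "n_sites")],
         seed = as.integer(seed))
  })
}

plant_one <- function(want, sites, len, max_tries = 200L) {
  all_sites <- unname(sites)
  clean_background <- function() {
    for (i in seq_len(max_tries)) {
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
      if (sum(vapply(all_sites, function(x) scan_utr(s, x), integer(1))) == 0L) return(s)
    }
    abort("Could not generate a site-free background.", class = "mirmimic_capacity_error")
  }
  for (attempt in seq_len(max_tries)) {
    s <- clean_background()
    chars <- strsplit(s, "")[[1]]
    taken <- integer(0)
    ok <- TRUE
    if (nrow(want)) {
      for (i in seq_len(nrow(want))) {
        site <- sites[[want$origin[i]]]
        k <- nchar(site)
        for (j in seq_len(want$n_sites[i])) {
          placed <- FALSE
          for (try in seq_len(max_tries)) {
            start <- sample.int(len - k + 1L, 1L)
            span <- seq.int(start, start + k - 1L)
            if (!any(span %in% taken)) {
              chars[span] <- strsplit(site, "")[[1]]
              taken <- c(taken, span)
              placed <- TRUE
              break
            }
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (!ok) next
    out <- paste(chars, collapse = "")
    # insertion junctions may fabricate extra occurrences; verify and retry
    counts <- vapply(names(sites), function(o) scan_utr(out, sites[[o]]), integer(1))
    wanted <- vapply(names(sites), function(o) {
      w <- want$n_sites[want$origin == o]
      if (length(w)) as.integer(w[1]) else 0L
    }, integer(1))
    if (identical(counts, wanted)) return(out)
  }
  abort("Could not pack the planted sites without collisions.",
        class = "mirmimic_capacity_error")
}

#' Default seeds used by the fixture generators
#'
#' The guide (antisense) and passenger (sense) seeds of the reference
#' miR-200c duplex.
#' @return Tibble `origin`, `heptamer`.
#' @export
default_seeds <- function() {
  tibble(origin = c("ANTISENSE", "SENSE"), heptamer = c("AAUACUG", "UCGUCAU"))
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Control-condition target Ct values are drawn around gene-specific base
#' levels; treated-condition target Ct values are offset by `-log2(ratio)` so
#' the comparative 2^-ddCt recovers the planted ratio exactly at zero noise;
#' the reference gene is unshifted. Gaussian noise of `noise_sd` cycles is
#' added independently to every record.
#'
#' @param true_ratios Data frame `gene`, `condition`, `ratio` (> 0) for the
#'   treated conditions; the control condition always has ratio 1.
#' @param ref_gene Reference gene name (default `"HPRT1"`).
#' @param control_condition Control condition name (default `"control"`).
#' @param noise_sd Ct noise standard deviation in cycles (default 0.2, a
#'   typical plate-to-plate spread; set 0 for exact recovery).
#' @param n_reps Biological replicates per condition (default 3).
#' @param seed Integer RNG seed.
#' @return List with `ct` (tibble `sample`, `condition`, `gene`, `ct`,
#'   `replicate`), `truth` (the completed ratio table) and `seed`.
#' @export
gen_ct_table <- function(true_ratios, ref_gene = "HPRT1",
                         control_condition = "control", noise_sd = 0.2,
                         n_reps = 3L, seed = 1L) {
  true_ratios <- as_tibble(true_ratios)
  stopifnot(all(c("gene", "condition", "ratio") %in% names(true_ratios)))
  if (any(true_ratios$ratio <= 0)) {
    abort("Planted ratios must be positive.", class = "mirmimic_value_error")
  }
  if (control_condition %in% true_ratios$condition &&
      any(true_ratios$ratio[true_ratios$condition == control_condition] != 1)) {
    abort("The control condition must have ratio 1.", class = "mirmimic_value_error")
  }
  genes <- unique(true_ratios$gene)
  conditions <- union(control_condition, unique(true_ratios$condition))
  grid <- tidyr::expand_grid(gene = genes, condition = conditions)
  grid <- dplyr::left_join(grid, true_ratios, by = c("gene", "condition"))
  grid$ratio[grid$condition == control_condition] <- 1
  if (anyNA(grid$ratio)) {
    abort("`true_ratios` must cover every gene for every treated condition.",
          class = "mirmimic_value_error")
  }
  mirmimic_local_seed(seed, {
    base_ct <- stats::setNames(stats::runif(length(genes), 20, 26), genes)
    ref_ct <- 20
    rows <- tidyr::expand_grid(condition = conditions, replicate = seq_len(n_reps))
    ct <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      cond <- rows$condition[i]
      rep <- rows$replicate[i]
      r <- grid$ratio[grid$condition == cond]
      g <- grid$gene[grid$condition == cond]
      tibble(
        sample = sprintf("%s_rep%d", cond, rep),
        condition = cond,
        gene = c(g, ref_gene),
        ct = c(base_ct[g] - log2(r), ref_ct) + stats::rnorm(length(g) + 1L, 0, noise_sd),
        replicate = rep
      )
    })
    list(ct = ct, truth = grid, seed = as.integer(seed))
  })
}

#' Generate a differential-expression table with known filter outcomes
#'
#' Draws log2 fold changes and FDR values from ranges straddling the default
#' 1.3 / 0.05 thresholds and records, per gene, which filter directions it
#' passes, so [filter_degs()] output can be asserted against the truth.
#'
#' @param n Number of genes.
#' @param frac_down Fraction of genes drawn with negative fold change.
#' @param l2fc_range,fdr_range Ranges the magnitudes are drawn from
#'   (defaults straddle the 1.3 and 0.05 cutoffs).
#' @param l2fc_cut,fdr_cut Thresholds used for the truth bookkeeping.
#' @param seed Integer RNG seed.
#' @return List with `degs` (tibble `gene`, `log2fc`, `fdr`), `truth`
#'   (adds logical `pass_down`, `pass_up`, `pass_both`) and `seed`.
#' @export
gen_deg_table <- function(n = 100L, frac_down = 0.5, l2fc_range = c(0.5, 2.5),
                          fdr_range = c(0, 0.1), l2fc_cut = 1.3, fdr_cut = 0.05,
                          seed = 1L) {
  mirmimic_local_seed(seed, {
    sign <- ifelse(stats::runif(n) < frac_down, -1, 1)
    degs <- tibble(
      gene = sprintf("gene%04d", seq_len(n)),
      log2fc = sign * stats::runif(n, l2fc_range[1], l2fc_range[2]),
      fdr = stats::runif(n, fdr_range[1], fdr_range[2])
    )
    truth <- degs
    truth$pass_down <- truth$log2fc <= -l2fc_cut & truth$fdr < fdr_cut
    truth$pass_up <- truth$log2fc >= l2fc_cut & truth$fdr < fdr_cut
    truth$pass_both <- abs(truth$log2fc) >= l2fc_cut & truth$fdr < fdr_cut
    list(degs = degs, truth = truth, seed = as.integer(seed))
  })
}
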