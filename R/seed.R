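#' Extract the seed heptamer of a strand
#'
#' The seed region comprises nucleotides 2-8 of the source strand — the
#' principal determinant of target recognition for the guide (antisense)
#' strand, and of off-target regulation when the passenger (sense) strand is
#' loaded instead.
#'
#' @param strand A [mimic_strand] (length >= 8) or a plain sequence string.
#' @param origin `"ANTISENSE"` (guide) or `"SENSE"` (passenger).
#' @return A tibble `origin`, `heptamer` (one row).
#' @examples
#' extract_seed(make_strand("UAAUACUGCCGGGUAAUGAUGGA")) # AAUACUG
#' @export
extract_seed <- function(strand, origin = c("ANTISENSE", "SENSE")) {
  origin <- match.arg(origin)
  seq <- if (inherits(strand, "mimic_strand")) strand_sequence(strand) else toupper(strand)
  if (nchar(seq) < 8L) {
    abort("Seed extraction requires a strand of length >= 8.",
          class = "mirmimic_length_error")
  }
  hept <- gsub("T", "U", substr(seq, 2L, 8L))
  if (grepl("[^ACGU]", hept)) {
    abort("Seed region contains a non-ACGU character.", class = "mirmimic_alphabet_error")
  }
  tibble(origin = origin, heptamer = hept)
}

#' DNA target site of a seed
#'
#' The reverse complement of the seed heptamer, transliterated to the DNA
#' alphabet — the exact motif searched in sense-strand 3'UTR sequence.
#'
#' @param seed A seed tibble from [extract_seed()], or a heptamer string.
#' @return Character vector of DNA site(s).
#' @examples
#' target_site("AAUACUG") # "CAGTATT"
#' @export
target_site <- function(seed) {
  hept <- if (is.data.frame(seed)) seed$heptamer else toupper(seed)
  vapply(hept, function(h) {
    bases <- rev(strsplit(h, "")[[1]])
    comp <- c(A = "T", U = "A", T = "A", G = "C", C = "G")[bases]
    if (anyNA(comp)) abort("Invalid seed alphabet.", class = "mirmimic_alphabet_error")
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Count exact site occurrences in UTR sequences
#'
#' Exact (zero-mismatch) occurrence counts of a DNA site in each UTR
#' sequence; overlapping occurrences are counted, and positions containing
#' `N` never match. Matching is delegated to Biostrings pattern matching.
#'
#' @param utrs Data frame with columns `id` and `sequence` (DNA, may contain
#'   `N`), e.g. from [read_fasta()] or [gen_utr_set()]; a single sequence
#'   string also works.
#' @param site DNA site sequence (e.g. from [target_site()]).
#' @return For a data frame input: the input with an `n_sites` column.
#'   For a single string: an integer count.
#' @examples
#' scan_utr("AACAGTATTGG", "CAGTATT") # 1
#' scan_utr("AAAA", "AA")             # 3 (overlaps counted)
#' @export
scan_utr <- function(utrs, site) {
  stopifnot(is.character(site), length(site) == 1L, nchar(site) >= 1L)
  count1 <- function(seq) {
    Biostrings::countPattern(site, Biostrings::DNAString(toupper(seq)),
                             max.mismatch = 0, fixed = TRUE)
  }
  if (is.character(utrs) && length(utrs) == 1L) {
    return(count1(utrs))
  }
  utrs <- as_tibble(utrs)
  stopifnot(all(c("id", "sequence") %in% names(utrs)))
  utrs$n_sites <- vapply(utrs$sequence, count1, integer(1), USE.NAMES = FALSE)
  utrs
}

#' Intersect seed matches with downregulated DEGs
#'
#' Implements the off-target readout of the transcriptome analysis: among
#' downregulated differentially expressed genes (log2 fold change at or below
#' `-l2fc_cut` and FDR strictly below `fdr_cut`), counts how many have at
#' least one exact 3'UTR site complementary to each strand's seed. An excess
#' of antisense-seed matches over sense-seed matches indicates that activity
#' is dominated by the intended guide strand.
#'
#' @param degs Data frame `gene`, `log2fc`, `fdr`.
#' @param utrs Data frame `id`, `sequence`; genes with multiple UTR records
#'   count as matched if any record carries a site. Genes without a UTR
#'   record are counted as zero-site (with a warning).
#' @param seeds Seed table (`origin`, `heptamer`) — typically the row-bound
#'   output of [extract_seed()] for the guide and passenger strands.
#' @param l2fc_cut,fdr_cut DEG thresholds (defaults 1.3 and 0.05).
#' @param orientation `"target_site"` (search the reverse complement of the
#'   seed in sense-strand UTR DNA; the default) or `"seed"` (search the seed
#'   itself, transliterated to DNA).
#' @return A `mimic_match_summary`: tibble `origin`, `site`,
#'   `n_genes_with_site`, `n_sites_total`, `genes` (list column), with the
#'   downregulated DEG table in `attr(, "downregulated")`.
#' @export
summarize_deg_matches <- function(degs, utrs, seeds, l2fc_cut = 1.3, fdr_cut = 0.05,
                                  orientation = c("target_site", "seed")) {
  orientation <- match.arg(orientation)
  degs <- as_tibble(degs)
  utrs <- as_tibble(utrs)
  stopifnot(all(c("gene", "log2fc", "fdr") %in% names(degs)))
  down <- filter_degs(degs, l2fc_cut = l2fc_cut, fdr_cut = fdr_cut, direction = "DOWN")
  missing <- setdiff(down$gene, utrs$id)
  if (length(missing)) {
    warn(sprintf("%d downregulated gene(s) have no UTR record; counted as zero-site.",
                 length(missing)))
  }
  out <- purrr::map_dfr(seq_len(nrow(seeds)), function(i) {
    site <- if (orientation == "target_site") target_site(seeds$heptamer[i])
            else gsub("U", "T", toupper(seeds$heptamer[i]))
    scanned <- if (nrow(utrs)) scan_utr(utrs[utrs$id %in% down$gene, ], site)
               else tibble(id = character(), sequence = character(), n_sites = integer())
    per_gene <- dplyr::summarise(dplyr::group_by(scanned, .data$id),
                                 n_sites = sum(.data$n_sites), .groups = "drop")
    hits <- per_gene[per_gene$n_sites > 0L, ]
    tibble(
      origin = seeds$origin[i],
      site = site,
      n_genes_with_site = nrow(hits),
      n_sites_total = as.integer(sum(per_gene$n_sites)),
      genes = list(sort(hits$id))
    )
  })
  structure(out, class = c("mimic_match_summary", class(out)),
            downregulated = down)
}

#' @describeIn tidy-mirmimic Match summary without the list column.
#' @export
tidy.mimic_match_summary <- function(x, ...) {
  out <- as_tibble(x)[, c("origin", "site", "n_genes_with_site", "n_sites_total")]
  out
}

#' @describeIn tidy-mirmimic One-row overview of a match summary: number of
#'   downregulated DEGs and the antisense:sense matched-gene counts.
#' @export
glance.mimic_match_summary <- function(x, ...) {
  anti <- x$n_genes_with_site[x$origin == "ANTISENSE"]
  sens <- x$n_genes_with_site[x$origin == "SENSE"]
  tibble(
    n_downregulated = nrow(attr(x, "downregulated")),
    antisense_genes = if (length(anti)) anti[1] else NA_integer_,
    sense_genes = if (length(sens)) sens[1] else NA_integer_
  )
}
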