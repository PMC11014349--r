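#' Read a FASTA sequence set
#'
#' Reads (possibly line-wrapped, mixed-case) FASTA into a UTR-record table;
#' sequences are upper-cased on read. DNA with `N` is accepted.
#'
#' @param path FASTA file path.
#' @return Tibble `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "mirmimic_format_error")
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(sprintf("Malformed FASTA '%s': %s", path, conditionMessage(e)),
                              class = "mirmimic_format_error")
  )
  tibble(
    id = sub("\\s.*$", "", names(set)),
    sequence = unname(toupper(as.character(set)))
  )
}

#' Write a sequence table to FASTA
#' @param utrs Tibble `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(utrs, path) {
  stopifnot(all(c("id", "sequence") %in% names(utrs)))
  writeLines(paste0(">", utrs$id, "\n", utrs$sequence), path)
  invisible(path)
}

read_table_checked <- function(path, required, reader, what) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "mirmimic_format_error")
  }
  tbl <- tryCatch(reader(path), error = function(e) {
    abort(sprintf("Malformed %s table '%s': %s", what, path, conditionMessage(e)),
          class = "mirmimic_format_error")
  })
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(sprintf("%s table '%s' is missing column(s): %s", what, path,
                  paste(missing, collapse = ", ")),
          class = "mirmimic_format_error")
  }
  as_tibble(tbl)
}

#' Read a qPCR Ct table (CSV)
#'
#' Expects columns `condition`, `gene`, `ct`, `replicate` (plus optional
#' `sample`); delimiter is sniffed from the extension (`.csv` comma,
#' otherwise tab).
#'
#' @param path CSV/TSV file path.
#' @return Tibble of Ct records.
#' @export
read_ct_csv <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    function(p) readr::read_csv(p, show_col_types = FALSE)
  } else {
    function(p) readr::read_tsv(p, show_col_types = FALSE)
  }
  tbl <- read_table_checked(path, c("condition", "gene", "ct", "replicate"), reader, "Ct")
  if (!is.numeric(tbl$ct) || any(!is.finite(tbl$ct)) || any(tbl$ct <= 0)) {
    abort(sprintf("Ct table '%s': `ct` must be positive numbers.", path),
          class = "mirmimic_format_error")
  }
  tbl
}

#' Read a differential-expression table (TSV)
#'
#' Expects columns `gene`, `log2fc`, `fdr`.
#' @param path TSV file path.
#' @return Tibble of DEG records.
#' @export
read_deg_tsv <- function(path) {
  tbl <- read_table_checked(path, c("gene", "log2fc", "fdr"),
                            function(p) readr::read_tsv(p, show_col_types = FALSE), "DEG")
  if (any(tbl$fdr < 0 | tbl$fdr > 1, na.rm = TRUE)) {
    abort(sprintf("DEG table '%s': `fdr` must lie in [0, 1].", path),
          class = "mirmimic_format_error")
  }
  tbl
}

#' Read a dual-luciferase plate table (TSV)
#'
#' Expects columns `well`, `group`, `fluc`, `rluc`.
#' @param path TSV file path.
#' @return Tibble of luciferase records.
#' @export
read_luc_tsv <- function(path) {
  read_table_checked(path, c("well", "group", "fluc", "rluc"),
                     function(p) readr::read_tsv(p, show_col_types = FALSE), "luciferase")
}
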