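#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Controlled vocabularies for residue chemistry. Every residue carries exactly
# one sugar modification; the 3'-terminal residue has no 3' linkage (NA).
SUGAR_MODS <- c("RIBO", "OME", "FLU", "DEOXY")
LINKAGES   <- c("PO", "PS")
RNA_BASES  <- c("A", "C", "G", "U", "T")
PYRIMIDINES <- c("C", "U", "T")
PURINES     <- c("A", "G")

#' Construct a uniformly modified strand
#'
#' Builds a [mimic_strand] from a plain sequence, applying one sugar chemistry
#' and one backbone linkage to every position. Positions are 1-based, 5' to 3'.
#' `T` is accepted only on 2'-deoxy sugars; the designs modelled here use `U`
#' overhangs, not dT, so ribose thymidine is rejected rather than coerced.
#'
#' @param sequence Character scalar over the alphabet `A C G U T`.
#' @param sugar_default One of `"RIBO"`, `"OME"`, `"FLU"`, `"DEOXY"`.
#' @param linkage_default `"PO"` or `"PS"`, applied to every internucleotide
#'   linkage. The 3'-terminal residue always has no 3' linkage.
#' @param five_prime_phosphate Logical; does the strand carry a 5'-phosphate?
#' @param name Optional strand name.
#' @return A `mimic_strand`: residue table plus strand-level attributes.
#' @examples
#' make_strand("UAAUACUGCCGGGUAAUGAUGGA")
#' make_strand("ACGT", sugar_default = "DEOXY")
#' @export
make_strand <- function(sequence, sugar_default = "RIBO", linkage_default = "PO",
                        five_prime_phosphate = FALSE, name = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    abort("`sequence` must be a single non-empty string.", class = "mirmimic_alphabet_error")
  }
  sugar_default <- match.arg(sugar_default, SUGAR_MODS)
  linkage_default <- match.arg(linkage_default, LINKAGES)
  bases <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(bases), RNA_BASES)
  if (length(bad)) {
    abort(paste0("Invalid character(s) in sequence: ", paste(bad, collapse = ", ")),
          class = "mirmimic_alphabet_error")
  }
  if (any(bases == "T") && sugar_default != "DEOXY") {
    abort("Base T is only permitted on 2'-deoxy sugars.",
          class = "mirmimic_chemistry_error")
  }
  n <- length(bases)
  new_strand(
    tibble(
      position = seq_len(n),
      base     = bases,
      sugar    = rep(sugar_default, n),
      linkage3 = c(rep(linkage_default, n - 1L), NA_character_)
    ),
    five_prime_phosphate = five_prime_phosphate,
    name = name
  )
}

#' Low-level strand constructor
#'
#' Assembles a `mimic_strand` from a residue table. Validates the strand
#' invariants: non-empty, contiguous 1-based positions, valid bases/sugars,
#' exactly the last residue lacking a 3' linkage, and T only on deoxy sugars.
#'
#' @param residues Data frame with columns `position`, `base`, `sugar`,
#'   `linkage3` (NA on the final row only).
#' @param five_prime_phosphate Logical scalar.
#' @param name Optional strand name.
#' @param facing Optional integer vector (one per residue) recording which
#'   guide position each residue faces; used by passenger derivation.
#' @return A `mimic_strand`.
#' @export
new_strand <- function(residues, five_prime_phosphate = FALSE, name = NULL,
                       facing = NULL) {
  residues <- as_tibble(residues)[, c("position", "base", "sugar", "linkage3")]
  n <- nrow(residues)
  if (n < 1L) abort("A strand must contain at least one residue.",
                    class = "mirmimic_alphabet_error")
  if (!identical(as.integer(residues$position), seq_len(n))) {
    abort("Residue positions must be 1..length in order.", class = "mirmimic_invariant_error")
  }
  if (!all(residues$base %in% RNA_BASES)) {
    abort("Invalid base in residue table.", class = "mirmimic_alphabet_error")
  }
  if (!all(residues$sugar %in% SUGAR_MODS)) {
    abort("Invalid sugar modification in residue table.", class = "mirmimic_invariant_error")
  }
  if (any(residues$base == "T" & residues$sugar != "DEOXY")) {
    abort("Base T is only permitted on 2'-deoxy sugars.", class = "mirmimic_chemistry_error")
  }
  link_ok <- is.na(residues$linkage3[n]) &&
    (n == 1L || all(residues$linkage3[-n] %in% LINKAGES))
  if (!link_ok) {
    abort("Exactly the 3'-terminal residue must lack a 3' linkage.",
          class = "mirmimic_invariant_error")
  }
  residues$position <- as.integer(residues$position)
  structure(
    list(
      name = name %||% NA_character_,
      residues = residues,
      five_prime_phosphate = isTRUE(five_prime_phosphate),
      facing = facing
    ),
    class = "mimic_strand"
  )
}

#' @export
print.mimic_strand <- function(x, ...) {
  nm <- if (is.na(x$name)) "" else paste0(" ", x$name)
  cat(sprintf("<mimic_strand%s> %d nt  5'%s\n", nm, strand_length(x),
              if (x$five_prime_phosphate) "-P" else ""))
  cat("  ", write_notation(x), "\n", sep = "")
  invisible(x)
}

#' Strand length in residues
#' @param strand A `mimic_strand`.
#' @return Integer count of residues.
#' @export
strand_length <- function(strand) {
  stopifnot(inherits(strand, "mimic_strand"))
  nrow(strand$residues)
}

#' Plain base sequence of a strand
#' @param strand A `mimic_strand`.
#' @return Character scalar, 5' to 3'.
#' @export
strand_sequence <- function(strand) {
  stopifnot(inherits(strand, "mimic_strand"))
  paste(strand$residues$base, collapse = "")
}

#' @describeIn tidy-mirmimic Per-residue table of a strand (position, base,
#'   sugar, 3' linkage, 5'-phosphate flag on row 1).
#' @export
tidy.mimic_strand <- function(x, ...) {
  out <- x$residues
  out$five_prime_phosphate <- c(x$five_prime_phosphate, rep(FALSE, nrow(out) - 1L))
  out
}

#' Watson-Crick complement of RNA bases
#'
#' `T` complements to `A`; `A` complements to `U` (RNA convention).
#' @param bases Character vector of single bases.
#' @return Character vector of complements.
#' @keywords internal
wc_complement <- function(bases) {
  unname(c(A = "U", U = "A", T = "A", G = "C", C = "G")[bases])
}

is_wc_pair <- function(a, b) {
  # Strict Watson-Crick only: G:U wobble counts as a mismatch.
  (a == "A" & b %in% c("U", "T")) | (a %in% c("U", "T") & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}
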