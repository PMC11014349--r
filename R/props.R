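ELEMENTS <- c("C", "H", "N", "O", "P", "S", "F")

# IUPAC 2021 standard atomic weights and principal-isotope (monoisotopic)
# masses for the elements occurring in modified oligonucleotides.
ATOMIC_MASS <- list(
  AVERAGE = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
              P = 30.973761998, S = 32.06, F = 18.998403163),
  MONOISOTOPIC = c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151, S = 31.97207069,
                   F = 18.99840322)
)

# Ribonucleoside elemental compositions (free nucleoside, no phosphate).
NUCLEOSIDE_FORMULA <- list(
  A = c(C = 10, H = 13, N = 5, O = 4, P = 0, S = 0, F = 0),  # adenosine
  G = c(C = 10, H = 13, N = 5, O = 5, P = 0, S = 0, F = 0),  # guanosine
  C = c(C = 9,  H = 13, N = 3, O = 5, P = 0, S = 0, F = 0),  # cytidine
  U = c(C = 9,  H = 12, N = 2, O = 6, P = 0, S = 0, F = 0),  # uridine
  T = c(C = 10, H = 14, N = 2, O = 6, P = 0, S = 0, F = 0)   # ribothymidine; dT = this - O
)

mol_formula <- function(x = numeric()) {
  out <- stats::setNames(numeric(length(ELEMENTS)), ELEMENTS)
  out[names(x)] <- x
  out
}

#' Elemental composition of a single modified nucleoside
#'
#' Returns the formula of the nucleoside with its sugar modification:
#' 2'-O-methyl adds CH2 relative to ribose, 2'-fluoro replaces the 2'-OH with
#' F (-O -H +H... i.e. -OH +F), and 2'-deoxy replaces the 2'-OH with H (-O).
#' Linkage and terminal phosphate contributions are added by
#' [strand_formula()], not here.
#'
#' @param base One of `A C G U T`.
#' @param sugar One of `r paste(SUGAR_MODS, collapse = ", ")`.
#' @return Named numeric vector over `C H N O P S F`.
#' @examples
#' residue_formula("A")                  # adenosine C10H13N5O4
#' residue_formula("A", "OME") - residue_formula("A")  # +CH2
#' @export
residue_formula <- function(base, sugar = "RIBO") {
  base <- match.arg(base, RNA_BASES)
  sugar <- match.arg(sugar, SUGAR_MODS)
  f <- mol_formula(NUCLEOSIDE_FORMULA[[base]])
  switch(sugar,
    RIBO = f,
    OME = f + mol_formula(c(C = 1, H = 2)),
    FLU = f + mol_formula(c(O = -1, H = -1, F = 1)),
    DEOXY = f + mol_formula(c(O = -1))
  )
}

#' Elemental composition of a modified strand
#'
#' Sums the nucleoside formulas and adds one phosphate bridge (HPO3, with one
#' H2O condensed out) per internucleotide linkage; each phosphorothioate
#' linkage swaps one oxygen for one sulfur. A 5'-phosphate adds one HPO3.
#' The neutral free-acid species is assumed (no counter-ions or adducts).
#'
#' @param strand A [mimic_strand].
#' @return Named numeric vector over `C H N O P S F`.
#' @export
strand_formula <- function(strand) {
  stopifnot(inherits(strand, "mimic_strand"))
  res <- strand$residues
  f <- mol_formula()
  for (i in seq_len(nrow(res))) {
    f <- f + residue_formula(res$base[i], res$sugar[i])
  }
  n_link <- nrow(res) - 1L
  n_ps <- sum(res$linkage3 == "PS", na.rm = TRUE)
  bridge <- mol_formula(c(H = 1, P = 1, O = 3)) - mol_formula(c(H = 2, O = 1))
  f <- f + n_link * bridge + n_ps * mol_formula(c(O = -1, S = 1))
  if (strand$five_prime_phosphate) f <- f + mol_formula(c(H = 1, P = 1, O = 3))
  f
}

#' Neutral mass of a modified strand
#'
#' Mass of [strand_formula()] under IUPAC standard atomic weights
#' (`"AVERAGE"`) or principal-isotope masses (`"MONOISOTOPIC"`), for the
#' neutral, non-ionised free acid — the deconvoluted-neutral-mass convention
#' used when comparing against LC-MS data.
#'
#' @param strand A [mimic_strand].
#' @param kind `"AVERAGE"` or `"MONOISOTOPIC"`.
#' @return Mass in Da.
#' @export
strand_mass <- function(strand, kind = c("AVERAGE", "MONOISOTOPIC")) {
  kind <- match.arg(kind)
  f <- strand_formula(strand)
  sum(f * ATOMIC_MASS[[kind]][names(f)])
}

#' Format a molecular formula as a Hill-style string
#' @param formula Named numeric vector over `C H N O P S F`.
#' @return Character scalar, e.g. `"C10H13N5O4"`.
#' @export
format_formula <- function(formula) {
  nz <- formula[formula != 0]
  paste0(names(nz), ifelse(nz == 1, "", nz), collapse = "")
}

#' G+C fraction of a strand
#' @param strand A [mimic_strand].
#' @return Fraction in `[0, 1]`.
#' @examples
#' gc_content(make_strand("GGCC")) # 1
#' @export
gc_content <- function(strand) {
  stopifnot(inherits(strand, "mimic_strand"))
  mean(strand$residues$base %in% c("G", "C"))
}
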