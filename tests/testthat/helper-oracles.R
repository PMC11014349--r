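# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Sliding-window exact match count; overlapping matches counted, N never
# matches (site is N-free).
brute_force_scan <- function(sequence, site) {
  n <- nchar(sequence)
  m <- nchar(site)
  if (m > n) return(0L)
  hits <- 0L
  for (i in seq_len(n - m + 1L)) {
    if (substr(sequence, i, i + m - 1L) == site) hits <- hits + 1L
  }
  hits
}

# Nucleoside composition assembled independently: free base + ribose - H2O,
# with sugar-modification arithmetic done on atom groups.
oracle_nucleoside <- function(base, sugar = "RIBO") {
  f0 <- function(...) {
    v <- stats::setNames(numeric(7), c("C", "H", "N", "O", "P", "S", "F"))
    args <- c(...)
    v[names(args)] <- args
    v
  }
  base_f <- switch(base,
    A = f0(C = 5, H = 5, N = 5),
    G = f0(C = 5, H = 5, N = 5, O = 1),
    C = f0(C = 4, H = 5, N = 3, O = 1),
    U = f0(C = 4, H = 4, N = 2, O = 2),
    T = f0(C = 5, H = 6, N = 2, O = 2)
  )
  ribose <- f0(C = 5, H = 10, O = 5)
  water <- f0(H = 2, O = 1)
  f <- base_f + ribose - water
  switch(sugar,
    RIBO = f,
    OME = f + f0(C = 1, H = 2),
    FLU = f - f0(H = 1, O = 1) + f0(F = 1),
    DEOXY = f - f0(O = 1)
  )
}

# Random valid strand for round-trip / property tests.
random_strand <- function(max_len = 30L) {
  n <- sample.int(max_len, 1L)
  sugars <- sample(c("RIBO", "OME", "FLU", "DEOXY"), n, replace = TRUE)
  bases <- vapply(sugars, function(s) {
    pool <- if (s == "DEOXY") c("A", "C", "G", "U", "T") else c("A", "C", "G", "U")
    sample(pool, 1L)
  }, character(1), USE.NAMES = FALSE)
  linkage3 <- c(sample(c("PO", "PS"), max(n - 1L, 0L), replace = TRUE), NA_character_)
  new_strand(
    tibble::tibble(position = seq_len(n), base = bases, sugar = sugars,
                   linkage3 = linkage3[seq_len(n)]),
    five_prime_phosphate = sample(c(TRUE, FALSE), 1L)
  )
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

MIR200C_GUIDE <- "UAAUACUGCCGGGUAAUGAUGGA"
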