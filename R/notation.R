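#' Strand notation
#'
#' A compact text encoding for chemically modified strands, used in registry
#' files and on the command line. The grammar, 5' to 3':
#'
#' * optional prefix `P-` marks a 5'-phosphate;
#' * one token per residue: a sugar code followed by a base. Sugar codes:
#'   `m` = 2'-O-methyl, `f` = 2'-fluoro, `d` = 2'-deoxy, `r` or nothing =
#'   unmodified ribose. Bases: `A C G U T` (`T` only after `d`);
#' * an asterisk `*` **between** two tokens marks a phosphorothioate (PS)
#'   linkage; its absence marks a phosphodiester (PO). Whitespace is forbidden.
#'
#' `write_notation()` emits the canonical form (ribose as bare base, never
#' `r...`), so `parse_notation(write_notation(s))` reproduces `s` exactly.
#'
#' @param text Notation string.
#' @return `parse_notation()`: a [mimic_strand]. `write_notation()`: a string.
#' @examples
#' s <- parse_notation("P-mU*fA*mA")
#' write_notation(s)
#' @name notation
NULL

SUGAR_CODE <- c(m = "OME", f = "FLU", d = "DEOXY", r = "RIBO")

#' @rdname notation
#' @param name Optional name for the parsed strand.
#' @export
parse_notation <- function(text, name = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("Notation must be a single string.", class = "mirmimic_parse_error")
  }
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  fail <- function(msg, col) {
    abort(sprintf("Notation parse error at column %d: %s", col, msg),
          class = "mirmimic_parse_error")
  }
  if (any(grepl("\\s", chars))) fail("whitespace is forbidden", which(grepl("\\s", chars))[1])
  i <- 1L
  p5 <- FALSE
  if (n >= 2L && chars[1] == "P" && chars[2] == "-") {
    p5 <- TRUE
    i <- 3L
  }
  if (any(chars[seq.int(i, length.out = n - i + 1L)] == "P") && i <= n) {
    j <- which(chars == "P")
    j <- j[j >= i]
    if (length(j)) fail("'P-' is only allowed at the start", j[1])
  }
  bases <- character()
  sugars <- character()
  ps <- logical()        # PS flag for the linkage *preceding* token k (k >= 2)
  expect_token <- TRUE   # a token must follow the start or an asterisk
  while (i <= n) {
    ch <- chars[i]
    if (ch == "*") {
      if (expect_token || length(bases) == 0L) fail("unexpected '*'", i)
      ps[length(bases)] <- TRUE  # linkage after current last token
      expect_token <- TRUE
      i <- i + 1L
      next
    }
    sugar <- "RIBO"
    if (ch %in% names(SUGAR_CODE)) {
      sugar <- SUGAR_CODE[[ch]]
      i <- i + 1L
      if (i > n) fail("sugar code not followed by a base", i)
      ch <- chars[i]
    }
    if (!ch %in% RNA_BASES) fail(sprintf("unknown sugar code or base '%s'", ch), i)
    if (ch == "T" && sugar != "DEOXY") fail("base T requires the 'd' sugar code", i)
    bases <- c(bases, ch)
    sugars <- c(sugars, sugar)
    ps <- c(ps, FALSE)
    expect_token <- FALSE
    i <- i + 1L
  }
  if (expect_token) fail("dangling '*' at end of notation", n)
  if (length(bases) == 0L) fail("empty notation", 1L)
  k <- length(bases)
  linkage3 <- if (k > 1L) c(ifelse(ps[seq_len(k - 1L)], "PS", "PO"), NA_character_) else NA_character_
  new_strand(
    tibble(position = seq_len(k), base = bases, sugar = sugars, linkage3 = linkage3),
    five_prime_phosphate = p5, name = name
  )
}

#' @rdname notation
#' @param strand A `mimic_strand`.
#' @export
write_notation <- function(strand) {
  stopifnot(inherits(strand, "mimic_strand"))
  res <- strand$residues
  code <- c(RIBO = "", OME = "m", FLU = "f", DEOXY = "d")[res$sugar]
  tokens <- paste0(code, res$base)
  sep <- if (nrow(res) > 1L) ifelse(res$linkage3[-nrow(res)] == "PS", "*", "") else character()
  body <- paste0(paste0(tokens[-length(tokens)], sep, collapse = ""), tokens[length(tokens)])
  if (nrow(res) == 1L) body <- tokens
  paste0(if (strand$five_prime_phosphate) "P-" else "", body)
}
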