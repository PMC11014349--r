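ARCHITECTURES <- c("BLUNT_SYMMETRIC", "OVERHANG_3P", "ASYMMETRIC", "NICKED", "HAIRPIN")
PAIRING_STATES <- c("PAIRED", "MISMATCH", "DELETION", "UNPAIRED")

#' Facing-position arithmetic
#'
#' Maps a guide-strand coordinate onto the passenger-strand coordinate paired
#' opposite it in the duplex geometry. For a blunt duplex of equal lengths the
#' map is `passenger_len - guide_pos + 1`, e.g. guide position 17 of a 23 + 23
#' duplex faces passenger position 7. `offset_3p` counts guide 3'-end positions
#' left unpaired by the passenger alignment (0 for a blunt 3' end).
#'
#' @param guide_pos 1-based guide position(s).
#' @param guide_len Guide length (nt).
#' @param passenger_len Passenger length (nt).
#' @param offset_3p Guide 3'-end positions left unpaired (default 0).
#' @return Integer passenger position, or `NA` when the computed index falls
#'   outside `[1, passenger_len]` (no facing residue).
#' @examples
#' facing_position(17, 23, 23) # 7
#' facing_position(10, 23, 23) # 14
#' @export
facing_position <- function(guide_pos, guide_len, passenger_len, offset_3p = 0L) {
  if (any(guide_pos < 1L | guide_pos > guide_len)) {
    abort("`guide_pos` out of range.", class = "mirmimic_index_error")
  }
  p <- guide_len - offset_3p - guide_pos + 1L
  p[p < 1L | p > passenger_len] <- NA_integer_
  as.integer(p)
}

#' Build a mismatch specification
#'
#' A mismatch specification lists design edits applied to the derived
#' complement passenger, in passenger coordinates (pre-deletion numbering):
#' substitutions (optionally with an explicit base) and deletions. The default
#' substitution base is a copy of the facing guide base, which reproduces the
#' canonical U-U mismatch at guide position 17 / passenger position 7.
#'
#' @param position Integer vector of 1-based passenger positions (unique).
#' @param kind `"SUBSTITUTION"` or `"DELETION"`, recycled to match `position`.
#' @param base Optional base override per entry (`NA` = copy facing guide
#'   base); must be `NA` for deletions.
#' @return A tibble with columns `position`, `kind`, `base`.
#' @export
mismatch_spec <- function(position = integer(), kind = "SUBSTITUTION", base = NA_character_) {
  n <- length(position)
  spec <- tibble(
    position = as.integer(position),
    kind = rep_len(toupper(kind), n),
    base = rep_len(as.character(base), n)
  )
  validate_mismatch_spec(spec)
}

validate_mismatch_spec <- function(spec) {
  spec <- as_tibble(spec)
  if (nrow(spec) == 0L) {
    return(tibble(position = integer(), kind = character(), base = character()))
  }
  if (anyDuplicated(spec$position)) {
    abort("Mismatch spec positions must be unique.", class = "mirmimic_spec_error")
  }
  if (!all(spec$kind %in% c("SUBSTITUTION", "DELETION"))) {
    abort("Mismatch kind must be SUBSTITUTION or DELETION.", class = "mirmimic_spec_error")
  }
  if (any(spec$kind == "DELETION" & !is.na(spec$base))) {
    abort("DELETION entries cannot carry a base override.", class = "mirmimic_spec_error")
  }
  spec[, c("position", "kind", "base")]
}

#' Derive a passenger strand from a guide
#'
#' Produces the reverse complement of the guide (A:U, G:C), truncated from the
#' passenger 3' end for asymmetric lengths, then applies the mismatch
#' specification: substitutions replace the complement base (by the explicit
#' override, or by a copy of the facing guide base when none is given) and
#' deletions remove the residue, shifting downstream positions. Spec positions
#' refer to the untruncated, pre-deletion passenger numbering.
#'
#' @param guide A [mimic_strand].
#' @param spec A [mismatch_spec()] table (or `NULL` for a perfect complement).
#' @param length Passenger length before deletions, or `NULL` for full length.
#' @param sugar_default,linkage_default Chemistry applied uniformly; templates
#'   overwrite it later.
#' @param name Optional strand name.
#' @return A `mimic_strand` whose residues remember the guide position each
#'   one faces (used by [build_pairing_map()]).
#' @examples
#' g <- make_strand("UAAU")
#' strand_sequence(derive_passenger(g)) # "AUUA"
#' @export
derive_passenger <- function(guide, spec = NULL, length = NULL,
                             sugar_default = "RIBO", linkage_default = "PO",
                             name = NULL) {
  stopifnot(inherits(guide, "mimic_strand"))
  G <- strand_length(guide)
  L <- as.integer(length %||% G)
  if (L < 1L || L > G) {
    abort("Passenger length must be in [1, guide length].", class = "mirmimic_spec_error")
  }
  spec <- validate_mismatch_spec(spec %||% tibble())
  gb <- guide$residues$base
  facing_g <- G - seq_len(L) + 1L          # passenger position p faces guide G - p + 1
  bases <- wc_complement(gb[facing_g])
  if (any(spec$position > L)) {
    abort("Mismatch spec position beyond derived passenger length.",
          class = "mirmimic_spec_error")
  }
  subs <- spec[spec$kind == "SUBSTITUTION", ]
  if (nrow(subs)) {
    bases[subs$position] <- ifelse(is.na(subs$base), gb[facing_g[subs$position]], subs$base)
  }
  keep <- setdiff(seq_len(L), spec$position[spec$kind == "DELETION"])
  bases <- bases[keep]
  facing_g <- facing_g[keep]
  n <- length(bases)
  if (n < 1L) abort("All passenger residues deleted.", class = "mirmimic_spec_error")
  new_strand(
    tibble(position = seq_len(n), base = bases,
           sugar = rep(match.arg(sugar_default, SUGAR_MODS), n),
           linkage3 = c(rep(match.arg(linkage_default, LINKAGES), n - 1L), NA_character_)),
    name = name, facing = as.integer(facing_g)
  )
}

#' Assemble a duplex from strands
#'
#' Combines a guide with one passenger strand (or two, for the nicked
#' architecture) and computes the per-guide-position pairing map. Passenger
#' segments are laid out 5' to 3' against the guide 3' end: concatenated
#' passenger coordinate `p` faces guide coordinate
#' `guide_len - offset_3p - p + 1`, skipping designed deletion slots.
#' Overhang, hairpin-loop and other residues beyond the duplex region face no
#' guide position and are reported as unpaired passenger residues.
#'
#' @param guide A [mimic_strand].
#' @param passenger_segments A `mimic_strand` or list of them (exactly 2 for
#'   `NICKED`, 1 otherwise).
#' @param architecture One of `r paste(ARCHITECTURES, collapse = ", ")`.
#' @param params List of architecture parameters: `offset_3p` (guide 3'
#'   positions left unpaired), `deletions` (guide positions with a designed
#'   passenger deletion; taken from the derived passenger when available),
#'   `overhang` (passenger 3' overhang sequence), `loop` (`c(start, end)`
#'   hairpin-loop boundaries within the passenger), `split` (nick position in
#'   passenger coordinates).
#' @param mimic_id Optional registry identifier carried on the duplex.
#' @return A `mimic_duplex` with a computed pairing map.
#' @export
assemble_duplex <- function(guide, passenger_segments, architecture = "BLUNT_SYMMETRIC",
                            params = list(), mimic_id = NULL) {
  stopifnot(inherits(guide, "mimic_strand"))
  if (inherits(passenger_segments, "mimic_strand")) {
    passenger_segments <- list(passenger_segments)
  }
  architecture <- match.arg(architecture, ARCHITECTURES)
  n_seg <- length(passenger_segments)
  if (architecture == "NICKED" && n_seg != 2L) {
    abort("NICKED architecture requires exactly 2 passenger segments.",
          class = "mirmimic_architecture_error")
  }
  if (architecture != "NICKED" && n_seg != 1L) {
    abort(sprintf("%s architecture requires exactly 1 passenger segment.", architecture),
          class = "mirmimic_architecture_error")
  }
  if (architecture == "HAIRPIN" && is.null(params$loop)) {
    abort("HAIRPIN architecture requires `params$loop` boundaries.",
          class = "mirmimic_architecture_error")
  }
  if (is.null(params$deletions)) {
    fac <- unlist(lapply(passenger_segments, function(s) s$facing))
    fac <- fac[!is.na(fac)]
    params$deletions <- if (length(fac)) {
      covered <- fac
      # designed deletions: guide slots inside the covered span with no facing residue
      setdiff(seq(min(covered), max(covered)), covered)
    } else integer()
  }
  params$offset_3p <- as.integer(params$offset_3p %||% 0L)
  dup <- structure(
    list(guide = guide, passenger_segments = passenger_segments,
         architecture = architecture, pairing = NULL,
         mimic_id = mimic_id %||% NA_character_, params = params),
    class = "mimic_duplex"
  )
  dup$pairing <- build_pairing_map(dup)
  dup
}

#' Compute the per-guide-position pairing map of a duplex
#'
#' Classifies every guide position as `PAIRED` (strict Watson-Crick; G:U
#' wobbles count as mismatches), `MISMATCH` (a facing residue exists but does
#' not pair), `DELETION` (the design removes the facing passenger residue), or
#' `UNPAIRED` (no facing residue due to length asymmetry or overhangs).
#'
#' @param duplex A `mimic_duplex`.
#' @return A tibble with one row per guide position: `guide_pos`,
#'   `guide_base`, `state`, `segment`, `passenger_pos`, `passenger_base`.
#' @export
build_pairing_map <- function(duplex) {
  stopifnot(inherits(duplex, "mimic_duplex"))
  G <- strand_length(duplex$guide)
  gb <- duplex$guide$residues$base
  dels <- as.integer(duplex$params$deletions %||% integer())
  off <- as.integer(duplex$params$offset_3p %||% 0L)
  seg_lens <- vapply(duplex$passenger_segments, strand_length, integer(1))
  seg_ends <- cumsum(seg_lens)
  state <- character(G)
  segment <- rep(NA_integer_, G)
  ppos <- rep(NA_integer_, G)
  pbase <- rep(NA_character_, G)
  seen <- character()
  for (g in seq_len(G)) {
    if (g %in% dels) {
      state[g] <- "DELETION"
      next
    }
    p0 <- G - off - g + 1L
    if (p0 < 1L) {
      state[g] <- "UNPAIRED"
      next
    }
    p <- p0 - sum(dels > g)
    if (p < 1L || p > sum(seg_lens)) {
      state[g] <- "UNPAIRED"
      next
    }
    seg <- which(seg_ends >= p)[1]
    within <- p - c(0L, seg_ends)[seg]
    key <- paste(seg, within)
    if (key %in% seen) {
      abort("Two guide positions face the same passenger residue; inconsistent offsets.",
            class = "mirmimic_geometry_error")
    }
    seen <- c(seen, key)
    b <- duplex$passenger_segments[[seg]]$residues$base[within]
    segment[g] <- seg
    ppos[g] <- within
    pbase[g] <- b
    state[g] <- if (is_wc_pair(gb[g], b)) "PAIRED" else "MISMATCH"
  }
  tibble(guide_pos = seq_len(G), guide_base = gb, state = state,
         segment = segment, passenger_pos = ppos, passenger_base = pbase)
}

#' Tally the pairing states of a duplex
#'
#' @param map A pairing map from [build_pairing_map()], or a `mimic_duplex`.
#' @return A tibble `state`, `n` covering all four states; `n` sums to the
#'   guide length.
#' @export
count_pairing_states <- function(map) {
  if (inherits(map, "mimic_duplex")) map <- map$pairing
  stopifnot(is.data.frame(map), "state" %in% names(map))
  counts <- table(factor(map$state, levels = PAIRING_STATES))
  tibble(state = PAIRING_STATES, n = as.integer(counts))
}

#' Passenger residues that face no guide position
#'
#' Overhang and hairpin-loop residues extend beyond the duplex region; this
#' lists them per segment.
#'
#' @param duplex A `mimic_duplex`.
#' @return Tibble `segment`, `position`, `base`.
#' @export
unpaired_passenger_residues <- function(duplex) {
  stopifnot(inherits(duplex, "mimic_duplex"))
  faced <- duplex$pairing[!is.na(duplex$pairing$segment), c("segment", "passenger_pos")]
  purrr::map_dfr(seq_along(duplex$passenger_segments), function(i) {
    res <- duplex$passenger_segments[[i]]$residues
    used <- faced$passenger_pos[faced$segment == i]
    free <- res[!res$position %in% used, c("position", "base")]
    if (nrow(free)) tibble(segment = i, position = free$position, base = free$base)
    else tibble(segment = integer(), position = integer(), base = character())
  })
}

#' @export
print.mimic_duplex <- function(x, ...) {
  id <- if (is.na(x$mimic_id)) "" else paste0(" [", x$mimic_id, "]")
  cat(sprintf("<mimic_duplex%s> %s, guide %d nt + %d passenger segment(s)\n",
              id, x$architecture, strand_length(x$guide), length(x$passenger_segments)))
  cat("  guide:     ", write_notation(x$guide), "\n", sep = "")
  for (s in x$passenger_segments) cat("  passenger: ", write_notation(s), "\n", sep = "")
  cs <- count_pairing_states(x)
  cat("  pairing:   ", paste(sprintf("%s=%d", cs$state, cs$n), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @describeIn tidy-mirmimic Pairing map of a duplex, one row per guide
#'   position.
#' @export
tidy.mimic_duplex <- function(x, ...) x$pairing

#' @describeIn tidy-mirmimic One-row duplex summary: id, architecture, strand
#'   lengths and pairing-state counts.
#' @export
glance.mimic_duplex <- function(x, ...) {
  cs <- count_pairing_states(x)
  wide <- stats::setNames(as.list(cs$n), tolower(cs$state))
  tibble(
    mimic_id = x$mimic_id,
    architecture = x$architecture,
    guide_len = strand_length(x$guide),
    passenger_len = sum(vapply(x$passenger_segments, strand_length, integer(1))),
    n_segments = length(x$passenger_segments),
    !!!wide
  )
}
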