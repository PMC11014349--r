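#' Apply a mimic template to a miRNA sequence
#'
#' Evaluates a template's declarative rules against a guide sequence and
#' returns the fully specified duplex. Rules are applied in a fixed order:
#' sugar chemistry (alternating and base-class rules first, positional rules
#' overriding them), then backbone PS rules, then architecture rules
#' (passenger length, overhang, hairpin loop, nick), then the 5'-phosphate.
#'
#' @param template A `mimic_template` from [load_registry()]/[get_template()].
#' @param guide_seq Guide sequence 5' to 3', or `NULL` for the template's
#'   native miRNA guide.
#' @param passenger_seq `"AUTO"` (derive the passenger from the guide via the
#'   template's mismatch specification) or an explicit sequence.
#' @return A `mimic_duplex` carrying the template id.
#' @examples
#' reg <- load_registry()
#' apply_template(get_template(reg, "M23"))
#' @export
apply_template <- function(template, guide_seq = NULL, passenger_seq = "AUTO") {
  stopifnot(inherits(template, "mimic_template"))
  build_from_template(template,
                      guide_seq = guide_seq %||% template$guide,
                      passenger_seq = passenger_seq,
                      spec = template$mismatch_spec,
                      clamp = FALSE,
                      mimic_id = template$id)
}

#' Translate a mimic template to a new miRNA
#'
#' Re-evaluates a template's rule set against a different guide sequence:
#' base-class rules re-select positions on the new sequence, terminal-PS and
#' passenger-length rules re-anchor, and positional entries beyond the new
#' strand length are dropped (with a warning). When no mismatch specification
#' is supplied the passenger defaults to the full complement — a loud warning
#' is emitted, because full complementarity is known to change mimic activity
#' and the tool must not silently fabricate mismatches.
#'
#' @param template A `mimic_template`.
#' @param new_guide Guide sequence of the target miRNA, 5' to 3'.
#' @param new_mismatch_spec A [mismatch_spec()] (e.g. transcribed from the
#'   target pre-miRNA), or `NULL` for the fully complementary default.
#' @param mirna_name Optional name of the target miRNA, used in the derived
#'   mimic id (`<template id>@<name>`).
#' @return A `mimic_duplex`.
#' @export
translate_template <- function(template, new_guide, new_mismatch_spec = NULL,
                               mirna_name = NULL) {
  stopifnot(inherits(template, "mimic_template"))
  if (is.null(new_mismatch_spec)) {
    warn(paste("No mismatch specification supplied: the passenger defaults to the",
               "full complement. Mimic activity depends on duplex mismatches;",
               "supply a pre-miRNA-derived spec for a faithful translation."),
         class = "mirmimic_translation_warning")
    new_mismatch_spec <- mismatch_spec()
  }
  id <- paste0(template$id, "@", mirna_name %||% "translated")
  build_from_template(template, guide_seq = new_guide, passenger_seq = "AUTO",
                      spec = validate_mismatch_spec(new_mismatch_spec),
                      clamp = TRUE, mimic_id = id)
}

build_from_template <- function(template, guide_seq, passenger_seq, spec, clamp,
                                mimic_id) {
  guide <- make_strand(guide_seq, name = paste0(mimic_id, "_guide"))
  G <- strand_length(guide)
  rules_g <- template$guide_rules
  rules_p <- template$passenger_rules

  plen <- find_rule(rules_p, "PASSENGER_LENGTH")
  L <- if (!is.null(plen)) {
    cnt <- as.integer(plen$count)
    if (clamp) cnt <- min(cnt, G)
    cnt
  } else G

  passenger <- if (identical(passenger_seq, "AUTO")) {
    derive_passenger(guide, spec, length = L, name = paste0(mimic_id, "_passenger"))
  } else {
    p <- make_strand(passenger_seq, name = paste0(mimic_id, "_passenger"))
    fac <- G - seq_len(strand_length(p)) + 1L
    fac[fac < 1L] <- NA_integer_
    p$facing <- as.integer(fac)
    p
  }

  guide <- apply_sugar_rules(guide, rules_g, clamp, template$id)
  passenger <- apply_sugar_rules(passenger, rules_p, clamp, template$id)
  guide <- apply_ps_rules(guide, rules_g, clamp, template$id)
  passenger <- apply_ps_rules(passenger, rules_p, clamp, template$id)

  params <- list()
  ov <- find_rule(rules_p, "OVERHANG")
  if (!is.null(ov)) passenger <- append_residues(passenger, ov$sequence)
  hp <- find_rule(rules_p, "HAIRPIN")
  if (!is.null(hp)) {
    L0 <- strand_length(passenger)
    passenger <- append_residues(passenger, hp$loop)
    params$loop <- c(L0 + 1L, L0 + nchar(hp$loop))
  }
  segments <- list(passenger)
  nick <- find_rule(rules_p, "NICK")
  if (!is.null(nick)) {
    segments <- split_strand(passenger, as.integer(nick$split))
    params$split <- as.integer(nick$split)
  }
  if (!is.null(find_rule(rules_g, "FIVE_PRIME_PHOSPHATE"))) {
    guide$five_prime_phosphate <- TRUE
  }
  if (!is.null(find_rule(rules_p, "FIVE_PRIME_PHOSPHATE"))) {
    segments[[1]]$five_prime_phosphate <- TRUE
  }
  assemble_duplex(guide, segments, template$architecture, params, mimic_id = mimic_id)
}

find_rule <- function(rules, tag) {
  hit <- Filter(function(r) identical(r$tag, tag), rules)
  if (length(hit)) hit[[1]] else NULL
}

apply_sugar_rules <- function(strand, rules, clamp, id) {
  res <- strand$residues
  n <- nrow(res)
  for (r in rules) {
    switch(r$tag,
      ALTERNATING = {
        first <- ((res$position - 1L + as.integer(r$phase %||% 0L)) %% 2L) == 0L
        res$sugar <- ifelse(first, r$first_sugar, r$second_sugar)
      },
      BASE_CLASS = {
        sel <- if (identical(r$base_class, "PYRIMIDINE")) res$base %in% PYRIMIDINES
               else res$base %in% PURINES
        res$sugar[sel] <- r$sugar
      },
      POSITIONAL = {
        pos <- as.integer(r$positions)
        if (any(pos > n)) {
          if (clamp) {
            warn(sprintf("Template %s: dropping positional sugar entries beyond length %d.",
                         id, n))
            pos <- pos[pos <= n]
          } else {
            abort(sprintf("Template %s: positional rule references position beyond strand length.", id),
                  class = "mirmimic_rule_error")
          }
        }
        res$sugar[pos] <- r$sugar
      }
    )
  }
  bad_t <- res$base == "T" & res$sugar != "DEOXY"
  if (any(bad_t)) {
    abort(sprintf("Template %s: rules place base T on a non-deoxy sugar.", id),
          class = "mirmimic_rule_error")
  }
  strand$residues <- res
  strand
}

apply_ps_rules <- function(strand, rules, clamp, id) {
  res <- strand$residues
  n_link <- nrow(res) - 1L
  for (r in rules) {
    if (identical(r$tag, "TERMINAL_PS")) {
      n5 <- min(as.integer(r$n_5prime), n_link)
      n3 <- min(as.integer(r$n_3prime), n_link)
      idx <- unique(c(seq_len(n5), seq.int(n_link - n3 + 1L, length.out = n3)))
      res$linkage3[idx] <- "PS"
    } else if (identical(r$tag, "POSITIONAL_PS")) {
      pos <- as.integer(r$positions)
      if (any(pos > n_link)) {
        if (clamp) {
          pos <- pos[pos <= n_link]
        } else {
          abort(sprintf("Template %s: PS rule references linkage beyond strand length.", id),
                class = "mirmimic_rule_error")
        }
      }
      res$linkage3[pos] <- "PS"
    }
  }
  strand$residues <- res
  strand
}

append_residues <- function(strand, sequence, sugar = "RIBO", linkage = "PO") {
  bases <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(all(bases %in% setdiff(RNA_BASES, "T")))
  res <- strand$residues
  n <- nrow(res)
  res$linkage3[n] <- linkage
  add <- tibble(position = n + seq_along(bases), base = bases,
                sugar = sugar,
                linkage3 = c(rep(linkage, length(bases) - 1L), NA_character_))
  new_strand(rbind(res, add),
             five_prime_phosphate = strand$five_prime_phosphate,
             name = strand$name,
             facing = c(strand$facing, rep(NA_integer_, length(bases))))
}

split_strand <- function(strand, split) {
  res <- strand$residues
  n <- nrow(res)
  if (split < 1L || split >= n) {
    abort("Nick split position must fall inside the passenger strand.",
          class = "mirmimic_architecture_error")
  }
  a <- res[seq_len(split), ]
  a$linkage3[split] <- NA_character_
  b <- res[seq.int(split + 1L, n), ]
  b$position <- seq_len(nrow(b))
  fac <- strand$facing
  list(
    new_strand(a, five_prime_phosphate = strand$five_prime_phosphate,
               name = paste0(strand$name, "_frag1"),
               facing = if (!is.null(fac)) fac[seq_len(split)]),
    new_strand(b, name = paste0(strand$name, "_frag2"),
               facing = if (!is.null(fac)) fac[seq.int(split + 1L, n)])
  )
}

#' Census of chemical modifications in a duplex
#'
#' Exhaustively counts sugar modifications, backbone linkages and the
#' 5'-phosphate flag per strand. Sugar counts per strand sum to the strand
#' length; linkage counts sum to length - 1.
#'
#' @param duplex A `mimic_duplex`.
#' @return A tibble `strand`, `category`, `value`, `n`.
#' @export
count_modifications <- function(duplex) {
  stopifnot(inherits(duplex, "mimic_duplex"))
  strands <- c(list(guide = duplex$guide),
               stats::setNames(duplex$passenger_segments,
                               paste0("passenger", seq_along(duplex$passenger_segments))))
  purrr::map_dfr(names(strands), function(nm) {
    s <- strands[[nm]]
    res <- s$residues
    sug <- table(factor(res$sugar, levels = SUGAR_MODS))
    lnk <- table(factor(res$linkage3[!is.na(res$linkage3)], levels = LINKAGES))
    rbind(
      tibble(strand = nm, category = "sugar", value = SUGAR_MODS, n = as.integer(sug)),
      tibble(strand = nm, category = "linkage", value = LINKAGES, n = as.integer(lnk)),
      tibble(strand = nm, category = "flag", value = "five_prime_phosphate",
             n = as.integer(s$five_prime_phosphate))
    )
  })
}
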