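RULE_TAGS <- c("ALTERNATING", "BASE_CLASS", "POSITIONAL", "TERMINAL_PS",
               "POSITIONAL_PS", "OVERHANG", "PASSENGER_LENGTH", "HAIRPIN",
               "NICK", "FIVE_PRIME_PHOSPHATE")

#' Load a mimic template registry
#'
#' Reads a JSON registry of mimic modification templates. The built-in
#' registry encodes the miR-200c design series M1-M38 (M1 being the
#' unmodified reference duplex) plus the designs translated to miR-155
#' (MA1-MA3) and miR-34a (MB1-MB3); eight M-designs are flagged as
#' shortlisted for extended profiling. Each template records its miRNA, its
#' guide/passenger modification rules, a mismatch specification, the duplex
#' architecture and a provenance note.
#'
#' @param path Path to a registry JSON file, or `NULL` for the built-in
#'   registry shipped with the package.
#' @return A `mimic_registry`.
#' @examples
#' reg <- load_registry()
#' dplyr::count(tidy(reg), shortlisted)
#' @export
load_registry <- function(path = NULL) {
  builtin <- is.null(path)
  if (builtin) {
    path <- system.file("extdata", "mimic_templates.json", package = "mirmimic",
                        mustWork = TRUE)
  }
  doc <- jsonlite::read_json(path)
  if (is.null(doc$templates) || is.null(doc$mirnas)) {
    abort("Registry JSON must contain `mirnas` and `templates`.",
          class = "mirmimic_registry_error")
  }
  templates <- lapply(doc$templates, parse_template_json, mirnas = doc$mirnas)
  ids <- vapply(templates, function(t) t$id, character(1))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate template id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "mirmimic_registry_error")
  }
  names(templates) <- ids
  reg <- structure(list(templates = templates, source = path), class = "mimic_registry")
  if (builtin) validate_builtin_registry(reg)
  reg
}

parse_template_json <- function(tpl, mirnas) {
  required <- c("id", "mirna", "guide_rules", "passenger_rules", "mismatch_spec",
                "architecture", "shortlisted", "provenance")
  missing <- setdiff(required, names(tpl))
  if (length(missing)) {
    abort(paste0("Template missing field(s): ", paste(missing, collapse = ", ")),
          class = "mirmimic_registry_error")
  }
  if (is.null(mirnas[[tpl$mirna]])) {
    abort(sprintf("Template %s references unknown miRNA '%s'.", tpl$id, tpl$mirna),
          class = "mirmimic_registry_error")
  }
  check_rules <- function(rules, where) {
    for (r in rules) {
      if (is.null(r$tag) || !r$tag %in% RULE_TAGS) {
        abort(sprintf("Template %s: unknown rule tag '%s' in %s.", tpl$id,
                      r$tag %||% "<missing>", where),
              class = "mirmimic_registry_error")
      }
    }
    lapply(rules, function(r) lapply(r, function(x) if (is.list(x)) unlist(x) else x))
  }
  spec <- if (length(tpl$mismatch_spec)) {
    tibble(
      position = vapply(tpl$mismatch_spec, function(e) as.integer(e$position), integer(1)),
      kind = vapply(tpl$mismatch_spec, function(e) e$kind, character(1)),
      base = vapply(tpl$mismatch_spec, function(e) e$base %||% NA_character_, character(1))
    )
  } else {
    tibble(position = integer(), kind = character(), base = character())
  }
  if (!tpl$architecture %in% ARCHITECTURES) {
    abort(sprintf("Template %s: unknown architecture '%s'.", tpl$id, tpl$architecture),
          class = "mirmimic_registry_error")
  }
  structure(
    list(
      id = tpl$id,
      mirna = tpl$mirna,
      guide = toupper(mirnas[[tpl$mirna]]$guide),
      guide_rules = check_rules(tpl$guide_rules, "guide_rules"),
      passenger_rules = check_rules(tpl$passenger_rules, "passenger_rules"),
      mismatch_spec = validate_mismatch_spec(spec),
      architecture = tpl$architecture,
      shortlisted = isTRUE(tpl$shortlisted),
      provenance = tpl$provenance
    ),
    class = "mimic_template"
  )
}

validate_builtin_registry <- function(reg) {
  ids <- names(reg$templates)
  n_m <- sum(grepl("^M[0-9]+$", ids))
  short <- ids[vapply(reg$templates, function(t) t$shortlisted, logical(1))]
  ok <- n_m == 38L &&
    all(paste0("MA", 1:3) %in% ids) && all(paste0("MB", 1:3) %in% ids) &&
    length(short) == 8L
  if (!ok) {
    abort("Built-in registry failed its consistency checks.",
          class = "mirmimic_registry_error")
  }
  invisible(reg)
}

#' Retrieve one template from a registry
#' @param registry A `mimic_registry`.
#' @param id Template identifier, e.g. `"M23"`.
#' @return A `mimic_template`.
#' @export
get_template <- function(registry, id) {
  stopifnot(inherits(registry, "mimic_registry"))
  tpl <- registry$templates[[id]]
  if (is.null(tpl)) {
    abort(sprintf("No template '%s' in registry.", id), class = "mirmimic_registry_error")
  }
  tpl
}

#' @export
print.mimic_registry <- function(x, ...) {
  cat(sprintf("<mimic_registry> %d templates (%s)\n", length(x$templates), x$source))
  print(tidy(x), n = 10)
  invisible(x)
}

#' @export
print.mimic_template <- function(x, ...) {
  cat(sprintf("<mimic_template %s> %s, %s%s\n", x$id, x$mirna, x$architecture,
              if (x$shortlisted) ", shortlisted" else ""))
  cat(sprintf("  %d guide rule(s), %d passenger rule(s), %d mismatch entries\n",
              length(x$guide_rules), length(x$passenger_rules), nrow(x$mismatch_spec)))
  cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @describeIn tidy-mirmimic One row per registry template.
#' @export
tidy.mimic_registry <- function(x, ...) {
  purrr::map_dfr(x$templates, function(t) {
    tibble(
      id = t$id, mirna = t$mirna, architecture = t$architecture,
      shortlisted = t$shortlisted,
      n_guide_rules = length(t$guide_rules),
      n_passenger_rules = length(t$passenger_rules),
      n_mismatch_entries = nrow(t$mismatch_spec)
    )
  })
}
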