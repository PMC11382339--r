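#' @title Monomer registry
#'
#' @description The registry maps short sequence-grammar codes to monomer
#'   chemistry: the free nucleobase composition and the intact nucleoside
#'   composition (sugar + base, 5'- and 3'-OH, no linkage applied).  Bridged
#'   (locked) sugars carry a `bridge` delta on top of the 2'-deoxy sugar:
#'   +CH2O for LNA (2'-O,4'-C methylene) and +C2H4O for cEt (constrained
#'   ethyl).  Users may add or override codes, including alternative
#'   terminal-group deltas.
#' @name registry
NULL

.monomer <- function(code, label, base, nucleoside, bridge = ef()) {
  base <- if (is.character(base)) parse_ef(base) else base
  nuc <- if (is.character(nucleoside)) parse_ef(nucleoside) else nucleoside
  bridge <- if (is.character(bridge)) parse_ef(bridge) else bridge
  nuc <- ef_finalize(nuc + bridge, paste0("nucleoside ", code))
  sugar <- nuc - base
  if (any(unclass(sugar) < 0))
    stop("monomer ", code, ": nucleoside minus base is not a valid sugar")
  structure(list(code = code, label = label, base = base,
                 nucleoside = nuc, bridge = bridge),
            class = "monomer")
}

#' Default monomer registry
#'
#' Covers 2'-deoxy DNA A/C/G/T, 5-methyl-C (`mC`), their LNA (`l` prefix)
#' and cEt (`e` prefix) bridged variants, plus terminal-group deltas for
#' 5'/3'-OH (default, empty delta) and 5'-phosphate / 5'-thiophosphate.
#'
#' @return an object of class `monomer_registry`.
#' @examples
#' reg <- default_registry()
#' reg$entries$A$nucleoside
#' @export
default_registry <- function() {
  bases <- list(
    A  = c("adenine",          "C5H5N5",   "C10H13N5O3"),
    C  = c("cytosine",         "C4H5N3O",  "C9H13N3O4"),
    G  = c("guanine",          "C5H5N5O",  "C10H13N5O4"),
    T  = c("thymine",          "C5H6N2O2", "C10H14N2O5"),
    mC = c("5-methylcytosine", "C5H7N3O",  "C10H15N3O4")
  )
  entries <- list()
  for (code in names(bases)) {
    b <- bases[[code]]
    entries[[code]] <- .monomer(code, paste0("DNA ", b[1]), b[2], b[3])
    lc <- paste0("l", code)
    entries[[lc]] <- .monomer(lc, paste0("LNA ", b[1]), b[2], b[3],
                              bridge = "CH2O")
    ec <- paste0("e", code)
    entries[[ec]] <- .monomer(ec, paste0("cEt ", b[1]), b[2], b[3],
                              bridge = "C2H4O")
  }
  terminals <- list(
    OH = ef(),                       # free hydroxyl terminus (default)
    P  = parse_ef("HPO3"),           # phosphate terminus
    PS = parse_ef("HPO2S")           # thiophosphate terminus
  )
  structure(list(entries = entries, terminals = terminals, source = NA_character_),
            class = "monomer_registry")
}

#' Read a monomer registry from JSON
#'
#' The JSON file holds an array of objects with fields `code`, `name`,
#' `base_formula`, `nucleoside_formula` and optional `bridge_delta`
#' (Hill-style formula strings).  Entries override the built-in defaults.
#'
#' @param path path to a JSON registry file.
#' @param base registry to extend; defaults to [default_registry()].
#' @return a `monomer_registry`.
#' @export
read_registry <- function(path, base = default_registry()) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (e in raw) {
    if (is.null(e$code) || is.null(e$nucleoside_formula) || is.null(e$base_formula))
      stop("registry entry missing code/base_formula/nucleoside_formula in ", path)
    base$entries[[e$code]] <- .monomer(
      e$code, if (is.null(e$name)) e$code else e$name,
      e$base_formula, e$nucleoside_formula,
      bridge = if (is.null(e$bridge_delta)) ef() else e$bridge_delta)
  }
  base$source <- path
  base
}

#' Write a registry to JSON
#'
#' @param registry a `monomer_registry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  items <- lapply(registry$entries, function(m) list(
    code = m$code, name = m$label,
    base_formula = ef_string(m$base),
    nucleoside_formula = ef_string(m$nucleoside - m$bridge),
    bridge_delta = ef_string(m$bridge)))
  jsonlite::write_json(unname(items), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
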