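#' @title Sequence grammar and oligo model
#'
#' @description Sequences are written as registry codes separated by
#'   linkage symbols: `*` for a phosphorothioate (PS) linkage and `.` for a
#'   phosphodiester (PO) linkage, mirroring vendor notation.  Example:
#'   `"lG*mC.A"` is LNA-G --PS-- 5-methyl-C --PO-- DNA-A.  Terminal groups
#'   default to 5'-OH/3'-OH; alternates are written as a bracketed prefix or
#'   suffix naming a registry terminal code, e.g. `"[P]A*T"` (5'-phosphate)
#'   or `"A*T[PS]"` (3'-thiophosphate).
#' @name oligo
NULL

.LINKAGE_FORMULA <- list(PO = "HPO3", PS = "HPO2S")

#' Linkage composition
#'
#' @param kind `"PO"` or `"PS"`.
#' @return `ef` of the bridging phosphate (HPO3) or thiophosphate (HPO2S).
#' @export
linkage_formula <- function(kind) {
  kind <- match.arg(kind, c("PO", "PS"))
  parse_ef(.LINKAGE_FORMULA[[kind]])
}

#' Parse a sequence string into an oligo
#'
#' @param text sequence in the grammar described in [oligo].
#' @param registry a `monomer_registry`; defaults to [default_registry()].
#' @return an object of class `oligo` with fields `monomers` (list of
#'   monomers), `linkages` (character, `"PO"`/`"PS"`, length n-1),
#'   `five_term`/`three_term` (`ef` deltas relative to free OH termini).
#' @examples
#' parse_oligo("lG*mC.A")
#' @export
parse_oligo <- function(text, registry = default_registry()) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("\\s", "", text)
  five <- "OH"; three <- "OH"
  m <- regmatches(s, regexec("^\\[([A-Za-z0-9]+)\\]", s))[[1]]
  if (length(m)) { five <- m[2]; s <- sub("^\\[[A-Za-z0-9]+\\]", "", s) }
  m <- regmatches(s, regexec("\\[([A-Za-z0-9]+)\\]$", s))[[1]]
  if (length(m)) { three <- m[2]; s <- sub("\\[[A-Za-z0-9]+\\]$", "", s) }
  for (tc in c(five, three))
    if (is.null(registry$terminals[[tc]]))
      stop("unknown terminal-group code: ", tc)
  if (s == "") stop("empty sequence")
  chars <- strsplit(s, "")[[1]]
  toks <- character(0); links <- character(0); cur <- ""
  for (ch in chars) {
    if (ch %in% c("*", ".")) {
      if (cur == "") stop("dangling linkage symbol in sequence: ", text)
      toks <- c(toks, cur); cur <- ""
      links <- c(links, if (ch == "*") "PS" else "PO")
    } else cur <- paste0(cur, ch)
  }
  if (cur == "") stop("sequence ends with a dangling linkage symbol: ", text)
  toks <- c(toks, cur)
  unknown <- setdiff(toks, names(registry$entries))
  if (length(unknown))
    stop("unknown monomer token(s): ", paste(unique(unknown), collapse = ", "))
  structure(list(
    monomers = lapply(toks, function(tk) registry$entries[[tk]]),
    linkages = links,
    five_term = registry$terminals[[five]],
    three_term = registry$terminals[[three]],
    five_code = five, three_code = three
  ), class = "oligo")
}

#' Serialize an oligo back to its sequence string
#'
#' `parse_oligo(oligo_string(o))` is the identity on the oligo model.
#'
#' @param o an `oligo`.
#' @return sequence string.
#' @export
oligo_string <- function(o) {
  codes <- vapply(o$monomers, `[[`, "", "code")
  syms <- c(PS = "*", PO = ".")[o$linkages]
  body <- paste0(codes, c(syms, ""), collapse = "")
  pre <- if (o$five_code != "OH") paste0("[", o$five_code, "]") else ""
  suf <- if (o$three_code != "OH") paste0("[", o$three_code, "]") else ""
  paste0(pre, body, suf)
}

#' @export
length.oligo <- function(x) length(x$monomers)

#' @export
print.oligo <- function(x, ...) {
  cat("<oligo> ", oligo_string(x), "  (n = ", length(x),
      ", M = ", sprintf("%.4f", neutral_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' Neutral composition of an oligo
#'
#' M = sum of nucleosides + sum of linkage formulas - (n-1) H2O + terminal
#' deltas.
#'
#' @param o an `oligo`.
#' @return `ef` of the neutral molecule.
#' @export
oligo_formula <- function(o) {
  n <- length(o)
  f <- Reduce(`+`, lapply(o$monomers, `[[`, "nucleoside"), ef())
  for (lk in o$linkages) f <- f + linkage_formula(lk)
  if (n > 1) f <- ef_combine(f, .water_times(n - 1L), -1L)
  ef_finalize(f + o$five_term + o$three_term, "oligo")
}

.water_times <- function(k) ef(H = 2L * k, O = k)

#' Neutral monoisotopic mass of an oligo
#'
#' @param o an `oligo`.
#' @return mass in Da.
#' @examples
#' neutral_mass(parse_oligo("A*T"))
#' @export
neutral_mass <- function(o) ef_mass(oligo_formula(o))
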