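#' @title Elemental formulas
#'
#' @description An `ef` object is a named integer vector mapping element
#'   symbols to atom counts.  Counts may go negative transiently while
#'   bookkeeping losses; [ef_finalize()] is the point where a composition is
#'   declared to be a real molecule and negative counts become an error.
#'
#' @details Monoisotopic atomic masses are pinned to the CODATA/AME-derived
#'   values tabulated by NIST ("Atomic Weights and Isotopic Compositions",
#'   2021 release) so that every mass in the test-suite is bit-stable.
#' @name ef
NULL

# Pinned monoisotopic masses (Da) of the most abundant isotope.
.ATOMIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668
)

# Isotope table: per element, exact masses (Da) and natural abundances.
# Abundances are IUPAC representative values; each row sums to 1.
.ISOTOPES <- list(
  H = list(mass = c(1.00782503207, 2.01410177785),
           ab   = c(0.999885, 0.000115)),
  C = list(mass = c(12.0, 13.0033548378),
           ab   = c(0.9893, 0.0107)),
  N = list(mass = c(14.0030740048, 15.0001088982),
           ab   = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146196, 16.9991316, 17.9991610),
           ab   = c(0.99757, 0.00038, 0.00205)),
  P = list(mass = 30.97376163, ab = 1.0),
  S = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           ab   = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = list(mass = 22.9897692809, ab = 1.0),
  K = list(mass = c(38.96370668, 39.96399848, 40.96182576),
           ab   = c(0.932581, 0.000117, 0.067302))
)

# Mass of a proton (H atom minus one electron); used for deprotonation m/z.
.PROTON_MASS <- 1.007276466

#' Construct an elemental formula
#'
#' @param ... named integer counts, e.g. `ef(C = 10, H = 13, N = 5, O = 3)`.
#' @param counts alternatively, a named numeric vector of counts.
#' @return an object of class `ef`.
#' @examples
#' ef(H = 2, O = 1)
#' @export
ef <- function(..., counts = NULL) {
  x <- if (is.null(counts)) c(...) else counts
  if (length(x) == 0) {
    out <- integer(0)
    names(out) <- character(0)
    return(structure(out, class = "ef"))
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all formula counts must be named by element symbol")
  if (any(x != round(x))) stop("atom counts must be integers")
  x <- x[x != 0]
  storage.mode(x) <- "integer"
  x <- x[order(names(x))]
  structure(x, class = "ef")
}

#' Parse a molecular-formula string
#'
#' Accepts Hill-style strings such as `"C10H13N5O3"`; element symbols are
#' one capital letter optionally followed by a lower-case letter, each with
#' an optional integer count.
#'
#' @param text formula string.
#' @return an `ef` object.
#' @examples
#' parse_ef("C10H14N2O5")
#' @export
parse_ef <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("\\s", "", text)
  if (s == "" || s == "0") return(ef())
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula string: ", text)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  counts <- tapply(ct, el, sum)
  ef(counts = counts[counts != 0])
}

#' Combine two formulas
#'
#' Element-wise `a + sign * b`.  Negative counts are permitted in the result
#' (loss bookkeeping); validity is only enforced by [ef_finalize()].
#'
#' @param a,b `ef` objects.
#' @param sign `+1` to add, `-1` to subtract.
#' @return an `ef` object.
#' @export
ef_combine <- function(a, b, sign = 1L) {
  stopifnot(inherits(a, "ef"), inherits(b, "ef"), sign %in% c(1L, -1L))
  els <- union(names(a), names(b))
  av <- unclass(a)[els]; av[is.na(av)] <- 0L
  bv <- unclass(b)[els]; bv[is.na(bv)] <- 0L
  out <- av + sign * bv
  names(out) <- els
  ef(counts = out)
}

#' @export
Ops.ef <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "=="))
    stop("operation '", .Generic, "' not defined for ef objects")
  if (.Generic == "==") return(isTRUE(all.equal(ef_combine(e1, e2, -1L), ef())))
  ef_combine(e1, e2, if (.Generic == "+") 1L else -1L)
}

#' Declare a composition final
#'
#' @param f an `ef` object.
#' @param what label used in the error message.
#' @return `f`, invisibly unchanged, or an error if any count is negative
#'   (impossible chemistry, e.g. a base loss from a span lacking that base).
#' @export
ef_finalize <- function(f, what = "molecule") {
  if (any(unclass(f) < 0L))
    stop("impossible chemistry: ", what, " has negative count for ",
         paste(names(f)[unclass(f) < 0L], collapse = ", "))
  f
}

#' Monoisotopic mass of a formula
#'
#' @param f an `ef` object with all counts >= 0.
#' @return mass in Da.
#' @examples
#' ef_mass(parse_ef("H2O"))
#' @export
ef_mass <- function(f) {
  stopifnot(inherits(f, "ef"))
  ef_finalize(f)
  if (length(f) == 0) return(0.0)
  unknown <- setdiff(names(f), names(.ATOMIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(unclass(f) * .ATOMIC_MASS[names(f)])
}

#' Format a formula as a Hill-style string
#'
#' @param f an `ef` object.
#' @return single string, e.g. `"C10H13N5O3"`; `""` for the empty formula.
#' @export
ef_string <- function(f) {
  if (length(f) == 0) return("")
  hill <- c(intersect(c("C", "H"), names(f)),
            sort(setdiff(names(f), c("C", "H"))))
  v <- unclass(f)[hill]
  paste0(hill, ifelse(v == 1, "", v), collapse = "")
}

#' @export
print.ef <- function(x, ...) {
  cat("<ef> ", if (length(x) == 0) "(empty)" else ef_string(x), "\n", sep = "")
  invisible(x)
}

#' m/z of a deprotonated species (negative ion mode)
#'
#' @param M neutral monoisotopic mass in Da.
#' @param z charge magnitude (number of protons removed), a positive integer.
#' @return m/z of the `[M - zH]^z-` ion.
#' @examples
#' mz_of(1000, 2)
#' @export
mz_of <- function(M, z) {
  stopifnot(is.numeric(M), is.numeric(z))
  if (any(z < 1) || any(z != round(z))) stop("charge z must be a positive integer")
  (M - z * .PROTON_MASS) / z
}

# internal helpers used across modules
.MASS_H2O <- function() ef_mass(parse_ef("H2O"))
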