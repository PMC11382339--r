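#' @title Theoretical fragment-ion generation
#'
#' @description Terminal fragments follow the McLuckey nomenclature: the
#'   four backbone bonds of each internucleotide linkage give 5' fragments
#'   a/b/c/d and complementary 3' fragments w/x/y/z.  The end chemistry is
#'   fixed so that every complementary pair sums exactly to the neutral
#'   mass M:
#'   b_i = prefix(i); a_i = b_i - H2O; d_i = b_i + linkage_i;
#'   c_i = d_i - H2O; y_k = suffix(k); z_k = y_k - H2O;
#'   w_k = y_k + linkage_(n-k); x_k = w_k - H2O.
#'   The cleaved linkage's PO/PS identity travels with the fragment that
#'   keeps its phosphorus (d/c on the 5' side, w/x on the 3' side).
#'
#'   Fragment sets are plain data frames with a list-column of elemental
#'   formulas, one row per candidate.
#' @name fragments
NULL

.prefix_formula <- function(o, i) {
  f <- Reduce(`+`, lapply(o$monomers[seq_len(i)], `[[`, "nucleoside"), ef())
  if (i > 1) {
    for (lk in o$linkages[seq_len(i - 1L)]) f <- f + linkage_formula(lk)
    f <- ef_combine(f, .water_times(i - 1L), -1L)
  }
  f + o$five_term
}

.suffix_formula <- function(o, k) {
  n <- length(o)
  idx <- seq.int(n - k + 1L, n)
  f <- Reduce(`+`, lapply(o$monomers[idx], `[[`, "nucleoside"), ef())
  if (k > 1) {
    for (lk in o$linkages[seq.int(n - k + 1L, n - 1L)]) f <- f + linkage_formula(lk)
    f <- ef_combine(f, .water_times(k - 1L), -1L)
  }
  f + o$three_term
}

.frag_df <- function(label, ion_type, idx, span_lo, span_hi, formula,
                     losses = "", adducts = "", charge = NA_integer_,
                     mass = NA_real_, mz = NA_real_) {
  data.frame(label = label, ion_type = ion_type, idx = idx,
             span_lo = span_lo, span_hi = span_hi,
             losses = losses, adducts = adducts, charge = charge,
             mass = mass, mz = mz,
             formula = I(formula), stringsAsFactors = FALSE)
}

.with_mass <- function(df) {
  df$mass <- vapply(df$formula, ef_mass, 0.0)
  df
}

#' All terminal McLuckey fragments of an oligo
#'
#' Emits the 8 ion types at each of the n-1 cleavage positions as neutral
#' compositions (no charge assigned yet).
#'
#' @param o an `oligo` with n >= 2.
#' @return fragment data frame (8 x (n-1) rows) with columns `label`,
#'   `ion_type`, `idx` (monomers retained), `span_lo`/`span_hi` (monomer
#'   span), `formula` (list of `ef`), `mass`.
#' @export
terminal_fragments <- function(o) {
  n <- length(o)
  if (n < 2) stop("terminal fragments require an oligo of length >= 2")
  water <- parse_ef("H2O")
  rows <- list()
  for (i in seq_len(n - 1L)) {
    b <- .prefix_formula(o, i)
    d <- b + linkage_formula(o$linkages[i])
    five <- list(a = b - water, b = b, c = d - water, d = d)
    for (tp in names(five))
      rows[[length(rows) + 1L]] <- .frag_df(
        paste0(tp, i), tp, i, 1L, i, list(ef_finalize(five[[tp]], tp)))
  }
  for (k in seq_len(n - 1L)) {
    y <- .suffix_formula(o, k)
    w <- y + linkage_formula(o$linkages[n - k])
    three <- list(w = w, x = w - water, y = y, z = y - water)
    for (tp in names(three))
      rows[[length(rows) + 1L]] <- .frag_df(
        paste0(tp, k), tp, k, n - k + 1L, n, list(ef_finalize(three[[tp]], tp)))
  }
  .with_mass(do.call(rbind, rows))
}

#' Precursor (intact molecule) pseudo-fragment
#'
#' @param o an `oligo`.
#' @return one-row fragment data frame of ion type `"precursor"`.
#' @export
precursor_fragment <- function(o) {
  n <- length(o)
  .with_mass(.frag_df("M", "precursor", n, 1L, n, list(oligo_formula(o))))
}

#' Default neutral-loss set
#'
#' Water, ammonia and two hydrogen atoms ("two atoms" interpreted as 2H).
#'
#' @return list of loss specs (`label`, `formula`, `kind`).
#' @export
default_losses <- function() list(
  list(label = "H2O", formula = parse_ef("H2O"), kind = "neutral"),
  list(label = "NH3", formula = parse_ef("NH3"), kind = "neutral"),
  list(label = "2H",  formula = parse_ef("H2"),  kind = "neutral")
)

#' Expand a fragment set with neutral losses
#'
#' One loss per candidate (depth 1); a loss that would drive an element
#' count negative is silently skipped for that fragment.
#'
#' @param frags fragment data frame.
#' @param losses list of loss specs as in [default_losses()].
#' @return the input plus one row per surviving (fragment, loss) pair,
#'   labelled e.g. `"b2-H2O"`.
#' @export
apply_neutral_losses <- function(frags, losses = default_losses()) {
  if (length(losses) == 0 || nrow(frags) == 0) return(frags)
  out <- list(frags)
  for (ls in losses) {
    for (r in seq_len(nrow(frags))) {
      f <- ef_combine(frags$formula[[r]], ls$formula, -1L)
      if (any(unclass(f) < 0)) next
      row <- frags[r, , drop = FALSE]
      row$formula <- I(list(f))
      row$label <- paste0(row$label, "-", ls$label)
      row$losses <- paste0(row$losses, ifelse(row$losses == "", "", "+"),
                           ls$label)
      out[[length(out) + 1L]] <- row
    }
  }
  .with_mass(do.call(rbind, out))
}

#' Expand a fragment set with nucleobase losses from any ion type
#'
#' For every fragment and every distinct nucleobase composition present in
#' the fragment's monomer span, emits the fragment minus the neutral free
#' base (BH).  Multiple copies of the same base collapse to one candidate.
#'
#' @param frags fragment data frame (spans required).
#' @param o the parent `oligo`.
#' @return the input plus base-loss rows labelled e.g. `"w4-T"`.
#' @export
apply_base_losses <- function(frags, o) {
  if (nrow(frags) == 0) return(frags)
  out <- list(frags)
  for (r in seq_len(nrow(frags))) {
    span <- seq.int(frags$span_lo[r], frags$span_hi[r])
    bases <- list()
    for (m in o$monomers[span]) {
      key <- ef_string(m$base)
      if (is.null(bases[[key]]))
        bases[[key]] <- list(code = sub("^[le]", "", m$code), formula = m$base)
    }
    for (b in bases) {
      f <- ef_combine(frags$formula[[r]], b$formula, -1L)
      if (any(unclass(f) < 0)) next
      row <- frags[r, , drop = FALSE]
      row$formula <- I(list(f))
      row$label <- paste0(row$label, "-", b$code)
      row$losses <- paste0(row$losses, ifelse(row$losses == "", "", "+"),
                           "B(", b$code, ")")
      out[[length(out) + 1L]] <- row
    }
  }
  .with_mass(do.call(rbind, out))
}

#' Internal (J) fragments
#'
#' Internal fragments carry McLuckey cleavages on both ends and contain
#' neither terminus.  For cut positions i < j (retaining monomers
#' i+1 .. j), the neutral composition is the subtraction identity
#' `R_j + L_(n-i) - M`, where R is the 3'-end chemistry (a/b/c/d) and L the
#' 5'-end chemistry (w/x/y/z).  By default only the four same-bond pairs
#' aw, bx, cy, dz are enumerated (`pairs = "named"`); `pairs = "full"`
#' crosses all 16 combinations.  Note aw/bx (and cy/dz) are exactly
#' isobaric, which is why assignment groups J possibilities into one
#' record.
#'
#' @param o an `oligo` with n >= 3.
#' @param pairs `"named"` or `"full"`.
#' @return fragment data frame of ion type `"J"`, labels like `"J(a3w4)"`.
#' @export
internal_fragments <- function(o, pairs = c("named", "full")) {
  pairs <- match.arg(pairs)
  n <- length(o)
  if (n < 3) stop("internal fragments require an oligo of length >= 3")
  combos <- if (pairs == "named")
    list(c("a", "w"), c("b", "x"), c("c", "y"), c("d", "z"))
  else {
    cb <- list()
    for (R in c("a", "b", "c", "d")) for (L in c("w", "x", "y", "z"))
      cb[[length(cb) + 1L]] <- c(R, L)
    cb
  }
  term <- terminal_fragments(o)
  Mf <- oligo_formula(o)
  key <- function(tp, idx) which(term$ion_type == tp & term$idx == idx)
  rows <- list()
  for (i in seq_len(n - 2L)) for (j in seq.int(i + 1L, n - 1L)) {
    for (cmb in combos) {
      R <- cmb[1]; L <- cmb[2]
      f <- ef_combine(term$formula[[key(R, j)]] + term$formula[[key(L, n - i)]],
                      Mf, -1L)
      rows[[length(rows) + 1L]] <- .frag_df(
        paste0("J(", R, j, L, n - i, ")"), "J", NA_integer_,
        i + 1L, j, list(ef_finalize(f, "internal fragment")))
    }
  }
  .with_mass(do.call(rbind, rows))
}

#' Sodium adduct spec
#' @return adduct spec (+Na -H), applied by summation of the signed delta.
#' @export
adduct_na <- function() list(label = "Na", delta = ef(Na = 1L, H = -1L))

#' Expand with adducts and (optionally) charged base loss
#'
#' Adduct candidates add the signed formula delta (masses are summed, not
#' deducted).  Charged base loss (CBL) removes a nucleobase anion B- and
#' decrements the charge by one; it therefore only applies to charged
#' candidates with z >= 2, and is recorded as a loss.  The qualitative CBL
#' propensity ordering A- > T- > G- > C- is metadata, not a filter.
#'
#' @param frags fragment data frame; must carry charges if `enable_cbl`.
#' @param adducts list of adduct specs, e.g. `list(adduct_na())`.
#' @param enable_cbl logical.
#' @param o parent `oligo` (needed for CBL base lookup).
#' @return expanded fragment data frame.
#' @export
apply_adducts_and_cbl <- function(frags, adducts = list(), enable_cbl = FALSE,
                                  o = NULL) {
  out <- list(frags)
  for (ad in adducts) {
    for (r in seq_len(nrow(frags))) {
      f <- frags$formula[[r]] + ad$delta
      if (any(unclass(f) < 0)) next
      row <- frags[r, , drop = FALSE]
      row$formula <- I(list(f))
      row$label <- paste0(row$label, "+", ad$label)
      row$adducts <- paste0(row$adducts, ifelse(row$adducts == "", "", "+"),
                            ad$label)
      out[[length(out) + 1L]] <- row
    }
  }
  if (enable_cbl) {
    if (is.null(o)) stop("CBL expansion needs the parent oligo")
    for (r in seq_len(nrow(frags))) {
      z <- frags$charge[r]
      if (is.na(z) || z < 2) next   # z-1 must remain >= 1
      span <- seq.int(frags$span_lo[r], frags$span_hi[r])
      bases <- list()
      for (m in o$monomers[span]) bases[[ef_string(m$base)]] <-
          list(code = sub("^[le]", "", m$code), formula = m$base)
      for (b in bases) {
        # losing anion B- leaves the neutral-equivalent F - BH + H at z-1
        f <- ef_combine(frags$formula[[r]] + ef(H = 1L), b$formula, -1L)
        if (any(unclass(f) < 0)) next
        row <- frags[r, , drop = FALSE]
        row$formula <- I(list(f))
        row$charge <- z - 1L
        row$label <- paste0(row$label, "-CBL(", b$code, ")")
        row$losses <- paste0(row$losses, ifelse(row$losses == "", "", "+"),
                             "CBL(", b$code, ")")
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- .with_mass(do.call(rbind, out))
  if (any(!is.na(res$charge))) {
    ok <- !is.na(res$charge)
    res$mz[ok] <- mz_of(res$mass[ok], res$charge[ok])
  }
  res
}

#' Default catalogue configuration
#'
#' @param mz_min,mz_max m/z window cutoffs.
#' @param max_charge maximum charge state enumerated.
#' @param losses neutral-loss list ([default_losses()]); `list()` disables.
#' @param adducts adduct list; empty by default.
#' @param base_loss enumerate base losses from every ion type.
#' @param internal enumerate internal (J) fragments (n >= 3).
#' @param internal_pairs `"named"` (aw/bx/cy/dz) or `"full"`.
#' @param cbl enable charged base loss candidates.
#' @return config list for [enumerate_candidates()].
#' @export
catalogue_config <- function(mz_min = 100, mz_max = 2000, max_charge = 8L,
                             losses = default_losses(), adducts = list(),
                             base_loss = TRUE, internal = TRUE,
                             internal_pairs = "named", cbl = FALSE) {
  list(mz_min = mz_min, mz_max = mz_max, max_charge = as.integer(max_charge),
       losses = losses, adducts = adducts, base_loss = base_loss,
       internal = internal, internal_pairs = internal_pairs, cbl = cbl)
}

#' Enumerate the full candidate catalogue for an oligo
#'
#' Deterministic, duplicate-free, sorted by m/z.  Terminal fragments and
#' the precursor are expanded with neutral losses and base losses, internal
#' fragments are added, every composition is enumerated over charge states
#' 1..max_charge, the m/z window is applied, and adduct/CBL candidates are
#' appended.
#'
#' @param o an `oligo`.
#' @param config list from [catalogue_config()].
#' @return a `fragment_catalogue`: fragment data frame with `charge` and
#'   `mz` filled, plus attributes `oligo` and `config`.
#' @examples
#' cat <- enumerate_candidates(parse_oligo("A*T*G*C"),
#'                             catalogue_config(max_charge = 2))
#' head(cat)
#' @export
enumerate_candidates <- function(o, config = catalogue_config()) {
  if (config$mz_min >= config$mz_max) stop("empty m/z window")
  base <- rbind(terminal_fragments(o), precursor_fragment(o))
  if (config$internal && length(o) >= 3)
    base <- rbind(base, internal_fragments(o, config$internal_pairs))
  plain <- base
  if (length(config$losses)) base <- apply_neutral_losses(base, config$losses)
  if (config$base_loss) {
    bl <- apply_base_losses(plain, o)
    base <- rbind(base, bl[-(seq_len(nrow(plain))), , drop = FALSE])
  }
  if (length(config$adducts))
    base <- apply_adducts_and_cbl(base, config$adducts, FALSE)
  charged <- list()
  for (z in seq_len(config$max_charge)) {
    dz <- base
    dz$charge <- z
    dz$mz <- mz_of(dz$mass, z)
    charged[[z]] <- dz
  }
  cat <- do.call(rbind, charged)
  cat <- cat[cat$mz >= config$mz_min & cat$mz <= config$mz_max, , drop = FALSE]
  if (config$cbl) {
    cat <- apply_adducts_and_cbl(cat, list(), TRUE, o)
    cat <- cat[cat$mz >= config$mz_min & cat$mz <= config$mz_max, , drop = FALSE]
  }
  cat <- cat[!duplicated(paste(cat$label, cat$charge)), , drop = FALSE]
  cat <- cat[order(cat$mz, cat$label, cat$charge), , drop = FALSE]
  rownames(cat) <- NULL
  structure(cat, oligo = o, config = config,
            class = c("fragment_catalogue", class(cat)))
}

#' Write a catalogue to CSV
#'
#' Columns: label, ion_type, index, span, losses, adducts, charge, formula,
#' mz.
#'
#' @param cat a `fragment_catalogue`.
#' @param path output path (or `""` for stdout).
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(cat, path) {
  df <- data.frame(
    label = cat$label, ion_type = cat$ion_type, index = cat$idx,
    span = paste0(cat$span_lo, "-", cat$span_hi),
    losses = cat$losses, adducts = cat$adducts, charge = cat$charge,
    formula = vapply(cat$formula, ef_string, ""),
    mz = sprintf("%.6f", cat$mz), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
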