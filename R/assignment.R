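#' @title Peak assignment, classification and summary metrics
#'
#' @description Experimental peaks are matched against a candidate
#'   catalogue within a ppm tolerance, charge-filtered when the peak charge
#'   is known, and classified into the standard peak taxonomy: precursor,
#'   plain McLuckey cleavage, McLuckey + neutral loss, McLuckey + base
#'   loss, internal fragment, backbone-retained loss (precursor-mass
#'   fragmentation without backbone cleavage), adduct, unassigned.
#'   Isobaric candidates (e.g. the aw/bx internal pairs, or a vs b-H2O)
#'   are grouped under a single record and counted once.
#' @name assignment
NULL

.CATEGORY_ORDER <- c("precursor", "mcluckey", "mcluckey_neutral_loss",
                     "mcluckey_base_loss", "internal", "backbone_retained",
                     "adduct", "unassigned")

#' Match peaks to a catalogue
#'
#' For each peak, candidates within `tol_ppm` are ranked by absolute ppm
#' error (after filtering on the peak's charge, when known); every
#' candidate isobaric with the winner (within 1e-6 Da) is retained in the
#' same record.  Ties are broken deterministically by (category
#' precedence, ion type, index).
#'
#' @param peaks data frame with columns `mz`, `intensity` and optional
#'   `charge`.
#' @param catalogue a `fragment_catalogue`.
#' @param tol_ppm matching tolerance in ppm (default 5; the instrument's
#'   average errors are sub-ppm).
#' @return list of class `assignment_records`; each record holds the peak,
#'   the grouped candidate rows, and `best_ppm`.
#' @export
match_peaks <- function(peaks, catalogue, tol_ppm = 5) {
  stopifnot(tol_ppm > 0)
  if (nrow(catalogue) == 0) stop("empty catalogue")
  if (!all(c("mz", "intensity") %in% names(peaks)))
    stop("peaks need columns mz, intensity")
  has_charge <- "charge" %in% names(peaks)
  n <- length(attr(catalogue, "oligo"))
  records <- vector("list", nrow(peaks))
  for (p in seq_len(nrow(peaks))) {
    pmz <- peaks$mz[p]
    pz <- if (has_charge) peaks$charge[p] else NA_integer_
    ppm <- (pmz - catalogue$mz) / catalogue$mz * 1e6
    ok <- abs(ppm) <= tol_ppm
    if (!is.na(pz)) ok <- ok & catalogue$charge == pz
    rec <- list(mz = pmz, intensity = peaks$intensity[p], charge = pz,
                best_ppm = NA_real_, candidates = NULL,
                category = "unassigned")
    if (any(ok)) {
      idx <- which(ok)
      best <- idx[which.min(abs(ppm[idx]))]
      grp <- idx[abs(catalogue$mz[idx] - catalogue$mz[best]) < 1e-6]
      cand <- catalogue[grp, , drop = FALSE]
      cand$category <- .candidate_category(cand)
      o <- order(match(cand$category, .CATEGORY_ORDER), cand$ion_type, cand$idx)
      rec$candidates <- cand[o, , drop = FALSE]
      rec$best_ppm <- ppm[best]
    }
    records[[p]] <- rec
  }
  structure(records, class = "assignment_records",
            oligo = attr(catalogue, "oligo"), tol_ppm = tol_ppm)
}

.candidate_category <- function(cand) {
  out <- character(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    losses <- cand$losses[r]; adds <- cand$adducts[r]; tp <- cand$ion_type[r]
    out[r] <-
      if (adds != "") "adduct"
      else if (tp == "precursor" && losses == "") "precursor"
      else if (tp == "precursor") "backbone_retained"
      else if (tp == "J") "internal"
      else if (grepl("B\\(|CBL\\(", losses)) "mcluckey_base_loss"
      else if (losses != "") "mcluckey_neutral_loss"
      else "mcluckey"
  }
  out
}

#' Classify matched records
#'
#' Each record takes the highest-precedence category among its grouped
#' candidates: precursor > McLuckey > McLuckey+neutral loss >
#' McLuckey+base loss > internal > backbone-retained > adduct.
#'
#' @param records an `assignment_records` list from [match_peaks()].
#' @return the records with `category` filled in.
#' @export
classify_records <- function(records) {
  for (i in seq_along(records)) {
    cand <- records[[i]]$candidates
    if (!is.null(cand) && nrow(cand) > 0)
      records[[i]]$category <-
        .CATEGORY_ORDER[min(match(cand$category, .CATEGORY_ORDER))]
  }
  records
}

#' Sequence coverage from terminal-ion assignments
#'
#' A cleavage position (one of the n-1 internucleotide linkages) is
#' covered when at least one terminal ion (any of the 8 types, with or
#' without losses) is assigned at that bond.  Internal fragments are
#' ambiguous and never count.  `denominator = "residues"` divides by n
#' instead of n-1 (an alternative rounding convention).
#'
#' @param records classified `assignment_records`.
#' @param o the parent `oligo`; defaults to the catalogue's.
#' @param denominator `"linkages"` (default) or `"residues"`.
#' @return coverage percentage.
#' @export
sequence_coverage <- function(records, o = attr(records, "oligo"),
                              denominator = c("linkages", "residues")) {
  denominator <- match.arg(denominator)
  n <- length(o)
  pos <- integer(0)
  for (rec in records) {
    cand <- rec$candidates
    if (is.null(cand)) next
    term <- cand[cand$ion_type %in% c("a", "b", "c", "d", "w", "x", "y", "z"), ,
                 drop = FALSE]
    if (nrow(term) == 0) next
    p5 <- term$idx[term$ion_type %in% c("a", "b", "c", "d")]
    p3 <- n - term$idx[term$ion_type %in% c("w", "x", "y", "z")]
    pos <- c(pos, p5, p3)
  }
  denom <- if (denominator == "linkages") n - 1L else n
  100 * length(unique(pos)) / denom
}

#' Fragmentation efficiency
#'
#' efficiency = 100 * sum(F_i) / (sum(F_i) + P), where F_i are the product
#' ion abundances and P the precursor intensity after activation.
#'
#' @param F_i numeric vector of product-ion intensities (may be empty).
#' @param P precursor intensity.
#' @return percentage in [0, 100].
#' @examples
#' fragmentation_efficiency(c(30, 20), 50)  # 50
#' @export
fragmentation_efficiency <- function(F_i, P) {
  stopifnot(all(F_i >= 0), length(P) == 1, P >= 0)
  tot <- sum(F_i) + P
  if (tot == 0) stop("undefined efficiency: no product or precursor signal")
  100 * sum(F_i) / tot
}

#' Linear recalibration from anchor pairs
#'
#' Fits mz_corr = alpha * mz + beta by least squares on (observed,
#' theoretical) anchors — internal calibration when the anchors come from
#' the same spectrum, external calibration when the returned model is
#' applied to another spectrum via [apply_calibration()].
#'
#' @param peaks peak data frame.
#' @param anchors data frame with columns `observed`, `theoretical` (>= 2
#'   rows, non-degenerate span).
#' @return list: `peaks` (corrected), `model` (named alpha/beta), `rmse_ppm`.
#' @export
recalibrate <- function(peaks, anchors) {
  if (nrow(anchors) < 2) stop("need at least 2 calibration anchors")
  if (diff(range(anchors$observed)) == 0)
    stop("anchors span a zero m/z range")
  fit <- stats::lm(theoretical ~ observed, data = anchors)
  model <- c(alpha = unname(stats::coef(fit)[2]),
             beta = unname(stats::coef(fit)[1]))
  resid_ppm <- stats::residuals(fit) / anchors$theoretical * 1e6
  list(peaks = apply_calibration(peaks, model), model = model,
       rmse_ppm = sqrt(mean(resid_ppm^2)))
}

#' Apply a calibration model to a peak list
#' @param peaks peak data frame.
#' @param model named vector `c(alpha=, beta=)` from [recalibrate()].
#' @return peaks with corrected `mz`.
#' @export
apply_calibration <- function(peaks, model) {
  peaks$mz <- model[["alpha"]] * peaks$mz + model[["beta"]]
  peaks
}

#' Summary report over classified records
#'
#' Computes the standard summary table: total peaks, backbone-retained,
#' assigned (McLuckey + losses + internal), per-category counts,
#' assignment percentage, sequence coverage, and fragmentation efficiency
#' (products vs surviving precursor), plus per-category intensity vectors
#' for beeswarm-style plots.
#'
#' @param records classified `assignment_records`.
#' @param o parent `oligo`; defaults to the catalogue's.
#' @return list of class `assignment_report`.
#' @export
summary_report <- function(records, o = attr(records, "oligo")) {
  cats <- vapply(records, `[[`, "", "category")
  ints <- vapply(records, `[[`, 0.0, "intensity")
  counts <- vapply(.CATEGORY_ORDER, function(cc) sum(cats == cc), 0L)
  assigned_cats <- c("mcluckey", "mcluckey_neutral_loss",
                     "mcluckey_base_loss", "internal")
  assigned <- sum(counts[assigned_cats])
  total <- length(records)
  Fi <- ints[!cats %in% c("precursor", "unassigned")]
  P <- sum(ints[cats == "precursor"])
  eff <- if (length(Fi) + P == 0 || (sum(Fi) + P) == 0) NA_real_
         else fragmentation_efficiency(Fi, P)
  structure(list(
    total_peaks = total,
    counts = as.list(counts),
    assigned_peaks = assigned,
    assigned_pct = if (total > 0) 100 * assigned / total else 0,
    sequence_coverage_pct = if (total > 0) sequence_coverage(records, o) else 0,
    fragmentation_efficiency_pct = eff,
    F_i = unname(Fi), P = P,
    intensities_by_category =
      lapply(stats::setNames(nm = .CATEGORY_ORDER),
             function(cc) unname(ints[cats == cc])),
    tol_ppm = attr(records, "tol_ppm"),
    sequence = if (!is.null(o)) oligo_string(o) else NA_character_
  ), class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  cat("<assignment_report> ", x$sequence, "\n", sep = "")
  cat(sprintf("  total peaks          %d\n", x$total_peaks))
  for (cc in names(x$counts))
    cat(sprintf("  %-20s %d\n", cc, x$counts[[cc]]))
  cat(sprintf("  assigned             %d (%.1f%%)\n", x$assigned_peaks,
              x$assigned_pct))
  cat(sprintf("  sequence coverage    %.1f%%\n", x$sequence_coverage_pct))
  cat(sprintf("  frag. efficiency     %.1f%%\n",
              x$fragmentation_efficiency_pct))
  invisible(x)
}

#' Write a report as JSON
#' @param report an `assignment_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write per-peak assignment records as CSV
#' @param records classified `assignment_records`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  rows <- lapply(records, function(r) data.frame(
    mz = r$mz, intensity = r$intensity, charge = r$charge,
    category = r$category, best_ppm = r$best_ppm,
    candidates = if (is.null(r$candidates)) ""
                 else paste(r$candidates$label, collapse = ";"),
    stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
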