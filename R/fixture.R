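#' @title Synthetic spectrum fixtures
#'
#' @description The fixture generator stands in for unavailable
#'   experimental spectra: it emits a peak list at the theoretical m/z
#'   values of a known sequence's catalogue (optionally ppm-jittered),
#'   plus uniform decoy peaks kept away from every true peak, together
#'   with the ground-truth assignment table.  Fragment intensities follow
#'   a centre-weighted profile by default, mimicking the observation that
#'   cleavage abundances fall off towards the termini roughly like a
#'   normal distribution; intensities never affect m/z-based assignment.
#' @name fixture
NULL

#' Fixture specification
#'
#' @param sequence sequence string in the package grammar.
#' @param categories which candidate classes to emit: subset of
#'   `"mcluckey"`, `"mcluckey_neutral_loss"`, `"mcluckey_base_loss"`,
#'   `"internal"`, `"precursor"`.
#' @param charges charge states of the emitted ions.
#' @param ppm_sigma Gaussian m/z jitter sigma in ppm (>= 0).
#' @param n_decoys number of uniform decoy peaks (>= 0).
#' @param guard_ppm decoys are kept at least `2 * guard_ppm` away from any
#'   true peak (twice the default assignment tolerance).
#' @param intensity_model `"center"` (centre-weighted) or `"flat"`.
#' @param mz_min,mz_max m/z window.
#' @param seed RNG seed; same seed, same fixture.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(sequence, categories = "mcluckey", charges = 1:2,
                         ppm_sigma = 0, n_decoys = 0L, guard_ppm = 5,
                         intensity_model = c("center", "flat"),
                         mz_min = 100, mz_max = 4000, seed = 1L) {
  stopifnot(ppm_sigma >= 0, n_decoys >= 0)
  structure(list(sequence = sequence, categories = categories,
                 charges = as.integer(charges), ppm_sigma = ppm_sigma,
                 n_decoys = as.integer(n_decoys), guard_ppm = guard_ppm,
                 intensity_model = match.arg(intensity_model),
                 mz_min = mz_min, mz_max = mz_max, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic peak list with ground truth
#'
#' @param spec a [fixture_spec()].
#' @param registry monomer registry.
#' @return list: `peaks` (data frame `mz, intensity, charge`), `truth`
#'   (data frame with the emitted candidate labels and `is_decoy`),
#'   `oligo`, `catalogue`.
#' @export
generate_fixture <- function(spec, registry = default_registry()) {
  set.seed(spec$seed)
  o <- parse_oligo(spec$sequence, registry)
  cfg <- catalogue_config(
    mz_min = spec$mz_min, mz_max = spec$mz_max,
    max_charge = max(spec$charges),
    losses = if ("mcluckey_neutral_loss" %in% spec$categories)
      default_losses() else list(),
    base_loss = "mcluckey_base_loss" %in% spec$categories,
    internal = "internal" %in% spec$categories && length(o) >= 3)
  cat <- enumerate_candidates(o, cfg)
  keep <- cat$charge %in% spec$charges
  if (!"precursor" %in% spec$categories)
    keep <- keep & cat$ion_type != "precursor"
  cat_keep <- cat[keep, , drop = FALSE]
  # one peak per distinct m/z (isobaric candidates share a peak)
  grp <- cumsum(c(TRUE, diff(cat_keep$mz) > 1e-6))
  n <- length(o)
  rows <- lapply(split(seq_len(nrow(cat_keep)), grp), function(ix) {
    sub <- cat_keep[ix, , drop = FALSE]
    pos <- sub$idx[1]
    inten <- if (spec$intensity_model == "center" && !is.na(pos)) {
      center <- n / 2
      100 * exp(-(pos - center)^2 / (2 * (n / 4)^2))
    } else 100
    data.frame(mz = sub$mz[1], intensity = inten, charge = sub$charge[1],
               labels = paste(sub$label, collapse = ";"),
               is_decoy = FALSE, stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  if (spec$ppm_sigma > 0)
    truth$mz <- truth$mz *
      (1 + stats::rnorm(nrow(truth), 0, spec$ppm_sigma) * 1e-6)
  if (spec$n_decoys > 0) {
    decoys <- numeric(0)
    guard <- 2 * spec$guard_ppm * 1e-6
    while (length(decoys) < spec$n_decoys) {
      cand <- stats::runif(1, spec$mz_min, spec$mz_max)
      if (all(abs(cand - cat$mz) / cat$mz > guard))
        decoys <- c(decoys, cand)
    }
    truth <- rbind(truth, data.frame(
      mz = decoys, intensity = stats::runif(spec$n_decoys, 1, 10),
      charge = NA_integer_, labels = "", is_decoy = TRUE))
  }
  truth <- truth[order(truth$mz), , drop = FALSE]
  rownames(truth) <- NULL
  list(peaks = truth[, c("mz", "intensity", "charge")], truth = truth,
       oligo = o, catalogue = cat)
}
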