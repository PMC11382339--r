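#' @title 2DMS acquisition simulation and processing
#'
#' @description Simulates two-dimensional FT-ICR acquisition: the
#'   precursor's cyclotron motion is modulated along the encoding delay t1,
#'   the fragment yield follows the fragmentation-zone profile of the
#'   modulated precursor radius, and each t1 row is the average of m
#'   accumulated scans (the multi-scan accumulation pulse scheme).  The
#'   processed map is the row-then-column magnitude 2D-FFT, with axes
#'   mapped to m/z through the single-term calibration f = A / (m/z).
#'   Low-rank denoising (truncated or randomized SVD, default rank 10) is a
#'   plug-point standing in for urQRd/sane.
#' @name twodms
NULL

#' Acquisition parameters for the 2DMS simulator
#'
#' @param n_t1 number of t1 rows N.
#' @param m_scans scans accumulated and averaged per t1 increment.
#' @param t1_step t1 increment in seconds.
#' @param n_t2 transient points per row.
#' @param sample_rate t2 sampling rate in Hz.
#' @param mz_cutoff_high detection high-mass cutoff (m/z); noise harmonics
#'   of this cutoff appear at mz_cutoff_high / n.
#' @param seed RNG seed; all simulator randomness flows from it.
#' @return list of class `acq2d_params`.
#' @export
acq2d_params <- function(n_t1 = 64L, m_scans = 1L, t1_step = 2e-5,
                         n_t2 = 256L, sample_rate = 1e6,
                         mz_cutoff_high = 2000, seed = NULL) {
  stopifnot(n_t1 >= 1, m_scans >= 1, n_t2 >= 1, t1_step > 0, sample_rate > 0)
  structure(list(n_t1 = as.integer(n_t1), m_scans = as.integer(m_scans),
                 t1_step = t1_step, n_t2 = as.integer(n_t2),
                 sample_rate = sample_rate, mz_cutoff_high = mz_cutoff_high,
                 seed = seed), class = "acq2d_params")
}

#' Species model for the 2DMS simulator
#'
#' @param precursor_mz,charge precursor ion.
#' @param fragments data frame with columns `mz`, `amp`.
#' @param precursor_amp residual precursor amplitude in each transient.
#' @param profile fragmentation-zone profile versus the modulated precursor
#'   radius: `"gaussian"` (laser beam) or `"flat"` (broad electron-cathode
#'   plateau, i.e. no t1 modulation).
#' @param profile_width Gaussian width of the laser profile, in units of
#'   the normalized precursor radius (0..1).
#' @param noise_sd additive white-noise sigma per scan.
#' @param scint_sd per-scan multiplicative (scintillation / t1-noise)
#'   amplitude jitter sigma.
#' @param freq_const calibration constant A in f = A / (m/z), Hz.
#' @return list of class `species_model`.
#' @export
species_model <- function(precursor_mz, charge = 1L,
                          fragments = data.frame(mz = numeric(), amp = numeric()),
                          precursor_amp = 1, profile = c("gaussian", "flat"),
                          profile_width = 0.5, noise_sd = 0, scint_sd = 0,
                          freq_const = 1e7) {
  profile <- match.arg(profile)
  stopifnot(all(fragments$amp >= 0), precursor_amp >= 0,
            noise_sd >= 0, scint_sd >= 0)
  structure(list(precursor_mz = precursor_mz, charge = as.integer(charge),
                 fragments = fragments, precursor_amp = precursor_amp,
                 profile = profile, profile_width = profile_width,
                 noise_sd = noise_sd, scint_sd = scint_sd,
                 freq_const = freq_const), class = "species_model")
}

.mz_to_freq <- function(mz, A) A / mz

.profile_value <- function(model, radius) {
  switch(model$profile,
         flat = rep(1, length(radius)),
         gaussian = exp(-radius^2 / (2 * model$profile_width^2)))
}

#' Simulate a 2DMS time-domain map
#'
#' Row r (t1 = r * t1_step) modulates the precursor radius as
#' cos(2 pi f_p t1); the fragment yield is the zone profile evaluated at
#' the normalized radius (1 + cos)/2.  Each of the m scans adds
#' independent white noise and scintillation jitter; the stored row is the
#' scan average.
#'
#' @param params an `acq2d_params`.
#' @param model a `species_model`.
#' @return list of class `map2d`: `matrix` (N x n_t2), `domain = "time"`,
#'   `params`, `model`, `log`.
#' @export
simulate_2d <- function(params, model) {
  if (!is.null(params$seed)) set.seed(params$seed)
  A <- model$freq_const
  t2 <- (seq_len(params$n_t2) - 1L) / params$sample_rate
  fp <- .mz_to_freq(model$precursor_mz, A)
  frag_cos <- if (nrow(model$fragments) > 0)
    vapply(seq_len(nrow(model$fragments)),
           function(i) cos(2 * pi * .mz_to_freq(model$fragments$mz[i], A) * t2),
           numeric(params$n_t2))
  else matrix(0, params$n_t2, 0)
  prec_vec <- model$precursor_amp * cos(2 * pi * fp * t2)
  X <- matrix(0, params$n_t1, params$n_t2)
  for (r in seq_len(params$n_t1)) {
    t1 <- (r - 1L) * params$t1_step
    radius <- (1 + cos(2 * pi * fp * t1)) / 2
    yield <- .profile_value(model, radius)
    sig <- prec_vec
    if (ncol(frag_cos) > 0)
      sig <- sig + as.vector(frag_cos %*% (model$fragments$amp * yield))
    scans <- matrix(0, params$m_scans, params$n_t2)
    for (s in seq_len(params$m_scans)) {
      jitter <- if (model$scint_sd > 0) 1 + stats::rnorm(1, 0, model$scint_sd) else 1
      noise <- if (model$noise_sd > 0) stats::rnorm(params$n_t2, 0, model$noise_sd) else 0
      scans[s, ] <- jitter * sig + noise
    }
    X[r, ] <- average_scans(scans)
  }
  structure(list(matrix = X, domain = "time", params = params, model = model,
                 log = sprintf("simulate_2d: N=%d m=%d", params$n_t1,
                               params$m_scans)),
            class = "map2d")
}

#' Average accumulated scans element-wise
#'
#' @param scans matrix with one scan per row (equal lengths), or a list of
#'   equal-length numeric vectors.
#' @return the averaged row; averaging m scans reduces white-noise sigma by
#'   sqrt(m) and reduces stored data size by the number of scans.
#' @export
average_scans <- function(scans) {
  if (is.list(scans)) {
    if (length(scans) == 0) stop("empty scan list")
    if (length(unique(lengths(scans))) != 1) stop("scans have unequal lengths")
    scans <- do.call(rbind, scans)
  }
  if (nrow(scans) == 0) stop("empty scan list")
  colMeans(scans)
}

#' Low-rank denoising of a 2D map
#'
#' Rank-k approximation of the time-domain (or interferogram) matrix via
#' truncated SVD, or a randomized range-finder variant.  The in-house
#' algorithms of 2DMS processing pipelines (urQRd, sane) are low-rank
#' projections of this kind; the rank-10 default mirrors common practice.
#'
#' @param map a `map2d`.
#' @param rank target rank k (1 <= k < min(dim)).
#' @param algorithm `"truncated"` or `"randomized"`.
#' @param oversample extra sketch columns for the randomized variant.
#' @return denoised `map2d` with an updated processing log.
#' @export
denoise_low_rank <- function(map, rank = 10L, algorithm = c("truncated",
                                                            "randomized"),
                             oversample = 8L) {
  algorithm <- match.arg(algorithm)
  X <- map$matrix
  if (rank < 1 || rank >= min(dim(X)))
    stop("rank must satisfy 1 <= rank < min(dim)")
  if (algorithm == "truncated") {
    sv <- svd(X, nu = rank, nv = rank)
    Y <- sv$u %*% (diag(sv$d[seq_len(rank)], rank) %*% t(sv$v))
  } else {
    l <- min(rank + oversample, min(dim(X)))
    Omega <- matrix(stats::rnorm(ncol(X) * l), ncol(X), l)
    Q <- qr.Q(qr(X %*% Omega))
    B <- t(Q) %*% X
    sv <- svd(B, nu = rank, nv = rank)
    Y <- (Q %*% sv$u) %*% (diag(sv$d[seq_len(rank)], rank) %*% t(sv$v))
  }
  map$matrix <- Y
  map$log <- c(map$log, sprintf("denoise_low_rank: %s rank=%d", algorithm, rank))
  map
}

.next_pow2 <- function(n) 2L^ceiling(log2(n))

#' Process a time-domain map into a magnitude 2D spectrum
#'
#' FFT along t2 for each row, magnitude, then FFT along t1 for each
#' column, magnitude.  Matrices are zero-filled to the next power of two
#' in both dimensions.  Axes are converted to m/z via the inverse
#' calibration m/z = A / f used by the simulator; the zero-frequency row
#' (the t1-noise axis, where unmodulated signal piles up) and column carry
#' non-finite m/z and are kept in place.
#'
#' @param map a time-domain `map2d`.
#' @return spectral `map2d` with `axes$precursor_mz` (rows) and
#'   `axes$fragment_mz` (columns).
#' @export
process_2d <- function(map) {
  if (map$domain != "time") stop("process_2d expects a time-domain map")
  X <- map$matrix
  p <- map$params; A <- map$model$freq_const
  n2 <- .next_pow2(ncol(X)); n1 <- .next_pow2(nrow(X))
  Xp <- matrix(0, n1, n2)
  Xp[seq_len(nrow(X)), seq_len(ncol(X))] <- X
  S <- Mod(t(stats::mvfft(t(Xp))))          # FFT along t2 (rows)
  S <- S[, seq_len(n2 %/% 2), drop = FALSE]
  S <- Mod(stats::mvfft(S))                 # FFT along t1 (columns)
  S <- S[seq_len(n1 %/% 2), , drop = FALSE]
  f2 <- (seq_len(n2 %/% 2) - 1L) * p$sample_rate / n2
  f1 <- (seq_len(n1 %/% 2) - 1L) / (n1 * p$t1_step)
  map$matrix <- S
  map$domain <- "spectrum"
  map$axes <- list(precursor_mz = ifelse(f1 > 0, A / f1, Inf),
                   fragment_mz = ifelse(f2 > 0, A / f2, Inf),
                   f1 = f1, f2 = f2)
  map$log <- c(map$log, sprintf("process_2d: zero-filled to %dx%d", n1, n2))
  map
}

.nearest_idx <- function(axis, mz) {
  ok <- is.finite(axis)
  if (!any(ok) || mz > max(axis[ok]) * 1.5 || mz < min(axis[ok]) / 1.5)
    stop("requested m/z ", mz, " outside the axis range")
  which(ok)[which.min(abs(axis[ok] - mz))]
}

#' Extract a 1D line from a processed 2D map
#'
#' The autocorrelation line samples the diagonal where the precursor axis
#' equals the fragment axis (it displays all precursors); a fragment line
#' is the row nearest a requested precursor m/z (that precursor's tandem
#' spectrum); a precursor line is the column nearest a requested fragment
#' m/z (which precursors share that fragment).
#'
#' @param map processed `map2d`.
#' @param which `"autocorrelation"`, `"fragment"` or `"precursor"`.
#' @param mz requested precursor m/z (fragment line) or fragment m/z
#'   (precursor line).
#' @return data frame `(mz, intensity)`.
#' @export
extract_line <- function(map, which = c("autocorrelation", "fragment",
                                        "precursor"), mz = NULL) {
  which <- match.arg(which)
  if (map$domain != "spectrum") stop("extract_line expects a processed map")
  ax <- map$axes
  if (which == "autocorrelation") {
    pr <- ax$precursor_mz[is.finite(ax$precursor_mz)]
    idx <- vapply(ax$fragment_mz, function(m)
      if (is.finite(m) && m <= max(pr) * 1.5 && m >= min(pr) / 1.5)
        .nearest_idx(ax$precursor_mz, m) else NA_integer_,
      0L)
    val <- vapply(seq_along(idx), function(j)
      if (is.na(idx[j])) NA_real_ else map$matrix[idx[j], j], 0.0)
    return(data.frame(mz = ax$fragment_mz, intensity = val))
  }
  if (is.null(mz)) stop("mz required for fragment/precursor lines")
  if (which == "fragment") {
    r <- .nearest_idx(ax$precursor_mz, mz)
    data.frame(mz = ax$fragment_mz, intensity = map$matrix[r, ])
  } else {
    j <- .nearest_idx(ax$fragment_mz, mz)
    data.frame(mz = ax$precursor_mz, intensity = map$matrix[, j])
  }
}

#' Signal-to-noise ratio of a peak in a 1D spectrum
#'
#' Peak magnitude (maximum within `halfwin` bins of the nearest bin to the
#' requested m/z) divided by the standard deviation of the noise region.
#'
#' @param spectrum data frame `(mz, intensity)`.
#' @param peak_mz peak position.
#' @param noise_region length-2 m/z range containing only noise.
#' @param halfwin peak search half-width in bins.
#' @return SNR.
#' @export
snr <- function(spectrum, peak_mz, noise_region, halfwin = 1L) {
  i <- .nearest_idx(spectrum$mz, peak_mz)
  win <- max(1, i - halfwin):min(nrow(spectrum), i + halfwin)
  peak <- max(spectrum$intensity[win])
  inr <- is.finite(spectrum$mz) & spectrum$mz >= min(noise_region) &
    spectrum$mz <= max(noise_region)
  if (sum(inr) < 2) stop("empty noise region")
  peak / stats::sd(spectrum$intensity[inr])
}

#' SNR of a 2D peak in a processed map
#'
#' @param map processed `map2d`.
#' @param precursor_mz,fragment_mz peak coordinates.
#' @param noise_rows,noise_cols index ranges of a signal-free rectangle.
#' @param halfwin search half-width in bins around the expected bin.
#' @return SNR.
#' @export
snr_map <- function(map, precursor_mz, fragment_mz, noise_rows, noise_cols,
                    halfwin = 1L) {
  r <- .nearest_idx(map$axes$precursor_mz, precursor_mz)
  j <- .nearest_idx(map$axes$fragment_mz, fragment_mz)
  rw <- max(1, r - halfwin):min(nrow(map$matrix), r + halfwin)
  cw <- max(1, j - halfwin):min(ncol(map$matrix), j + halfwin)
  peak <- max(map$matrix[rw, cw])
  noise <- map$matrix[noise_rows, noise_cols]
  peak / stats::sd(noise)
}

#' m/z of the n-th harmonic artifact
#'
#' ICR frequency scales as 1/(m/z), so the n-th harmonic of a fundamental
#' appears at m/z fundamental / n (e.g. the m/z 2000 detection cutoff puts
#' harmonics at m/z 1000 and 667).
#'
#' @param fundamental fundamental m/z.
#' @param n harmonic order (>= 1).
#' @return harmonic m/z.
#' @export
harmonic_mz <- function(fundamental, n) {
  if (any(n < 1)) stop("harmonic order must be >= 1")
  fundamental / n
}

#' Distance of closest approach of an electron to a multiply charged anion
#'
#' Coulomb turning radius d = q1 q2 / (4 pi eps0 V); with q1 = z elementary
#' charges, q2 = e, and V in volts this reduces to d = 14.39964 z / V
#' angstroms.
#'
#' @param z precursor charge magnitude (elementary charges, >= 1).
#' @param V_bias electron bias energy in eV (> 0).
#' @return distance in angstroms.
#' @examples
#' closest_approach(5, 22.8)
#' @export
closest_approach <- function(z, V_bias) {
  if (any(V_bias <= 0)) stop("electron bias must be positive")
  if (any(z < 1)) stop("charge must be >= 1")
  14.39964 * z / V_bias
}

#' Photon energy of a laser wavelength
#'
#' E (eV) = 1239.841 / lambda (nm).
#'
#' @param wavelength_nm wavelength in nm (> 0).
#' @return photon energy in eV.
#' @examples
#' photon_energy(193)   # ArF excimer, ~6.4 eV
#' @export
photon_energy <- function(wavelength_nm) {
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  1239.841 / wavelength_nm
}

#' Save / load a 2D map as text (CSV matrix + JSON metadata)
#'
#' @param map a `map2d`.
#' @param path basename; writes `<path>.csv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_map2d <- function(map, path) {
  utils::write.table(map$matrix, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(domain = map$domain, params = unclass(map$params),
               model = c(unclass(map$model)[setdiff(names(map$model),
                                                    "fragments")],
                         list(fragments = map$model$fragments)),
               log = map$log, axes = map$axes)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_map2d
#' @export
read_map2d <- function(path) {
  X <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(X) <- NULL
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  out <- list(matrix = X, domain = meta$domain,
              params = do.call(acq2d_params,
                               meta$params[names(meta$params) != "seed"]),
              model = do.call(species_model, meta$model), log = meta$log)
  if (!is.null(meta$axes)) out$axes <- lapply(meta$axes, as.numeric)
  structure(out, class = "map2d")
}
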