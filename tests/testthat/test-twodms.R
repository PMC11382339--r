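base_model <- function(...) {
  species_model(precursor_mz = 1000, charge = 8,
                fragments = data.frame(mz = c(500, 800), amp = c(1, 0.7)),
                precursor_amp = 1, ...)
}

test_that("simulation is seeded-reproducible and degenerate cases hold", {
  p <- acq2d_params(n_t1 = 16, n_t2 = 64, seed = 99)
  m <- base_model(noise_sd = 0.3, scint_sd = 0.05)
  expect_equal(simulate_2d(p, m)$matrix, simulate_2d(p, m)$matrix)
  # zero noise + flat profile: no t1 modulation, every row identical
  flat <- base_model(profile = "flat")
  X <- simulate_2d(acq2d_params(n_t1 = 8, n_t2 = 64), flat)$matrix
  expect_equal(X, matrix(rep(X[1, ], each = 8), nrow = 8), tolerance = 1e-12)
  # zero noise + gaussian profile: fragment interferogram periodic at the
  # precursor frequency (compare t1 = 0 and t1 = one precursor period)
  gm <- base_model(profile = "gaussian")
  fp <- gm$freq_const / gm$precursor_mz
  step <- 1 / fp / 8                       # 8 rows per precursor period
  Xp <- simulate_2d(acq2d_params(n_t1 = 17, n_t2 = 64, t1_step = step),
                    gm)$matrix
  expect_equal(Xp[1, ], Xp[9, ], tolerance = 1e-9)
  expect_equal(Xp[1, ], Xp[17, ], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(Xp[1, ], Xp[5, ])))
})

test_that("scan averaging: identity, pass-through, sqrt(m) noise reduction", {
  row <- sin(seq_len(64))
  expect_equal(average_scans(rbind(row, row, row)), row)
  expect_equal(average_scans(matrix(row, 1)), row)
  expect_error(average_scans(list()), "empty")
  expect_error(average_scans(list(1:3, 1:4)), "unequal")
  set.seed(71)
  sds <- replicate(200, stats::sd(average_scans(
    matrix(stats::rnorm(8 * 64), 8, 64))))
  expect_equal(mean(sds), 1 / sqrt(8), tolerance = 0.05)
})

test_that("low-rank denoising: exactness at true rank, SNR gain on noise", {
  set.seed(81)
  U <- matrix(stats::rnorm(64 * 3), 64, 3)
  V <- matrix(stats::rnorm(128 * 3), 128, 3)
  X <- U %*% t(V)
  map <- structure(list(matrix = X, domain = "time",
                        params = acq2d_params(n_t1 = 64, n_t2 = 128),
                        model = base_model(), log = character()),
                   class = "map2d")
  for (alg in c("truncated", "randomized")) {
    Y <- denoise_low_rank(map, rank = 3, algorithm = alg)$matrix
    expect_lt(max(abs(Y - X)), 1e-8)
  }
  expect_error(denoise_low_rank(map, rank = 64), "rank")
  # rank-10 default on rank-3 signal + noise improves SNR
  noisy <- map; noisy$matrix <- X + matrix(stats::rnorm(64 * 128, 0, 0.5),
                                           64, 128)
  den <- denoise_low_rank(noisy, rank = 10)
  err_in <- sqrt(mean((noisy$matrix - X)^2))
  err_out <- sqrt(mean((den$matrix - X)^2))
  # rank-10 keeps ~ (64+128)*10 of 64*128 noise dof: ~0.48x error expected
  expect_lt(err_out, 0.7 * err_in)
  expect_match(den$log[length(den$log)], "rank=10")
})

test_that("2D-FFT processing localizes peaks and conserves power", {
  p <- acq2d_params(n_t1 = 64, n_t2 = 256)
  m <- base_model(profile = "gaussian", profile_width = 0.5)
  tmap <- simulate_2d(p, m)
  smap <- process_2d(tmap)
  # every (precursor, fragment) pair lands within 1 bin of its expected
  # coordinates
  A <- m$freq_const
  f1_exp <- A / m$precursor_mz
  r_exp <- round(f1_exp * 64 * p$t1_step) + 1
  for (k in seq_len(nrow(m$fragments))) {
    c_exp <- round((A / m$fragments$mz[k]) * 256 / p$sample_rate) + 1
    win <- smap$matrix[(r_exp - 1):(r_exp + 1), (c_exp - 1):(c_exp + 1)]
    away <- smap$matrix[(r_exp + 5):(r_exp + 15), (c_exp + 5):(c_exp + 15)]
    expect_gt(max(win), 10 * max(away))
  }
  # unmodulated species: energy confined to the zero-frequency (DC) row
  flat <- process_2d(simulate_2d(p, base_model(profile = "flat")))
  col <- which.max(flat$matrix[1, ])
  expect_gt(flat$matrix[1, col], 50 * max(flat$matrix[5:32, col]))
  # Parseval at the t2 FFT stage (zero-filled length 256)
  X <- tmap$matrix
  sp <- Mod(t(stats::mvfft(t(X))))
  expect_equal(sum(sp^2) / 256, sum(X^2), tolerance = 1e-6)
  expect_error(process_2d(smap), "time-domain")
})

test_that("line extraction recovers precursors and shared fragments", {
  frags_a <- data.frame(mz = c(400, 700), amp = c(1, 1))
  p <- acq2d_params(n_t1 = 128, n_t2 = 512, t1_step = 1e-5)
  two_prec <- function(mz1, mz2) {
    m1 <- species_model(mz1, fragments = frags_a, profile = "gaussian")
    m2 <- species_model(mz2, fragments = data.frame(mz = 700, amp = 1),
                        profile = "gaussian")
    map1 <- simulate_2d(p, m1); map2 <- simulate_2d(p, m2)
    map1$matrix <- map1$matrix + map2$matrix
    map1
  }
  smap <- process_2d(two_prec(1000, 1250))
  # autocorrelation shows both precursors
  ac <- extract_line(smap, "autocorrelation")
  for (mzp in c(1000, 1250)) {
    i <- which.min(abs(ac$mz - mzp))
    expect_gt(ac$intensity[i], 0.1 * max(ac$intensity, na.rm = TRUE))
  }
  # fragment line of precursor 1000 contains 400; of 1250 it does not
  fl1 <- extract_line(smap, "fragment", mz = 1000)
  fl2 <- extract_line(smap, "fragment", mz = 1250)
  i400 <- which.min(abs(fl1$mz - 400))
  expect_gt(fl1$intensity[i400], 10 * fl2$intensity[i400])
  # the shared 700 fragment appears at both precursor rows of its column
  # (ignoring the zero-frequency t1-noise row, where unmodulated signal
  # piles up)
  pl <- extract_line(smap, "precursor", mz = 700)
  off_dc <- max(pl$intensity[-(1:3)], na.rm = TRUE)
  for (mzp in c(1000, 1250)) {
    i <- which.min(abs(pl$mz - mzp))
    expect_gt(pl$intensity[i], 0.2 * off_dc)
  }
  expect_error(extract_line(smap, "fragment", mz = 1e9), "outside")
})

test_that("SNR definition: O(1) on pure noise, linear in amplitude", {
  set.seed(91)
  spec <- data.frame(mz = seq(100, 1000, length.out = 512),
                     intensity = abs(stats::rnorm(512)))
  s0 <- snr(spec, 550, c(100, 400))
  expect_lt(s0, 10)
  spec2 <- spec
  i <- which.min(abs(spec$mz - 550))
  spec2$intensity[i] <- 50
  s1 <- snr(spec2, 550, c(100, 400))
  spec2$intensity[i] <- 100
  expect_equal(snr(spec2, 550, c(100, 400)) / s1, 2, tolerance = 1e-9)
  expect_error(snr(spec, 550, c(2000, 3000)), "outside|empty")
})

test_that("8-scan accumulation: same peak positions, ~sqrt(8) SNR gain", {
  m <- base_model(noise_sd = 0.5, scint_sd = 0.02)
  one <- function(mscans, seed) {
    p <- acq2d_params(n_t1 = 64, n_t2 = 256, m_scans = mscans, seed = seed)
    process_2d(simulate_2d(p, m))
  }
  gains <- vapply(1:12, function(s) {
    s1 <- one(1, 2 * s); s8 <- one(8, 2 * s + 1)
    pk1 <- which(s1$matrix[6:32, ] == max(s1$matrix[6:32, ]), arr.ind = TRUE)
    pk8 <- which(s8$matrix[6:32, ] == max(s8$matrix[6:32, ]), arr.ind = TRUE)
    expect_lt(max(abs(pk1 - pk8)), 2)       # same positions, only SNR differs
    snr_map(s8, 1000, 500, 20:30, 100:128) /
      snr_map(s1, 1000, 500, 20:30, 100:128)
  }, 0.0)
  expect_gt(stats::median(gains), 1.7)
  expect_lt(stats::median(gains), 3.0)
})

test_that("SNR grows as sqrt(m): fitted exponent 0.5 +/- 0.1", {
  # bin-centred frequencies (precursor on t1 bin 8, fragment on t2 bin 2)
  # so spectral leakage does not set a noise floor that saturates the fit
  m <- species_model(1000, 8, data.frame(mz = 500, amp = 1),
                     precursor_amp = 1, profile = "gaussian", noise_sd = 0.5)
  ms <- c(1, 2, 4, 8, 16)
  med_snr <- vapply(ms, function(mm) {
    stats::median(vapply(1:8, function(s) {
      p <- acq2d_params(n_t1 = 32, n_t2 = 128, m_scans = mm,
                        t1_step = 2.5e-5, sample_rate = 1.28e6,
                        seed = 1000 * mm + s)
      snr_map(process_2d(simulate_2d(p, m)), 1000, 500, 13:16, 40:64)
    }, 0.0))
  }, 0.0)
  slope <- stats::coef(stats::lm(log(med_snr) ~ log(ms)))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.1)
})

test_that("physics utilities reproduce their closed forms", {
  expect_equal(harmonic_mz(2000, 2), 1000)
  expect_equal(harmonic_mz(2000, 3), 666.7, tolerance = 0.05)
  expect_equal(harmonic_mz(1234, 1), 1234)
  expect_error(harmonic_mz(2000, 0), ">= 1")
  expect_equal(closest_approach(5, 22.8), 3.158, tolerance = 1e-3)
  expect_equal(closest_approach(9, 22.8), 5.684, tolerance = 1e-3)
  expect_equal(closest_approach(1, 14.39964), 1.0)
  # exact linearity in z, inverse proportionality in V
  expect_equal(closest_approach(6, 20), 2 * closest_approach(3, 20))
  expect_equal(closest_approach(3, 40), closest_approach(3, 20) / 2)
  expect_error(closest_approach(3, -1), "positive")
  expect_equal(photon_energy(193), 6.42, tolerance = 5e-3)
  expect_equal(photon_energy(1239.841), 1.0)
  expect_equal(photon_energy(10600), 0.117, tolerance = 5e-4)
  expect_error(photon_energy(0), "positive")
})

test_that("2D maps round-trip through the text store", {
  p <- acq2d_params(n_t1 = 8, n_t2 = 32, seed = 5)
  map <- simulate_2d(p, base_model(noise_sd = 0.1))
  base <- tempfile(); on.exit(unlink(paste0(base, c(".csv", ".json"))))
  save_map2d(map, base)
  back <- read_map2d(base)
  expect_equal(back$matrix, map$matrix, tolerance = 1e-12)
  expect_equal(back$params$n_t2, 32L)
  expect_equal(back$model$fragments$mz, map$model$fragments$mz)
})
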