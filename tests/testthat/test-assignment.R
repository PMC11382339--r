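make_cat <- function(seqtext = "lG*mC*A*T*G*C*A*eT", ...) {
  o <- parse_oligo(seqtext)
  enumerate_candidates(o, catalogue_config(mz_min = 100, mz_max = 4000, ...))
}

test_that("exact synthetic peaks assign 100% at 0 ppm; isobars group", {
  cat <- make_cat(max_charge = 2)
  mzs <- cat$mz[c(TRUE, diff(cat$mz) > 1e-6)]   # one peak per isobar group
  peaks <- data.frame(mz = mzs, intensity = 100)
  recs <- classify_records(match_peaks(peaks, cat, tol_ppm = 5))
  cats <- vapply(recs, `[[`, "", "category")
  expect_false(any(cats == "unassigned"))
  expect_true(all(abs(vapply(recs, `[[`, 0.0, "best_ppm")) < 1e-6))
  # a3 and b3-H2O are exact isobars: one record, both candidates listed
  tfa <- cat[cat$label == "a3" & cat$charge == 1, ]
  rec <- recs[[which.min(abs(peaks$mz - tfa$mz))]]
  expect_true(all(c("a3", "b3-H2O") %in% rec$candidates$label))
  expect_equal(sequence_coverage(recs), 100)
})

test_that("tolerance gates assignment; charge filters candidates", {
  cat <- make_cat(max_charge = 2, losses = list(), base_loss = FALSE,
                  internal = FALSE)
  target <- cat[cat$label == "w3" & cat$charge == 1, ]
  off <- data.frame(mz = target$mz * (1 + 10e-6), intensity = 1)
  recs <- classify_records(match_peaks(off, cat, tol_ppm = 5))
  expect_equal(recs[[1]]$category, "unassigned")
  # same m/z, wrong declared charge
  wrongz <- data.frame(mz = target$mz, intensity = 1, charge = 2L)
  recs <- classify_records(match_peaks(wrongz, cat, tol_ppm = 5))
  expect_equal(recs[[1]]$category, "unassigned")
  expect_error(match_peaks(off, cat[0, ], 5), "empty catalogue")
})

test_that("taxonomy classification follows the precedence rules", {
  o <- parse_oligo("A*T*G*C*A*T")
  # 2H loss excluded here: d1-2H is exactly isobaric with J(a3w4)
  # (guanine = adenine + O and H2O - 2H = O), which would outrank internal
  cat <- enumerate_candidates(o, catalogue_config(mz_min = 50, mz_max = 4000,
                                                  max_charge = 2,
                                                  losses = default_losses()[1:2]))
  pick <- function(lab, z) cat[cat$label == lab & cat$charge == z, ]
  peaks <- data.frame(
    # w4-NH3 (not w4-H2O, which is the same molecule as plain x4)
    mz = c(pick("w4", 1)$mz, pick("w4-NH3", 1)$mz, pick("w4-T", 1)$mz,
           pick("J(a3w4)", 1)$mz, pick("M", 2)$mz, pick("M-A", 2)$mz),
    intensity = c(50, 20, 20, 10, 200, 30))
  recs <- classify_records(match_peaks(peaks, cat, tol_ppm = 5))
  expect_equal(vapply(recs, `[[`, "", "category"),
               c("mcluckey", "mcluckey_neutral_loss", "mcluckey_base_loss",
                 "internal", "precursor", "backbone_retained"))
})

test_that("coverage counts cleavage positions from terminal ions only", {
  # composition-asymmetric sequence so no d/w isobars inflate coverage
  o <- parse_oligo("A*A*A*T*G*C")          # n = 6, 5 positions
  cat <- enumerate_candidates(o, catalogue_config(mz_min = 50, mz_max = 4000,
                                                  max_charge = 1,
                                                  losses = list(),
                                                  base_loss = FALSE))
  # w4 covers position n-4 = 2; b2 covers position 2; J covers nothing
  # (J span = the lone T, not isobaric with any terminal ion here)
  sub <- cat[cat$label %in% c("w4", "b2", "J(a4w3)"), ]
  peaks <- data.frame(mz = sub$mz, intensity = 1)
  recs <- classify_records(match_peaks(peaks, cat, 5))
  expect_equal(sequence_coverage(recs, o), 100 * 1 / 5)
  expect_equal(sequence_coverage(recs, o, denominator = "residues"),
               100 * 1 / 6)
  # empty case
  none <- classify_records(match_peaks(
    data.frame(mz = 123.456, intensity = 1), cat, 5))
  expect_equal(sequence_coverage(none, o), 0)
  # 14 of 15 positions on a 16-mer: the two rounding conventions
  expect_equal(round(100 * 14 / 15, 1), 93.3)
  expect_equal(round(100 * 15 / 16), 94)
})

test_that("fragmentation efficiency is Brodbelt's product-ion fraction", {
  expect_equal(fragmentation_efficiency(c(30, 20), 50), 50.0)
  expect_equal(fragmentation_efficiency(c(1, 2), 0), 100.0)
  expect_equal(fragmentation_efficiency(numeric(0), 10), 0.0)
  expect_error(fragmentation_efficiency(numeric(0), 0), "undefined")
  # monotonicity and bounds
  set.seed(61)
  for (rep in 1:20) {
    Fi <- stats::runif(5, 0, 100); P <- stats::runif(1, 0, 100)
    e <- fragmentation_efficiency(Fi, P)
    expect_true(e >= 0 && e <= 100)
    expect_gt(fragmentation_efficiency(Fi + 1, P), e)
    expect_lt(fragmentation_efficiency(Fi, P + 1), e)
  }
})

test_that("linear recalibration recovers a synthetic ppm distortion", {
  cat <- make_cat(max_charge = 2, losses = list(), base_loss = FALSE,
                  internal = FALSE)
  theo <- cat$mz[seq(1, nrow(cat), by = 3)]
  distort <- function(mz) mz * (1 + 3e-6)          # uniform +3 ppm shift
  anchors <- data.frame(observed = distort(theo[1:6]), theoretical = theo[1:6])
  held_out <- theo[7:length(theo)]
  rc <- recalibrate(data.frame(mz = distort(held_out), intensity = 1), anchors)
  resid_ppm <- (rc$peaks$mz - held_out) / held_out * 1e6
  expect_lt(max(abs(resid_ppm)), 0.1)
  expect_error(recalibrate(data.frame(mz = 1, intensity = 1),
                           anchors[1, , drop = FALSE]), "at least 2")
  expect_error(recalibrate(data.frame(mz = 1, intensity = 1),
                           data.frame(observed = c(500, 500),
                                      theoretical = c(500, 501))),
               "zero m/z range")
  # identity anchors leave peaks untouched
  id <- recalibrate(data.frame(mz = c(400, 900), intensity = 1),
                    data.frame(observed = c(300, 600, 1200),
                               theoretical = c(300, 600, 1200)))
  expect_equal(id$peaks$mz, c(400, 900), tolerance = 1e-12)
})

test_that("summary report: partitions, round trips, decoys, empty input", {
  fx <- generate_fixture(fixture_spec("lG*mC*A*T*G*C*A*eT",
                                      charges = 1:2, n_decoys = 10,
                                      seed = 7))
  recs <- classify_records(match_peaks(fx$peaks, fx$catalogue, 5))
  rep <- summary_report(recs, fx$oligo)
  expect_equal(rep$counts$unassigned, 10)
  expect_equal(Reduce(`+`, rep$counts), rep$total_peaks)   # partition
  expect_equal(rep$assigned_peaks + rep$counts$unassigned +
                 rep$counts$precursor + rep$counts$backbone_retained +
                 rep$counts$adduct, rep$total_peaks)
  expect_equal(rep$sequence_coverage_pct, 100)
  # determinism of the whole pipeline
  recs2 <- classify_records(match_peaks(fx$peaks, fx$catalogue, 5))
  expect_identical(summary_report(recs2, fx$oligo)$counts, rep$counts)
  # empty peak list: zeros everywhere, no crash
  empty <- classify_records(match_peaks(
    data.frame(mz = numeric(), intensity = numeric()), fx$catalogue, 5))
  rep0 <- summary_report(empty, fx$oligo)
  expect_equal(rep0$total_peaks, 0)
  expect_equal(rep0$assigned_pct, 0)
  # serializers
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  on.exit(unlink(c(jp, cp)))
  write_report_json(rep, jp)
  expect_equal(jsonlite::fromJSON(jp)$counts$unassigned, 10)
  write_records_csv(recs, cp)
  expect_equal(nrow(utils::read.csv(cp)), rep$total_peaks)
})
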