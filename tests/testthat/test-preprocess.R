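test_that("scan averaging is idempotent and counts absences as zero", {
  s <- spectrum(c(100, 200.5, 300.002), c(8, 4, 2), "positive")
  avg <- average_scans(rep(list(s), 10))
  expect_equal(avg$mz, s$mz)
  expect_equal(avg$intensity, s$intensity)
  # peak present in one of two scans at 8 averages to 4
  s2 <- spectrum(c(200.5, 300.002), c(4, 2), "positive")
  avg2 <- average_scans(list(s, s2))
  expect_equal(avg2$intensity[avg2$mz == 100], 4)
  # peaks within the +/-0.005 Da rule merge into one averaged peak
  a <- spectrum(100.000, 6, "positive")
  b <- spectrum(100.004, 2, "positive")
  merged <- average_scans(list(a, b))
  expect_length(merged$mz, 1)
  expect_equal(merged$intensity, 4)
  expect_equal(merged$mz, (100.000 * 6 + 100.004 * 2) / 8)  # weighted mean
  expect_error(
    average_scans(list(a, spectrum(100, 1, "negative"))), "polarity")
})

test_that("binning groups by the gap rule and fills absences with zero", {
  sp <- list(s1 = spectrum(c(100.000, 150.0), c(5, 1), "positive"),
             s2 = spectrum(100.004, 3, "positive"))
  pm <- bin_to_matrix(sp)
  expect_equal(dim(pm$values), c(2, 2))
  expect_true(all(pm$values[, 1] > 0))  # shared 100-ish bin
  expect_equal(pm$values["s2", 2], 0)
  # gap of 0.020 Da exceeds the 2 x tolerance window: two bins
  pm2 <- bin_to_matrix(list(a = spectrum(c(100.000, 100.020), c(1, 1),
                                         "positive")))
  expect_equal(ncol(pm2$values), 2)
  # single peak, single sample
  pm3 <- bin_to_matrix(list(a = spectrum(500, 7, "positive")))
  expect_equal(unname(pm3$values[1, 1]), 7)
  expect_error(bin_to_matrix(list()), "no spectra")
  # an empty spectrum among others becomes a row of zeros
  pm4 <- bin_to_matrix(list(a = spectrum(500, 7, "positive"),
                            b = spectrum(numeric(0), numeric(0),
                                         "positive")))
  expect_true(all(pm4$values["b", ] == 0))
})

test_that("binning is invariant to sample order", {
  set.seed(31)
  sp <- lapply(1:5, function(i) {
    spectrum(sort(runif(30, 50, 500)), rexp(30), "positive")
  })
  names(sp) <- paste0("s", 1:5)
  pm <- bin_to_matrix(sp)
  shuffled <- sp[c(3, 1, 5, 2, 4)]
  pm_shuf <- bin_to_matrix(shuffled)
  expect_equal(pm$bin_mz, pm_shuf$bin_mz)
  expect_equal(pm$values[names(sp), ], pm_shuf$values[names(sp), ])
})

test_that("TIC normalization divides by the row mean and is scale-free", {
  samples <- data.frame(sample_id = c("a", "b", "c"))
  pm <- peak_matrix(rbind(c(10, 30, 60), c(20, 60, 120), c(0, 0, 0)),
                    bin_mz = c(100, 200, 300), samples = samples)
  expect_warning(norm <- tic_normalize(pm), "all-zero")
  expect_equal(unname(norm$values["a", ]), c(0.3, 0.9, 1.8))
  # rows proportional by a factor normalize identically
  expect_equal(unname(norm$values["a", ]), unname(norm$values["b", ]))
  expect_true(all(norm$values["c", ] == 0))
  expect_equal(unname(rowMeans(norm$values[1:2, ])), c(1, 1))
  expect_error(tic_normalize(norm), "raw")
})

test_that("log autoscaling yields column mean 0 / sd 1 and zeroes constants", {
  set.seed(8)
  v <- matrix(rexp(60, 0.1), 10, 6)
  v[, 6] <- 3  # constant bin after normalization
  norm <- peak_matrix(v, bin_mz = 1:6,
                      samples = data.frame(sample_id = letters[1:10]),
                      stage = "tic_normalized")
  scaled <- log_autoscale(norm)
  expect_equal(scaled$stage, "log_scaled")
  expect_equal(unname(colMeans(scaled$values)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(scaled$values[, 1:5], 2, sd)), rep(1, 5),
               tolerance = 1e-12)
  expect_true(all(scaled$values[, 6] == 0))
  # two samples at v and v * e^2: ln difference 2, centred +/-1, sample sd
  # (n - 1) scales to +/- 1/sqrt(2)
  pm2 <- peak_matrix(matrix(c(5, 5 * exp(2)), 2, 1), bin_mz = 100,
                     samples = data.frame(sample_id = c("a", "b")),
                     stage = "tic_normalized")
  out <- log_autoscale(pm2, epsilon = 0)
  expect_equal(unname(out$values[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("QC report computes RSD and drift statistics", {
  samples <- data.frame(sample_id = c("q1", "s1", "q2", "q3"),
                        specimen = c("qc", "serum", "qc", "qc"),
                        run_index = c(1, 2, 3, 4))
  v <- rbind(c(90, 10), c(55, 5), c(100, 10), c(110, 10))
  pm <- peak_matrix(v, bin_mz = c(100, 200), samples = samples)
  rep <- qc_report(pm)
  expect_equal(rep$per_bin$rsd_pct[1], 100 * sd(c(90, 100, 110)) / 100)  # 10%
  expect_equal(rep$per_bin$rsd_pct[2], 0)
  expect_equal(rep$per_bin$drift_rho[1], 1)  # strictly increasing with run
  expect_equal(rep$per_bin$drift_rho[2], 0)  # constant bin: no drift
  expect_equal(rep$summary$frac_stable, 1)
  pm1 <- peak_matrix(v[1:2, ], bin_mz = c(100, 200), samples = samples[1:2, ])
  expect_error(qc_report(pm1), "2 QC")
})

test_that("a peak matrix survives a disk round trip bit-identically", {
  set.seed(12)
  sp <- list(x = spectrum(sort(runif(20, 50, 900)), rlnorm(20, 5), "positive"),
             y = spectrum(sort(runif(15, 50, 900)), rlnorm(15, 5), "positive"))
  pm <- tic_normalize(bin_to_matrix(
    sp, samples = data.frame(sample_id = c("x", "y"),
                             group = c("TNBC", "HD"))))
  path <- file.path(tempdir(), "pm_roundtrip.tsv")
  write_peak_matrix(pm, path)
  back <- read_peak_matrix(path)
  expect_identical(back$values, pm$values)
  expect_identical(back$bin_mz, pm$bin_mz)
  expect_equal(back$samples, pm$samples)
  expect_identical(back$stage, pm$stage)
})

test_that("polarity merge concatenates features and keeps mode tags", {
  pos <- peak_matrix(matrix(1:4, 2), bin_mz = c(100, 200),
                     samples = data.frame(sample_id = c("a", "b")))
  neg <- peak_matrix(matrix(5:8, 2), bin_mz = c(90, 150),
                     samples = data.frame(sample_id = c("a", "b")),
                     polarity = "negative")
  both <- merge_polarities(pos, neg)
  expect_equal(ncol(both$values), 4)
  expect_equal(substr(colnames(both$values), 1, 1), c("P", "P", "N", "N"))
  expect_error(merge_polarities(pos, peak_matrix(
    matrix(5:6, 1, 2), bin_mz = c(90, 150),
    samples = data.frame(sample_id = "z"), polarity = "negative")),
    "sample sets")
})

test_that("peak-list CSV round trip preserves a spectrum", {
  s <- spectrum(c(89.0244, 175.119), c(1200.5, 540.25), "negative")
  path <- file.path(tempdir(), "peaks.csv")
  write_peaklist_csv(s, path)
  back <- read_peaklist_csv(path, polarity = "negative")
  expect_equal(back$mz, s$mz)
  expect_equal(back$intensity, s$intensity)
  expect_equal(back$polarity, "negative")
})
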