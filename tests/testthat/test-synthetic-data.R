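test_that("cohort counts follow the design arithmetic", {
  design <- cohort_design()
  cohort <- generate_cohort(design)
  rec <- cohort$records
  expect_equal(sum(rec$specimen == "tissue"),
               design$n_patients * 2 * design$points_per_tissue)  # 240
  expect_equal(sum(rec$specimen == "serum"),
               design$n_tnbc_serum + design$n_hd_serum)  # 381
  # closed-form QC count: one insertion per full block of qc_every runs
  expect_equal(sum(rec$specimen == "qc" & rec$batch == "tissue"),
               (design$n_patients * 2 * design$points_per_tissue) %/%
                 design$qc_every)
  expect_equal(sum(rec$specimen == "qc" & rec$batch == "serum"),
               (design$n_tnbc_serum + design$n_hd_serum) %/% design$qc_every)
  # every tissue sample carries a patient id; serum and QC do not
  expect_true(all(nzchar(rec$patient_id[rec$specimen == "tissue"])))
  expect_true(all(!nzchar(rec$patient_id[rec$specimen != "tissue"])))
  # run indices unique within each batch
  for (b in unique(rec$batch)) {
    expect_false(anyDuplicated(rec$run_index[rec$batch == b]) > 0)
  }
  # QC records sit at every (qc_every + 1)-th run position
  qc_runs <- rec$run_index[rec$specimen == "qc" & rec$batch == "serum"]
  expect_true(all(qc_runs %% (design$qc_every + 1L) == 0))
})

test_that("paired tissue arm and patient-level split arithmetic", {
  cohort <- generate_cohort(cohort_design())
  tis <- cohort$records[cohort$records$specimen == "tissue", ]
  counts <- table(tis$patient_id, tis$group)
  expect_true(all(counts == 3))  # 3 points per tissue, both groups, all patients
  sp <- split_by_patient(cohort$records, n_train = 25, seed = 9)
  expect_equal(nrow(sp$train), 150)
  expect_equal(nrow(sp$test), 90)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
})

test_that("cohort generation is reproducible and validates marker indices", {
  d <- cohort_design(n_patients = 3, n_ions = 100, seed = 7)
  expect_identical(generate_cohort(d), generate_cohort(d))
  expect_error(
    cohort_design(n_ions = 10,
                  marker_spec = data.frame(ion = 11, fc = 4,
                                           direction = "up")),
    "1..n_ions", fixed = TRUE)
  expect_error(cohort_design(n_patients = 0), "counts")
  expect_error(
    cohort_design(n_ions = 50,
                  marker_spec = data.frame(ion = 5, fc = -1,
                                           direction = "down")),
    "> 0")
})

test_that("scan sets carry the designed ion count and are seed-stable", {
  d <- cohort_design(n_patients = 2, points_per_tissue = 1, n_ions = 120,
                     seed = 3)
  rec <- generate_cohort(d)$records[1, ]
  scans <- generate_scan_set(rec, d, n_scans = 10)
  expect_length(scans, 10)
  expect_true(all(vapply(scans, length, 0L) == 120))
  expect_identical(scans, generate_scan_set(rec, d, n_scans = 10))
})

test_that("zero-noise design gives identical non-marker intensities", {
  d <- cohort_design(n_patients = 2, points_per_tissue = 1, n_ions = 60,
                     tic_cv = 0, noise_sd = 0, patient_effect_sd = 0,
                     drift_slope = 1, n_tnbc_serum = 3, n_hd_serum = 3,
                     seed = 11)
  cohort <- generate_cohort(d)
  ser <- cohort$records[cohort$records$specimen == "serum", ]
  ints <- sapply(seq_len(nrow(ser)), function(i) {
    generate_scan_set(ser[i, ], d, n_scans = 1)[[1]]$intensity
  })
  nonmarker <- setdiff(seq_len(60), cohort$truth$markers$ion)
  expect_true(all(apply(ints[nonmarker, ], 1,
                        function(r) max(r) - min(r)) == 0))
  # marker rows differ exactly by the designed fold change
  case <- ser$group == "TNBC"
  for (k in seq_len(nrow(cohort$truth$markers))) {
    i <- cohort$truth$markers$ion[k]
    ratio <- mean(ints[i, case]) / mean(ints[i, !case])
    expect_equal(ratio, cohort$truth$markers$fc[k], tolerance = 1e-12)
  }
})

test_that("marker fold change is recovered in the Monte-Carlo mean", {
  # >= 200 simulated samples; the mean case/control intensity ratio of a
  # spiked x4 marker must sit within sampling error of 4
  d <- cohort_design(n_patients = 2, points_per_tissue = 1, n_ions = 40,
                     n_tnbc_serum = 120, n_hd_serum = 120,
                     marker_spec = data.frame(ion = 7L, fc = 4,
                                              direction = "up"),
                     tic_cv = 0.05, noise_sd = 0.2, seed = 5)
  cohort <- generate_cohort(d)
  ser <- cohort$records[cohort$records$specimen == "serum", ]
  ints <- sapply(seq_len(nrow(ser)), function(i) {
    generate_scan_set(ser[i, ], d, n_scans = 2)[[1]]$intensity
  })
  case <- ser$group == "TNBC"
  ratio <- mean(ints[7, case]) / mean(ints[7, !case])
  expect_equal(ratio, 4, tolerance = 0.15)
})

test_that("spiked markers are separable by t-test at moderate n (power)", {
  d <- cohort_design(n_patients = 2, points_per_tissue = 1, n_ions = 50,
                     n_tnbc_serum = 20, n_hd_serum = 20,
                     noise_sd = 0.1, tic_cv = 0.05, seed = 13)
  cohort <- generate_cohort(d)
  ser <- cohort$records[cohort$records$specimen == "serum", ]
  ints <- t(sapply(seq_len(nrow(ser)), function(i) {
    generate_scan_set(ser[i, ], d, n_scans = 1)[[1]]$intensity
  }))
  st <- differential_stats(ints, ser$group, case = "TNBC")
  markers <- cohort$truth$markers$ion
  expect_true(all(st$q[markers] < 0.05))
})

test_that("QC samples are the deterministic pooled profile with drift only", {
  d <- cohort_design(n_patients = 10, points_per_tissue = 3, n_ions = 30,
                     drift_slope = 1.001, seed = 2)
  cohort <- generate_cohort(d)
  qc <- cohort$records[cohort$records$specimen == "qc" &
                         cohort$records$batch == "tissue", ]
  expect_gte(nrow(qc), 2)
  s1 <- generate_scan_set(qc[1, ], d, n_scans = 1)[[1]]$intensity
  s2 <- generate_scan_set(qc[2, ], d, n_scans = 1)[[1]]$intensity
  drift_ratio <- d$drift_slope^(qc$run_index[2] - qc$run_index[1])
  expect_equal(s2 / s1, rep(drift_ratio, 30), tolerance = 1e-12)
})

test_that("raster geometry follows the grid arithmetic", {
  flat <- generate_raster(2, 2, raster_speed = 0.2, line_spacing = 0.2,
                          scan_rate = 1, pattern = function(x, y) 50)
  expect_length(flat, 100)  # 10 lines x 10 scans
  expect_equal(range(vapply(flat, function(s) s$line, 0)), c(0, 9))
  ints <- vapply(flat, function(s) s$spectrum$intensity, 0)
  expect_true(all(ints == 50))
  # step pattern splits exactly at the midline column
  step <- generate_raster(2, 2, 0.2, 0.2, 1,
                          pattern = function(x, y) if (x < 1) 100 else 10)
  img <- vapply(step, function(s) s$spectrum$intensity, 0)
  m <- matrix(img, nrow = 10, byrow = TRUE)
  expect_true(all(m[, 1:5] == 100))
  expect_true(all(m[, 6:10] == 10))
  expect_error(generate_raster(-1, 2, 0.2, 0.2, 1, function(x, y) 1),
               "> 0")
})
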