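test_that("the spec validates its parameters", {
  expect_error(cohort_spec(class_fraction_high = 0),
               class = "relaxo_bad_parameter")
  expect_error(cohort_spec(t1_high = c(2400, -1)),
               class = "relaxo_bad_parameter")
  expect_error(cohort_spec(echo_times = c(40, 20)),
               class = "relaxo_bad_parameter")
})

test_that("the same spec and seed reproduce a patient bit-identically", {
  spec <- test_spec()
  p1 <- simulate_patient(spec, 1)
  p2 <- simulate_patient(spec, 1)
  expect_identical(p1$t1$data, p2$t1$data)
  expect_identical(p1$pet$data, p2$pet$data)
  expect_identical(p1$biopsies, p2$biopsies)
  expect_identical(p1$echoes$TE020$data, p2$echoes$TE020$data)
})

test_that("a patient's data is invariant to the cohort size", {
  spec_small <- test_spec()
  spec_big <- test_spec()
  spec_big$n_patients <- 5L
  p_a <- simulate_patient(spec_small, 2, include_echoes = FALSE)
  p_b <- simulate_patient(spec_big, 2, include_echoes = FALSE)
  expect_identical(p_a$t1$data, p_b$t1$data)
  expect_identical(p_a$biopsies, p_b$biopsies)
})

test_that("different patients and seeds give different data", {
  spec <- test_spec()
  p1 <- simulate_patient(spec, 1, include_echoes = FALSE)
  p2 <- simulate_patient(spec, 2, include_echoes = FALSE)
  expect_false(identical(p1$t1$data, p2$t1$data))
  spec2 <- test_spec(seed = 43)
  p1b <- simulate_patient(spec2, 1, include_echoes = FALSE)
  expect_false(identical(p1$t1$data, p1b$t1$data))
})

test_that("class distributions land on their specified locations", {
  spec <- cohort_spec(n_patients = 1, grid_dims = c(128L, 128L, 40L),
                      mask_fraction = 0.7, n_biopsies = 4, seed = 5)
  p <- simulate_patient(spec, 1, include_echoes = FALSE)
  m <- p$analysis_mask$data
  expect_gt(sum(m), 1e5)
  high <- p$truth$class_high
  t1m <- p$t1$data[m]
  for (cls in list(list(sel = high, par = spec$t1_high),
                   list(sel = !high, par = spec$t1_low))) {
    x <- t1m[cls$sel]
    se <- cls$par[2] / sqrt(length(x))
    # the class draws are truncated at 0, which lifts the wide low-class
    # mean by ~29 ms; compare against the truncated-normal mean
    expect_lt(abs(mean(x) - tnorm_mean(cls$par[1], cls$par[2])), 3 * se)
  }
  # the high class is narrower when the spec says so
  expect_lt(var(t1m[high]), var(t1m[!high]))
  expect_gt(mean(t1m[high]), mean(t1m[!high]))
})

test_that("a pure high-uptake mask exceeds the T/N cutoff almost surely", {
  spec <- cohort_spec(n_patients = 1, grid_dims = c(48L, 48L, 16L),
                      class_fraction_high = 1, tn_high = c(2.0, 0.05),
                      n_biopsies = 4, seed = 8)
  p <- simulate_patient(spec, 1, include_echoes = FALSE)
  tn <- compute_tn_map(p$pet, p$reference_mask)
  frac <- mean(tn$data[p$analysis_mask$data] > 1.5)
  expect_gte(frac, 0.99)
})

test_that("PET scaling makes measured T/N equal the drawn T/N", {
  spec <- test_spec()
  p <- simulate_patient(spec, 1, include_echoes = FALSE)
  tn <- compute_tn_map(p$pet, p$reference_mask)
  m <- p$analysis_mask$data
  expect_equal(tn$data[m], p$truth$tn[m], tolerance = 1e-12)
})

test_that("noiseless echoes invert exactly through the T2 estimator", {
  spec <- test_spec(noise_sd = 0)
  p <- simulate_patient(spec, 1)
  i <- which(p$analysis_mask$data)[1]
  s <- vapply(p$echoes, function(e) e$data[i], numeric(1))
  fit <- fit_t2_monoexponential(s, spec$echo_times)
  expect_equal(fit$t2, p$t2$data[i], tolerance = 1e-8)
  expect_equal(fit$s0, spec$s0, tolerance = 1e-8)
})

test_that("biopsy TCD honors the T1 band and the field-count construction", {
  spec <- test_spec(count_noise_sd = 1e-9)
  p <- simulate_patient(spec, 1, include_echoes = FALSE)
  # with negligible count noise: counts = round(TCD * 0.0497)
  expected <- vapply(p$truth$tcd, function(t) round(t * 0.0497), numeric(1))
  got <- vapply(p$biopsies$field_counts, function(fc) fc[1], integer(1))
  expect_equal(as.numeric(got), expected)
  # in-band samples draw from the hotter TCD distribution on average
  expect_gt(mean(p$truth$tcd[p$truth$tcd_inband]),
            mean(p$truth$tcd[!p$truth$tcd_inband]))
})

test_that("simulate_cohort writes patients, manifest, and reproduces hashes", {
  spec <- test_spec(n_patients = 3)
  d1 <- file.path(tempdir(), "cohortA")
  d2 <- file.path(tempdir(), "cohortB")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- simulate_cohort(spec, d1)
  m2 <- simulate_cohort(spec, d2)
  expect_identical(length(m1$patient_ids), 3L)
  expect_true(all(file.exists(file.path(d1, c("p01", "p02", "p03"),
                                        "t1.nii.gz"))))
  expect_true(file.exists(file.path(d1, "manifest.yaml")))
  # same spec, fresh directory: identical content hash by hash
  expect_identical(unlist(m1$files), unlist(m2$files))
  # biopsy bookkeeping: rows match the configured count
  tab <- parse_biopsy_table(file.path(d1, "p02", "biopsies.csv"))
  expect_identical(nrow(tab), spec$n_biopsies)
  # written volume matches the configured grid
  v <- read_volume(file.path(d1, "p01", "t1.nii.gz"))
  expect_identical(dim(v$data), spec$grid_dims)
})

test_that("pooled per-class voxel totals equal the per-patient sums", {
  spec <- test_spec(n_patients = 3)
  per_patient <- vapply(1:3, function(i) {
    p <- simulate_patient(spec, i, include_echoes = FALSE)
    tn <- compute_tn_map(p$pet, p$reference_mask)
    part <- partition_by_tn(tn, p$analysis_mask)
    c(part$n_high, part$n_low)
  }, integer(2))
  d <- file.path(tempdir(), "cohortC")
  unlink(d, recursive = TRUE)
  simulate_cohort(spec, d)
  cfg <- run_config(d, output_dir = NULL, quantities = "T1")
  s1 <- suppressMessages(run_stage1(cfg))
  expect_identical(s1$n_high, sum(per_patient[1, ]))
  expect_identical(s1$n_low, sum(per_patient[2, ]))
})
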