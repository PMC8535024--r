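test_that("cohort generation is reproducible and honors requested composition", {
  cfg <- phantom_config(n_patients = 10, lesions_per_patient = c(1, 1),
                        class_prevalence = 0.5, seed = 1)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_length(co1$patches, 10)
  expect_identical(co1$records, co2$records)
  expect_identical(co1$patches, co2$patches)
  expect_true(all(co1$records$label %in% 0:1))

  # prevalence given as a count pins the composition exactly
  cfg2 <- phantom_config(n_patients = 142, lesions_per_patient = c(1, 1),
                         class_prevalence = 78, seed = 3)
  co <- generate_cohort(cfg2)
  expect_equal(nrow(co$records), 142)
  expect_equal(sum(co$records$label == 1), 78)
  expect_equal(sum(co$records$label == 0), 64)
})

test_that("degenerate settings give a constant non-csPCa patch", {
  cfg <- phantom_config(n_patients = 4, lesions_per_patient = c(1, 1),
                        class_prevalence = 0.5, noise_sd = 0,
                        smoothness_pos = 1, smoothness_neg = Inf, seed = 2)
  co <- generate_cohort(cfg)
  neg <- co$patches[co$records$label == 0]
  expect_gt(length(neg), 0)
  for (p in neg) {
    expect_equal(diff(range(p$t2w)), 0)
    expect_equal(diff(range(p$adc)), 0)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(smoothness_pos = 3, smoothness_neg = 1),
               "smoothness")
  bad_conf <- matrix(c(0.5, 0.5, 0.5, 0.2, 0.2, 0.2), nrow = 3)
  expect_error(phantom_config(pirads_confusion = bad_conf), "pirads_confusion")
  expect_error(phantom_config(zone_probs = c(PZ = 0.5, TZ = 0.2, AFS = 0.1)),
               "sum")
  expect_error(phantom_config(patch_shape_range = c(2, 8)))
})

test_that("splits are patient-level, deterministic, largest-remainder sized", {
  co <- generate_cohort(phantom_config(n_patients = 10, seed = 4))
  r1 <- split_cohort(co$records, seed = 9)
  r2 <- split_cohort(co$records, seed = 9)
  expect_identical(r1$split, r2$split)

  # all lesions of a patient share a split
  by_pat <- tapply(r1$split, r1$patient_id, function(s) length(unique(s)))
  expect_true(all(by_pat == 1))
  pat_split <- tapply(r1$split, r1$patient_id, `[`, 1)
  expect_equal(unname(table(pat_split)[c("train", "validation", "test")]),
               c(6L, 1L, 3L), ignore_attr = TRUE)

  # largest-remainder apportionment at a 402-patient cohort
  recs <- tibble::tibble(patient_id = sprintf("P%03d", 1:402),
                         lesion_id = sprintf("L%03d", 1:402))
  r <- split_cohort(recs, seed = 1)
  expect_equal(unname(table(r$split)[c("train", "validation", "test")]),
               c(241L, 40L, 121L), ignore_attr = TRUE)
  # every achieved count within one patient of nominal
  expect_true(all(abs(c(241, 40, 121) - 402 * c(0.6, 0.1, 0.3)) <= 1.5))

  # exact sizes override reproduces an externally specified split
  r3 <- split_cohort(recs, seed = 1, sizes = c(239, 42, 121))
  expect_equal(unname(table(r3$split)[c("train", "validation", "test")]),
               c(239L, 42L, 121L), ignore_attr = TRUE)

  expect_error(split_cohort(recs[1:2, ], fractions = c(a = .5, b = .3, c = .2)),
               "fewer patients")
})

test_that("csPCa phantoms are more locally heterogeneous than non-csPCa", {
  for (seed in c(1, 7, 23)) {
    co <- generate_cohort(phantom_config(n_patients = 12, seed = seed))
    lv <- vapply(co$patches, function(p) local_variance_mean(p$t2w), numeric(1))
    lab <- co$records$label
    expect_gt(mean(lv[lab == 1]), mean(lv[lab == 0]))
  }
})
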