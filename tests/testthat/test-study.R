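test_that("five uniformly positive pairs give exact p = 0.0625", {
  w <- wilcoxon_signed_rank(c(3, 1, 4, 2, 5), c(1, 0, 2, 1, 3))
  expect_equal(w$statistic, 15)
  expect_equal(w$p_value, 0.0625)
  expect_match(w$method, "exact")
})

test_that("signed-rank p matches exhaustive enumeration and wilcox.test", {
  set.seed(21)
  for (rep in 1:5) {
    d <- round(rnorm(8, 0.3, 1), 2)
    d <- d[d != 0]
    w <- wilcoxon_signed_rank(d)
    expect_equal(w$p_value, brute_wilcoxon_p(d), tolerance = 1e-12)
    # tie-free data: agree with the standard exact implementation
    if (!any(duplicated(abs(d)))) {
      ref <- stats::wilcox.test(d, exact = TRUE)
      expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(w$statistic, unname(ref$statistic))
    }
  }
  # tied magnitudes still match the enumeration oracle
  d_tied <- c(1, -1, 2, 2, 3, -2, 1.5, 4)
  expect_equal(wilcoxon_signed_rank(d_tied)$p_value,
               brute_wilcoxon_p(d_tied), tolerance = 1e-12)
})

test_that("signed-rank test is antisymmetric and the large-n path is sane", {
  set.seed(33)
  d <- rnorm(12, 0.5)
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               wilcoxon_signed_rank(-d)$p_value)
  dl <- rnorm(40, 0.4)
  w <- wilcoxon_signed_rank(dl)
  ref <- stats::wilcox.test(dl, exact = FALSE, correct = FALSE)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
  expect_match(w$method, "approximation")
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "zero")
})

test_that("percent decrease is the obvious ratio", {
  expect_equal(percent_decrease(20, 10), 50)
  expect_equal(percent_decrease(7, 7), 0)
  expect_equal(percent_decrease(10, 12), -20)
  expect_error(percent_decrease(0, 1), "baseline")
})

test_that("a zero-motion patient shows no 3D-vs-4D difference", {
  pr <- run_patient(coarse_config(motion_amplitude_mm = c(0, 0, 0)))
  keys <- intersect(names(pr$values_3d), names(pr$values_4d))
  gy <- grepl("Dmean|Dmax", keys)
  expect_lte(max(abs(pr$values_3d[keys][gy] - pr$values_4d[keys][gy])),
             0.01 * 50)
  pct <- grepl("_V\\d+$|NTCP", keys)
  expect_lte(max(abs(pr$values_3d[keys][pct] - pr$values_4d[keys][pct])), 1)
})

test_that("a moving patient is spared by tracking, with the expected geometry", {
  pr <- run_patient(coarse_config())
  expect_gt(pr$volumes_cm3[["ptv_3d"]], pr$volumes_cm3[["ptv_4d_mean"]])
  keys <- c(paste0("liver_V", seq(5, 40, 5)), "liver_Dmean",
            "normal_liver_Dmean", "liver_NTCP")
  expect_true(all(pr$values_4d[keys] < pr$values_3d[keys]))
  # realized motion should be near the configured amplitudes
  expect_equal(unname(pr$amplitude_mm), c(3, 8, 12),
               tolerance = 0.25)
  expect_true(all(pr$values_4d >= 0 & pr$values_3d >= 0))
})

test_that("small cohorts are reproducible and directionally consistent", {
  rep1 <- run_cohort(3, master_seed = 11, base_config = coarse_config())
  rep2 <- run_cohort(3, master_seed = 11, base_config = coarse_config())
  expect_identical(rep1$summary, rep2$summary)
  expect_identical(rep1$per_patient_3d, rep2$per_patient_3d)

  # every patient: merged PTV bigger than mean per-phase PTV, liver spared
  expect_true(all(rep1$volumes_cm3[, "ptv_3d"] >
                    rep1$volumes_cm3[, "ptv_4d_mean"]))
  lv <- paste0("liver_V", seq(5, 40, 5))
  expect_true(all(rep1$per_patient_4d[, lv] < rep1$per_patient_3d[, lv]))

  dir <- tempfile()
  write_cohort_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "per_patient_metrics.csv")))
  js <- jsonlite::read_json(file.path(dir, "cohort_summary.json"))
  expect_equal(js$n_patients, 3)
})

test_that("a zero-motion cohort flags nothing as significant", {
  rep0 <- run_cohort(3, master_seed = 5, base_config = coarse_config(),
                     motion_scale = 0)
  expect_false(any(rep0$summary$significant))
})
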