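# r/c/I validation rules and library output round trips.

test_that("validation applies inclusive r/c/I comparisons and enumerates failures", {
  th <- validation_thresholds()            # r = 6, c = 15, I = 1000
  expect_length(validate_entry(fake_metrics(std_blk = 50, rsd_rt = 2,
                                            max_intensity = 1e5), th), 0)
  # boundary values pass (inclusive comparisons)
  expect_length(validate_entry(fake_metrics(std_blk = 6, rsd_rt = 15,
                                            max_intensity = 1000), th), 0)
  expect_equal(validate_entry(fake_metrics(std_blk = 4.719), th),
               "std_blk_below_r")
  expect_equal(validate_entry(fake_metrics(max_intensity = 915.368), th),
               "intensity_below_I")
  expect_equal(validate_entry(fake_metrics(rsd_rt = 45.6), th), "rsd_above_c")
  expect_setequal(validate_entry(fake_metrics(std_blk = 1, rsd_rt = 30,
                                              max_intensity = 10), th),
                  c("std_blk_below_r", "rsd_above_c", "intensity_below_I"))
  expect_true("missing_replicate_peak" %in%
                validate_entry(fake_metrics(), th, peak_in_all = FALSE))
  # undefined metrics fail closed
  expect_true("std_blk_below_r" %in%
                validate_entry(fake_metrics(std_blk = NA_real_), th))
})

test_that("validation is monotone in the thresholds", {
  set.seed(31)
  th0 <- validation_thresholds()
  for (i in 1:1000) {
    m <- fake_metrics(std_blk = runif(1, 0, 20), rsd_rt = runif(1, 0, 40),
                      max_intensity = runif(1, 0, 5000))
    ok0 <- length(validate_entry(m, th0)) == 0
    tighter <- validation_thresholds(
      r = th0$r * runif(1, 1, 3),
      c = th0$c * runif(1, 0.2, 1),
      I = th0$I * runif(1, 1, 3))
    ok1 <- length(validate_entry(m, tighter)) == 0
    if (!ok0) expect_false(ok1)
  }
})

test_that("permissive thresholds validate every analyte that peaks in all replicates", {
  th <- validation_thresholds(r = 1e-6, c = 100, I = 1e-6)
  set.seed(14)
  for (i in 1:200) {
    m <- fake_metrics(std_blk = runif(1, 1e-3, 100),
                      rsd_rt = runif(1, 0, 100),
                      max_intensity = runif(1, 1, 1e6))
    expect_length(validate_entry(m, th), 0)
  }
})

test_that("threshold constructor rejects out-of-range values", {
  expect_error(validation_thresholds(r = 0), class = "chromeval_config_error")
  expect_error(validation_thresholds(c = 120), class = "chromeval_config_error")
  expect_error(validation_thresholds(I = -5), class = "chromeval_config_error")
})

test_that("build_library requires at least two replicates", {
  sc <- list(a = synth_scene(0, 5, 0.02,
                             peaks = list(synth_peak(2, 0.1, 0, 1e4))))
  an <- list(analyte_spec("a", 105))
  dir <- withr::local_tempdir()
  files <- make_run_files(sc, an, dir, n_replicates = 1, blank = FALSE)
  run <- read_ms_run(files$replicates[1])
  expect_error(build_library(list(run), NULL, an),
               class = "chromeval_config_error")
})

test_that("library CSV round-trips with NA sentinels and stable column order", {
  entries <- structure(list(
    structure(list(analyte_id = "tauro", rt_mean = 5.1,
                   metrics = fake_metrics(std_blk = 50),
                   validated = TRUE, fail_reasons = character(0)),
              class = "library_entry"),
    structure(list(analyte_id = "estra", rt_mean = 6.0,
                   metrics = fake_metrics(std_blk = 4.719),
                   validated = FALSE, fail_reasons = "std_blk_below_r"),
              class = "library_entry"),
    structure(list(analyte_id = "nopk", rt_mean = NA_real_,
                   metrics = fake_metrics(std_blk = NA_real_,
                                          rsd_rt = NA_real_),
                   validated = FALSE,
                   fail_reasons = c("missing_replicate_peak",
                                    "std_blk_below_r", "rsd_above_c")),
              class = "library_entry")),
    class = "analyte_library")
  path <- withr::local_tempfile(fileext = ".csv")
  write_library(entries, path)
  df <- read_library(path)
  expect_equal(names(df),
               c("analyte_id", "rt_mean", "mcq", "max_intensity", "rsd_rt",
                 "std_blk", "jaggedness", "asymmetry", "fwhm", "modality",
                 "validated", "fail_reasons"))
  expect_equal(nrow(df), 3)
  expect_true(is.na(df$std_blk[3]))                 # NA, never 0
  expect_true(is.na(df$rt_mean[3]))
  expect_equal(df$std_blk[2], 4.719)
  expect_equal(df$fail_reasons[3],
               "missing_replicate_peak;std_blk_below_r;rsd_above_c")
  expect_equal(df$validated, c(TRUE, FALSE, FALSE))
  # raw text check: undefined metrics are literally "NA" in the file
  raw <- readLines(path)
  expect_match(raw[4], "NA")
})

test_that("a designed 20-analyte study rejects exactly the 3 planted failures", {
  dir <- withr::local_tempdir()
  study <- write_study(dir, seed = 42L)
  runs <- lapply(study$replicates, read_ms_run)
  blank <- read_ms_run(study$blank)
  lib <- build_library(runs, blank, study$analytes)
  df <- as.data.frame(lib)
  expect_equal(nrow(df), 20)

  rejected <- df$analyte_id[!df$validated]
  expect_setequal(rejected, c("low_stdblk", "low_intensity", "high_rsd"))
  expect_equal(df$fail_reasons[df$analyte_id == "low_stdblk"],
               "std_blk_below_r")
  expect_equal(df$fail_reasons[df$analyte_id == "low_intensity"],
               "intensity_below_I")
  expect_equal(df$fail_reasons[df$analyte_id == "high_rsd"], "rsd_above_c")

  # validated entries carry consensus RTs near the designed centers
  clean <- df[df$validated, ]
  expect_true(all(is.finite(clean$rt_mean)))
  expect_true(all(clean$std_blk >= 6))
  expect_true(all(clean$max_intensity >= 1000))
  expect_true(all(clean$rsd_rt <= 15))
  # high_rsd analyte: apexes at 3, 8, 8 give RSD 45.6%
  expect_equal(df$rsd_rt[df$analyte_id == "high_rsd"],
               100 * sd(c(3, 8, 8)) / mean(c(3, 8, 8)), tolerance = 0.05)
})
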