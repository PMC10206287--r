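# The eight peak-quality metrics against independent oracles.

whole_region <- function(x) {
  y <- x$intensity
  structure(list(apex_idx = which.max(y), left_idx = 1L,
                 right_idx = length(y), rt_apex = x$rt[which.max(y)],
                 apex_intensity = max(y)),
            class = "peak_region")
}

test_that("MCQ is high for clean peaks, low for noise, zero for constants", {
  g <- gaussian_eic(center = 1, sigma = 0.03, height = 1e4,
                    rt_start = 0, rt_end = 1.99, step = 0.01)  # 200 points
  expect_gte(mcq(g), 0.95)
  expect_equal(mcq(g), oracle_mcq(g$intensity), tolerance = 1e-10)

  set.seed(19)
  noise <- eic("n", seq_len(200), runif(200, 0, 1000))
  expect_lt(mcq(noise), 0.5)
  expect_equal(mcq(noise), oracle_mcq(noise$intensity), tolerance = 1e-10)

  expect_equal(mcq(eic("c", 1:50, rep(7, 50))), 0)
})

test_that("MCQ is invariant to intensity scaling", {
  set.seed(2)
  v <- gaussian_eic(center = 5, sigma = 0.2, height = 100)$intensity +
       abs(rnorm(1001, 0, 3))
  x1 <- eic("a", seq_along(v), v)
  x2 <- eic("a", seq_along(v), 1e4 * v)
  expect_equal(mcq(x1), mcq(x2), tolerance = 1e-12)
})

test_that("asymmetry factor is 1 for a symmetric peak and matches the dense-grid oracle for tailed peaks", {
  g <- gaussian_eic(center = 5, sigma = 0.1, height = 1e4, step = 0.005)
  pk <- detect_peaks(g)[[1]]
  expect_equal(asymmetry_factor(g, pk), 1, tolerance = 0.01)

  # EMG with strong tailing: asymmetry > 1, within a grid step of the
  # analytic dense-grid crossing search
  rt <- seq(0, 10, 0.005)
  y <- emg_analytic(rt, 5, 0.08, 0.15, 1e4)
  x <- eic("emg", rt, y)
  pk <- detect_peaks(x)[[1]]
  as_got <- asymmetry_factor(x, pk)
  expect_gt(as_got, 1.2)
  dc <- dense_crossing(function(t) emg_analytic(t, 5, 0.08, 0.15, 1e4),
                       4, 7, 0.10)
  expect_equal(as_got, dc$asym, tolerance = 0.02)

  # mirrored (fronting) peak: asymmetry is the reciprocal of the tailing case
  xm <- eic("m", rt, rev(y))
  pkm <- detect_peaks(xm)[[1]]
  expect_equal(asymmetry_factor(xm, pkm), 1 / as_got, tolerance = 0.02)
})

test_that("asymmetry is undefined when the 10% crossing lies outside the region", {
  g <- gaussian_eic(center = 5, sigma = 0.1, height = 1e4, step = 0.01)
  # clamp the region to +-0.5 sigma around the apex: no 10% crossing inside
  apex <- which.max(g$intensity)
  tight <- structure(list(apex_idx = apex, left_idx = apex - 5L,
                          right_idx = apex + 5L, rt_apex = g$rt[apex],
                          apex_intensity = max(g$intensity)),
                     class = "peak_region")
  expect_true(is.na(asymmetry_factor(g, tight)))
  expect_true(is.na(fwhm(g, tight)))
})

test_that("FWHM matches the Gaussian closed form and scales with sigma", {
  g1 <- gaussian_eic(center = 5, sigma = 0.1, height = 1e4, step = 0.005)
  pk1 <- detect_peaks(g1)[[1]]
  expect_equal(fwhm(g1, pk1), 2 * sqrt(2 * log(2)) * 0.1, tolerance = 0.005 / 0.2355)

  g2 <- gaussian_eic(center = 5, sigma = 0.2, height = 1e4, step = 0.005)
  pk2 <- detect_peaks(g2)[[1]]
  expect_equal(fwhm(g2, pk2) / fwhm(g1, pk1), 2, tolerance = 0.02)

  # triangle of half-width w at base has width w at half height
  rt <- seq(0, 4, 0.01)
  w <- 0.8
  tri <- eic("t", rt, pmax(0, 1 - abs(rt - 2) / w) * 1000)
  pkt <- detect_peaks(tri)[[1]]
  expect_equal(fwhm(tri, pkt), w, tolerance = 0.02)
})

test_that("jaggedness is 0 for unimodal, ~1 for sawtooth, and recountable on noisy peaks", {
  g <- gaussian_eic(center = 5, sigma = 0.2, height = 1e3, step = 0.02)
  expect_equal(jaggedness(g, whole_region(g)), 0)

  saw <- eic("s", 1:100, 500 + rep(c(0, 100), 50))
  expect_gt(jaggedness(saw, whole_region(saw)), 0.9)

  set.seed(8)
  noisy <- gaussian_eic(center = 5, sigma = 0.2, height = 1e3, step = 0.02)
  noisy$intensity <- noisy$intensity + rnorm(length(noisy$rt), 0, 30)
  reg <- whole_region(noisy)
  d <- diff(noisy$intensity[reg$left_idx:reg$right_idx])
  s <- sign(d); s <- s[s != 0]
  flips <- sum(s[-1] != s[-length(s)])
  expect_equal(jaggedness(noisy, reg),
               max(0, flips - 1) / (length(d) - 1), tolerance = 1e-12)
})

test_that("modality measures the deepest interior dip relative to the apex", {
  g <- gaussian_eic(center = 5, sigma = 0.2, height = 1e3)
  expect_equal(modality(g, whole_region(g)), 0)

  # two equal Gaussians whose valley sits at 40% of the apex -> modality 0.6
  sigma <- 0.15
  valley_frac <- function(d) {
    f <- function(t) exp(-0.5 * ((t - (5 - d / 2)) / sigma)^2) +
      exp(-0.5 * ((t - (5 + d / 2)) / sigma)^2)
    tt <- seq(4, 6, length.out = 4e4)
    y <- f(tt)
    y[which.min(abs(tt - 5))] / max(y)
  }
  d <- uniroot(function(d) valley_frac(d) - 0.4, c(0.2, 1.2))$root
  rt <- seq(3, 7, 0.005)
  y <- 1e4 * (exp(-0.5 * ((rt - (5 - d / 2)) / sigma)^2) +
              exp(-0.5 * ((rt - (5 + d / 2)) / sigma)^2))
  x <- eic("bi", rt, y)
  expect_equal(modality(x, whole_region(x)), 0.6, tolerance = 0.01)

  # halving the dip halves the modality: the affine map (y + apex) / 2
  # preserves the extremum structure, keeps the apex height, and halves
  # every dip depth
  m1 <- modality(x, whole_region(x))
  x2 <- eic("bi2", rt, (y + max(y)) / 2)
  m2 <- modality(x2, whole_region(x2))
  expect_equal(m2, m1 / 2, tolerance = 1e-9)
})

test_that("retention-time RSD follows the textbook formula", {
  expect_equal(rsd_rt(c(5, 5, 5)), 0)
  expect_equal(rsd_rt(c(4, 5, 6)), 20)
  expect_equal(rsd_rt(3 * c(4, 5, 6)), 20)        # scale invariance
  expect_true(is.na(rsd_rt(5)))
})

test_that("Std/Blk compares the apex to the blank's local maximum with an epsilon floor", {
  blank <- eic("b", seq(0, 10, 0.1), c(rep(0, 45), 1000, rep(0, 55)))
  expect_equal(std_blk(6000, blank, rt_apex = 4.5), 6)
  zero_blank <- eic("b", seq(0, 10, 0.1), rep(0, 101))
  expect_equal(std_blk(500, zero_blank, rt_apex = 4.5), 500)
  # the printed failure case: 4719 over a 1000-count blank fails r = 6
  expect_equal(std_blk(4719, blank, rt_apex = 4.5), 4.719)
  expect_lt(std_blk(4719, blank, rt_apex = 4.5), 6)
  # blank signal outside the +-0.5 min window is ignored
  far_blank <- eic("b", seq(0, 10, 0.1), c(rep(0, 80), 5000, rep(0, 20)))
  expect_equal(std_blk(500, far_blank, rt_apex = 2), 500)
})

test_that("evaluate_peak assembles all eight metrics and flags missing inputs", {
  sc <- synth_scene(0, 10, 0.01, peaks = list(synth_peak(5, 0.1, 0.05, 2e4)),
                    baseline_offset = 30, noise_sd = 10, seed = 3)
  x <- make_eic(sc)$eic
  ce <- correct_eic(x)
  pk <- select_analyte_peak(detect_peaks(ce), analyte_spec("a", 100))
  blank <- eic("a", x$rt, 0.02 * x$intensity, is_blank = TRUE)

  full <- evaluate_peak(ce, pk, blank = blank,
                        replicate_rts = c(5.00, 5.01, 4.99))
  for (nm in c("mcq", "max_intensity", "rsd_rt", "std_blk", "jaggedness",
               "asymmetry", "fwhm", "modality"))
    expect_false(is.na(full[[nm]]))
  expect_true(full$mcq >= 0 && full$mcq <= 1)
  expect_true(full$jaggedness >= 0 && full$jaggedness <= 1)
  expect_true(full$modality >= 0 && full$modality <= 1)
  expect_gt(full$asymmetry, 0)

  no_blank <- evaluate_peak(ce, pk, replicate_rts = c(5.00, 5.01))
  expect_true(is.na(no_blank$std_blk))
  expect_false(is.na(no_blank$mcq))

  single_rep <- evaluate_peak(ce, pk, blank = blank, replicate_rts = 5.0)
  expect_true(is.na(single_rep$rsd_rt))
})

test_that("metrics respond to intensity scaling as documented", {
  sc <- synth_scene(0, 10, 0.01, peaks = list(synth_peak(5, 0.1, 0.05, 2e4)),
                    noise_sd = 15, seed = 21)
  x <- make_eic(sc)$eic
  x10 <- x; x10$intensity <- 10 * x$intensity
  m1 <- evaluate_eic(x)
  m2 <- evaluate_eic(x10)
  expect_equal(m2$max_intensity / m1$max_intensity, 10, tolerance = 1e-6)
  for (nm in c("mcq", "jaggedness", "asymmetry", "fwhm", "modality"))
    expect_equal(m2[[nm]], m1[[nm]], tolerance = 1e-6)
})

test_that("added noise degrades MCQ and raises jaggedness on average", {
  base <- gaussian_eic(center = 5, sigma = 0.15, height = 1e4, step = 0.02)
  reg <- whole_region(base)
  mcq_clean <- mcq(base)
  jag_clean <- jaggedness(base, reg)
  mcqs <- jags <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    noisy <- base
    noisy$intensity <- pmax(0, base$intensity + rnorm(length(base$rt), 0, 300))
    mcqs[s] <- mcq(noisy)
    jags[s] <- jaggedness(noisy, whole_region(noisy))
  }
  expect_lte(mean(mcqs), mcq_clean)
  expect_gte(mean(jags), jag_clean)
})
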