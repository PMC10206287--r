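# Shared fixture builders and independent oracles. Oracles are written as
# plain, naive code so they stay independent of the package implementation.

# simple Gaussian trace on a uniform grid, returned as an eic
gaussian_eic <- function(center = 5, sigma = 0.1, height = 1e4,
                         rt_start = 0, rt_end = 10, step = 0.01,
                         baseline = 0, id = "g") {
  rt <- seq(rt_start, rt_end, by = step)
  eic(id, rt, height * exp(-0.5 * ((rt - center) / sigma)^2) + baseline)
}

# analytic EMG (independent of the package's emg_profile): direct erfc form
# evaluated in high precision via pracma::erfc
emg_analytic <- function(t, center, sigma, tau, height) {
  if (tau == 0) return(height * exp(-0.5 * ((t - center) / sigma)^2))
  arg <- (sigma / tau - (t - center) / sigma) / sqrt(2)
  height * sigma / tau * sqrt(pi / 2) *
    exp(0.5 * (sigma / tau)^2 - (t - center) / tau) * pracma::erfc(arg)
}

# dense-grid crossing oracle: width/asymmetry of an analytic curve measured
# at `frac` of its maximum by scanning a very fine grid
dense_crossing <- function(f, lo, hi, frac, n = 2e5) {
  tt <- seq(lo, hi, length.out = n)
  y <- f(tt)
  imax <- which.max(y)
  target <- frac * y[imax]
  left <- tt[min(which(y >= target))]
  right <- tt[max(which(y >= target))]
  list(apex = tt[imax], left = left, right = right,
       width = right - left,
       asym = (right - tt[imax]) / (tt[imax] - left))
}

# independent MCQ oracle: plain-loop evaluation of the CODA formula
oracle_mcq <- function(v, window = 3) {
  n <- length(v)
  h <- (window - 1) / 2
  idx <- (h + 1):(n - h)
  sm <- numeric(length(idx))
  for (k in seq_along(idx)) sm[k] <- mean(v[(idx[k] - h):(idx[k] + h)])
  xa <- v[idx]
  if (sd(sm) == 0 || sqrt(sum(xa^2)) == 0) return(0)
  yhat <- (sm - mean(sm)) / sd(sm)
  xhat <- xa / sqrt(sum(xa^2))
  min(max(sum(xhat * yhat) / sqrt(length(idx) - 1), 0), 1)
}

# naive reference peak detector: same stated rules (strict local maxima with
# leftmost-plateau apexes, relative height threshold, walk-down boundaries,
# minimum region size) written as a direct loop
oracle_detect_count <- function(y, min_rel_height = 0.01,
                                boundary_frac = 0.01, min_points = 5L) {
  n <- length(y)
  gmax <- max(y)
  if (gmax <= 0) return(0L)
  count <- 0L
  for (i in 2:(n - 1)) {
    if (!(y[i] > y[i - 1])) next
    # end of the plateau starting at i
    j <- i
    while (j < n && y[j + 1] == y[j]) j <- j + 1
    if (j >= n || !(y[j + 1] < y[j])) next
    if (y[i] < min_rel_height * gmax) next
    cutoff <- boundary_frac * y[i]
    left <- i
    while (left > 1 && y[left] > cutoff && y[left - 1] <= y[left])
      left <- left - 1
    right <- j
    while (right < n && y[right] > cutoff && y[right + 1] <= y[right])
      right <- right + 1
    if (right - left + 1 >= min_points && left < i && right > i)
      count <- count + 1L
  }
  count
}

# build a peak_metrics record directly (for scoring/validation tests)
fake_metrics <- function(mcq = 0.9, max_intensity = 5000, rsd_rt = 2,
                         std_blk = 50, jaggedness = 0, asymmetry = 1.1,
                         fwhm = 0.2, modality = 0) {
  structure(list(mcq = mcq, max_intensity = max_intensity, rsd_rt = rsd_rt,
                 std_blk = std_blk, jaggedness = jaggedness,
                 asymmetry = asymmetry, fwhm = fwhm, modality = modality),
            class = "peak_metrics")
}

# a phase_result with `n_val` validated analytes out of `ids`, whose common
# analytes carry the given asymmetry values
fake_phase <- function(phase_id, ids, n_val, asym_values) {
  per <- lapply(seq_along(ids), function(i)
    fake_metrics(asymmetry = asym_values[i]))
  names(per) <- ids
  phase_result(phase_id, per, validated_ids = ids[seq_len(n_val)])
}

# independent sort-based ascending rank with ties sharing the block minimum
oracle_min_rank <- function(x) {
  vapply(x, function(v) sum(x < v) + 1L, integer(1))
}

# scenes for the 20-analyte end-to-end study: 17 clean analytes plus three
# designed failures (low Std/Blk, low intensity, high RT RSD). The high-RSD
# analyte gets per-replicate centers 3, 8, 8 min (RSD 45.6%), so its
# rejection is deterministic. Returns per-replicate scene lists.
study_scenes <- function(seed = 42L, n_replicates = 3L) {
  set.seed(seed)
  ids <- c(sprintf("clean_%02d", 1:17), "low_stdblk", "low_intensity",
           "high_rsd")
  centers <- seq(2, 8, length.out = 20)
  heights <- c(stats::runif(17, 5e3, 5e4), 2e4, 600, 2e4)
  blankf <- c(rep(0.01, 17), 0.3, 0.01, 0.01)
  seeds <- sample.int(1e6, 20)
  rsd_centers <- c(3, 8, 8)
  lapply(seq_len(n_replicates), function(r) {
    sc <- lapply(seq_along(ids), function(i) {
      ctr <- if (ids[i] == "high_rsd") rsd_centers[r] else centers[i]
      synth_scene(0, 10, 0.02,
                  peaks = list(synth_peak(ctr, 0.08, 0, heights[i])),
                  baseline_offset = 20, baseline_slope = 2, noise_sd = 3,
                  rt_jitter_sd = 0.005, blank_fraction = blankf[i],
                  seed = seeds[i] + r)
    })
    names(sc) <- ids
    sc
  })
}

study_analytes <- function() {
  ids <- c(sprintf("clean_%02d", 1:17), "low_stdblk", "low_intensity",
           "high_rsd")
  lapply(seq_along(ids), function(i)
    analyte_spec(ids[i], target_mz = 100 + 5 * i))
}

# write the study as per-replicate run files plus a blank; returns paths
write_study <- function(dir, seed = 42L, dialect = "mzml",
                        n_replicates = 3L) {
  scenes_by_rep <- study_scenes(seed, n_replicates)
  analytes <- study_analytes()
  reps <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    sub <- file.path(dir, sprintf("rep%d", r))
    res <- make_run_files(scenes_by_rep[[r]], analytes, sub,
                          dialect = dialect, n_replicates = 1L,
                          blank = (r == 1L))
    reps[r] <- res$replicates[1]
    if (r == 1L) blank <- res$blank
  }
  list(replicates = reps, blank = blank, analytes = analytes)
}
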