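# Synthetic chromatograms and runs with known ground truth. Peaks are
# Gaussian or exponentially modified Gaussian (EMG) — the EMG gives
# analytically controlled tailing for asymmetry/modality testing. Noise is
# additive Gaussian (not Poisson) for simplicity; generation is always
# seeded and bit-reproducible.

#' Synthetic peak specification
#'
#' @param center_rt Gaussian center in minutes (for `tau > 0` the true apex
#'   shifts right of this; ground truth reports the actual apex).
#' @param sigma Gaussian width in minutes.
#' @param tau Exponential tailing time constant in minutes; 0 gives a pure
#'   Gaussian.
#' @param height Gaussian amplitude in counts (the pre-convolution height).
#' @return An object of class `synth_peak`.
#' @export
synth_peak <- function(center_rt, sigma, tau = 0, height = 1e4) {
  if (sigma <= 0) stop_validation("sigma must be > 0")
  if (height <= 0) stop_validation("height must be > 0")
  if (tau < 0) stop_validation("tau must be >= 0")
  structure(list(center_rt = center_rt, sigma = sigma, tau = tau,
                 height = height), class = "synth_peak")
}

#' Synthetic scene specification
#'
#' Describes one analyte channel: an RT grid, a set of peaks, a drifting
#' baseline `offset + slope * t + exp_amp * exp(-exp_rate * t)`, white
#' noise, replicate-to-replicate RT jitter, and the fraction of the peak
#' signal leaking into the blank channel.
#'
#' @param rt_start,rt_end,rt_step RT grid in minutes.
#' @param peaks List of [synth_peak()]s.
#' @param baseline_offset,baseline_slope,baseline_exp_amp,baseline_exp_rate
#'   Baseline model parameters (counts, counts/min, counts, 1/min).
#' @param noise_sd White-noise standard deviation in counts.
#' @param rt_jitter_sd Replicate-to-replicate apex jitter SD in minutes.
#' @param blank_fraction Fraction of the noiseless peak signal present in
#'   the blank channel.
#' @param seed Integer seed; all generation is reproducible.
#' @return An object of class `synth_scene`.
#' @export
synth_scene <- function(rt_start = 0, rt_end = 10, rt_step = 0.01,
                        peaks = list(), baseline_offset = 0,
                        baseline_slope = 0, baseline_exp_amp = 0,
                        baseline_exp_rate = 1, noise_sd = 0,
                        rt_jitter_sd = 0, blank_fraction = 0, seed = 1L) {
  if (rt_step <= 0) stop_validation("rt_step must be > 0")
  if (rt_end <= rt_start) stop_validation("rt_end must exceed rt_start")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  if (inherits(peaks, "synth_peak")) peaks <- list(peaks)
  structure(list(rt_start = rt_start, rt_end = rt_end, rt_step = rt_step,
                 peaks = peaks, baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope,
                 baseline_exp_amp = baseline_exp_amp,
                 baseline_exp_rate = baseline_exp_rate,
                 noise_sd = noise_sd, rt_jitter_sd = rt_jitter_sd,
                 blank_fraction = blank_fraction, seed = as.integer(seed)),
            class = "synth_scene")
}

# EMG profile, numerically stable over the whole trace; tau -> 0 limit is
# the Gaussian itself. Leading flank (u >= 0): scaled-complementary-error
# form with erfcx. Trailing flank (u < 0): the direct exponential-decay
# form, whose exponent a*(a/2 - z) is negative there, so nothing overflows.
emg_profile <- function(t, center, sigma, tau, height) {
  z <- (t - center) / sigma
  if (tau < 1e-12) return(height * exp(-0.5 * z^2))
  a <- sigma / tau
  u <- (a - z) / sqrt(2)
  out <- numeric(length(t))
  lead <- u >= 0
  out[lead] <- exp(-0.5 * z[lead]^2) * erfcx_safe(u[lead])
  out[!lead] <- exp(a * (0.5 * a - z[!lead])) * pracma::erfc(u[!lead])
  height * a * sqrt(pi / 2) * out
}

# erfcx overflows internally for large arguments; switch to the asymptotic
# series 1/(u sqrt(pi)) * (1 - 1/(2u^2) + 3/(4u^4)) well inside its accuracy
erfcx_safe <- function(u) {
  big <- u > 25
  out <- numeric(length(u))
  if (any(!big)) out[!big] <- pracma::erfcx(u[!big])
  if (any(big)) {
    ub <- u[big]
    out[big] <- (1 - 0.5 / ub^2 + 0.75 / ub^4) / (ub * sqrt(pi))
  }
  out
}

scene_rt_grid <- function(scene) {
  seq(scene$rt_start, scene$rt_end, by = scene$rt_step)
}

scene_peak_signal <- function(scene, rt, rt_shift = 0) {
  sig <- numeric(length(rt))
  for (p in scene$peaks)
    sig <- sig + emg_profile(rt, p$center_rt + rt_shift, p$sigma, p$tau,
                             p$height)
  sig
}

scene_baseline <- function(scene, rt) {
  scene$baseline_offset + scene$baseline_slope * rt +
    scene$baseline_exp_amp * exp(-scene$baseline_exp_rate * rt)
}

# true apex RT and FWHM of each peak, evaluated on a dense (step/50) grid of
# the noiseless, baseline-free signal of that single peak
peak_ground_truth <- function(scene, rt_shift = 0) {
  lapply(scene$peaks, function(p) {
    lo <- p$center_rt + rt_shift - 6 * p$sigma
    hi <- p$center_rt + rt_shift + 6 * p$sigma + 8 * p$tau
    tt <- seq(lo, hi, by = scene$rt_step / 50)
    y <- emg_profile(tt, p$center_rt + rt_shift, p$sigma, p$tau, p$height)
    imax <- which.max(y)
    above <- which(y >= y[imax] / 2)
    list(apex_rt = tt[imax], apex_intensity = y[imax],
         fwhm = tt[max(above)] - tt[min(above)])
  })
}

#' Generate a synthetic EIC with ground truth
#'
#' `intensity(t) = sum(peaks) + baseline(t) + noise(t)`, clipped at 0.
#'
#' @param scene A [synth_scene()].
#' @param analyte_id Analyte id to attach to the EIC.
#' @param rt_shift RT shift applied to every peak center (used for replicate
#'   jitter).
#' @param noise `TRUE` to add seeded white noise.
#' @return A list with `eic` (an [eic()]) and `truth` (per-peak `apex_rt`,
#'   `apex_intensity`, `fwhm` on a dense grid, plus the `baseline` vector).
#' @export
make_eic <- function(scene, analyte_id = "synthetic", rt_shift = 0,
                     noise = TRUE) {
  rt <- scene_rt_grid(scene)
  base <- scene_baseline(scene, rt)
  sig <- scene_peak_signal(scene, rt, rt_shift)
  y <- sig + base
  if (noise && scene$noise_sd > 0) {
    set.seed(scene$seed)
    y <- y + rnorm(length(rt), 0, scene$noise_sd)
  }
  list(eic = eic(analyte_id, rt, pmax(y, 0)),
       truth = list(peaks = peak_ground_truth(scene, rt_shift),
                    baseline = base))
}

#' Generate replicate EICs with RT jitter
#'
#' Each replicate shifts every peak center by a seeded N(0, `rt_jitter_sd`)
#' draw and resamples the noise; the empirical apex-RT RSD converges to the
#' designed jitter as the number of replicates grows.
#'
#' @param scene A [synth_scene()].
#' @param n Number of replicates.
#' @param analyte_id Analyte id to attach.
#' @return A list of `n` results in the form returned by [make_eic()].
#' @export
make_replicates <- function(scene, n, analyte_id = "synthetic") {
  set.seed(scene$seed)
  shifts <- rnorm(n, 0, scene$rt_jitter_sd)
  noise_seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    sc <- scene
    sc$seed <- noise_seeds[i]
    res <- make_eic(sc, analyte_id = analyte_id, rt_shift = shifts[i])
    res$eic$meta$replicate <- i
    res
  })
}

# ---- minimal standards-conformant mzML / mzXML writers --------------------

b64_doubles <- function(x, endian = "little") {
  # base64_enc wraps long output; binary-data elements must be one line
  gsub("[\r\n]", "",
       jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                     endian = endian)))
}

#' Write scans as a minimal mzML file
#'
#' @param scans List of `list(rt, mz, intensity)` with `rt` in minutes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(scans, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., file = con, sep = "")
  w('<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">\n',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '<cv id="UO" fullName="Unit Ontology" version="09:04:2014" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>\n',
    '</cvList>\n',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="chromeval" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="chromeval"/></software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="DP1"><processingMethod order="1" softwareRef="chromeval"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>\n')
  w(sprintf('<run id="run1" defaultInstrumentConfigurationRef="IC1">\n<spectrumList count="%d" defaultDataProcessingRef="DP1">\n',
            length(scans)))
  for (i in seq_along(scans)) {
    s <- scans[[i]]
    mzb <- b64_doubles(s$mz)
    inb <- b64_doubles(s$intensity)
    w(sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
              i - 1L, i, length(s$mz)),
      '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      sprintf('<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.17g" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/></scan></scanList>\n',
              s$rt),
      '<binaryDataArrayList count="2">\n',
      sprintf('<binaryDataArray encodedLength="%d">\n<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n<binary>%s</binary>\n</binaryDataArray>\n',
              nchar(mzb), mzb),
      sprintf('<binaryDataArray encodedLength="%d">\n<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n<binary>%s</binary>\n</binaryDataArray>\n',
              nchar(inb), inb),
      '</binaryDataArrayList>\n</spectrum>\n')
  }
  w('</spectrumList>\n</run>\n</mzML>\n')
  invisible(path)
}

#' Write scans as a minimal mzXML file
#'
#' @inheritParams write_mzml
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(scans, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., file = con, sep = "")
  w('<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">\n',
    sprintf('<msRun scanCount="%d">\n', length(scans)))
  for (i in seq_along(scans)) {
    s <- scans[[i]]
    pairs <- as.double(rbind(s$mz, s$intensity))   # interleaved m/z,intensity
    pk <- b64_doubles(pairs, endian = "big")
    w(sprintf('<scan num="%d" msLevel="1" peaksCount="%d" retentionTime="PT%.17gS">\n',
              i, length(s$mz), s$rt * 60),
      sprintf('<peaks precision="64" byteOrder="network" contentType="m/z-int" compressionType="none" compressedLen="0">%s</peaks>\n',
              pk),
      '</scan>\n')
  }
  w('</msRun>\n</mzXML>\n')
  invisible(path)
}

#' Write a synthetic study as mzML/mzXML run files
#'
#' Builds full MS1 runs in which each analyte's synthetic EIC is embedded at
#' its target m/z, plus an optional blank run carrying `blank_fraction`
#' times each analyte's noiseless peak signal (no baseline, no noise), and
#' writes them in the requested dialect. All scenes must share one RT grid.
#'
#' @param scenes Named list mapping analyte_id to a [synth_scene()].
#' @param analytes List of [analyte_spec()]s; names must match `scenes`.
#' @param out_dir Output directory (created if needed).
#' @param dialect `"mzml"` or `"mzxml"`.
#' @param n_replicates Number of replicate sample runs.
#' @param blank Whether to write a blank run.
#' @return A list with `replicates` (character paths) and `blank` (path or
#'   `NULL`).
#' @export
make_run_files <- function(scenes, analytes, out_dir,
                           dialect = c("mzml", "mzxml"), n_replicates = 3L,
                           blank = TRUE) {
  dialect <- match.arg(dialect)
  ids <- vapply(analytes, `[[`, character(1), "analyte_id")
  if (!setequal(names(scenes), ids))
    stop_config("scene names must match analyte ids")
  grids <- lapply(scenes, scene_rt_grid)
  rt <- grids[[1]]
  if (!all(vapply(grids, function(g) isTRUE(all.equal(g, rt)), logical(1))))
    stop_config("all scenes must share one RT grid")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "mzml") ".mzML" else ".mzXML"
  writer <- if (dialect == "mzml") write_mzml else write_mzxml
  mzs <- vapply(analytes, `[[`, numeric(1), "target_mz")

  reps_by_analyte <- lapply(ids, function(id)
    make_replicates(scenes[[id]], n_replicates, analyte_id = id))
  names(reps_by_analyte) <- ids
  traces_per_rep <- lapply(seq_len(n_replicates), function(r) {
    vapply(ids, function(id) reps_by_analyte[[id]][[r]]$eic$intensity,
           numeric(length(rt)))
  })
  rep_paths <- vapply(seq_len(n_replicates), function(r) {
    tr <- traces_per_rep[[r]]
    scans <- lapply(seq_along(rt), function(i)
      list(rt = rt[i], mz = mzs, intensity = as.numeric(tr[i, ])))
    path <- file.path(out_dir, sprintf("replicate_%d%s", r, ext))
    writer(scans, path)
    path
  }, character(1))

  blank_path <- NULL
  if (blank) {
    btr <- vapply(ids, function(id) {
      sc <- scenes[[id]]
      sc$blank_fraction * scene_peak_signal(sc, rt)
    }, numeric(length(rt)))
    scans <- lapply(seq_along(rt), function(i)
      list(rt = rt[i], mz = mzs, intensity = as.numeric(btr[i, ])))
    blank_path <- file.path(out_dir, paste0("blank", ext))
    writer(scans, blank_path)
  }
  list(replicates = rep_paths, blank = blank_path)
}
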