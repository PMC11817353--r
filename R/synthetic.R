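#' Configuration for the synthetic 12-lead ECG generator
#'
#' Defaults state the emulated world: 1321 records across the seven
#' occlusion classes (180/185/252/183/173/156/192), 500 Hz, 10 s per
#' record, NSTEMI-like ST-segment depression of 0.15 mV on the occluded
#' arteries' territory leads with T-wave inversion on half the records,
#' 0.02 mV white noise and 0.05 mV respiratory baseline wander.
#'
#' @param fs Sampling frequency in Hz.
#' @param duration Record length in seconds (`fs * duration` must be an
#'   integer).
#' @param heart_rate_bpm Length-2 range of heart rates; each record draws
#'   one rate uniformly.
#' @param st_shift_mv Magnitude of the ST-segment level depression applied
#'   to territory leads, in mV.
#' @param t_inversion_prob Probability that a record's territory leads get
#'   an inverted T wave.
#' @param noise_sd_mv Standard deviation of additive white noise, mV.
#' @param baseline_wander_mv Amplitude of the 0.2-0.5 Hz baseline drift, mV.
#' @param per_class_counts Integer vector of 7 record counts in
#'   [OCCLUSION_CLASSES] order.
#' @param seed Master seed for dataset generation.
#' @return A list of class `ecg_sim_config`.
#' @export
sim_config <- function(fs = 500, duration = 10,
                       heart_rate_bpm = c(55, 95),
                       st_shift_mv = 0.15, t_inversion_prob = 0.5,
                       noise_sd_mv = 0.02, baseline_wander_mv = 0.05,
                       per_class_counts = c(180, 185, 252, 183, 173, 156, 192),
                       seed = 1L) {
  stopifnot(fs > 0, duration > 0,
            abs(fs * duration - round(fs * duration)) < 1e-9,
            length(heart_rate_bpm) == 2, all(heart_rate_bpm > 0),
            st_shift_mv >= 0, t_inversion_prob >= 0, t_inversion_prob <= 1,
            noise_sd_mv >= 0, baseline_wander_mv >= 0,
            length(per_class_counts) == 7, all(per_class_counts >= 0))
  structure(list(fs = fs, duration = duration,
                 heart_rate_bpm = heart_rate_bpm, st_shift_mv = st_shift_mv,
                 t_inversion_prob = t_inversion_prob,
                 noise_sd_mv = noise_sd_mv,
                 baseline_wander_mv = baseline_wander_mv,
                 per_class_counts = as.integer(per_class_counts),
                 seed = as.integer(seed)),
            class = "ecg_sim_config")
}

# Per-lead projection of the common beat template. aVR sees the heart from
# the opposite direction (negative polarity). Gains are deliberately
# uniform: the generator's purpose is a separable, measurable class
# effect, and per-lead amplitude scaling would leak into the per-image
# normalization and confound the territory contrast (physiological
# fidelity is an explicit non-goal).
LEAD_GAIN <- c(I = 1, II = 1, III = 1, aVR = -1, aVL = 1,
               aVF = 1, V1 = 1, V2 = 1, V3 = 1, V4 = 1,
               V5 = 1, V6 = 1)

# Gaussian bump helper: amplitude a, centre mu (s), width sigma (s).
gauss_wave <- function(t, a, mu, sigma) a * exp(-0.5 * ((t - mu) / sigma)^2)

#' Generate one labeled synthetic 12-lead ECG record
#'
#' The waveform is a train of beats (P, Q, R, S, T parameterized Gaussian
#' bumps, scaled per lead) at a heart rate drawn from the configured
#' range. The class effect is an NSTEMI-like ST-segment depression
#' (`-st_shift_mv`) over the 80 ms window following the QRS offset of
#' every beat, plus optional T-wave inversion, applied only to the leads
#' in the label's territory ([class_territory()]); aVR carries no class
#' effect. Baseline wander and white noise are added on top. Output is
#' bit-deterministic in `(label, config, seed)`.
#'
#' @param label Class name from [OCCLUSION_CLASSES].
#' @param config An [sim_config()].
#' @param seed Integer seed for this record.
#' @param record_id Identifier (default derived from label and seed).
#' @return An [ecg_record()] with `meta$r_peaks` holding the R-peak times
#'   (seconds, comma-separated) for downstream ST-window measurement.
#' @export
generate_record <- function(label, config = sim_config(), seed = 1L,
                            record_id = sprintf("%s_seed%d", gsub("\\+", "", label), seed)) {
  label <- match.arg(label, OCCLUSION_CLASSES)
  stopifnot(inherits(config, "ecg_sim_config"))
  local_seed(seed)
  fs <- config$fs
  n <- as.integer(round(fs * config$duration))
  t <- (seq_len(n) - 1) / fs

  hr <- runif(1, config$heart_rate_bpm[1], config$heart_rate_bpm[2])
  rr <- 60 / hr
  r_peaks <- seq(0.4, config$duration - 0.45, by = rr)
  invert_t <- runif(1) < config$t_inversion_prob
  territory <- class_territory(label)

  # common beat template per lead, then territory-specific ischemia marks
  st_on <- 0.045  # QRS offset relative to R peak (s)
  st_len <- 0.08  # ST window length (s)
  leads <- setNames(vector("list", 12), ECG_LEADS)
  # precompute per-beat template on the full time axis
  base <- numeric(n); stwin <- numeric(n); twave <- numeric(n)
  for (r in r_peaks) {
    base <- base +
      gauss_wave(t, 0.12, r - 0.16, 0.022) +   # P
      gauss_wave(t, -0.15, r - 0.025, 0.008) + # Q
      gauss_wave(t, 1.00, r, 0.010) +          # R
      gauss_wave(t, -0.25, r + 0.025, 0.008)   # S
    twave <- twave + gauss_wave(t, 0.30, r + 0.30, 0.050)
    stwin <- stwin + as.numeric(t >= r + st_on & t < r + st_on + st_len)
  }
  stwin <- pmin(stwin, 1)

  for (ld in ECG_LEADS) {
    g <- LEAD_GAIN[[ld]]
    tsign <- if (ld %in% territory && invert_t) -1 else 1
    x <- g * (base + tsign * twave)
    if (ld %in% territory) x <- x - config$st_shift_mv * stwin
    if (config$baseline_wander_mv > 0) {
      f_bw <- runif(1, 0.2, 0.5); ph <- runif(1, 0, 2 * pi)
      x <- x + config$baseline_wander_mv * sin(2 * pi * f_bw * t + ph)
    }
    if (config$noise_sd_mv > 0) x <- x + rnorm(n, 0, config$noise_sd_mv)
    leads[[ld]] <- x
  }
  ecg_record(leads, fs = fs, record_id = record_id, label = label,
             meta = list(r_peaks = paste(signif(r_peaks, 9), collapse = ","),
                         seed = as.character(seed),
                         t_inverted = as.character(invert_t)))
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `per_class_counts[i]` records of class `i` via the package CSV
#' dialect plus a manifest CSV (`record_id,label,seed,path`). Per-record
#' seeds follow a stated counter scheme: `master seed + running record
#' index` (index starting at 1 across the whole dataset, classes in
#' canonical order), so generation is a pure function of the config.
#'
#' @param config An [sim_config()].
#' @param dir Output directory (created if needed).
#' @param write If `FALSE`, no waveform files are written; the manifest
#'   (with empty paths) and in-memory records are still produced when
#'   `keep = TRUE`.
#' @param keep If `TRUE`, return the generated records in memory as well.
#' @return A list with `manifest` (data.frame) and, if `keep`, `records`
#'   (list of [ecg_record()]).
#' @export
generate_dataset <- function(config = sim_config(), dir = tempfile("ecgds"),
                             write = TRUE, keep = FALSE) {
  stopifnot(inherits(config, "ecg_sim_config"))
  if (write) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- config$per_class_counts
  total <- sum(counts)
  manifest <- data.frame(record_id = character(total),
                         label = character(total),
                         seed = integer(total), path = character(total),
                         stringsAsFactors = FALSE)
  records <- if (keep) vector("list", total) else NULL
  idx <- 0L
  for (ci in seq_along(OCCLUSION_CLASSES)) {
    for (j in seq_len(counts[ci])) {
      idx <- idx + 1L
      seed_i <- as.integer((config$seed + idx) %% 2147483647)
      rid <- sprintf("rec%04d_%s", idx, gsub("\\+", "", OCCLUSION_CLASSES[ci]))
      rec <- generate_record(OCCLUSION_CLASSES[ci], config, seed = seed_i,
                             record_id = rid)
      p <- ""
      if (write) {
        p <- file.path(dir, paste0(rid, ".csv"))
        write_record(rec, p, "csv")
      }
      manifest[idx, ] <- list(rid, OCCLUSION_CLASSES[ci], seed_i, p)
      if (keep) records[[idx]] <- rec
    }
  }
  if (write)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  out <- list(manifest = manifest, dir = if (write) dir else NA_character_)
  if (keep) out$records <- records
  out
}

#' Territory-rule baseline classifier
#'
#' Brute-force oracle used to certify that the synthetic classes are
#' separable before any model sees them: estimate each lead's ST-window
#' deviation (mean amplitude in the 80 ms window after the QRS offset,
#' relative to the isoelectric baseline before the P wave), then assign
#' the class whose territory leads show the largest mean absolute ST
#' deviation contrast against non-territory leads (aVR excluded).
#'
#' @param record An [ecg_record()].
#' @return Predicted class name.
#' @export
classify_st_rule <- function(record) {
  dev <- st_deviation(record)
  scores <- vapply(OCCLUSION_CLASSES, function(cl) {
    terr <- class_territory(cl)
    rest <- setdiff(ECG_LEADS, c(terr, "aVR"))
    mean(abs(dev[terr])) - if (length(rest)) mean(abs(dev[rest])) else 0
  }, numeric(1))
  names(which.max(scores))
}

# Per-lead ST deviation estimate (mV). R peaks are detected from the
# lead with the largest range (threshold at 60% of max with a 250 ms
# refractory period); baseline is taken 280-200 ms before each R peak.
st_deviation <- function(record) {
  fs <- record$fs
  ref <- record$leads[["II"]]
  thr <- 0.6 * max(ref)
  above <- which(ref > thr)
  peaks <- c()
  last <- -Inf
  for (i in above) {
    if ((i - last) / fs > 0.25) { peaks <- c(peaks, i); last <- i }
    else if (ref[i] > ref[last]) { peaks[length(peaks)] <- i; last <- i }
  }
  dev <- setNames(numeric(12), ECG_LEADS)
  for (ld in ECG_LEADS) {
    x <- record$leads[[ld]]
    d <- 0; m <- 0
    for (p in peaks) {
      st_i <- p + round(0.055 * fs):round(0.115 * fs)
      bl_i <- p - round(0.28 * fs):round(0.20 * fs)
      st_i <- st_i[st_i >= 1 & st_i <= length(x)]
      bl_i <- bl_i[bl_i >= 1 & bl_i <= length(x)]
      if (length(st_i) && length(bl_i)) {
        d <- d + mean(x[st_i]) - mean(x[bl_i]); m <- m + 1
      }
    }
    dev[ld] <- if (m > 0) d / m else 0
  }
  dev
}
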