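#' Spectrogram transform parameters
#'
#' Defaults follow the stated time-frequency front end: a 10-sample
#' Hamming window, 512-point FFT at 500 Hz, viridis colormap, and a
#' 64 x 64 RGB output image. The hop (frame stride) is 5 samples, i.e.
#' 50% overlap, a standard default where the overlap is not otherwise
#' pinned down.
#'
#' @param window Hamming window length in samples.
#' @param hop Samples between successive frames.
#' @param nfft FFT length (frames are zero-padded to this length).
#' @param fs Sampling frequency in Hz.
#' @param colormap Colormap name; `"viridis"` and `"gray"` are supported.
#' @param out_size Side of the square output image in pixels.
#' @return A list of class `spec_params`.
#' @export
spec_params <- function(window = 10, hop = 5, nfft = 512, fs = 500,
                        colormap = "viridis", out_size = 64) {
  stopifnot(window >= 2, window <= nfft, hop >= 1, out_size >= 8, fs > 0)
  structure(list(window = as.integer(window), hop = as.integer(hop),
                 nfft = as.integer(nfft), fs = fs, colormap = colormap,
                 out_size = as.integer(out_size)),
            class = "spec_params")
}

# symmetric Hamming window (0.54 - 0.46 cos), the common textbook form
hamming <- function(L) {
  if (L == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
}

#' Short-time Fourier transform magnitude spectrogram
#'
#' Frames of length `window` are taken every `hop` samples, multiplied by
#' a symmetric Hamming window, zero-padded to `nfft`, and the one-sided
#' magnitude spectrum is converted to dB as `20*log10(|.| + 1e-12)`.
#'
#' @param signal Numeric vector.
#' @param params A [spec_params()].
#' @return A list of class `spectrogram_matrix` with `values`
#'   ((nfft/2 + 1) x n_frames dB matrix), `freq` (Hz) and `time`
#'   (frame centres, seconds). `n_frames = floor((n - window)/hop) + 1`.
#' @export
stft_spectrogram <- function(signal, params = spec_params()) {
  stopifnot(inherits(params, "spec_params"))
  n <- length(signal)
  L <- params$window
  if (n < L) stop("signal-too-short: ", n, " samples < window ", L)
  nf <- (n - L) %/% params$hop + 1L
  starts <- (seq_len(nf) - 1L) * params$hop
  idx <- outer(seq_len(L), starts, `+`)      # L x nf sample indices
  frames <- matrix(signal[idx], nrow = L) * hamming(L)
  padded <- matrix(0, params$nfft, nf)
  padded[seq_len(L), ] <- frames
  spec <- stats::mvfft(padded)[seq_len(params$nfft %/% 2L + 1L), , drop = FALSE]
  db <- 20 * log10(Mod(spec) + 1e-12)
  structure(list(values = db,
                 freq = (0:(params$nfft %/% 2L)) * params$fs / params$nfft,
                 time = (starts + (L - 1) / 2) / params$fs,
                 params = params),
            class = "spectrogram_matrix")
}

viridis_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      f <- system.file("extdata", "viridis_256.csv", package = "coromix")
      lut <<- as.matrix(utils::read.csv(f))
    }
    lut
  }
})

colormap_lut <- function(name) {
  switch(name,
         viridis = viridis_lut(),
         gray = cbind(r = 0:255, g = 0:255, b = 0:255) / 255,
         stop("unknown colormap '", name,
              "'; supported: viridis, gray"))
}

# bilinear resample of a matrix to nr x nc (pixel-centre convention)
bilinear_resize <- function(m, nr, nc) {
  sr <- nrow(m); sc <- ncol(m)
  ri <- pmin(pmax((seq_len(nr) - 0.5) * sr / nr - 0.5, 0), sr - 1)
  ci <- pmin(pmax((seq_len(nc) - 0.5) * sc / nc - 0.5, 0), sc - 1)
  r0 <- pmin(floor(ri), sr - 1); r1 <- pmin(r0 + 1, sr - 1); fr <- ri - r0
  c0 <- pmin(floor(ci), sc - 1); c1 <- pmin(c0 + 1, sc - 1); fc <- ci - c0
  a <- m[r0 + 1, c0 + 1, drop = FALSE] * outer(1 - fr, 1 - fc) +
       m[r1 + 1, c0 + 1, drop = FALSE] * outer(fr, 1 - fc) +
       m[r0 + 1, c1 + 1, drop = FALSE] * outer(1 - fr, fc) +
       m[r1 + 1, c1 + 1, drop = FALSE] * outer(fr, fc)
  a
}

#' Render a spectrogram matrix as an RGB image
#'
#' The dB matrix is min-max normalized to `[0, 1]` per image (a constant
#' matrix maps to all zeros, i.e. the colormap's value at 0), passed
#' through the colormap's 256-entry RGB lookup table, and resized to
#' `out_size x out_size` by bilinear interpolation on each channel.
#'
#' @param mat A `spectrogram_matrix` from [stft_spectrogram()], or a plain
#'   numeric matrix of dB values.
#' @param params A [spec_params()] (supplies colormap and output size).
#' @return A `spectrogram_image`: list with `pixels`
#'   (out_size x out_size x 3 array in `[0, 1]`), `lead`, `params`.
#' @export
spectrogram_to_image <- function(mat, params = spec_params()) {
  v <- if (inherits(mat, "spectrogram_matrix")) mat$values else mat
  stopifnot(is.matrix(v), all(is.finite(v)))
  rng <- range(v)
  u <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
       else matrix(0, nrow(v), ncol(v))
  lut <- colormap_lut(params$colormap)
  idx <- matrix(as.integer(round(u * 255)) + 1L, nrow(u))
  s <- params$out_size
  px <- array(0, c(s, s, 3))
  for (ch in 1:3) {
    chan <- matrix(lut[idx, ch], nrow(u))
    px[, , ch] <- bilinear_resize(chan, s, s)
  }
  px <- pmin(pmax(px, 0), 1)
  structure(list(pixels = px, lead = NA_character_, params = params),
            class = "spectrogram_image")
}

#' Convert a 12-lead record into its 12 spectrogram images
#'
#' One image per lead, in canonical lead order; the model's multi-input
#' front end consumes these (each at two patch scales).
#'
#' @param record An [ecg_record()].
#' @param params A [spec_params()].
#' @return Named list of 12 `spectrogram_image` objects, ordered I..V6.
#' @export
record_to_inputs <- function(record, params = spec_params()) {
  stopifnot(inherits(record, "ecg_record"))
  out <- lapply(ECG_LEADS, function(ld) {
    img <- spectrogram_to_image(stft_spectrogram(record$leads[[ld]], params),
                                params)
    img$lead <- ld
    img
  })
  names(out) <- ECG_LEADS
  out
}

#' Build the stacked image matrix for a set of records
#'
#' Flattens each lead image (row-major within channel; `out_size^2 * 3`
#' values per image) into one big numeric matrix, the input format the
#' ConvMixer trainer consumes.
#'
#' @param records List of [ecg_record()] objects.
#' @param params A [spec_params()].
#' @param verbose Log progress every 100 records.
#' @return List of class `ecg_image_set`: `images` is an
#'   `(n_records * 12) x (out_size^2 * 3)` matrix with lead varying
#'   fastest, `labels` a character vector, `record_ids`, `n`, `params`.
#' @export
records_to_image_set <- function(records, params = spec_params(),
                                 verbose = FALSE) {
  n <- length(records)
  d <- params$out_size^2 * 3
  images <- matrix(0, n * 12L, d)
  labels <- character(n); ids <- character(n)
  for (i in seq_len(n)) {
    imgs <- record_to_inputs(records[[i]], params)
    for (l in 1:12) images[(i - 1L) * 12L + l, ] <- as.numeric(imgs[[l]]$pixels)
    labels[i] <- records[[i]]$label
    ids[i] <- records[[i]]$record_id
    if (verbose && i %% 100 == 0) log_msg("spectrogram", i, "/", n, " records")
  }
  structure(list(images = images, labels = labels, record_ids = ids,
                 n = n, params = params),
            class = "ecg_image_set")
}
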