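# Shared fixtures, all generated in code at test time.

# a random (not physiological) valid 12-lead record
random_record <- function(n = 50, fs = 500, seed = 1, label = NA_character_) {
  set.seed(seed)
  leads <- setNames(lapply(1:12, function(i) round(rnorm(n), 6)), ECG_LEADS)
  ecg_record(leads, fs = fs, record_id = paste0("rnd", seed), label = label)
}

# random image matrix in the (n_records * 12) x (size^2 * 3) layout
random_images <- function(n, size = 16, seed = 1) {
  set.seed(seed)
  matrix(runif(n * 12 * size^2 * 3), n * 12L)
}

# small synthetic ECG spectrogram image set, built once per test run
shared_imgset <- local({
  cache <- NULL
  function(per_class = 6, duration = 5, seed = 99) {
    if (is.null(cache)) {
      cfg <- sim_config(per_class_counts = rep(per_class, 7),
                        duration = duration, seed = seed)
      ds <- generate_dataset(cfg, write = FALSE, keep = TRUE)
      cache <<- records_to_image_set(ds$records, spec_params())
    }
    cache
  }
})
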