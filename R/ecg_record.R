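#' Construct a 12-lead ECG record
#'
#' The canonical in-memory container for one 12-lead ECG. Leads are stored
#' in the canonical order ([ECG_LEADS]) regardless of input order, all in
#' millivolts.
#'
#' @param leads Named list of 12 equal-length numeric vectors (mV), named
#'   with the standard lead names in any order.
#' @param fs Sampling frequency in Hz. 500 and 1000 are the expected
#'   values; any other positive value is accepted with a warning.
#' @param record_id Identifier string.
#' @param label Optional occlusion class name (one of
#'   [OCCLUSION_CLASSES]) or `NA`.
#' @param meta Named list of free-form character metadata (e.g. age, sex).
#' @param check If `TRUE` (default), reject NaN/Inf samples.
#' @return An object of class `ecg_record`: a list with elements
#'   `record_id`, `fs`, `leads`, `label`, `meta`.
#' @export
ecg_record <- function(leads, fs, record_id = "record", label = NA_character_,
                       meta = list(), check = TRUE) {
  if (!is.list(leads)) stop("leads must be a named list")
  missing <- setdiff(ECG_LEADS, names(leads))
  if (length(missing))
    stop("missing-lead: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(leads), ECG_LEADS)
  if (length(extra))
    stop("unknown lead name(s): ", paste(extra, collapse = ", "))
  leads <- leads[ECG_LEADS]
  n <- vapply(leads, length, integer(1))
  if (length(unique(n)) != 1L)
    stop("length-mismatch: lead sample counts differ (",
         paste(sprintf("%s=%d", names(n), n), collapse = ", "), ")")
  if (n[1] < 1L) stop("length-mismatch: leads must have >= 1 sample")
  if (!is.numeric(fs) || length(fs) != 1L || is.na(fs) || fs <= 0)
    stop("bad-sampling-rate: fs must be a positive number")
  if (!fs %in% c(500, 1000))
    warning("fs = ", fs, " Hz is unusual; 500 Hz and 1 kHz are expected")
  if (check) {
    bad <- vapply(leads, function(x) any(!is.finite(x)), logical(1))
    if (any(bad))
      stop("nan-sample: non-finite samples in lead(s) ",
           paste(names(bad)[bad], collapse = ", "))
  }
  if (!is.na(label)) label <- match.arg(label, OCCLUSION_CLASSES)
  structure(list(record_id = as.character(record_id), fs = as.numeric(fs),
                 leads = lapply(leads, as.numeric),
                 label = label, meta = meta),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  n <- length(x$leads[[1]])
  cat(sprintf("<ecg_record '%s': 12 leads x %d samples @ %g Hz (%.1f s)%s>\n",
              x$record_id, n, x$fs, n / x$fs,
              if (is.na(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Screen an ECG record for signal-quality issues
#'
#' Automated stand-in for the manual exclusion of noisy records by
#' cardiologists: reports non-finite samples, leads that are flat
#' (constant) for more than half of their samples, and samples outside
#' a physiologically plausible +/- 25 mV range. An empty result means
#' "keep".
#'
#' @param record An [ecg_record()].
#' @param flat_frac Fraction of zero first-differences above which a lead
#'   is flagged flat (default 0.5).
#' @param amp_limit Absolute amplitude limit in mV (default 25).
#' @return A data.frame with columns `issue`, `lead`, `detail`
#'   (zero rows when the record is clean).
#' @export
validate_record <- function(record, flat_frac = 0.5, amp_limit = 25) {
  stopifnot(inherits(record, "ecg_record"))
  issues <- list()
  for (ld in ECG_LEADS) {
    x <- record$leads[[ld]]
    if (any(!is.finite(x)))
      issues[[length(issues) + 1L]] <- data.frame(
        issue = "nan-sample", lead = ld,
        detail = sprintf("%d non-finite samples", sum(!is.finite(x))))
    xf <- x[is.finite(x)]
    if (length(xf) > 1 && mean(diff(xf) == 0) > flat_frac)
      issues[[length(issues) + 1L]] <- data.frame(
        issue = "flat-lead", lead = ld,
        detail = sprintf("%.0f%% of samples unchanged",
                         100 * mean(diff(xf) == 0)))
    if (any(abs(xf) > amp_limit))
      issues[[length(issues) + 1L]] <- data.frame(
        issue = "amplitude", lead = ld,
        detail = sprintf("max |x| = %.1f mV", max(abs(xf))))
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(issue = character(), lead = character(),
                  detail = character())
}
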