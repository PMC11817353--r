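#' Read a 12-lead ECG record from disk
#'
#' Two plain-text dialects are supported (the vendor XML the original
#' recordings were stored in is proprietary and unpublished, so the
#' package defines its own):
#'
#' * **CSV**: header `time,I,II,...,V6` (the `time` column is optional and
#'   ignored on read); metadata (`fs`, `label`, `record_id`) in a JSON
#'   sidecar `<name>.meta.json` next to the file.
#' * **XML**: root `<ecg fs="500" label="RCA" id="...">` with one
#'   `<lead name="I" unit="mV">` element per lead containing
#'   whitespace-separated samples. A `unit="uV"` attribute is honoured by
#'   dividing by 1000; the in-memory unit is always millivolts.
#'
#' Lead order in the file is irrelevant; the returned record is always in
#' canonical order.
#'
#' @param path File path.
#' @param format `"csv"`, `"xml"`, or `"auto"` (by file extension).
#' @return An [ecg_record()].
#' @export
read_record <- function(path, format = c("auto", "csv", "xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "xml" else "csv"
  if (format == "csv") read_record_csv(path) else read_record_xml(path)
}

read_record_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- trimws(names(df))
  df <- df[, setdiff(names(df), "time"), drop = FALSE]
  missing <- setdiff(ECG_LEADS, names(df))
  if (length(missing))
    stop("missing-lead: ", paste(missing, collapse = ", "))
  sidecar <- paste0(sub("\\.csv$", "", path, ignore.case = TRUE), ".meta.json")
  fs <- 500; label <- NA_character_
  record_id <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  meta <- list()
  if (file.exists(sidecar)) {
    m <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(m$fs)) {
      fs <- suppressWarnings(as.numeric(m$fs))
      if (is.na(fs)) stop("bad-sampling-rate: fs = ", m$fs)
    }
    if (!is.null(m$label) && !is.na(m$label)) label <- as.character(m$label)
    if (!is.null(m$record_id)) record_id <- as.character(m$record_id)
    meta <- m[setdiff(names(m), c("fs", "label", "record_id"))]
  }
  ecg_record(as.list(df[ECG_LEADS]), fs = fs, record_id = record_id,
             label = label, meta = meta)
}

read_record_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "ecg") stop("root element must be <ecg>")
  fs <- suppressWarnings(as.numeric(xml2::xml_attr(doc, "fs")))
  if (is.na(fs)) stop("bad-sampling-rate: fs attribute missing or unparsable")
  label <- xml2::xml_attr(doc, "label")
  if (is.na(label) || label == "") label <- NA_character_
  record_id <- xml2::xml_attr(doc, "id")
  if (is.na(record_id)) record_id <- sub("\\.xml$", "", basename(path))
  nodes <- xml2::xml_find_all(doc, "./lead")
  leads <- list()
  for (nd in nodes) {
    nm <- xml2::xml_attr(nd, "name")
    x <- as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]])
    unit <- xml2::xml_attr(nd, "unit")
    if (!is.na(unit) && tolower(unit) %in% c("uv", "µv")) x <- x / 1000
    leads[[nm]] <- x
  }
  missing <- setdiff(ECG_LEADS, names(leads))
  if (length(missing))
    stop("missing-lead: ", paste(missing, collapse = ", "))
  ecg_record(leads, fs = fs, record_id = record_id, label = label)
}

#' Write a 12-lead ECG record to disk
#'
#' Inverse of [read_record()]; lossless to 9 significant digits. CSV
#' output includes a leading `time` column (seconds) and a
#' `<name>.meta.json` sidecar carrying `fs`, `label` and `record_id`.
#'
#' @param record An [ecg_record()].
#' @param path Output file path.
#' @param format `"csv"` or `"xml"`.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "xml")) {
  stopifnot(inherits(record, "ecg_record"))
  format <- match.arg(format)
  n <- length(record$leads[[1]])
  if (format == "csv") {
    df <- data.frame(time = signif((seq_len(n) - 1) / record$fs, 9))
    for (ld in ECG_LEADS) df[[ld]] <- signif(record$leads[[ld]], 9)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    sidecar <- paste0(sub("\\.csv$", "", path, ignore.case = TRUE),
                      ".meta.json")
    meta <- c(list(fs = record$fs, label = record$label,
                   record_id = record$record_id), record$meta)
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, null = "null",
                         na = "null", digits = NA)
  } else {
    root <- xml2::xml_new_root("ecg", fs = format(record$fs),
                               id = record$record_id)
    if (!is.na(record$label)) xml2::xml_set_attr(root, "label", record$label)
    for (ld in ECG_LEADS) {
      nd <- xml2::xml_add_child(root, "lead", name = ld, unit = "mV")
      xml2::xml_set_text(nd, paste(formatC(record$leads[[ld]], digits = 9,
                                           format = "g"), collapse = " "))
    }
    xml2::write_xml(root, path)
  }
  invisible(path)
}
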