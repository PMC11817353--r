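#' Assemble a full pipeline configuration
#'
#' Nested blocks mirror the module-level parameter objects; every default
#' equals the corresponding module default. Unknown keys are rejected by
#' [load_config()].
#'
#' @param generator Overrides for [sim_config()] fields.
#' @param spectrogram Overrides for [spec_params()] fields.
#' @param model Overrides for [convmixer_config()] fields.
#' @param train Overrides for [train_options()] fields.
#' @param relieff List with `k`, `sigma`.
#' @param wsse List with `k`, `vote`, `kernel`, `C`.
#' @param evaluation List with `folds`, `arms`, `q`.
#' @param seed Master seed; all stage seeds derive from it by
#'   stage-name hashing.
#' @param out_dir Output directory for artifacts (`NULL` = no files).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = list(), spectrogram = list(),
                            model = list(), train = list(),
                            relieff = list(), wsse = list(),
                            evaluation = list(), seed = 17L,
                            out_dir = NULL) {
  check_keys <- function(given, allowed, block) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("unknown key(s) in '", block, "': ", paste(bad, collapse = ", "))
    given
  }
  generator <- check_keys(generator, names(formals(sim_config)), "generator")
  spectrogram <- check_keys(spectrogram, names(formals(spec_params)),
                            "spectrogram")
  model <- check_keys(model, names(formals(convmixer_config)), "model")
  train <- check_keys(train, names(formals(train_options)), "train")
  relieff <- check_keys(relieff, c("k", "sigma"), "relieff")
  wsse <- check_keys(wsse, c("k", "vote", "kernel", "C"), "wsse")
  evaluation <- check_keys(evaluation, c("folds", "arms", "q"), "evaluation")
  ev <- utils::modifyList(list(folds = 10, arms = c("a", "b", "c", "d"),
                               q = 500), evaluation)
  if (ev$folds < 2) stop("evaluation$folds must be >= 2")
  rf <- utils::modifyList(list(k = 10, sigma = 20), relieff)
  ws <- utils::modifyList(list(k = 10, vote = "mass", kernel = "rbf", C = 1),
                          wsse)
  structure(list(generator = generator, spectrogram = spectrogram,
                 model = model, train = train, relieff = rf, wsse = ws,
                 evaluation = ev, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON or YAML
#'
#' Defaults are filled for any key not present; unknown keys raise a
#' validation error naming the key. An empty file yields the all-defaults
#' configuration. YAML requires the optional `yaml` package.
#'
#' @param path Path to a `.json`, `.yaml`/`.yml` file.
#' @return A validated [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::parse_json(txt,
                                                               simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  allowed <- c("generator", "spectrogram", "model", "train", "relieff",
               "wsse", "evaluation", "seed", "out_dir")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown key(s): ", paste(bad, collapse = ", "))
  args <- raw[intersect(names(raw), allowed)]
  do.call(pipeline_config, args)
}

#' Serialize the effective configuration
#'
#' Written alongside pipeline outputs so a run can be reproduced from its
#' echo (the echo is itself loadable by [load_config()]).
#'
#' @param config A [pipeline_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Simulate a labeled dataset, convert records to spectrogram image sets,
#' and run the four-arm cross-validated ablation
#' (train ConvMixer, extract fc features, ReliefF, SVM / WSSE). All
#' randomness derives from the single master seed by stage-name hashing.
#' When `out_dir` is set, the effective config, the dataset manifest, the
#' per-arm confusion matrices (CSV) and the report (JSON) are written
#' there.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress.
#' @param self_check If `TRUE`, additionally verify on the final fold
#'   features that a k = 1 ensemble reproduces the plain SVM (degenerate
#'   equivalence), and record the result in the report.
#' @return List of class `pipeline_report`: the ablation report, the
#'   manifest, timings, and the effective config.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE,
                         self_check = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- c()
  tick <- function(stage) {
    d <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    timings[stage] <<- d
    t0 <<- Sys.time()
    if (verbose) log_msg(stage, sprintf("done in %.1f s", d))
  }

  gen_args <- utils::modifyList(config$generator,
                                list(seed = derive_seed(config$seed, "simulate")))
  gcfg <- do.call(sim_config, gen_args)
  ds <- generate_dataset(gcfg, write = FALSE, keep = TRUE)
  tick("simulate")

  sp <- do.call(spec_params, config$spectrogram)
  imgset <- records_to_image_set(ds$records, sp, verbose = verbose)
  tick("spectrogram")

  mcfg <- do.call(convmixer_config,
                  utils::modifyList(list(input_size = sp$out_size),
                                    config$model))
  opts <- do.call(train_options, config$train)
  report <- run_ablation(imgset, arms = config$evaluation$arms,
                         folds = config$evaluation$folds, seed = config$seed,
                         model_config = mcfg, opts = opts,
                         relieff_k = config$relieff$k,
                         relieff_sigma = config$relieff$sigma,
                         q = config$evaluation$q, wsse_k = config$wsse$k,
                         kernel = config$wsse$kernel, C = config$wsse$C,
                         verbose = verbose)
  tick("evaluate")

  check <- NULL
  if (self_check) {
    plan <- report$fold_plan
    te <- plan$folds[[plan$k]]
    tr <- setdiff(seq_len(imgset$n), te)
    rows_of <- function(ix) as.vector(t(outer((ix - 1L) * 12L, 1:12, "+")))
    model <- convmixer_fit(mcfg, imgset$images[rows_of(tr), , drop = FALSE],
                           imgset$labels[tr], opts,
                           seed = derive_seed(config$seed, "selfcheck"))
    Ftr <- predict(model, imgset$images[rows_of(tr), , drop = FALSE],
                   type = "features")
    Fte <- predict(model, imgset$images[rows_of(te), , drop = FALSE],
                   type = "features")
    w <- relieff_weights(Ftr, imgset$labels[tr], k = config$relieff$k,
                         sigma = config$relieff$sigma)
    e1 <- predict(wsse_fit(Ftr, imgset$labels[tr], w, k = 1,
                           kernel = config$wsse$kernel, C = config$wsse$C,
                           classes = OCCLUSION_CLASSES), Fte)$labels
    e2 <- predict(svm_fit(Ftr, imgset$labels[tr], kernel = config$wsse$kernel,
                          C = config$wsse$C, classes = OCCLUSION_CLASSES), Fte)
    check <- list(k1_equals_svm = identical(e1, e2))
    tick("self_check")
  }

  out <- structure(list(report = report, manifest = ds$manifest,
                        timings = timings, config = config,
                        self_check = check),
                   class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(config$out_dir, "config_echo.json"))
    utils::write.csv(ds$manifest, file.path(config$out_dir, "manifest.csv"),
                     row.names = FALSE)
    for (a in names(report$arms))
      utils::write.csv(report$arms[[a]]$confusion,
                       file.path(config$out_dir,
                                 paste0("confusion_arm_", a, ".csv")))
    jsonlite::write_json(report_to_list(out),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# JSON-ready summary of a pipeline run (no model objects)
report_to_list <- function(x) {
  arms <- lapply(x$report$arms, function(a) list(
    accuracy = a$accuracy,
    confusion = unname(apply(a$confusion, 1, as.list)),
    metrics = a$metrics$per_class[, c("class", "sensitivity", "specificity",
                                      "precision", "f_score")]))
  list(seed = x$config$seed,
       n_records = nrow(x$manifest),
       folds = x$config$evaluation$folds,
       arms = arms,
       self_check = x$self_check,
       timings_sec = as.list(round(x$timings, 2)))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report: %d records, %d folds, seed %d>\n",
              nrow(x$manifest), x$config$evaluation$folds, x$config$seed))
  print(x$report)
  if (!is.null(x$self_check))
    cat(sprintf("  self-check k=1 == plain SVM: %s\n",
                x$self_check$k1_equals_svm))
  invisible(x)
}
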