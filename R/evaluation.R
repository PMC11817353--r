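#' Stratified k-fold plan
#'
#' Every class's members are shuffled (seeded) and dealt so that
#' per-class counts per fold differ by at most one; remainders go to the
#' currently least-loaded folds, so overall fold sizes also differ by at
#' most one. Folds are disjoint and cover all samples; the plan is a pure
#' function of `(labels, k, seed)`.
#'
#' @param labels Class labels, length n.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Object of class `fold_plan`: list with `k`, `folds` (list of
#'   index vectors), `seed`.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  labels <- as.character(labels)
  n <- length(labels)
  tab <- table(labels)
  if (any(tab < k))
    warning("class(es) with fewer than k members: ",
            paste(names(tab)[tab < k], collapse = ", "),
            "; some folds will miss them")
  local_seed(derive_seed(seed, "folds"))
  folds <- vector("list", k)
  load <- integer(k)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    base <- length(idx) %/% k
    r <- length(idx) %% k
    extra_folds <- order(load, seq_len(k))[seq_len(r)]
    sizes <- rep(base, k)
    sizes[extra_folds] <- sizes[extra_folds] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1) + 1L)
    for (f in seq_len(k)) {
      if (sizes[f] > 0)
        folds[[f]] <- c(folds[[f]], idx[starts[f]:ends[f]])
      load[f] <- load[f] + sizes[f]
    }
  }
  folds <- lapply(folds, sort)
  structure(list(k = as.integer(k), folds = folds, seed = as.integer(seed),
                 n = n), class = "fold_plan")
}

#' Confusion matrix over the seven occlusion classes
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Fixed class order (default [OCCLUSION_CLASSES]).
#' @return k x k integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = OCCLUSION_CLASSES) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(truth, classes), factor(predicted, classes))
  cm <- matrix(as.integer(tab), length(classes),
               dimnames = list(truth = classes, predicted = classes))
  cm
}

#' Per-class one-vs-rest metrics
#'
#' Collapses the confusion matrix to 2x2 per class and reports
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP), F-score = 2TP/(2TP+FP+FN), plus overall
#' accuracy = trace/total. Divisions 0/0 yield 0 and set the
#' `zero_division` flag.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return List of class `metrics_table`: `per_class` data.frame
#'   (class, tp, fp, fn, tn, sensitivity, specificity, precision,
#'   f_score), `accuracy`, `zero_division`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  classes <- rownames(cm)
  total <- sum(cm)
  zero_div <- FALSE
  safe_div <- function(a, b) {
    if (b == 0) { zero_div <<- TRUE; 0 } else a / b
  }
  rows <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    data.frame(class = classes[i], tp = tp, fp = fp, fn = fn, tn = tn,
               sensitivity = safe_div(tp, tp + fn),
               specificity = safe_div(tn, tn + fp),
               precision = safe_div(tp, tp + fp),
               f_score = safe_div(2 * tp, 2 * tp + fp + fn))
  })
  structure(list(per_class = do.call(rbind, rows),
                 accuracy = sum(diag(cm)) / total,
                 zero_division = zero_div),
            class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, digits = 4, ...) {
  df <- x$per_class
  df[, 6:9] <- round(df[, 6:9], digits)
  print(df, row.names = FALSE)
  cat(sprintf("accuracy: %.4f%s\n", x$accuracy,
              if (x$zero_division) " (zero-division metrics set to 0)" else ""))
  invisible(x)
}

#' Four-arm ablation under one cross-validation plan
#'
#' Runs the ablation ladder on a spectrogram image set with a single
#' stratified fold plan and master seed:
#'
#' * **a** — the end-to-end softmax ConvMixer;
#' * **b** — fc-embedding features into a single SVM;
#' * **c** — top-`q` ReliefF-selected features into an SVM;
#' * **d** — features into the weighted subspace SVM ensemble.
#'
#' ReliefF weights, the feature selection and every classifier are fitted
#' strictly inside each training fold; test folds are only ever scored.
#' Predictions are pooled over folds before computing confusion matrices
#' and metrics.
#'
#' @param image_set An `ecg_image_set` ([records_to_image_set()]).
#' @param arms Subset of `c("a","b","c","d")`.
#' @param folds Number of CV folds.
#' @param seed Master seed (folds, init, shuffling all derive from it).
#' @param model_config A [convmixer_config()].
#' @param opts A [train_options()].
#' @param relieff_k,relieff_sigma ReliefF parameters.
#' @param q Number of top-ranked features kept in arm c.
#' @param wsse_k Number of subspaces in arm d.
#' @param kernel,C SVM options for arms b-d.
#' @param plan Optional precomputed [stratified_kfold()] plan (must cover
#'   the image set); default builds one from `folds` and `seed`.
#' @param verbose Log fold progress.
#' @return List of class `ablation_report`: per arm a list with
#'   `confusion`, `metrics`, `accuracy`; plus `fold_plan`, `settings`.
#' @export
run_ablation <- function(image_set, arms = c("a", "b", "c", "d"),
                         folds = 10, seed = 17L,
                         model_config = convmixer_config(),
                         opts = train_options(),
                         relieff_k = 10, relieff_sigma = 20,
                         q = 500, wsse_k = 10, kernel = "rbf", C = 1,
                         plan = NULL, verbose = FALSE) {
  stopifnot(inherits(image_set, "ecg_image_set"))
  arms <- match.arg(arms, c("a", "b", "c", "d"), several.ok = TRUE)
  labels <- image_set$labels
  n <- image_set$n
  if (is.null(plan)) plan <- stratified_kfold(labels, folds, seed)
  stopifnot(inherits(plan, "fold_plan"), plan$n == n)
  pred <- lapply(arms, function(a) character(n))
  names(pred) <- arms
  need_feats <- any(arms %in% c("b", "c", "d"))

  for (f in seq_len(plan$k)) {
    te <- plan$folds[[f]]
    tr <- setdiff(seq_len(n), te)
    if (verbose) log_msg("ablation", sprintf("fold %d/%d: training model on %d records",
                                             f, plan$k, length(tr)))
    rows_of <- function(ix) as.vector(t(outer((ix - 1L) * 12L, 1:12, "+")))
    tr_imgs <- image_set$images[rows_of(tr), , drop = FALSE]
    model <- convmixer_fit(model_config, tr_imgs, labels[tr], opts,
                           seed = derive_seed(seed, paste0("fold", f)))
    if ("a" %in% arms)
      pred$a[te] <- predict(model, image_set$images[rows_of(te), , drop = FALSE],
                            type = "class")
    if (need_feats) {
      Ftr <- predict(model, tr_imgs, type = "features")
      Fte <- predict(model, image_set$images[rows_of(te), , drop = FALSE],
                     type = "features")
      if ("b" %in% arms) {
        m <- svm_fit(Ftr, labels[tr], kernel = kernel, C = C,
                     classes = OCCLUSION_CLASSES)
        pred$b[te] <- predict(m, Fte)
      }
      if (any(c("c", "d") %in% arms)) {
        w <- relieff_weights(Ftr, labels[tr], k = relieff_k,
                             sigma = relieff_sigma)
        if ("c" %in% arms) {
          keep <- rank_features(w)[seq_len(min(q, ncol(Ftr)))]
          keep <- sort(keep)
          m <- svm_fit(Ftr[, keep, drop = FALSE], labels[tr],
                       kernel = kernel, C = C, classes = OCCLUSION_CLASSES)
          pred$c[te] <- predict(m, Fte[, keep, drop = FALSE])
        }
        if ("d" %in% arms) {
          m <- wsse_fit(Ftr, labels[tr], w, k = wsse_k, kernel = kernel,
                        C = C, classes = OCCLUSION_CLASSES)
          pred$d[te] <- predict(m, Fte)$labels
        }
      }
    }
  }

  out <- lapply(arms, function(a) {
    cm <- confusion_matrix(labels, pred[[a]])
    mt <- per_class_metrics(cm)
    list(confusion = cm, metrics = mt, accuracy = mt$accuracy,
         predicted = pred[[a]])
  })
  names(out) <- arms
  structure(list(arms = out, fold_plan = plan,
                 settings = list(folds = folds, seed = seed, q = q,
                                 wsse_k = wsse_k, kernel = kernel, C = C,
                                 relieff_k = relieff_k,
                                 relieff_sigma = relieff_sigma)),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("<ablation_report>\n")
  for (a in names(x$arms))
    cat(sprintf("  arm %s: accuracy %.4f\n", a, x$arms[[a]]$accuracy))
  invisible(x)
}
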