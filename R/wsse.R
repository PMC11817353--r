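#' Partition ranked features into subspaces
#'
#' Features sorted by descending importance weight are split into `k`
#' contiguous blocks; the first block holds the highest-ranked features.
#' Block sizes are `ceiling(p/k)` or `floor(p/k)` with the larger blocks
#' first. Each subspace's vote mass is the sum of its features' weights,
#' floored at 0; with sorted weights and larger-first blocks the masses
#' are non-increasing.
#'
#' @param weights A `relieff_weights` object or numeric vector.
#' @param k Number of subspaces (1 to p).
#' @return Object of class `subspace_partition`: list with `k`,
#'   `subspaces` (list of 1-based feature-index vectors in rank order)
#'   and `vote_mass`.
#' @export
partition_subspaces <- function(weights, k) {
  w <- if (inherits(weights, "relieff_weights")) weights$weights else weights
  p <- length(w)
  if (k > p) stop("too-many-subspaces: k = ", k, " > p = ", p)
  stopifnot(k >= 1)
  ranked <- rank_features(w)
  r <- p %% k
  sizes <- c(rep(ceiling(p / k), r), rep(floor(p / k), k - r))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  subspaces <- lapply(seq_len(k), function(i) ranked[starts[i]:ends[i]])
  mass <- vapply(subspaces, function(ix) max(0, sum(w[ix])), numeric(1))
  structure(list(k = as.integer(k), subspaces = subspaces,
                 vote_mass = mass, weights = w),
            class = "subspace_partition")
}

#' Fit a weighted subspace SVM ensemble (WSSE)
#'
#' ReliefF-ranked features are partitioned into `k` subspaces
#' ([partition_subspaces()]); one multi-class SVM is trained per subspace
#' on that subspace's columns only; predictions are combined by
#' importance-weighted majority voting ([predict.wsse()]).
#'
#' Two vote-weighting readings are provided: the default continuous rule
#' gives subspace i a vote mass equal to the (floored) sum of its
#' features' ReliefF weights; `vote = "replicate"` instead casts
#' `k - i + 1` integer votes for subspace i (highest-importance subspace
#' votes most often).
#'
#' @param X n x p training feature matrix.
#' @param y Class labels.
#' @param weights ReliefF weights ([relieff_weights()]) or numeric vector,
#'   or a ready-made `subspace_partition`.
#' @param k Number of subspaces (default 10; ignored when a partition is
#'   passed).
#' @param vote `"mass"` (continuous, default) or `"replicate"`.
#' @param kernel,C,gamma,tol,max_iter Passed to [svm_fit()]. Within each
#'   subspace the columns are used in ascending original index order, so
#'   a `k = 1` ensemble is arithmetically identical to a single SVM on
#'   all features.
#' @param classes Optional fixed class order.
#' @return Object of class `wsse`: the partition, the `k` fitted
#'   classifiers, and the voting configuration.
#' @export
wsse_fit <- function(X, y, weights, k = 10, vote = c("mass", "replicate"),
                     kernel = "rbf", C = 1, gamma = "scale", tol = 1e-3,
                     max_iter = 200000L, classes = NULL) {
  vote <- match.arg(vote)
  X <- as.matrix(X)
  partition <- if (inherits(weights, "subspace_partition")) weights
  else partition_subspaces(weights, k)
  if (max(unlist(partition$subspaces)) > ncol(X))
    stop("partition references feature index beyond ncol(X)")
  if (is.null(classes)) classes <- sort(unique(as.character(y)))
  models <- lapply(partition$subspaces, function(ix) {
    cols <- sort(ix)        # column order must not matter; fix it for
    fit <- svm_fit(X[, cols, drop = FALSE], y, kernel = kernel, C = C,
                   gamma = gamma, tol = tol, max_iter = max_iter,
                   classes = classes)   # bitwise reproducibility
    list(cols = cols, fit = fit)
  })
  mass <- switch(vote,
                 mass = partition$vote_mass,
                 replicate = as.numeric(rev(seq_len(partition$k))))
  structure(list(partition = partition, models = models, vote = vote,
                 vote_mass = mass, classes = classes, p = ncol(X)),
            class = "wsse")
}

#' @export
print.wsse <- function(x, ...) {
  cat(sprintf("<wsse: %d subspaces of %s features, %s voting (mass %s), %s kernel>\n",
              x$partition$k,
              paste(range(lengths(x$partition$subspaces)), collapse = "-"),
              x$vote, paste(signif(x$vote_mass, 3), collapse = "/"),
              x$models[[1]]$fit$kernel))
  invisible(x)
}

#' Predict with a WSSE model
#'
#' Each subspace's SVM casts its predicted label with the subspace's vote
#' mass; the final label is the class with the largest total mass. Ties
#' are broken in favour of the label predicted by the lowest-index
#' (highest-importance) subspace among the tied classes. The per-sample
#' prediction matrix `M` and voting matrix `V` are returned for
#' inspection.
#'
#' @param object A `wsse` model.
#' @param newdata m x p feature matrix (same p as training).
#' @param ... Unused.
#' @return List of class `wsse_prediction`: `labels` (length m),
#'   `votes` (m x n_classes mass matrix `V`), `predictions`
#'   (m x k label matrix `M`).
#' @export
predict.wsse <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("feature-count mismatch: model expects ", object$p, " features")
  m <- nrow(newdata)
  k <- object$partition$k
  M <- matrix(NA_character_, m, k)
  for (i in seq_len(k)) {
    mod <- object$models[[i]]
    M[, i] <- predict(mod$fit, newdata[, mod$cols, drop = FALSE])
  }
  v <- wsse_vote(M, object$vote_mass, object$classes)
  structure(list(labels = v$labels, votes = v$votes, predictions = M),
            class = "wsse_prediction")
}

# weighted majority vote: subspace i casts its predicted label with mass
# vote_mass[i]; argmax over classes, ties resolved by the label of the
# earliest (highest-mass) subspace among the tied classes
wsse_vote <- function(M, vote_mass, classes) {
  m <- nrow(M); k <- ncol(M)
  V <- matrix(0, m, length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(k)) {
    for (cl in classes) {
      hit <- M[, i] == cl
      V[hit, cl] <- V[hit, cl] + vote_mass[i]
    }
  }
  labels <- character(m)
  for (r in seq_len(m)) {
    top <- which(V[r, ] == max(V[r, ]))
    if (length(top) == 1L) labels[r] <- classes[top]
    else {
      tied <- classes[top]
      first <- which(M[r, ] %in% tied)[1]
      labels[r] <- M[r, first]
    }
  }
  list(labels = labels, votes = V)
}

#' @export
print.wsse_prediction <- function(x, ...) {
  cat(sprintf("<wsse_prediction: %d samples; label counts: %s>\n",
              length(x$labels),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
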