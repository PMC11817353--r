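#' Fit a multi-class support vector machine
#'
#' A from-scratch C-SVC (no SVM package ships with the supported
#' environment): binary subproblems are solved by sequential minimal
#' optimization with maximal-violating-pair working-set selection, and
#' multi-class problems use one-vs-one voting (ties go to the earlier
#' class in the supplied class order). Deterministic for fixed inputs.
#'
#' @param X n x p numeric feature matrix.
#' @param y Class labels, length n.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C Box constraint (default 1).
#' @param gamma RBF width; default `"scale"` = `1 / (p * var(X))` with
#'   `var` the variance of all (standardized) matrix entries.
#' @param scale Standardize columns to zero mean / unit variance using
#'   training statistics (the convention of the classic SVM interfaces);
#'   constant columns are left untouched. Default `TRUE`.
#' @param tol SMO stopping tolerance.
#' @param max_iter SMO iteration cap per binary problem.
#' @param classes Optional fixed class order (default: sorted unique `y`).
#' @return Object of class `svm_model`.
#' @export
svm_fit <- function(X, y, kernel = c("rbf", "linear"), C = 1,
                    gamma = "scale", scale = TRUE, tol = 1e-3,
                    max_iter = 200000L, classes = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), C > 0)
  if (is.null(classes)) classes <- sort(unique(y))
  stopifnot(all(y %in% classes))
  if (length(unique(y)) < 2) stop("degenerate-labels: need >= 2 classes")
  center <- scl <- NULL
  if (scale) {
    center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scl, "/")
  }
  if (identical(gamma, "scale")) {
    v <- stats::var(as.numeric(X))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1
  }
  K <- kernel_matrix(X, X, kernel, gamma)
  present <- classes[classes %in% y]
  pairs <- utils::combn(present, 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    sel <- which(y %in% pr)
    ys <- ifelse(y[sel] == pr[1], 1L, -1L)
    sol <- smo_solve(K[sel, sel, drop = FALSE], as.integer(ys), C, tol,
                     as.integer(max_iter))
    sv <- which(abs(sol$alpha) > 1e-12)
    list(pair = pr, idx = sel[sv], coef = sol$alpha[sv] * ys[sv],
         rho = sol$rho)
  })
  structure(list(X = X, kernel = kernel, gamma = gamma, C = C,
                 center = center, scale = scl,
                 classes = classes, fits = fits),
            class = "svm_model")
}

kernel_matrix <- function(A, B, kernel, gamma) {
  if (kernel == "linear") return(A %*% t(B))
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

#' @export
print.svm_model <- function(x, ...) {
  nsv <- length(unique(unlist(lapply(x$fits, `[[`, "idx"))))
  cat(sprintf("<svm_model: %s kernel (gamma %.3g), C=%g, %d classes, %d support vectors>\n",
              x$kernel, x$gamma, x$C, length(x$classes), nsv))
  invisible(x)
}

#' Predict with a fitted SVM
#'
#' @param object An `svm_model`.
#' @param newdata m x p numeric matrix.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X))
    stop("feature-count mismatch: model has ", ncol(object$X),
         " features, newdata has ", ncol(newdata))
  if (!is.null(object$center))
    newdata <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  m <- nrow(newdata)
  votes <- matrix(0L, m, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (f in object$fits) {
    Kt <- kernel_matrix(newdata, object$X[f$idx, , drop = FALSE],
                        object$kernel, object$gamma)
    dec <- as.numeric(Kt %*% f$coef) - f$rho
    win <- ifelse(dec >= 0, f$pair[1], f$pair[2])
    for (cl in f$pair) votes[win == cl, cl] <- votes[win == cl, cl] + 1L
  }
  object$classes[max.col(votes, ties.method = "first")]
}
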