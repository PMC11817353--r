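#' ReliefF feature importance weights
#'
#' Classical multi-class ReliefF with exponential distance-rank decay:
#' every sample is used as an anchor (m = n); for each anchor its
#' `k` nearest hits (same class) and, for every other class, `k` nearest
#' misses are found by Manhattan distance on range-normalized features.
#' Neighbor at rank j carries weight `exp(-(j/sigma)^2)`, normalized to
#' sum to one over the neighbors used. Hit differences decrease a
#' feature's weight, miss differences increase it with the prior
#' coefficient `P(C) / (1 - P(class(anchor)))`; all differences are
#' `|a_f - b_f| / range_f`. Classes with fewer than `k + 1` members use
#' all available neighbors; constant features get weight exactly 0.
#'
#' @param X n x p numeric feature matrix.
#' @param y Class labels (length n, at least 2 classes).
#' @param k Number of nearest hits/misses per anchor (default 10).
#' @param sigma Distance-rank decay parameter (default 20).
#' @return Object of class `relieff_weights`: list with `weights`
#'   (length-p vector), `summary` (max/min/mean), `k`, `sigma`.
#' @export
relieff_weights <- function(X, y, k = 10, sigma = 20) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 2, k >= 1, sigma > 0)
  y <- as.character(y)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (length(unique(y)) < 2) stop("degenerate-labels: need >= 2 classes")
  if (p == 0)
    return(structure(list(weights = numeric(0),
                          summary = c(max = NA, min = NA, mean = NA),
                          k = k, sigma = sigma), class = "relieff_weights"))
  rng <- apply(X, 2, max) - apply(X, 2, min)
  live <- rng > 0
  Xn <- X[, live, drop = FALSE] /
    rep(rng[live], each = n)             # range-normalized
  # Manhattan distances on normalized live features
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  classes <- sort(unique(y))
  prior <- table(factor(y, classes)) / n
  W <- numeric(sum(live))
  rank_w <- function(m) {
    d <- exp(-(seq_len(m) / sigma)^2)
    d / sum(d)
  }
  for (i in seq_len(n)) {
    ci <- y[i]
    # hits
    hit_pool <- which(y == ci & seq_len(n) != i)
    if (length(hit_pool)) {
      ord <- hit_pool[order(D[i, hit_pool], hit_pool)]
      hits <- ord[seq_len(min(k, length(ord)))]
      dw <- rank_w(length(hits))
      diffs <- abs(Xn[rep(i, length(hits)), , drop = FALSE] -
                   Xn[hits, , drop = FALSE])
      W <- W - colSums(diffs * dw) / n
    }
    # misses, per other class
    for (cl in classes[classes != ci]) {
      pool <- which(y == cl)
      ord <- pool[order(D[i, pool], pool)]
      miss <- ord[seq_len(min(k, length(ord)))]
      dw <- rank_w(length(miss))
      coef <- as.numeric(prior[cl]) / (1 - as.numeric(prior[ci]))
      diffs <- abs(Xn[rep(i, length(miss)), , drop = FALSE] -
                   Xn[miss, , drop = FALSE])
      W <- W + coef * colSums(diffs * dw) / n
    }
  }
  weights <- numeric(p)
  weights[live] <- W
  structure(list(weights = weights,
                 summary = c(max = max(weights), min = min(weights),
                             mean = mean(weights)),
                 k = k, sigma = sigma),
            class = "relieff_weights")
}

#' @export
print.relieff_weights <- function(x, ...) {
  cat(sprintf("<relieff_weights: %d features, k=%d sigma=%g; max %.4f min %.4f mean %.4f>\n",
              length(x$weights), x$k, x$sigma,
              x$summary["max"], x$summary["min"], x$summary["mean"]))
  invisible(x)
}

#' Rank features by descending importance weight
#'
#' Stable: ties are broken by ascending original feature index.
#'
#' @param weights A `relieff_weights` object or plain numeric vector.
#' @return Integer vector of 1-based feature indices, best first.
#' @export
rank_features <- function(weights) {
  w <- if (inherits(weights, "relieff_weights")) weights$weights else weights
  stopifnot(all(is.finite(w)))
  order(-w, seq_along(w))
}
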