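# Independent brute-force oracles, deliberately literal implementations.

# ReliefF by the book: nested loops over anchors, hits, misses.
relieff_oracle <- function(X, y, k, sigma) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  y <- as.character(y)
  rng <- apply(X, 2, function(col) max(col) - min(col))
  W <- numeric(p)
  classes <- sort(unique(y))
  prior <- sapply(classes, function(cl) mean(y == cl))
  names(prior) <- classes
  dist1 <- function(a, b) {
    s <- 0
    for (f in 1:p) if (rng[f] > 0) s <- s + abs(X[a, f] - X[b, f]) / rng[f]
    s
  }
  diff1 <- function(f, a, b) {
    if (rng[f] == 0) 0 else abs(X[a, f] - X[b, f]) / rng[f]
  }
  for (i in 1:n) {
    d <- sapply(1:n, function(j) dist1(i, j))
    for (cl in classes) {
      pool <- setdiff(which(y == cl), i)
      if (!length(pool)) next
      pool <- pool[order(d[pool], pool)]
      nb <- pool[1:min(k, length(pool))]
      dw <- exp(-(seq_along(nb) / sigma)^2)
      dw <- dw / sum(dw)
      if (cl == y[i]) {
        for (j in seq_along(nb)) for (f in 1:p)
          W[f] <- W[f] - dw[j] * diff1(f, i, nb[j]) / n
      } else {
        coef <- prior[cl] / (1 - prior[y[i]])
        for (j in seq_along(nb)) for (f in 1:p)
          W[f] <- W[f] + coef * dw[j] * diff1(f, i, nb[j]) / n
      }
    }
  }
  unname(W)
}

# one STFT frame by direct DFT summation
dft_frame_oracle <- function(segment, nfft) {
  L <- length(segment)
  w <- if (L == 1) 1 else 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  xw <- segment * w
  nb <- nfft %/% 2 + 1
  mag <- numeric(nb)
  for (b in 0:(nb - 1)) {
    re <- sum(xw * cos(-2 * pi * b * (0:(L - 1)) / nfft))
    im <- sum(xw * sin(-2 * pi * b * (0:(L - 1)) / nfft))
    mag[b + 1] <- sqrt(re^2 + im^2)
  }
  20 * log10(mag + 1e-12)
}

# confusion matrix by nested loops
confusion_oracle <- function(truth, pred, classes) {
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(truth = classes, predicted = classes))
  for (i in seq_along(truth))
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  cm
}

# one-vs-rest metrics by hand from a confusion matrix
metrics_oracle <- function(cm) {
  total <- sum(cm)
  t(sapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp; fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
      specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
      precision = if (tp + fp > 0) tp / (tp + fp) else 0,
      f_score = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
  }))
}
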