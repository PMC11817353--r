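#' MI-MS ConvMixer architecture configuration
#'
#' One branch per (lead, patch scale) pair: the 12 lead images are fed to
#' one branch set per patch size, 24 branches at the defaults. Each branch
#' is a ConvMixer: patch embedding (stride-P convolution), GeLU, BatchNorm,
#' then `depth` mixer blocks of a depthwise KxK convolution with residual
#' connection followed by a pointwise HxH channel-mixing convolution
#' (GeLU + BatchNorm after both, in the printed order BatchNorm(GeLU(.))),
#' then global average pooling to H values. Branch outputs are
#' concatenated and fed through a 1000-wide fully connected embedding
#' layer (`fc_embed`, the feature layer) and a softmax output over the 7
#' classes.
#'
#' The reference hidden width is 750; the default here is 32 so that the
#' model trains at desk scale (the 750-channel model is available by
#' setting `hidden = 750`).
#'
#' @param input_size Image side in pixels; must be divisible by every
#'   patch size.
#' @param patch_sizes Integer vector of patch scales.
#' @param hidden Channels per branch (H).
#' @param kernel Depthwise kernel size (odd).
#' @param depth Mixer blocks per branch (D).
#' @param n_leads Number of input leads (12).
#' @param n_classes Number of output classes (7).
#' @param embed_dim Width of the fully connected embedding layer.
#' @return A list of class `convmixer_config`.
#' @export
convmixer_config <- function(input_size = 64, patch_sizes = c(16, 8),
                             hidden = 32, kernel = 3, depth = 4,
                             n_leads = 12, n_classes = 7, embed_dim = 1000) {
  stopifnot(hidden >= 1, depth >= 1, embed_dim >= 1, kernel %% 2 == 1)
  if (any(input_size %% patch_sizes != 0))
    stop("input_size (", input_size, ") must be divisible by every patch size")
  structure(list(input_size = as.integer(input_size),
                 patch_sizes = as.integer(patch_sizes),
                 hidden = as.integer(hidden), kernel = as.integer(kernel),
                 depth = as.integer(depth), n_leads = as.integer(n_leads),
                 n_classes = as.integer(n_classes),
                 embed_dim = as.integer(embed_dim),
                 n_scales = length(patch_sizes),
                 n_branches = as.integer(n_leads * length(patch_sizes))),
            class = "convmixer_config")
}

#' SGDM training options
#'
#' Defaults follow the reference training recipe: 100 epochs, mini-batch
#' 128, initial learning rate 0.001, SGD with momentum 0.9, validation
#' every 30 iterations on a 10% held-out slice of the training set.
#'
#' @param epochs,minibatch,lr,momentum,validation_fraction,val_freq
#'   Standard knobs, see description.
#' @param verbose Log per-epoch progress.
#' @return A list of class `train_options`.
#' @export
train_options <- function(epochs = 100, minibatch = 128, lr = 0.001,
                          momentum = 0.9, validation_fraction = 0.1,
                          val_freq = 30, verbose = FALSE) {
  stopifnot(epochs >= 1, minibatch >= 1, lr >= 0, momentum >= 0,
            momentum < 1, validation_fraction >= 0, validation_fraction < 1,
            val_freq >= 1)
  structure(list(epochs = as.integer(epochs), minibatch = as.integer(minibatch),
                 lr = lr, momentum = momentum,
                 validation_fraction = validation_fraction,
                 val_freq = as.integer(val_freq), verbose = verbose),
            class = "train_options")
}

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

add_bias <- function(A, b) A + rep(b, each = nrow(A))

# ---- geometry -------------------------------------------------------------

# im2col column indices for non-overlapping PxP patches of an SxSx3 image
# flattened in R array order (row fastest, then column, then channel).
patch_indices <- function(S, P) {
  g <- S %/% P
  np <- g * g
  pdim <- P * P * 3
  idx <- matrix(0L, pdim, np)
  for (pc in seq_len(g)) for (pr in seq_len(g)) {
    pi <- pr + (pc - 1L) * g
    rows <- (pr - 1L) * P + seq_len(P)
    cols <- (pc - 1L) * P + seq_len(P)
    flat <- integer(0)
    for (ch in 0:2) for (cl in cols)
      flat <- c(flat, rows + (cl - 1L) * S + ch * S * S)
    idx[, pi] <- flat
  }
  idx
}

# source position maps for a KxK depthwise convolution on a g x g grid
# (correlation convention, zero padding): one integer vector per offset,
# NA marking out-of-bounds.
shift_maps <- function(g, K) {
  half <- (K - 1L) %/% 2L
  maps <- list()
  o <- 0L
  for (dc in -half:half) for (dr in -half:half) {
    o <- o + 1L
    src <- integer(g * g)
    for (c in seq_len(g)) for (r in seq_len(g)) {
      rs <- r + dr; cs <- c + dc
      src[r + (c - 1L) * g] <-
        if (rs >= 1 && rs <= g && cs >= 1 && cs <= g) rs + (cs - 1L) * g
        else NA_integer_
    }
    maps[[o]] <- src
  }
  maps
}

branch_geometry <- function(config) {
  lapply(config$patch_sizes, function(P) {
    g <- config$input_size %/% P
    list(P = P, g = g, np = g * g, pdim = P * P * 3,
         patch_idx = patch_indices(config$input_size, P),
         shifts = shift_maps(g, config$kernel))
  })
}

# ---- parameters -----------------------------------------------------------

bn_new <- function(H) list(gamma = rep(1, H), beta = rep(0, H))
bn_rs_new <- function(H) list(mean = rep(0, H), var = rep(1, H))

init_params <- function(config, seed) {
  local_seed(seed)
  H <- config$hidden; K2 <- config$kernel^2
  branches <- list()
  for (s in seq_len(config$n_scales)) {
    P <- config$patch_sizes[s]; pdim <- P * P * 3
    for (l in seq_len(config$n_leads)) {
      blocks <- lapply(seq_len(config$depth), function(d) list(
        wdw = matrix(rnorm(K2 * H, sd = sqrt(2 / K2)), K2, H),
        bdw = rep(0, H), bn1 = bn_new(H),
        Wpw = matrix(rnorm(H * H, sd = sqrt(2 / H)), H, H),
        bpw = rep(0, H), bn2 = bn_new(H)))
      branches[[length(branches) + 1L]] <- list(
        Wp = matrix(rnorm(pdim * H, sd = sqrt(2 / pdim)), pdim, H),
        bp = rep(0, H), bn0 = bn_new(H), blocks = blocks)
    }
  }
  Fdim <- config$n_branches * H
  list(branches = branches,
       We = matrix(rnorm(Fdim * config$embed_dim, sd = sqrt(2 / Fdim)),
                   Fdim, config$embed_dim),
       be = rep(0, config$embed_dim),
       Wo = matrix(rnorm(config$embed_dim * config$n_classes,
                         sd = sqrt(2 / config$embed_dim)),
                   config$embed_dim, config$n_classes),
       bo = rep(0, config$n_classes))
}

init_run_stats <- function(config) {
  H <- config$hidden
  lapply(seq_len(config$n_branches), function(b) list(
    bn0 = bn_rs_new(H),
    blocks = lapply(seq_len(config$depth), function(d)
      list(bn1 = bn_rs_new(H), bn2 = bn_rs_new(H)))))
}

# ---- batch norm -----------------------------------------------------------

BN_EPS <- 1e-5
BN_MOM <- 0.1

bn_forward <- function(X, par, rs, training) {
  N <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = N)
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * rep(istd, each = N)
    rs$mean <- (1 - BN_MOM) * rs$mean + BN_MOM * mu
    rs$var <- (1 - BN_MOM) * rs$var + BN_MOM * v
    Y <- xhat * rep(par$gamma, each = N) + rep(par$beta, each = N)
    list(Y = Y, cache = list(xhat = xhat, istd = istd, gamma = par$gamma),
         rs = rs)
  } else {
    istd <- 1 / sqrt(rs$var + BN_EPS)
    xhat <- (X - rep(rs$mean, each = N)) * rep(istd, each = N)
    Y <- xhat * rep(par$gamma, each = N) + rep(par$beta, each = N)
    list(Y = Y, cache = NULL, rs = rs)
  }
}

bn_backward <- function(dY, cache) {
  N <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(cache$gamma, each = N)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dX <- (dxhat - rep(m1, each = N) - xhat * rep(m2, each = N)) *
    rep(cache$istd, each = N)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- depthwise convolution ------------------------------------------------

dw_rows <- function(shifts, np, B) {
  lapply(shifts, function(src) {
    vp <- which(!is.na(src))
    off <- rep((0:(B - 1)) * np, each = length(vp))
    list(dst = off + vp, src = off + src[vp])
  })
}

dw_forward <- function(A, wdw, bdw, rows) {
  Z <- matrix(0, nrow(A), ncol(A))
  for (o in seq_along(rows)) {
    r <- rows[[o]]
    Z[r$dst, ] <- Z[r$dst, ] + A[r$src, ] * rep(wdw[o, ], each = length(r$dst))
  }
  add_bias(Z, bdw)
}

dw_backward <- function(dZ, A, wdw, rows) {
  dA <- matrix(0, nrow(A), ncol(A))
  dw <- matrix(0, nrow(wdw), ncol(wdw))
  for (o in seq_along(rows)) {
    r <- rows[[o]]
    dZo <- dZ[r$dst, , drop = FALSE]
    dA[r$src, ] <- dA[r$src, ] + dZo * rep(wdw[o, ], each = length(r$src))
    dw[o, ] <- colSums(A[r$src, , drop = FALSE] * dZo)
  }
  list(dA = dA, dw = dw, db = colSums(dZ))
}

# ---- branch forward / backward -------------------------------------------

branch_forward <- function(Xc, prm, rs, geom, B, training, keep_cache = TRUE,
                           debug = FALSE) {
  np <- geom$np
  rows <- dw_rows(geom$shifts, np, B)
  cache <- list(Xc = if (keep_cache) Xc else NULL, rows = rows, blocks = list())
  A0 <- add_bias(Xc %*% prm$Wp, prm$bp)
  G0 <- gelu(A0)
  bn <- bn_forward(G0, prm$bn0, rs$bn0, training)
  rs$bn0 <- bn$rs
  A <- bn$Y
  cache$A0 <- if (keep_cache) A0 else NULL
  cache$bn0 <- bn$cache
  dbg <- list()
  for (d in seq_along(prm$blocks)) {
    blk <- prm$blocks[[d]]
    Ain <- A
    Z <- dw_forward(Ain, blk$wdw, blk$bdw, rows)
    Gz <- gelu(Z)
    b1 <- bn_forward(Gz, blk$bn1, rs$blocks[[d]]$bn1, training)
    rs$blocks[[d]]$bn1 <- b1$rs
    U <- b1$Y + Ain                      # residual connection
    V <- add_bias(U %*% blk$Wpw, blk$bpw)
    Gv <- gelu(V)
    b2 <- bn_forward(Gv, blk$bn2, rs$blocks[[d]]$bn2, training)
    rs$blocks[[d]]$bn2 <- b2$rs
    A <- b2$Y
    if (keep_cache)
      cache$blocks[[d]] <- list(Ain = Ain, Z = Z, bn1 = b1$cache, U = U,
                                V = V, bn2 = b2$cache)
    if (debug) dbg[[d]] <- list(Ain = Ain, U = U)
  }
  grp <- rep(seq_len(B), each = np)
  gap <- rowsum(A, grp) / np
  cache$Afinal_nrow <- nrow(A)
  list(gap = gap, cache = cache, rs = rs, debug = dbg)
}

branch_backward <- function(dgap, prm, cache, geom, B) {
  np <- geom$np
  dA <- dgap[rep(seq_len(B), each = np), , drop = FALSE] / np
  g <- list(blocks = list())
  for (d in rev(seq_along(prm$blocks))) {
    blk <- prm$blocks[[d]]
    cb <- cache$blocks[[d]]
    b2 <- bn_backward(dA, cb$bn2)
    dV <- b2$dX * gelu_grad(cb$V)
    dWpw <- crossprod(cb$U, dV)
    dbpw <- colSums(dV)
    dU <- dV %*% t(blk$Wpw)
    b1 <- bn_backward(dU, cb$bn1)
    dZ <- b1$dX * gelu_grad(cb$Z)
    dwb <- dw_backward(dZ, cb$Ain, blk$wdw, cache$rows)
    dA <- dwb$dA + dU                    # residual path
    g$blocks[[d]] <- list(wdw = dwb$dw, bdw = dwb$db,
                          bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                          Wpw = dWpw, bpw = dbpw,
                          bn2 = list(gamma = b2$dgamma, beta = b2$dbeta))
  }
  b0 <- bn_backward(dA, cache$bn0)
  dA0 <- b0$dX * gelu_grad(cache$A0)
  g$Wp <- crossprod(cache$Xc, dA0)
  g$bp <- colSums(dA0)
  g$bn0 <- list(gamma = b0$dgamma, beta = b0$dbeta)
  g
}

# im2col for a batch: image rows of `images` for (record, lead), columns
# gathered per patch. Row layout of the result is sample-major.
batch_im2col <- function(images, rec_idx, lead, geom) {
  B <- length(rec_idx)
  rows <- (rec_idx - 1L) * 12L + lead
  Xc <- matrix(0, B * geom$np, geom$pdim)
  for (pi in seq_len(geom$np))
    Xc[(0:(B - 1)) * geom$np + pi, ] <-
      images[rows, geom$patch_idx[, pi], drop = FALSE]
  Xc
}

# full forward pass; returns probs, embedding, per-branch caches
model_forward <- function(model, images, rec_idx, training = FALSE,
                          keep_cache = FALSE, debug = FALSE) {
  config <- model$config
  B <- length(rec_idx)
  H <- config$hidden
  Cmat <- matrix(0, B, config$n_branches * H)
  caches <- if (keep_cache) vector("list", config$n_branches) else NULL
  dbg <- if (debug) vector("list", config$n_branches) else NULL
  b <- 0L
  for (s in seq_len(config$n_scales)) {
    geom <- model$geometry[[s]]
    for (l in seq_len(config$n_leads)) {
      b <- b + 1L
      Xc <- batch_im2col(images, rec_idx, l, geom)
      fw <- branch_forward(Xc, model$theta$branches[[b]],
                           model$run_stats[[b]], geom, B, training,
                           keep_cache = keep_cache, debug = debug)
      if (training) model$run_stats[[b]] <- fw$rs
      Cmat[, (b - 1L) * H + seq_len(H)] <- fw$gap
      if (keep_cache) caches[[b]] <- fw$cache
      if (debug) dbg[[b]] <- fw$debug
    }
  }
  E <- add_bias(Cmat %*% model$theta$We, model$theta$be)
  logits <- add_bias(E %*% model$theta$Wo, model$theta$bo)
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  list(probs = probs, embed = E, concat = Cmat, caches = caches,
       model = model, debug = dbg)
}

model_backward <- function(model, fw, rec_idx, y_idx) {
  config <- model$config
  B <- length(rec_idx)
  H <- config$hidden
  dlogits <- fw$probs
  dlogits[cbind(seq_len(B), y_idx)] <- dlogits[cbind(seq_len(B), y_idx)] - 1
  dlogits <- dlogits / B
  g <- list(branches = vector("list", config$n_branches))
  g$Wo <- crossprod(fw$embed, dlogits)
  g$bo <- colSums(dlogits)
  dE <- dlogits %*% t(model$theta$Wo)
  g$We <- crossprod(fw$concat, dE)
  g$be <- colSums(dE)
  dC <- dE %*% t(model$theta$We)
  b <- 0L
  for (s in seq_len(config$n_scales)) {
    geom <- model$geometry[[s]]
    for (l in seq_len(config$n_leads)) {
      b <- b + 1L
      dgap <- dC[, (b - 1L) * H + seq_len(H), drop = FALSE]
      g$branches[[b]] <- branch_backward(dgap, model$theta$branches[[b]],
                                         fw$caches[[b]], geom, B)
    }
  }
  g
}

# recursive SGDM update: v <- momentum*v - lr*g ; theta <- theta + v
sgdm_update <- function(theta, vel, grad, lr, momentum) {
  if (is.list(theta)) {
    for (nm in names(theta)) {
      if (nm %in% c("blocks", "branches")) {
        for (i in seq_along(theta[[nm]])) {
          r <- sgdm_update(theta[[nm]][[i]], vel[[nm]][[i]], grad[[nm]][[i]],
                           lr, momentum)
          theta[[nm]][[i]] <- r$theta; vel[[nm]][[i]] <- r$vel
        }
      } else {
        r <- sgdm_update(theta[[nm]], vel[[nm]], grad[[nm]], lr, momentum)
        theta[[nm]] <- r$theta; vel[[nm]] <- r$vel
      }
    }
    list(theta = theta, vel = vel)
  } else {
    vel <- momentum * vel - lr * grad
    list(theta = theta + vel, vel = vel)
  }
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

#' Build an (untrained) MI-MS ConvMixer model
#'
#' Allocates and seeds all parameters of the architecture described in
#' [convmixer_config()].
#'
#' @param config A [convmixer_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mims_convmixer` with `trained = FALSE`.
#' @export
convmixer_build <- function(config = convmixer_config(), seed = 1L) {
  stopifnot(inherits(config, "convmixer_config"))
  structure(list(config = config, theta = init_params(config, seed),
                 run_stats = init_run_stats(config),
                 geometry = branch_geometry(config),
                 classes = OCCLUSION_CLASSES[seq_len(config$n_classes)],
                 history = NULL, trained = FALSE, seed = as.integer(seed)),
            class = "mims_convmixer")
}

#' Count learnable parameters
#'
#' Counts every learnable scalar: convolution kernels and biases,
#' batch-norm scale/shift, and fully connected weights (running batch
#' statistics are not learnable and are excluded).
#'
#' @param model A `mims_convmixer`.
#' @return Named list: `total`, `per_branch` (vector), `head`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mims_convmixer"))
  count <- function(x) if (is.list(x)) sum(vapply(x, count, numeric(1))) else length(x)
  per_branch <- vapply(model$theta$branches, count, numeric(1))
  head_n <- count(model$theta[c("We", "be", "Wo", "bo")])
  list(total = sum(per_branch) + head_n, per_branch = per_branch,
       head = head_n)
}

#' Train an MI-MS ConvMixer with SGDM
#'
#' Cross-entropy loss, SGD with momentum, mini-batches reshuffled every
#' epoch from a seeded stream; the run is deterministic for a fixed seed
#' and platform. A `validation_fraction` slice of the training records is
#' held out and evaluated every `val_freq` iterations.
#'
#' @param model A `mims_convmixer` from [convmixer_build()], or a
#'   [convmixer_config()] (a model is then built with `seed`).
#' @param image_set An `ecg_image_set` from [records_to_image_set()], or a
#'   plain `(n*12) x d` image matrix (then `labels` must be given).
#' @param labels Character class labels, one per record (ignored when
#'   `image_set` carries labels).
#' @param opts A [train_options()].
#' @param seed Seed controlling shuffling (and initialization when a
#'   config is passed).
#' @return The trained model, with a `history` data.frame of
#'   per-iteration loss and accuracy (plus validation columns).
#' @export
convmixer_fit <- function(model, image_set, labels = NULL,
                          opts = train_options(), seed = 1L) {
  if (inherits(model, "convmixer_config")) model <- convmixer_build(model, seed)
  stopifnot(inherits(model, "mims_convmixer"), inherits(opts, "train_options"))
  if (inherits(image_set, "ecg_image_set")) {
    images <- image_set$images
    if (is.null(labels)) labels <- image_set$labels
  } else images <- image_set
  n <- nrow(images) / 12L
  stopifnot(n == round(n), length(labels) == n)
  y_idx <- match(labels, model$classes)
  if (anyNA(y_idx)) stop("unknown label(s): ",
                         paste(unique(labels[is.na(y_idx)]), collapse = ", "))
  if (length(unique(y_idx)) < 2) stop("degenerate-training-set: < 2 classes")

  local_seed(derive_seed(seed, "train"))
  idx_all <- sample.int(n)
  n_val <- floor(opts$validation_fraction * n)
  val_idx <- if (n_val >= 1) idx_all[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx_all, val_idx)

  vel <- zero_like(model$theta)
  hist <- list()
  iter <- 0L
  for (ep in seq_len(opts$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    batches <- split(ord, ceiling(seq_along(ord) / opts$minibatch))
    for (bt in batches) {
      iter <- iter + 1L
      fw <- model_forward(model, images, bt, training = TRUE,
                          keep_cache = TRUE)
      model <- fw$model   # running BN stats updated
      p_true <- fw$probs[cbind(seq_along(bt), y_idx[bt])]
      loss <- -mean(log(pmax(p_true, 1e-12)))
      acc <- mean(max.col(fw$probs, ties.method = "first") == y_idx[bt])
      grad <- model_backward(model, fw, bt, y_idx[bt])
      upd <- sgdm_update(model$theta, vel, grad, opts$lr, opts$momentum)
      model$theta <- upd$theta; vel <- upd$vel
      vl <- va <- NA_real_
      if (length(val_idx) && iter %% opts$val_freq == 0L) {
        pv <- model_forward(model, images, val_idx)$probs
        vl <- -mean(log(pmax(pv[cbind(seq_along(val_idx), y_idx[val_idx])],
                             1e-12)))
        va <- mean(max.col(pv, ties.method = "first") == y_idx[val_idx])
      }
      hist[[iter]] <- data.frame(iteration = iter, epoch = ep, loss = loss,
                                 accuracy = acc, val_loss = vl, val_accuracy = va)
    }
    if (opts$verbose)
      log_msg("train", sprintf("epoch %d/%d loss %.4f", ep, opts$epochs,
                               hist[[iter]]$loss))
  }
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

#' Predict class probabilities, labels, or embedding features
#'
#' @param object A `mims_convmixer`.
#' @param image_set An `ecg_image_set`, an `(n*12) x d` image matrix, or a
#'   list of 12 `spectrogram_image` objects (a single record).
#' @param type `"prob"` (n x 7 probability matrix, rows sum to 1),
#'   `"class"` (character labels), or `"features"` (n x embed_dim matrix
#'   of `fc_embed` activations, the pre-softmax embedding used by the
#'   downstream feature classifiers).
#' @param chunk Records per forward chunk (memory bound).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.mims_convmixer <- function(object, image_set,
                                   type = c("prob", "class", "features"),
                                   chunk = 128L, ...) {
  type <- match.arg(type)
  images <- if (inherits(image_set, "ecg_image_set")) image_set$images
  else if (is.list(image_set) && length(image_set) == 12 &&
           inherits(image_set[[1]], "spectrogram_image"))
    do.call(rbind, lapply(image_set, function(im) as.numeric(im$pixels)))
  else image_set
  stopifnot(is.matrix(images))
  d_expect <- object$config$input_size^2 * 3
  if (ncol(images) != d_expect)
    stop("image width ", ncol(images), " does not match configured ",
         object$config$input_size, "x", object$config$input_size, "x3 (",
         d_expect, ")")
  n <- nrow(images) / 12L
  if (n != round(n)) stop("image matrix must contain 12 rows per record")
  n <- as.integer(n)
  probs <- NULL; feats <- NULL
  for (st in seq(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    fw <- model_forward(object, images, st:en)
    probs <- rbind(probs, fw$probs)
    if (type == "features") feats <- rbind(feats, fw$embed)
  }
  switch(type,
         prob = { colnames(probs) <- object$classes; probs },
         class = object$classes[max.col(probs, ties.method = "first")],
         features = feats)
}

#' Extract the fc-layer feature matrix for a dataset
#'
#' Row i holds the `embed_dim` (default 1000) activations of the named
#' embedding layer `fc_embed` for record i. Features are pre-softmax
#' activations and are not constrained to `[0, 1]`.
#'
#' @param model A `mims_convmixer`.
#' @param image_set An `ecg_image_set` or image matrix.
#' @param layer Layer name; only `"fc_embed"` exists.
#' @return n x embed_dim numeric matrix.
#' @export
extract_features <- function(model, image_set, layer = "fc_embed") {
  if (!identical(layer, "fc_embed"))
    stop("unknown layer '", layer, "'; available layers: fc_embed")
  predict(model, image_set, type = "features")
}

#' @export
print.mims_convmixer <- function(x, ...) {
  cfg <- x$config
  pc <- count_parameters(x)
  cat(sprintf(paste0("<mims_convmixer: %d branches (%d leads x scales P={%s}), ",
                     "H=%d, D=%d, K=%d, embed %d, %d classes; %s; ",
                     "%s parameters>\n"),
              cfg$n_branches, cfg$n_leads,
              paste(cfg$patch_sizes, collapse = ","), cfg$hidden, cfg$depth,
              cfg$kernel, cfg$embed_dim, cfg$n_classes,
              if (x$trained) "trained" else "untrained",
              format(pc$total, big.mark = ",")))
  invisible(x)
}

#' @export
summary.mims_convmixer <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  training: %d iterations, final loss %.4f, final accuracy %.3f\n",
                nrow(h), h$loss[nrow(h)], h$accuracy[nrow(h)]))
    hv <- h[!is.na(h$val_loss), ]
    if (nrow(hv))
      cat(sprintf("  validation: last loss %.4f, accuracy %.3f\n",
                  hv$val_loss[nrow(hv)], hv$val_accuracy[nrow(hv)]))
  }
  invisible(object)
}

#' Plot training history
#'
#' Loss and accuracy against iteration, with validation points when
#' recorded.
#'
#' @param x A trained `mims_convmixer`.
#' @param ... Passed to [plot()].
#' @export
plot.mims_convmixer <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1)); on.exit(par(op))
  plot(h$iteration, h$loss, type = "l", xlab = "iteration", ylab = "loss",
       main = "training loss", ...)
  hv <- h[!is.na(h$val_loss), ]
  if (nrow(hv)) points(hv$iteration, hv$val_loss, col = 2, pch = 19)
  plot(h$iteration, h$accuracy, type = "l", xlab = "iteration",
       ylab = "accuracy", main = "training accuracy", ylim = c(0, 1), ...)
  if (nrow(hv)) points(hv$iteration, hv$val_accuracy, col = 2, pch = 19)
  invisible(x)
}

#' @importFrom graphics par points
NULL
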