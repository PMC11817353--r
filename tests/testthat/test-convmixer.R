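micro_cfg <- convmixer_config(input_size = 16, patch_sizes = 8, hidden = 2,
                              kernel = 3, depth = 1, n_leads = 2,
                              n_classes = 3, embed_dim = 5)

micro7 <- function() convmixer_config(input_size = 16, patch_sizes = 8,
                                      hidden = 2, depth = 1, embed_dim = 5)

test_that("configuration validates patch divisibility and derives sizes", {
  expect_error(convmixer_config(input_size = 64, patch_sizes = c(16, 12)),
               "divisible")
  cfg <- convmixer_config()
  expect_identical(cfg$n_branches, 24L)
  # concatenated feature length at the reference width: 12 * 2 * 750
  ref <- convmixer_config(hidden = 750)
  expect_identical(ref$n_branches * ref$hidden, 18000L)
  # pooling grids: 64/16 = 4x4, 64/8 = 8x8
  m <- convmixer_build(convmixer_config(hidden = 2, depth = 1), seed = 1)
  expect_identical(vapply(m$geometry, function(g) g$np, 0L), c(16L, 64L))
})

test_that("parameter count matches the hand-derived micro example", {
  cfg1 <- convmixer_config(input_size = 64, patch_sizes = 16, hidden = 2,
                           kernel = 3, depth = 1, n_leads = 1, embed_dim = 10)
  m1 <- convmixer_build(cfg1, seed = 1)
  expect_identical(count_parameters(m1)$per_branch, 1576)
  # depth enters linearly: each extra block adds dw + pw + 2 BN layers
  cfg2 <- convmixer_config(input_size = 64, patch_sizes = 16, hidden = 2,
                           kernel = 3, depth = 2, n_leads = 1, embed_dim = 10)
  m2 <- convmixer_build(cfg2, seed = 1)
  block_params <- (9 * 2 + 2) + (2 * 2 + 2) + 2 * (2 * 2)
  expect_identical(count_parameters(m2)$per_branch, 1576 + block_params)
  # weight sharing: count invariant to input size at fixed patch size
  cfg3 <- convmixer_config(input_size = 32, patch_sizes = 16, hidden = 2,
                           kernel = 3, depth = 1, n_leads = 1, embed_dim = 10)
  expect_identical(count_parameters(convmixer_build(cfg3, 1))$per_branch, 1576)
})

test_that("outputs are softmax-normalized for random weights and inputs", {
  for (s in 1:3) {
    m <- convmixer_build(micro_cfg, seed = s)
    img <- random_images(5, size = 16, seed = s)
    p <- predict(m, img, type = "prob")
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("zeroed depthwise kernels make the residual unit an identity", {
  m <- convmixer_build(convmixer_config(input_size = 16, patch_sizes = 8,
                                        hidden = 3, depth = 2, n_leads = 2,
                                        n_classes = 3, embed_dim = 4), seed = 2)
  for (b in seq_along(m$theta$branches))
    for (d in seq_along(m$theta$branches[[b]]$blocks))
      m$theta$branches[[b]]$blocks[[d]]$wdw[] <- 0
  img <- random_images(2, size = 16, seed = 3)
  fw <- coromix:::model_forward(m, img, 1:2, training = TRUE,
                                keep_cache = TRUE, debug = TRUE)
  for (b in seq_along(fw$debug))
    for (d in seq_along(fw$debug[[b]]))
      expect_identical(fw$debug[[b]][[d]]$U, fw$debug[[b]][[d]]$Ain)
})

test_that("analytic gradients match finite differences on the micro config", {
  model <- convmixer_build(micro_cfg, seed = 3)
  set.seed(7)
  n <- 3
  images <- random_images(n, size = 16, seed = 7)
  y <- c(1L, 2L, 3L)
  loss_fn <- function(m) {
    fw <- coromix:::model_forward(m, images, 1:n, training = TRUE,
                                  keep_cache = TRUE)
    -mean(log(fw$probs[cbind(1:n, y)]))
  }
  fw <- coromix:::model_forward(model, images, 1:n, training = TRUE,
                                keep_cache = TRUE)
  g <- coromix:::model_backward(model, fw, 1:n, y)
  eps <- 1e-6
  check_group <- function(get, set, ga) {
    th <- get(model$theta)
    idx <- sample(length(th), min(4, length(th)))
    for (i in idx) {
      m1 <- model; t1 <- get(m1$theta); t1[i] <- t1[i] + eps
      m1$theta <- set(m1$theta, t1)
      m2 <- model; t2 <- get(m2$theta); t2[i] <- t2[i] - eps
      m2$theta <- set(m2$theta, t2)
      num <- (loss_fn(m1) - loss_fn(m2)) / (2 * eps)
      rel <- abs(num - ga[i]) / max(1e-8, abs(num) + abs(ga[i]))
      expect_lt(rel, 1e-4)
    }
  }
  br <- function(t) t$branches[[1]]
  check_group(function(t) br(t)$Wp,
              function(t, v) { t$branches[[1]]$Wp[] <- v; t },
              g$branches[[1]]$Wp)
  check_group(function(t) br(t)$bn0$gamma,
              function(t, v) { t$branches[[1]]$bn0$gamma[] <- v; t },
              g$branches[[1]]$bn0$gamma)
  check_group(function(t) br(t)$blocks[[1]]$wdw,
              function(t, v) { t$branches[[1]]$blocks[[1]]$wdw[] <- v; t },
              g$branches[[1]]$blocks[[1]]$wdw)
  check_group(function(t) br(t)$blocks[[1]]$Wpw,
              function(t, v) { t$branches[[1]]$blocks[[1]]$Wpw[] <- v; t },
              g$branches[[1]]$blocks[[1]]$Wpw)
  check_group(function(t) br(t)$blocks[[1]]$bn2$beta,
              function(t, v) { t$branches[[1]]$blocks[[1]]$bn2$beta[] <- v; t },
              g$branches[[1]]$blocks[[1]]$bn2$beta)
  check_group(function(t) t$We,
              function(t, v) { t$We[] <- v; t }, g$We)
  check_group(function(t) t$Wo,
              function(t, v) { t$Wo[] <- v; t }, g$Wo)
})

test_that("training is seeded-reproducible and lr = 0 freezes parameters", {
  img <- random_images(14, size = 16, seed = 11)
  labs <- rep(OCCLUSION_CLASSES[1:7], 2)
  opts <- train_options(epochs = 2, minibatch = 8, validation_fraction = 0)
  m1 <- convmixer_fit(micro7(), img, labs, opts, seed = 5)
  m2 <- convmixer_fit(micro7(), img, labs, opts, seed = 5)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$theta, m2$theta)

  m0 <- convmixer_build(micro7(), seed = 6)
  mf <- convmixer_fit(m0, img, labs,
                      train_options(epochs = 1, minibatch = 8, lr = 0,
                                    validation_fraction = 0), seed = 6)
  expect_identical(mf$theta, m0$theta)
  expect_error(convmixer_fit(micro7(), img, rep("CX", 14), opts, seed = 1),
               "degenerate-training-set")
})

test_that("swapping two same-size scale branch sets leaves output unchanged", {
  cfg <- convmixer_config(input_size = 16, patch_sizes = c(8, 8), hidden = 2,
                          depth = 1, n_leads = 2, n_classes = 3, embed_dim = 4)
  m <- convmixer_build(cfg, seed = 4)
  img <- random_images(3, size = 16, seed = 5)
  p0 <- predict(m, img, type = "prob")
  # swap scale-1 and scale-2 branch parameter sets plus the matching
  # row blocks of the embedding weights
  nb <- cfg$n_leads
  H <- cfg$hidden
  m2 <- m
  m2$theta$branches <- m$theta$branches[c((nb + 1):(2 * nb), 1:nb)]
  m2$run_stats <- m$run_stats[c((nb + 1):(2 * nb), 1:nb)]
  rows <- c((nb * H + 1):(2 * nb * H), 1:(nb * H))
  m2$theta$We <- m$theta$We[rows, , drop = FALSE]
  expect_equal(predict(m2, img, type = "prob"), p0, tolerance = 1e-12)
})

test_that("feature extraction exposes the fc embedding deterministically", {
  m <- convmixer_build(micro_cfg, seed = 8)
  img <- random_images(4, size = 16, seed = 9)
  f1 <- extract_features(m, img)
  expect_identical(dim(f1), c(4L, 5L))
  # identical records produce identical rows
  img2 <- img
  img2[(3 * 12 + 1):(4 * 12), ] <- img[1:12, ]
  f2 <- extract_features(m, img2)
  expect_identical(f2[4, ], f2[1, ])
  expect_error(extract_features(m, img, layer = "fc9"), "fc_embed")
  expect_error(predict(m, img[, 1:100], type = "prob"), "does not match")
})
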