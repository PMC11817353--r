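ref_labels <- rep(OCCLUSION_CLASSES, c(180, 185, 252, 183, 173, 156, 192))

test_that("stratified folds: sizes, stratification, determinism", {
  plan <- stratified_kfold(ref_labels, 10, seed = 1)
  sizes <- lengths(plan$folds)
  expect_true(all(sizes %in% c(132L, 133L)))
  expect_identical(sum(sizes), 1321L)
  # RCA (185) contributes 18 or 19 per fold
  rca <- vapply(plan$folds, function(f) sum(ref_labels[f] == "RCA"), 0L)
  expect_true(all(rca %in% c(18L, 19L)))
  expect_identical(plan, stratified_kfold(ref_labels, 10, seed = 1))
  expect_error(stratified_kfold(ref_labels, 1), ">= 2")
  expect_warning(stratified_kfold(c("A", "A", "B"), 2), "fewer than k")
})

test_that("fold invariants hold across random label sets and seeds", {
  set.seed(6)
  for (i in 1:15) {
    n <- sample(40:200, 1)
    k <- sample(2:8, 1)
    labs <- sample(LETTERS[1:4], n, TRUE, prob = runif(4, 0.5, 1.5))
    while (any(table(labs) < k)) labs <- sample(LETTERS[1:4], n, TRUE)
    plan <- stratified_kfold(labs, k, seed = i)
    idx <- unlist(plan$folds)
    expect_identical(sort(idx), seq_len(n))          # disjoint + covering
    expect_lte(diff(range(lengths(plan$folds))), 1L) # balanced
    for (cl in unique(labs)) {
      per <- vapply(plan$folds, function(f) sum(labs[f] == cl), 0L)
      expect_lte(diff(range(per)), 1L)               # stratified
    }
  }
})

test_that("confusion matrices match the nested-loop oracle", {
  n <- 200
  set.seed(7)
  truth <- sample(OCCLUSION_CLASSES, n, TRUE)
  pred <- sample(OCCLUSION_CLASSES, n, TRUE)
  expect_identical(confusion_matrix(truth, pred),
                   confusion_oracle(truth, pred, OCCLUSION_CLASSES))
  cmp <- confusion_matrix(truth, truth)
  expect_identical(unname(diag(cmp)),
                   as.integer(table(factor(truth, OCCLUSION_CLASSES))))
  expect_identical(sum(cmp) - sum(diag(cmp)), 0L)
  all0 <- confusion_matrix(truth, rep("CX", n))
  expect_true(all(all0[, -1] == 0))
  expect_error(confusion_matrix(truth, c(pred[-1], "LCX")), "unknown label")
})

test_that("per-class metrics match formulas, identities, and edge rules", {
  set.seed(8)
  for (i in 1:25) {
    cm <- matrix(rpois(49, 8), 7, dimnames = list(truth = OCCLUSION_CLASSES,
                                                  predicted = OCCLUSION_CLASSES))
    mt <- per_class_metrics(cm)
    or <- metrics_oracle(cm)
    expect_equal(mt$per_class$sensitivity, unname(or[, "sensitivity"]))
    expect_equal(mt$per_class$specificity, unname(or[, "specificity"]))
    expect_equal(mt$per_class$precision, unname(or[, "precision"]))
    expect_equal(mt$per_class$f_score, unname(or[, "f_score"]))
    # accuracy = support-weighted mean sensitivity
    support <- rowSums(cm)
    expect_equal(mt$accuracy,
                 sum(mt$per_class$sensitivity * support) / sum(support))
  }
  # perfect classifier
  perfect <- diag(c(10, 20, 30, 40, 50, 60, 70))
  rownames(perfect) <- colnames(perfect) <- OCCLUSION_CLASSES
  mp <- per_class_metrics(perfect)
  expect_true(all(unlist(mp$per_class[, 6:9]) == 1))
  expect_identical(mp$accuracy, 1)
  # an empty predicted column: precision 0/0 -> 0 with a flag
  degen <- perfect; degen[1, 1] <- 0; degen[1, 2] <- 10
  md <- per_class_metrics(degen)
  expect_identical(md$per_class$precision[1], 0)
  expect_true(md$zero_division)
})

test_that("ablation fits strictly inside training folds (no leakage)", {
  imgset <- list(images = random_images(28, size = 16, seed = 12),
                 labels = rep(OCCLUSION_CLASSES, 4),
                 record_ids = sprintf("r%02d", 1:28), n = 28L,
                 params = spec_params(out_size = 16))
  class(imgset) <- "ecg_image_set"
  plan <- stratified_kfold(imgset$labels, 2, seed = 3)
  cfg <- convmixer_config(input_size = 16, patch_sizes = 8, hidden = 2,
                          depth = 1, embed_dim = 12)
  opts <- train_options(epochs = 1, minibatch = 14, validation_fraction = 0)
  r1 <- run_ablation(imgset, arms = c("b", "d"), seed = 5, plan = plan,
                     model_config = cfg, opts = opts, q = 6, wsse_k = 3)
  # scramble the labels of fold-1 test records only; with the fold plan
  # pinned, fitted models see identical training data, so test-fold
  # predictions must not move
  imgset2 <- imgset
  te <- plan$folds[[1]]
  imgset2$labels[te] <- rev(imgset2$labels[te])
  r2 <- run_ablation(imgset2, arms = c("b", "d"), seed = 5, plan = plan,
                     model_config = cfg, opts = opts, q = 6, wsse_k = 3)
  expect_identical(r1$arms$b$predicted[te], r2$arms$b$predicted[te])
  expect_identical(r1$arms$d$predicted[te], r2$arms$d$predicted[te])
  # report shape: per-arm confusion + 4 metrics x 7 classes + accuracy
  expect_identical(dim(r1$arms$b$confusion), c(7L, 7L))
  expect_identical(nrow(r1$arms$b$metrics$per_class), 7L)
})
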