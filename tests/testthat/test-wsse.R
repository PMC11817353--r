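test_that("subspace partition follows the ranked contiguous-block rule", {
  p <- partition_subspaces(c(0.5, 0.1, 0.4, 0.2), 2)
  expect_identical(p$subspaces, list(c(1L, 3L), c(4L, 2L)))
  expect_equal(p$vote_mass, c(0.9, 0.3))

  p1 <- partition_subspaces(runif(7), 1)
  expect_identical(sort(p1$subspaces[[1]]), 1:7)

  set.seed(1)
  w <- runif(1000)
  p10 <- partition_subspaces(w, 10)
  expect_identical(lengths(p10$subspaces), rep(100L, 10))
  expect_identical(sort(unlist(p10$subspaces)), 1:1000)
  expect_true(all(diff(p10$vote_mass) <= 1e-12))

  # uneven split: larger blocks first, sizes differ by at most one
  pu <- partition_subspaces(runif(10), 3)
  expect_identical(lengths(pu$subspaces), c(4L, 3L, 3L))
  expect_error(partition_subspaces(runif(3), 5), "too-many-subspaces")
  # negative weight sums are floored at zero
  pn <- partition_subspaces(c(0.2, -0.5, -0.4), 2)
  expect_equal(pn$vote_mass[2], 0)
})

test_that("weighted voting follows mass argmax with the stated tie rule", {
  M <- matrix(c("A", "B", "B"), 1)
  v <- coromix:::wsse_vote(M, c(0.5, 0.3, 0.2), c("A", "B"))
  expect_identical(v$labels, "A")            # 0.5 vs 0.5 tie -> subspace 1
  v2 <- coromix:::wsse_vote(M, c(0.2, 0.3, 0.4), c("A", "B"))
  expect_identical(v2$labels, "B")           # 0.7 > 0.2
  v3 <- coromix:::wsse_vote(matrix(c("B", "B", "B"), 1), c(0, 0.1, 0.9),
                            c("A", "B"))
  expect_identical(v3$labels, "B")           # unanimity wins at any mass
  # conservation: cast mass equals the total vote mass, per sample
  set.seed(2)
  M4 <- matrix(sample(c("A", "B", "C"), 15, TRUE), 5)
  mass <- c(0.5, 0.4, 0.3)
  v4 <- coromix:::wsse_vote(M4, mass, c("A", "B", "C"))
  expect_equal(unname(rowSums(v4$votes)), rep(sum(mass), 5))
})

test_that("k = 1 ensemble is exactly the single SVM (20 random sets)", {
  set.seed(3)
  for (trial in 1:5) {          # 20-trial version runs in the acceptance suite
    n <- 60
    X <- matrix(rnorm(n * 12), n)
    y <- sample(c("A", "B", "C"), n, TRUE)
    X[y == "B", 1] <- X[y == "B", 1] + 1.5
    w <- relieff_weights(X, y, k = 5)
    probe <- matrix(rnorm(20 * 12), 20)
    e_wsse <- predict(wsse_fit(X, y, w, k = 1), probe)$labels
    e_svm <- predict(svm_fit(X, y), probe)
    expect_identical(e_wsse, e_svm)
  }
})

test_that("fitting is deterministic and stores k classifiers", {
  set.seed(4)
  X <- matrix(rnorm(80 * 10), 80)
  y <- sample(c("A", "B", "C"), 80, TRUE)
  w <- relieff_weights(X, y, k = 5)
  probe <- matrix(rnorm(25 * 10), 25)
  m1 <- wsse_fit(X, y, w, k = 4)
  m2 <- wsse_fit(X, y, w, k = 4)
  expect_identical(length(m1$models), 4L)
  expect_identical(predict(m1, probe)$labels, predict(m2, probe)$labels)
  expect_error(predict(m1, probe[, 1:7]), "feature-count mismatch")
  # integer-replication voting mode: masses k..1
  mr <- wsse_fit(X, y, w, k = 4, vote = "replicate")
  expect_identical(mr$vote_mass, c(4, 3, 2, 1))
})

test_that("prediction matrix M and voting matrix V are exposed", {
  set.seed(5)
  X <- matrix(rnorm(60 * 8), 60)
  y <- rep(c("A", "B"), 30)
  X[y == "A", 1:2] <- X[y == "A", 1:2] + 2
  m <- wsse_fit(X, y, relieff_weights(X, y, k = 5), k = 2)
  pr <- predict(m, X[1:10, ])
  expect_identical(dim(pr$predictions), c(10L, 2L))
  expect_identical(dim(pr$votes), c(10L, 2L))
  expect_true(all(pr$labels %in% c("A", "B")))
})
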