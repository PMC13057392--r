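test_that("pca_reduce picks the minimal k at the variance cutoff", {
  # one non-constant direction
  set.seed(30)
  base <- rnorm(40)
  X1 <- cbind(a = base, b = 2 * base + 1, c = -base)
  f1 <- pca_reduce(X1, 0.95)
  expect_equal(f1$k, 1L)
  expect_equal(f1$cum_var_achieved, 1, tolerance = 1e-10)
  # seeded Gaussian data matches the eigendecomposition oracle
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(200 * 10), 200, 10)
    expect_equal(pca_reduce(X, 0.95)$k, oracle_pca_k(X, 0.95))
  }
  # cum_var = 1 retains the full rank of the centred matrix
  set.seed(31)
  Xr <- matrix(rnorm(20 * 5), 20, 5)
  Xr <- cbind(Xr, Xr[, 1] + Xr[, 2]) # rank 5
  expect_equal(pca_reduce(Xr, 1)$k, 5L)
  expect_error(pca_reduce(Xr, 0), "cum_var")
  expect_error(pca_reduce(Xr, 1.2), "cum_var")
})

test_that("pca scores are centred with non-increasing variances", {
  set.seed(32)
  X <- matrix(rnorm(60 * 8), 60, 8)
  X[, 1:3] <- X[, 1:3] %*% matrix(rnorm(9, sd = 2), 3, 3)
  f <- pca_reduce(X, 0.99)
  expect_true(all(abs(colMeans(f$scores)) < 1e-10))
  v <- apply(f$scores, 2, var)
  expect_true(all(diff(v) < 1e-10))
  # deterministic sign: largest-magnitude loading positive
  expect_true(all(apply(f$rotation, 2, function(r) r[which.max(abs(r))] > 0)))
})

test_that("fuse concatenates aligned blocks and rejects shuffles", {
  set.seed(33)
  meta <- tibble::tibble(batch_id = paste0("b", 1:12),
                         replicate = 1L, grade = rep(c("g1", "g2"), 6))
  mk <- function(p, tag) {
    pca_reduce(matrix(rnorm(12 * p), 12, p), 0.99, platform = tag,
               meta = meta)
  }
  blocks <- list(mk(6, "p1"), mk(5, "p2"))
  fused <- fuse(blocks)
  expect_equal(ncol(fused$features), blocks[[1]]$k + blocks[[2]]$k)
  expect_equal(as.integer(table(fused$provenance)[c("p1", "p2")]),
               c(blocks[[1]]$k, blocks[[2]]$k))
  # single block: fused equals that block
  f1 <- fuse(blocks[1])
  expect_equal(f1$features, blocks[[1]]$scores)
  # shuffled rows in one block are caught and named
  shuffled <- blocks[[2]]
  shuffled$meta <- shuffled$meta[c(2:12, 1), ]
  expect_error(fuse(list(blocks[[1]], shuffled)), "b1")
})

test_that("split sizes follow the floor rule and the study-size flag", {
  meta <- default_dataset()$volatile[, c("batch_id", "grade")]
  meta$replicate <- default_dataset()$volatile$replicate
  s1 <- split_data(meta, split_spec(seed = 1))
  expect_equal(length(s1$train), 136L)
  expect_equal(length(s1$test), 59L)
  s2 <- split_data(meta, split_spec(seed = 1, study_size = TRUE))
  expect_equal(length(s2$train), 135L)
  expect_equal(length(s2$test), 60L)
  # partition without leakage
  expect_length(intersect(s2$train, s2$test), 0L)
  expect_setequal(c(s2$train, s2$test), seq_len(nrow(meta)))
  # determinism
  s3 <- split_data(meta, split_spec(seed = 1, study_size = TRUE))
  expect_identical(s2, s3)
  # full-train edge case warns
  expect_warning(s4 <- split_data(meta, split_spec(train_frac = 1)),
                 "empty test")
  expect_length(s4$test, 0L)
  # batch-grouped option keeps batches intact
  sg <- split_data(meta, split_spec(seed = 2, group_by_batch = TRUE))
  tb <- unique(meta$batch_id[sg$train])
  expect_length(intersect(tb, unique(meta$batch_id[sg$test])), 0L)
})

test_that("all classifiers solve well-separated class blobs", {
  set.seed(34)
  n_per <- 30
  X <- do.call(rbind, lapply(0:3, function(g) {
    matrix(rnorm(n_per * 4), n_per, 4) + 10 * g
  }))
  y <- factor(rep(paste0("g", 1:4), each = n_per))
  ev <- train_and_evaluate(X, y, classifier_config(seed = 1),
                           split_spec(seed = 1))
  expect_equal(ev$report$test_accuracy, rep(1, 3))
  expect_equal(ev$report$train_accuracy, rep(1, 3))
  # confusion trace identity
  for (cl in names(ev$confusion)) {
    cm <- ev$confusion[[cl]]
    expect_equal(sum(diag(cm)) / sum(cm),
                 ev$report$test_accuracy[ev$report$classifier == cl])
  }
  expect_error(train_and_evaluate(X, factor(rep("g1", nrow(X)))),
               "2 classes")
  expect_error(classifier_config(classifiers = "svm"), "unknown classifier")
})

test_that("deterministic KNN breaks ties with the nearest neighbour", {
  train_x <- rbind(c(0, 0), c(1, 0), c(4, 0))
  train_y <- factor(c("a", "b", "b"))
  # test point at 0.4: nearest is class a (d=0.4), then b (d=0.6): tie at K=2
  p <- knn_predict(train_x, train_y, rbind(c(0.4, 0)), k = 2)
  expect_equal(as.character(p), "a")
  # clear majority wins
  p2 <- knn_predict(train_x, train_y, rbind(c(2, 0)), k = 3)
  expect_equal(as.character(p2), "b")
})

test_that("compare_sources reports every source and is seed-deterministic", {
  ds <- default_dataset()
  cfg <- classifier_config(seed = 5, classifiers = c("knn", "rf"))
  sp <- split_spec(seed = 5, study_size = TRUE)
  c1 <- compare_sources(ds, cfg, sp)
  expect_setequal(unique(c1$report$source),
                  c("HS-GC-MS", "LC-MS", "E-nose", "E-tongue", "Fusion"))
  expect_equal(nrow(c1$report), 10L)
  expect_true(all(c1$report$n_train == 135L))
  expect_true(all(c1$report$test_accuracy >= 0 &
                    c1$report$test_accuracy <= 1))
  c2 <- compare_sources(ds, cfg, sp)
  expect_identical(c1$report, c2$report)
  expect_identical(c1$confusion, c2$confusion)
})

test_that("with no planted signal, grouped-split accuracy is near chance", {
  e0 <- effect_spec(effect_scale = 0)
  ds0 <- generate_dataset(study_design(seed = 9L), e0)
  cmp <- compare_sources(ds0, classifier_config(seed = 1,
                                                classifiers = "rf"),
                         split_spec(seed = 1, group_by_batch = TRUE))
  # majority-class rate with 3 sigma binomial slack
  for (i in seq_len(nrow(cmp$report))) {
    n_te <- cmp$report$n_test[i]
    grades <- factor(ds0$volatile$grade)
    p0 <- max(table(grades[cmp$split$test])) / n_te
    expect_lte(cmp$report$test_accuracy[i],
               p0 + 3 * sqrt(p0 * (1 - p0) / n_te))
  }
})
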