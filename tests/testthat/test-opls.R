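test_that("preprocessing gives exact unit variance and handles constants", {
  set.seed(1)
  X <- cbind(a = rnorm(20, 5, 3), b = runif(20), const = rep(2, 20))
  pr <- preprocess(X)
  expect_equal(pr$dropped, "const")
  expect_true(all(abs(colMeans(pr$X)) < 1e-8))
  expect_true(all(abs(apply(pr$X, 2, var) - 1) < 1e-8))
  expect_error(preprocess(matrix(1, 5, 2)), "zero-variance")
  # held-out rows are transformed with training parameters, not their own
  new <- apply_preprocess(pr, X[1:2, ])
  expect_equal(new[1, "a"], (X[1, "a"] - mean(X[, "a"])) / sd(X[, "a"]))
})

test_that("OPLS-DA with 0 orthogonal components equals brute-force NIPALS
           PLS to sign", {
  set.seed(10)
  X <- matrix(rnorm(8 * 3), 8, 3)
  y <- factor(rep(c("a", "b"), 4))
  m <- fit_opls_da(X, y, n_ortho = 0, n_pred = 1)
  or <- oracle_nipals_pls(X, matrix(as.numeric(y == "b")), 1)
  expect_equal(abs(drop(m$scores)), abs(drop(or$T)), tolerance = 1e-8)
  expect_equal(unname(abs(drop(m$weights))), abs(drop(or$W)),
               tolerance = 1e-8)
  # larger multiclass case
  set.seed(11)
  Xm <- matrix(rnorm(30 * 6), 30, 6)
  ym <- factor(rep(letters[1:3], each = 10))
  Ym <- sapply(letters[1:3], function(l) as.numeric(ym == l))
  mm <- fit_opls_da(Xm, ym, n_ortho = 0)
  om <- oracle_nipals_pls(Xm, Ym, 2)
  for (a in 1:2) {
    expect_equal(abs(mm$scores[, a]), abs(om$T[, a]), tolerance = 1e-6)
  }
})

test_that("a perfectly predictive column dominates the fit", {
  set.seed(12)
  y <- factor(rep(c("a", "b"), each = 6))
  X <- cbind(sig = as.numeric(y == "b"), matrix(rnorm(12 * 5), 12, 5))
  # with the full predictive expansion the fit reproduces the exact
  # least-squares solution, and y lies in the column span of X
  m <- fit_opls_da(X, y, n_ortho = 0, n_pred = ncol(X))
  expect_equal(m$r2y_cum, 1, tolerance = 1e-6)
  m1 <- fit_opls_da(X, y, n_ortho = 0, n_pred = 1)
  v <- vip(m1)$vip
  expect_equal(names(which.max(v)), "sig")
  expect_gt(v["sig"], 1)
})

test_that("orthogonal scores are exactly uncorrelated with the class block", {
  set.seed(13)
  for (i in 1:5) {
    X <- matrix(rnorm(24 * 8), 24, 8)
    y <- factor(rep(c("a", "b"), each = 12))
    m <- fit_opls_da(X, y, n_ortho = 2)
    expect_lt(max(abs(cor(m$ortho_scores, m$Yc))), 1e-8)
  }
  # multiclass with one-hot block
  Xm <- matrix(rnorm(40 * 7), 40, 7)
  ym <- factor(rep(letters[1:4], each = 10))
  mm <- fit_opls_da(Xm, ym, n_ortho = 1)
  expect_equal(mm$n_pred, 3L)
  expect_lt(max(abs(cor(mm$ortho_scores, mm$Yc))), 1e-8)
})

test_that("model quality metrics respect their algebraic bounds", {
  set.seed(14)
  X <- matrix(rnorm(30 * 10), 30, 10)
  X[16:30, 1:2] <- X[16:30, 1:2] + 2
  y <- factor(rep(c("a", "b"), each = 15))
  m <- fit_opls_da(X, y, n_ortho = 1)
  expect_gte(m$r2x_cum, 0); expect_lte(m$r2x_cum, 1)
  expect_gte(m$r2y_cum, 0); expect_lte(m$r2y_cum, 1)
  q2 <- cross_validated_q2(X, y, n_ortho = 1, seed = 3)$q2
  expect_lte(q2, m$r2y_cum + 1e-8)
  # R2X(cum) non-decreasing in the number of predictive components
  r2x <- sapply(1:3, function(a) {
    fit_opls_da(X, y, n_ortho = 0, n_pred = a)$r2x_cum
  })
  expect_true(all(diff(r2x) > -1e-10))
  # orientation: first class level has negative mean predictive score
  expect_lt(mean(m$scores[y == "a", 1]), 0)
})

test_that("VIP is normalised and ranks planted variables first", {
  set.seed(15)
  for (i in 1:5) {
    X <- matrix(rnorm(26 * 9), 26, 9)
    y <- factor(rep(c("a", "b"), 13))
    m <- fit_opls_da(X, y, n_ortho = sample(0:1, 1))
    expect_equal(mean(vip(m)$vip^2), 1, tolerance = 1e-8)
  }
  # single-variable model: VIP forced to exactly 1
  x1 <- matrix(rnorm(20), 20, 1)
  y1 <- factor(rep(c("a", "b"), 10))
  expect_equal(unname(vip(fit_opls_da(x1, y1, n_ortho = 0))$vip), 1)
  # two planted variables (3 SD shift) among 10 are the top-2 VIP, both > 1
  set.seed(16)
  X <- matrix(rnorm(30 * 10), 30, 10)
  colnames(X) <- paste0("v", 1:10)
  y <- factor(rep(c("a", "b"), each = 15))
  X[y == "b", 1:2] <- X[y == "b", 1:2] + 3
  v <- vip(fit_opls_da(X, y, n_ortho = 0))$vip
  expect_setequal(names(sort(v, decreasing = TRUE))[1:2], c("v1", "v2"))
  expect_true(all(v[1:2] > 1))
})

test_that("Q2 separates signal from noise and matches brute-force LOO", {
  # planted 5-SD separation is confidently predictive
  set.seed(17)
  X <- matrix(rnorm(60 * 10), 60, 10)
  y <- factor(rep(c("a", "b"), each = 30))
  X[y == "b", 1:3] <- X[y == "b", 1:3] + 5
  expect_gt(cross_validated_q2(X, y, n_ortho = 1, seed = 1)$q2, 0.9)
  # labels carry no information: Q2 stays near or below zero
  null_q2 <- sapply(1:20, function(s) {
    set.seed(s)
    Xn <- matrix(rnorm(60 * 10), 60, 10)
    yn <- factor(sample(rep(c("a", "b"), 30)))
    cross_validated_q2(Xn, yn, n_ortho = 0, seed = s)$q2
  })
  expect_gte(mean(null_q2 <= 0.05), 0.95)
  # leave-one-out equals an exhaustive per-observation PRESS
  set.seed(18)
  X6 <- matrix(rnorm(6 * 3), 6, 3)
  y6 <- factor(rep(c("a", "b"), each = 3))
  cv <- cross_validated_q2(X6, y6, n_ortho = 0, k = 6, seed = 1)
  Y <- as.numeric(y6 == "b")
  press <- sum(sapply(1:6, function(i) {
    m <- fit_opls_da(X6[-i, ], y6[-i], n_ortho = 0)
    (Y[i] - drop(predict(m, X6[i, , drop = FALSE])$y))^2
  }))
  expect_equal(cv$press, press, tolerance = 1e-10)
})

test_that("fold construction is stratified and rejects degenerate folds", {
  y <- factor(rep(c("a", "b"), c(14, 7)))
  cv <- cross_validated_q2(matrix(rnorm(21 * 4), 21, 4), y, n_ortho = 0,
                           k = 7, seed = 2)
  expect_equal(sort(unique(cv$folds)), 1:7)
  expect_error(
    cross_validated_q2(matrix(rnorm(8), 4, 2),
                       factor(c("a", "a", "b", "b")), k = 5),
    "k <= n"
  )
  expect_error(fit_opls_da(matrix(rnorm(9), 3, 3), factor(c("a", "a", "b"))),
               "fewer than 2")
})

test_that("permutation test calibrates against label reshuffling", {
  # strong separation: no permutation reaches the observed Q2
  set.seed(19)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- factor(rep(c("a", "b"), each = 15))
  X[y == "b", 1:3] <- X[y == "b", 1:3] + 5
  pt <- permutation_test(X, y, n_perm = 50, n_ortho = 1, seed = 4)
  expect_equal(pt$p_value, 1 / 51)
  expect_equal(pt$verdict, "valid")
  expect_true(all(pt$q2_perm < pt$q2_obs))
  # n_perm = 1 with a losing permutation gives p = 1/2
  expect_equal((1 + 0) / (1 + 1), 0.5)
  pt1 <- permutation_test(X, y, n_perm = 1, n_ortho = 0, seed = 5)
  expect_equal(pt1$p_value, 0.5)
  # independence: the verdict fires rarely
  hits <- sapply(1:15, function(s) {
    set.seed(s + 50)
    Xn <- matrix(rnorm(24 * 5), 24, 5)
    yn <- factor(rep(c("a", "b"), 12))
    permutation_test(Xn, yn, n_perm = 19, n_ortho = 0,
                     seed = s)$verdict == "valid"
  })
  expect_lte(mean(hits), 0.2)
  expect_error(permutation_test(X, factor(rep("a", 30)), n_perm = 5),
               "2 classes")
})

test_that("block permutation keeps batch-constant labels batch-constant", {
  set.seed(20)
  blocks <- rep(paste0("b", 1:8), each = 3)
  y <- factor(rep(rep(c("a", "b"), each = 4), each = 3))
  X <- matrix(rnorm(24 * 4), 24, 4)
  X[y == "b", 1] <- X[y == "b", 1] + 3
  pt <- permutation_test(X, y, n_perm = 10, n_ortho = 0, seed = 6,
                         blocks = blocks)
  expect_s3_class(pt, "permutation_summary")
  expect_error(permutation_test(X, factor(rep(c("a", "b"), 12)), n_perm = 2,
                                blocks = blocks),
               "constant within a block")
})

test_that("relative content is the analyte-to-standard ratio", {
  areas <- rbind(obs1 = c(x = 100, y = 100), obs2 = c(x = 200, y = 50))
  rc <- relative_content(areas, c(100, 100))
  expect_equal(unname(rc["obs1", ]), c(1, 1))
  expect_equal(unname(rc["obs2", ]), c(2, 0.5))
  expect_error(relative_content(areas, c(100, 0)), "obs2")
})

test_that("spearman_matrix matches the rank-then-Pearson oracle", {
  expect_equal(spearman_matrix(cbind(x = c(1, 2, 3)),
                               cbind(y = c(3, 1, 2)))$rho[1, 1], -0.5)
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- if (i %% 2) rnorm(n) else sample(round(rnorm(n)))  # with ties
    got <- spearman_matrix(cbind(a = x), cbind(b = y))$rho[1, 1]
    expect_equal(got, oracle_spearman(x, y), tolerance = 1e-12)
  }
  # self-correlation of a non-constant column is 1; constants are missing
  m <- spearman_matrix(cbind(x = rnorm(10), k = rep(1, 10)))
  expect_equal(m$rho["x", "x"], 1)
  expect_true(is.na(m$rho["k", "x"]))
  expect_true(is.na(m$rho["x", "k"]))
  expect_error(spearman_matrix(cbind(1:2), cbind(2:1)), "3 observations")
})
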