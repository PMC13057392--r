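# OPLS-DA written from first principles (NIPALS + orthogonal signal
# deflation). Scores, loadings and weights follow the usual chemometrics
# conventions: predictive weights W (unit norm), scores T = X W (after
# orthogonal filtering), X-loadings P, Y-loadings C; orthogonal components
# W_o, T_o, P_o carry the class-uncorrelated structured variation.

#' Centre and unit-variance scale a feature matrix
#'
#' @param X Numeric matrix or data frame (observations x variables).
#' @param center,scale Apply mean centring / unit-variance (UV) scaling.
#' @param zero_var What to do with zero-variance columns when scaling:
#'   `"drop"` (default; dropped columns are recorded) or `"error"`.
#' @return List with the transformed matrix `X`, the fitted `center` and
#'   `scale` vectors, the retained column names `kept` and `dropped`.
#' @export
preprocess <- function(X, center = TRUE, scale = TRUE,
                       zero_var = c("drop", "error")) {
  zero_var <- match.arg(zero_var)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty matrix", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cols <- colnames(X)
  sds <- apply(X, 2, stats::sd)
  dropped <- character(0)
  if (scale) {
    zero <- sds < 1e-12 | !is.finite(sds)
    if (any(zero)) {
      if (zero_var == "error" || all(zero)) {
        stop("zero-variance column(s): ",
             paste(colnames(X)[zero], collapse = ", "), call. = FALSE)
      }
      dropped <- colnames(X)[zero]
      X <- X[, !zero, drop = FALSE]
      sds <- sds[!zero]
    }
  }
  ctr <- if (center) colMeans(X) else rep(0, ncol(X))
  scl <- if (scale) sds else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  list(X = Xs, center = ctr, scale = scl, kept = colnames(Xs),
       dropped = dropped, cols = cols)
}

# Apply fitted preprocessing parameters to held-out data.
apply_preprocess <- function(prep, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(prep$cols)) {
      stop("new data has ", ncol(X), " columns; training data had ",
           length(prep$cols), call. = FALSE)
    }
    colnames(X) <- prep$cols
  }
  X <- X[, prep$kept, drop = FALSE]
  sweep(sweep(X, 2, prep$center), 2, prep$scale, "/")
}

# One NIPALS PLS2 component on (X, Y): returns unit weight w, score t,
# X-loading p, Y-loading c. Converges in one pass for single-column Y.
nipals_component <- function(X, Y, tol = 1e-12, max_iter = 500L) {
  u <- Y[, which.max(colSums(Y^2)), drop = TRUE]
  t_old <- rep(0, nrow(X))
  for (it in seq_len(max_iter)) {
    w <- drop(crossprod(X, u))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) return(NULL)
    w <- w / nw
    tt <- drop(X %*% w)
    cc <- drop(crossprod(Y, tt)) / sum(tt^2)
    u <- drop(Y %*% cc) / sum(cc^2)
    if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
    t_old <- tt
  }
  p <- drop(crossprod(X, tt)) / sum(tt^2)
  list(w = w, t = tt, p = p, c = cc)
}

# NIPALS PLS2 with X- and Y-deflation; inputs already centred/scaled.
nipals_pls <- function(X, Y, ncomp, tol = 1e-12) {
  p <- ncol(X)
  m <- ncol(Y)
  W <- matrix(0, p, 0); TT <- matrix(0, nrow(X), 0)
  P <- matrix(0, p, 0); C <- matrix(0, m, 0)
  ssy_expl <- numeric(0)
  Xc <- X; Yc <- Y
  for (a in seq_len(ncomp)) {
    comp <- nipals_component(Xc, Yc, tol = tol)
    if (is.null(comp) || sum(comp$t^2) < 1e-14) break
    W <- cbind(W, comp$w); TT <- cbind(TT, comp$t)
    P <- cbind(P, comp$p); C <- cbind(C, comp$c)
    ssy_expl <- c(ssy_expl, sum(comp$t^2) * sum(comp$c^2))
    Xc <- Xc - tcrossprod(comp$t, comp$p)
    Yc <- Yc - tcrossprod(comp$t, comp$c)
  }
  rownames(W) <- rownames(P) <- colnames(X)
  list(W = W, T = TT, P = P, C = C, ssy_expl = ssy_expl,
       Xres = Xc, Yres = Yc)
}

# Class dummy block: a single 0/1 column for two classes, one-hot otherwise.
class_dummy <- function(classes) {
  classes <- droplevels(as.factor(classes))
  lev <- levels(classes)
  if (length(lev) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (length(lev) == 2L) {
    Y <- matrix(as.numeric(classes == lev[2]), ncol = 1,
                dimnames = list(NULL, lev[2]))
  } else {
    Y <- vapply(lev, function(l) as.numeric(classes == l),
                numeric(length(classes)))
  }
  list(Y = Y, levels = lev, classes = classes)
}

#' Fit an OPLS-DA model
#'
#' Orthogonal partial least squares discriminant analysis: class-orthogonal
#' structured variation is removed from the (centred, UV-scaled) predictor
#' block component by component before a NIPALS PLS fit of the class dummy
#' block. Each orthogonal weight is the X-loading of a provisional PLS
#' component projected off the span of \eqn{X'Y}, so every orthogonal score
#' is exactly uncorrelated with the class block. Two classes are coded as a
#' single 0/1 column and modelled with one predictive component; k > 2
#' classes as a one-hot block with k - 1 predictive components. Predictive
#' scores are oriented so the first class level has a negative mean score.
#'
#' @param X Feature matrix or data frame (observations x variables).
#' @param classes Class labels (factor or character), one per row; every
#'   class needs at least 2 observations.
#' @param n_ortho Number of orthogonal components (default 1; 0 gives a plain
#'   PLS-DA fit).
#' @param n_pred Number of predictive components; defaults to
#'   `nlevels - 1`.
#' @param center,scale Preprocessing of X (default: UV scaling).
#' @param platform,comparison Optional tags carried into downstream
#'   differential sets.
#' @return An object of class `opls_da` with scores/loadings/weights,
#'   orthogonal counterparts, `r2x_cum`, `r2y_cum`, per-component explained
#'   Y-variance and the fitted preprocessing parameters.
#' @export
fit_opls_da <- function(X, classes, n_ortho = 1L, n_pred = NULL,
                        center = TRUE, scale = TRUE, platform = NULL,
                        comparison = NULL) {
  cd <- class_dummy(classes)
  n <- nrow(as.matrix(X))
  if (length(cd$classes) != n) stop("length(classes) != nrow(X)",
                                    call. = FALSE)
  small <- table(cd$classes) < 2L
  if (any(small)) {
    stop("class(es) with fewer than 2 observations: ",
         paste(names(which(small)), collapse = ", "), call. = FALSE)
  }
  if (n_ortho < 0L) stop("n_ortho must be >= 0", call. = FALSE)
  n_pred <- n_pred %||% (length(cd$levels) - 1L)

  prep <- preprocess(X, center = center, scale = scale)
  Xs <- prep$X
  rk <- qr(Xs)$rank
  if (n_ortho > max(rk - 1L, 0L)) {
    stop(sprintf("n_ortho = %d exceeds what the matrix rank (%d) supports",
                 n_ortho, rk), call. = FALSE)
  }
  ymeans <- colMeans(cd$Y)
  Yc <- sweep(cd$Y, 2, ymeans)

  Xcur <- Xs
  W_o <- matrix(0, ncol(Xs), 0); T_o <- matrix(0, n, 0)
  P_o <- matrix(0, ncol(Xs), 0)
  for (a in seq_len(n_ortho)) {
    Wy <- qr.Q(qr(crossprod(Xcur, Yc)))
    comp <- nipals_component(Xcur, Yc)
    if (is.null(comp)) break
    w_o <- comp$p - Wy %*% crossprod(Wy, comp$p)
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-10) break # no Y-orthogonal structure left
    w_o <- w_o / nw
    t_o <- drop(Xcur %*% w_o)
    p_o <- drop(crossprod(Xcur, t_o)) / sum(t_o^2)
    W_o <- cbind(W_o, w_o); T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o)
    Xcur <- Xcur - tcrossprod(t_o, p_o)
  }

  pls <- nipals_pls(Xcur, Yc, n_pred)
  if (ncol(pls$T) == 0L) {
    stop("no predictive component could be extracted", call. = FALSE)
  }
  # orient: first class level gets a negative mean predictive score
  first <- cd$classes == cd$levels[1]
  for (a in seq_len(ncol(pls$T))) {
    if (mean(pls$T[first, a]) > 0) {
      pls$W[, a] <- -pls$W[, a]; pls$T[, a] <- -pls$T[, a]
      pls$P[, a] <- -pls$P[, a]; pls$C[, a] <- -pls$C[, a]
    }
  }

  ssx <- sum(Xs^2)
  expl_pred <- colSums(pls$T^2) * colSums(pls$P^2)
  expl_orth <- if (ncol(T_o)) colSums(T_o^2) * colSums(P_o^2) else numeric(0)
  r2x <- (sum(expl_pred) + sum(expl_orth)) / ssx
  ssy <- sum(Yc^2)
  r2y <- 1 - sum(pls$Yres^2) / ssy

  B <- pls$W %*% solve(crossprod(pls$P, pls$W), t(pls$C))

  structure(list(
    weights = pls$W, scores = pls$T, loadings = pls$P, y_loadings = pls$C,
    ortho_weights = W_o, ortho_scores = T_o, ortho_loadings = P_o,
    n_pred = ncol(pls$T), n_ortho = ncol(T_o),
    coef = B, prep = prep, y_means = ymeans, Y = cd$Y, Yc = Yc,
    classes = cd$classes, levels = cd$levels,
    r2x_cum = r2x, r2y_cum = r2y, ssy_expl = pls$ssy_expl, ssy_total = ssy,
    platform = platform, comparison = comparison
  ), class = "opls_da")
}

#' @export
print.opls_da <- function(x, ...) {
  cat(sprintf("OPLS-DA: %d predictive + %d orthogonal component(s), %d classes\n",
              x$n_pred, x$n_ortho, length(x$levels)))
  cat(sprintf("  R2X(cum) = %.3f  R2Y(cum) = %.3f\n", x$r2x_cum, x$r2y_cum))
  if (!is.null(x$comparison)) cat("  comparison:", x$comparison, "\n")
  invisible(x)
}

#' Predict from a fitted OPLS-DA model
#'
#' New observations are transformed with the training preprocessing
#' parameters, orthogonal-filtered with the training orthogonal components,
#' and pushed through the predictive regression coefficients.
#'
#' @param object A fitted [fit_opls_da()] model.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return List with the predicted dummy block `y`, predictive `scores` and
#'   the predicted `class` factor.
#' @export
predict.opls_da <- function(object, newdata, ...) {
  Xs <- apply_preprocess(object$prep, newdata)
  for (a in seq_len(object$n_ortho)) {
    t_o <- drop(Xs %*% object$ortho_weights[, a])
    Xs <- Xs - tcrossprod(t_o, object$ortho_loadings[, a])
  }
  yhat_c <- Xs %*% object$coef
  yhat <- sweep(yhat_c, 2, object$y_means, "+")
  scores <- Xs %*% object$weights %*%
    solve(crossprod(object$loadings, object$weights))
  cls <- if (length(object$levels) == 2L) {
    object$levels[1L + (drop(yhat) > 0.5)]
  } else {
    object$levels[max.col(yhat, ties.method = "first")]
  }
  list(y = yhat, scores = scores,
       class = factor(cls, levels = object$levels))
}

#' Variable importance in projection (VIP)
#'
#' VIP over the predictive components:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\|w_a\|)^2 / \sum_a SSY_a}}
#' with p the number of variables and SSY_a the Y sum of squares explained by
#' component a, so that the mean squared VIP is exactly 1.
#'
#' @param model A fitted [fit_opls_da()] model.
#' @param threshold Screening threshold carried along (default 1).
#' @return Object of class `vip_scores`: named per-variable VIP values plus
#'   the threshold.
#' @export
vip <- function(model, threshold = 1) {
  stopifnot(inherits(model, "opls_da"))
  ssy <- model$ssy_expl
  if (sum(ssy) < 1e-12) {
    stop("VIP undefined: the model explains no Y-variance", call. = FALSE)
  }
  W <- model$weights # columns already unit norm
  p <- nrow(W)
  v <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(v) <- rownames(W)
  structure(list(vip = v, threshold = threshold), class = "vip_scores")
}

#' @export
print.vip_scores <- function(x, ...) {
  over <- sum(x$vip > x$threshold)
  cat(sprintf("VIP scores for %d variables; %d above threshold %g\n",
              length(x$vip), over, x$threshold))
  print(utils::head(sort(x$vip, decreasing = TRUE), 10))
  invisible(x)
}

# Seeded stratified fold assignment; every fold's training part must retain
# all classes.
make_folds <- function(classes, k, seed) {
  n <- length(classes)
  if (k < 2L || k > n) stop("need 2 <= k <= n folds", call. = FALSE)
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (l in levels(classes)) {
      idx <- sample(which(classes == l))
      fold[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
      offset <- offset + length(idx)
    }
  })
  for (f in seq_len(k)) {
    train_classes <- unique(classes[fold != f])
    lost <- setdiff(levels(classes), as.character(train_classes))
    if (length(lost)) {
      stop(sprintf("fold %d would lose class %s from the training part",
                   f, paste(lost, collapse = ", ")), call. = FALSE)
    }
  }
  fold
}

#' Cross-validated predictive ability Q2
#'
#' Q2 = 1 - PRESS / SS, with PRESS accumulated over held-out folds of a
#' seeded, class-stratified k-fold split. Preprocessing and the full OPLS-DA
#' model are refit within every training fold; held-out rows are transformed
#' with the training-fold parameters only.
#'
#' @inheritParams fit_opls_da
#' @param k Number of folds (default 7; `k = n` gives leave-one-out).
#' @param seed Seed for the fold assignment.
#' @return List of class `opls_cv`: `q2`, `press`, `ssy`, and the fold
#'   assignment `folds`.
#' @export
cross_validated_q2 <- function(X, classes, n_ortho = 1L, k = 7L, seed = 1L,
                               n_pred = NULL, center = TRUE, scale = TRUE) {
  cd <- class_dummy(classes)
  X <- as.matrix(X)
  fold <- make_folds(cd$classes, k, seed)
  Yc_all <- sweep(cd$Y, 2, colMeans(cd$Y))
  ssy <- sum(Yc_all^2)
  press <- 0
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    if (!any(te)) next
    m <- fit_opls_da(X[tr, , drop = FALSE], cd$classes[tr],
                     n_ortho = n_ortho, n_pred = n_pred,
                     center = center, scale = scale)
    pr <- predict(m, X[te, , drop = FALSE])
    # align dummy columns (training levels order equals full order here)
    press <- press + sum((cd$Y[te, , drop = FALSE] - pr$y)^2)
  }
  structure(list(q2 = 1 - press / ssy, press = press, ssy = ssy,
                 folds = fold), class = "opls_cv")
}

#' Permutation validation of an OPLS-DA model
#'
#' Class labels are randomly permuted `n_perm` times; R2Y and cross-validated
#' Q2 are recomputed for every permutation. The empirical p-value is
#' `(1 + #[Q2_perm >= Q2_obs]) / (n_perm + 1)` and the model is declared
#' valid when p <= 0.05. The regression intercepts of R2Y and Q2 against the
#' permuted-to-original label correlation are reported as a secondary
#' diagnostic, not used as the gate.
#'
#' @inheritParams cross_validated_q2
#' @param n_perm Number of permutations (default 200).
#' @param blocks Optional block identifiers (e.g. batch ids) defining the
#'   exchangeability unit: labels must be constant within a block and whole
#'   blocks are permuted. Replicate observations of one batch are not
#'   exchangeable across batches, so replicate-level tables should be
#'   permuted at batch level to avoid an anti-conservative test.
#' @return Object of class `permutation_summary`.
#' @export
permutation_test <- function(X, classes, n_perm = 200L, n_ortho = 1L,
                             k = 7L, seed = 1L, n_pred = NULL,
                             blocks = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  cd <- class_dummy(classes) # errors on constant labels
  X <- as.matrix(X)
  if (!is.null(blocks)) {
    blocks <- as.character(blocks)
    if (length(blocks) != length(cd$classes)) {
      stop("one block id per observation required", call. = FALSE)
    }
    per_block <- tapply(as.character(cd$classes), blocks,
                        function(x) length(unique(x)))
    if (any(per_block > 1L)) {
      stop("labels must be constant within a block", call. = FALSE)
    }
  }
  obs_fit <- fit_opls_da(X, cd$classes, n_ortho = n_ortho, n_pred = n_pred)
  obs_cv <- cross_validated_q2(X, cd$classes, n_ortho = n_ortho, k = k,
                               seed = substream_seed(seed, "cv-obs"),
                               n_pred = n_pred)
  r2_perm <- q2_perm <- cor_perm <- numeric(n_perm)
  perms <- with_seed(substream_seed(seed, "perm-labels"), {
    if (is.null(blocks)) {
      lapply(seq_len(n_perm), function(i) sample(length(cd$classes)))
    } else {
      ub <- unique(blocks)
      first <- match(ub, blocks) # representative row per block
      lapply(seq_len(n_perm), function(i) {
        donor <- stats::setNames(first[sample(length(ub))], ub)
        unname(donor[blocks])
      })
    }
  })
  for (i in seq_len(n_perm)) {
    cls_p <- cd$classes[perms[[i]]]
    Yp <- cd$Y[perms[[i]], , drop = FALSE]
    cor_perm[i] <- mean(abs(diag(stats::cor(cd$Y, Yp))))
    fit_p <- fit_opls_da(X, cls_p, n_ortho = n_ortho, n_pred = n_pred)
    r2_perm[i] <- fit_p$r2y_cum
    cv_p <- cross_validated_q2(X, cls_p, n_ortho = n_ortho, k = k,
                               seed = substream_seed(seed, paste0("cv", i)),
                               n_pred = n_pred)
    q2_perm[i] <- cv_p$q2
  }
  p <- (1 + sum(q2_perm >= obs_cv$q2)) / (n_perm + 1)
  xx <- c(cor_perm, 1)
  r2_int <- unname(stats::coef(stats::lm(c(r2_perm, obs_fit$r2y_cum) ~ xx))[1])
  q2_int <- unname(stats::coef(stats::lm(c(q2_perm, obs_cv$q2) ~ xx))[1])
  structure(list(
    n_perm = n_perm, r2y_obs = obs_fit$r2y_cum, q2_obs = obs_cv$q2,
    r2y_perm = r2_perm, q2_perm = q2_perm, cor_perm = cor_perm,
    p_value = p, verdict = if (p <= 0.05) "valid" else "not valid",
    r2y_intercept = r2_int, q2_intercept = q2_int
  ), class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations)\n", x$n_perm))
  cat(sprintf("  observed R2Y = %.3f, Q2 = %.3f; empirical p = %.4f (%s)\n",
              x$r2y_obs, x$q2_obs, x$p_value, x$verdict))
  cat(sprintf("  intercepts: R2Y %.3f, Q2 %.3f\n",
              x$r2y_intercept, x$q2_intercept))
  invisible(x)
}

#' Relative content against an internal standard
#'
#' @param areas Observations x analytes matrix (or data frame) of peak areas.
#' @param is_area Internal-standard peak area per observation (> 0).
#' @return Matrix of relative contents, `areas / is_area` row-wise.
#' @export
relative_content <- function(areas, is_area) {
  areas <- as.matrix(areas)
  if (length(is_area) != nrow(areas)) {
    stop("one internal-standard area per observation required", call. = FALSE)
  }
  bad <- which(!is.finite(is_area) | is_area <= 0)
  if (length(bad)) {
    ids <- rownames(areas) %||% as.character(seq_len(nrow(areas)))
    stop("non-positive internal-standard area for observation(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  sweep(areas, 1, is_area, "/")
}

#' Screen differential variables by VIP
#'
#' @param model A fitted [fit_opls_da()] model.
#' @param threshold Variables with VIP strictly greater than this are
#'   flagged (default 1).
#' @return Object of class `differential_set`: tibble of flagged variables
#'   sorted by decreasing VIP, plus platform/comparison tags.
#' @export
screen_differentials <- function(model, threshold = 1) {
  v <- vip(model, threshold)$vip
  flagged <- sort(v[v > threshold], decreasing = TRUE)
  structure(list(
    table = tibble::tibble(variable = names(flagged), vip = unname(flagged)),
    platform = model$platform, comparison = model$comparison,
    threshold = threshold
  ), class = "differential_set")
}

#' @export
print.differential_set <- function(x, ...) {
  cat(sprintf("Differential set%s%s: %d variable(s) with VIP > %g\n",
              if (!is.null(x$platform)) paste0(" [", x$platform, "]") else "",
              if (!is.null(x$comparison)) paste0(" ", x$comparison) else "",
              nrow(x$table), x$threshold))
  print(x$table, n = 10)
  invisible(x)
}

#' Variables shared by every differential set
#'
#' @param sets List of `differential_set` objects from one platform.
#' @return Character vector: the exact intersection of the flagged ids.
#' @export
shared_differentials <- function(sets) {
  if (length(sets) < 1L) stop("need at least one set", call. = FALSE)
  platforms <- unique(unlist(lapply(sets, function(s) s$platform %||% NA)))
  platforms <- platforms[!is.na(platforms)]
  if (length(platforms) > 1L) {
    stop("sets come from different platforms: ",
         paste(platforms, collapse = ", "), call. = FALSE)
  }
  Reduce(intersect, lapply(sets, function(s) s$table$variable))
}

#' Spearman correlation map between two variable blocks
#'
#' Tie-corrected (average-rank) Spearman rho with two-sided p-values from the
#' t approximation; pairs involving a constant column are reported as missing
#' rather than zero.
#'
#' @param A,B Row-aligned matrices or data frames (B defaults to A).
#' @param alpha Significance level for the mask (default 0.05).
#' @return Object of class `correlation_map` with matrices `rho`, `p`,
#'   logical `significant`, plus `alpha` and `n`.
#' @export
spearman_matrix <- function(A, B = NULL, alpha = 0.05) {
  A <- as.matrix(A)
  self <- is.null(B)
  B <- if (self) A else as.matrix(B)
  if (nrow(A) != nrow(B)) stop("A and B must be row-aligned", call. = FALSE)
  n <- nrow(A)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  const_a <- apply(A, 2, function(x) stats::sd(x) < 1e-12)
  const_b <- apply(B, 2, function(x) stats::sd(x) < 1e-12)
  rho <- suppressWarnings(stats::cor(A, B, method = "spearman"))
  rho[const_a, ] <- NA_real_
  rho[, const_b] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-15))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(rho) & abs(rho) >= 1 - 1e-12] <- 0
  if (self) diag(p)[!const_a] <- 0
  structure(list(rho = rho, p = p, significant = p < alpha,
                 alpha = alpha, n = n), class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("Spearman correlation map: %d x %d, n = %d, alpha = %g\n",
              nrow(x$rho), ncol(x$rho), x$n, x$alpha))
  cat(sprintf("  %d significant pair(s)\n", sum(x$significant, na.rm = TRUE)))
  invisible(x)
}
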