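# Independent oracles used to cross-check the package implementations, kept
# deliberately naive (explicit loops, no shared code with R/).

# Plain NIPALS PLS2 run to convergence, deflating X and Y.
oracle_nipals_pls <- function(X, Y, ncomp, tol = 1e-12) {
  X <- scale(X)
  Y <- scale(Y, scale = FALSE)
  scores <- NULL
  weights <- NULL
  for (a in seq_len(ncomp)) {
    u <- Y[, 1]
    t_prev <- rep(Inf, nrow(X))
    repeat {
      w <- drop(t(X) %*% u)
      w <- w / sqrt(sum(w * w))
      tt <- drop(X %*% w)
      cc <- drop(t(Y) %*% tt) / sum(tt * tt)
      u <- drop(Y %*% cc) / sum(cc * cc)
      if (sum((tt - t_prev)^2) < tol^2 * sum(tt * tt)) break
      t_prev <- tt
    }
    p <- drop(t(X) %*% tt) / sum(tt * tt)
    X <- X - outer(tt, p)
    Y <- Y - outer(tt, cc)
    scores <- cbind(scores, tt)
    weights <- cbind(weights, w)
  }
  list(T = scores, W = weights)
}

# Brute-force fuzzy score: explicit double loop over criteria and levels.
oracle_fuzzy_score <- function(w, M, V) {
  b <- 0
  for (i in seq_along(w)) {
    for (j in seq_along(V)) {
      b <- b + w[i] * M[i, j] * V[j]
    }
  }
  b
}

# Spearman rho as Pearson correlation of average ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Number of principal components needed to reach a cumulative-variance
# fraction, from an explicit eigendecomposition of the correlation matrix.
oracle_pca_k <- function(X, cum_var) {
  ev <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  which(cumsum(ev) / sum(ev) >= cum_var - 1e-12)[1]
}

# The default synthetic dataset (seed 42), generated once per test run.
.dataset_cache <- new.env(parent = emptyenv())
default_dataset <- function(seed = 42L) {
  key <- paste0("ds", seed)
  if (is.null(.dataset_cache[[key]])) {
    .dataset_cache[[key]] <- generate_dataset(study_design(seed = seed),
                                              effect_spec(), noise_model())
  }
  .dataset_cache[[key]]
}

named_volatile_shared <- c("atractylone", "aromadendrene", "gamma_elemene",
                           "caryophyllene")
named_nonvolatile_shared <- c("isoatractylode_A", "beta_sitosterol",
                              "atractylenolide_I", "maltose", "sucrose",
                              "dihydroxy_atractylenolide_III")
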