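#' Simulate one E-nose acquisition run
#'
#' Mirrors the acquisition protocol of a metal-oxide sensor array: a sample is
#' injected `n_injections` times in a row, the first injection is discarded as
#' a conditioning run, and the maximum-response feature vector of each
#' retained injection is kept. Each retained response is the non-negative
#' linear combination of the sample's latent odor-class abundances through the
#' sensor loading matrix, times multiplicative log-normal acquisition noise.
#'
#' @param latents Named numeric vector of latent log-abundances (one per
#'   loading-matrix column).
#' @param loadings Non-negative sensor loading matrix (sensors x latents).
#' @param noise A [noise_model()]; only `sigma_acquisition` is used.
#' @param n_injections Total consecutive injections (>= 2; the first is
#'   discarded).
#' @return Matrix of retained responses, `(n_injections - 1)` rows x sensors.
#' @export
simulate_enose_acquisition <- function(latents, loadings, noise,
                                       n_injections = 4L) {
  stopifnot(inherits(noise, "noise_model"))
  if (n_injections < 2L) {
    stop("n_injections must be >= 2: the first injection is discarded and ",
         "nothing would be retained", call. = FALSE)
  }
  latents <- latents[colnames(loadings)]
  if (anyNA(latents)) stop("latents must cover every loading column",
                           call. = FALSE)
  clean <- drop(loadings %*% exp(latents))
  kept <- n_injections - 1L
  eps <- matrix(stats::rnorm(kept * nrow(loadings), 0,
                             noise$sigma_acquisition),
                nrow = kept)
  out <- matrix(rep(clean, each = kept), nrow = kept) * exp(eps)
  colnames(out) <- rownames(loadings)
  out
}

#' Simulate one E-tongue acquisition run
#'
#' A sample is measured `n_measurements` times; the first `n_discard`
#' measurements are discarded (sensor conditioning) and the remaining
#' measurement vectors are averaged into the reported response.
#'
#' @inheritParams simulate_enose_acquisition
#' @param n_measurements Total measurements (default 9).
#' @param n_discard Leading measurements to discard (default 4); must be
#'   smaller than `n_measurements`.
#' @return Named numeric vector: the averaged sensor response.
#' @export
simulate_etongue_acquisition <- function(latents, loadings, noise,
                                         n_measurements = 9L,
                                         n_discard = 4L) {
  stopifnot(inherits(noise, "noise_model"))
  if (n_discard < 0L || n_discard >= n_measurements) {
    stop("need n_measurements > n_discard >= 0", call. = FALSE)
  }
  latents <- latents[colnames(loadings)]
  if (anyNA(latents)) stop("latents must cover every loading column",
                           call. = FALSE)
  clean <- drop(loadings %*% exp(latents))
  kept <- n_measurements - n_discard
  eps <- matrix(stats::rnorm(kept * nrow(loadings), 0,
                             noise$sigma_acquisition),
                nrow = kept)
  resp <- matrix(rep(clean, each = kept), nrow = kept) * exp(eps)
  out <- colMeans(resp)
  names(out) <- rownames(loadings)
  out
}

# Two-level "bracket" probabilities over level values whose expectation equals
# the target score; a concentration exponent sharpens (Inf = degenerate on the
# closest level) or flattens the distribution.
bracket_probs <- function(target, values, concentration = 1) {
  if (target > max(values) || target < min(values)) {
    stop(sprintf("score target %.1f outside the attainable range [%g, %g]",
                 target, min(values), max(values)), call. = FALSE)
  }
  p <- numeric(length(values))
  j <- max(which(values >= target)) # values strictly decreasing
  if (j == length(values) || values[j] == target) {
    p[j] <- 1
  } else {
    w <- (target - values[j + 1L]) / (values[j] - values[j + 1L])
    p[j] <- w
    p[j + 1L] <- 1 - w
  }
  if (is.infinite(concentration)) {
    out <- numeric(length(values))
    out[which.max(p)] <- 1
    return(out)
  }
  p <- p^concentration
  p / sum(p)
}

#' Generate evaluator count tables for the fuzzy sensory panel
#'
#' For each batch and each of the four sensory criteria, draws the number of
#' panel evaluators assigning each of the four quality levels from a
#' multinomial whose expectation places the fuzzy score (under the default
#' weights and level values) near the batch's target score.
#'
#' @param design A [study_design()].
#' @param score_targets Named numeric vector of target scores per group.
#' @param panel_size Number of evaluators (default 10).
#' @param levels Strictly decreasing numeric level values (default
#'   `c(90, 70, 50, 30)`).
#' @param concentration Sharpening exponent on the level distribution;
#'   `Inf` puts all evaluators on the level closest to the target.
#' @param criteria Criterion names (default: the four appearance criteria).
#' @param batch_targets Optional named per-batch targets overriding the group
#'   targets (used by [generate_dataset()] for compound-coupled targets).
#' @param seed Optional seed; defaults to a substream of the design seed.
#' @return Long tibble: `batch_id`, `criterion`, `level` (1 = best), `count`.
#' @export
generate_evaluator_counts <- function(design,
                                      score_targets = c("ZJ" = 75,
                                                        "AH-HN-1" = 68,
                                                        "AH-HN-2" = 52,
                                                        "HB" = 46),
                                      panel_size = 10L,
                                      levels = c(90, 70, 50, 30),
                                      concentration = 1,
                                      criteria = c("sectional_color",
                                                   "chrysanthemum_pattern",
                                                   "oil_spots",
                                                   "number_per_kg"),
                                      batch_targets = NULL,
                                      seed = NULL) {
  stopifnot(inherits(design, "study_design"), panel_size >= 1L,
            all(diff(levels) < 0))
  batches <- design_batches(design)
  if (is.null(batch_targets)) {
    missing_groups <- setdiff(batches$group, names(score_targets))
    if (length(missing_groups)) {
      stop("no score target for group(s): ",
           paste(missing_groups, collapse = ", "), call. = FALSE)
    }
    batch_targets <- stats::setNames(score_targets[batches$group],
                                     batches$batch_id)
  }
  # validate all targets up front so a bad target fails before any draw
  for (t in batch_targets) bracket_probs(t, levels, concentration)
  seed <- seed %||% substream_seed(design$seed, "sensory-counts")
  with_seed(seed, {
    rows <- lapply(batches$batch_id, function(b) {
      probs <- bracket_probs(batch_targets[[b]], levels, concentration)
      counts <- vapply(criteria, function(cr) {
        drop(stats::rmultinom(1, panel_size, probs))
      }, numeric(length(levels)))
      tibble::tibble(
        batch_id = b,
        criterion = rep(criteria, each = length(levels)),
        level = rep(seq_along(levels), times = length(criteria)),
        count = as.integer(counts)
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "panel_size") <- as.integer(panel_size)
    attr(out, "level_values") <- levels
    out
  })
}

# Simulate one compound platform (volatile or non-volatile) on the log scale:
# baseline + planted group effect (in pooled-SD units) + shared batch factor
# + per-compound batch noise + per-replicate preparation noise + acquisition
# noise. Values are exponentiated, hence strictly positive.
simulate_compound_table <- function(batches, replicates, mu, lambda, effects,
                                    noise, seed) {
  with_seed(seed, {
    sp <- pooled_sd(noise)
    p <- length(mu)
    nb <- nrow(batches)
    # shared technical factor (sample amount / matrix), balanced across
    # groups: acquisition-order randomisation keeps it class-orthogonal
    shared <- stats::rnorm(nb, 0, noise$sigma_shared)
    shared <- shared - stats::ave(shared, batches$group)
    batch_noise <- matrix(stats::rnorm(nb * p, 0, noise$sigma_batch), nb, p)
    batch_log <- matrix(mu, nb, p, byrow = TRUE) +
      sp * t(effects[, batches$group, drop = FALSE]) +
      outer(shared, lambda) + batch_noise
    obs <- batches[rep(seq_len(nb), each = replicates), ]
    obs$replicate <- rep(seq_len(replicates), times = nb)
    n <- nrow(obs)
    rep_noise <- matrix(stats::rnorm(n * p, 0, noise$sigma_replicate), n, p)
    acq_noise <- matrix(stats::rnorm(n * p, 0, noise$sigma_acquisition), n, p)
    logx <- batch_log[rep(seq_len(nb), each = replicates), , drop = FALSE] +
      rep_noise + acq_noise
    x <- exp(logx)
    colnames(x) <- names(mu)
    dplyr::bind_cols(obs, tibble::as_tibble(x))
  })
}

# Simulate a sensor platform: batch-level latent log-abundances (group mean +
# batch noise), per-replicate preparation noise on the latents, then the
# platform's acquisition protocol per replicate.
simulate_sensor_table <- function(batches, replicates, latent_means, loadings,
                                  noise, seed, protocol = c("enose", "etongue")) {
  protocol <- match.arg(protocol)
  with_seed(seed, {
    nb <- nrow(batches)
    k <- nrow(latent_means)
    grade_varying <- rownames(latent_means) != "background"
    sds <- ifelse(grade_varying, noise$sensor_latent_sd,
                  noise$sensor_background_sd)
    lat_noise <- matrix(stats::rnorm(k * nb, 0, sds), k, nb)
    # grade-constant background latents are balanced across groups (see
    # the shared-factor note in simulate_compound_table)
    for (i in which(!grade_varying)) {
      lat_noise[i, ] <- lat_noise[i, ] - stats::ave(lat_noise[i, ],
                                                    batches$group)
    }
    batch_latents <- latent_means[, batches$group, drop = FALSE] + lat_noise
    rows <- vector("list", nb * replicates)
    idx <- 0L
    for (b in seq_len(nb)) {
      for (r in seq_len(replicates)) {
        lat <- batch_latents[, b] +
          stats::rnorm(k, 0, noise$sigma_replicate)
        names(lat) <- rownames(latent_means)
        resp <- if (protocol == "enose") {
          colMeans(simulate_enose_acquisition(lat, loadings, noise,
                                              n_injections = 4L))
        } else {
          simulate_etongue_acquisition(lat, loadings, noise,
                                       n_measurements = 9L, n_discard = 4L)
        }
        idx <- idx + 1L
        rows[[idx]] <- resp
      }
    }
    x <- do.call(rbind, rows)
    obs <- batches[rep(seq_len(nb), each = replicates), ]
    obs$replicate <- rep(seq_len(replicates), times = nb)
    dplyr::bind_cols(obs, tibble::as_tibble(x))
  })
}

#' Generate a complete synthetic multi-platform grading dataset
#'
#' Produces row-aligned feature tables for the four measurement platforms
#' (volatile relative contents, non-volatile peak areas, E-nose maximum
#' responses, E-tongue averaged responses), an evaluator-count table for the
#' fuzzy sensory panel, and the planted ground truth. Identical inputs and
#' seed give bit-identical output.
#'
#' @param design A [study_design()] (its `seed` drives all randomness).
#' @param effects An [effect_spec()].
#' @param noise A [noise_model()].
#' @return An object of class `amr_dataset`: tibbles `volatile`,
#'   `nonvolatile`, `enose`, `etongue` (metadata columns `batch_id`, `group`,
#'   `grade`, `replicate`, then feature columns), `evaluator_counts`, and
#'   `truth` (the effect spec plus realized per-batch sensory targets).
#' @export
generate_dataset <- function(design = study_design(),
                             effects = effect_spec(),
                             noise = noise_model()) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_spec"),
            inherits(noise, "noise_model"))
  panel <- effects$panel
  for (s in effects$volatile_sets) check_ids(s, panel$volatile$id, "volatile")
  for (s in effects$nonvolatile_sets) {
    check_ids(s, panel$nonvolatile$id, "non-volatile")
  }
  batches <- design_batches(design)
  R <- design$replicates

  volatile <- simulate_compound_table(
    batches, R, effects$baselines$volatile_mu,
    effects$baselines$volatile_lambda,
    effects$volatile_effects, noise,
    substream_seed(design$seed, "volatile")
  )
  nonvolatile <- simulate_compound_table(
    batches, R, effects$baselines$nonvolatile_mu,
    effects$baselines$nonvolatile_lambda,
    effects$nonvolatile_effects, noise,
    substream_seed(design$seed, "nonvolatile")
  )
  enose <- simulate_sensor_table(
    batches, R, effects$enose_latent_means, effects$enose_loadings, noise,
    substream_seed(design$seed, "enose"), protocol = "enose"
  )
  etongue <- simulate_sensor_table(
    batches, R, effects$etongue_latent_means, effects$etongue_loadings, noise,
    substream_seed(design$seed, "etongue"), protocol = "etongue"
  )

  # Sensory targets: group base target plus positive coupling to the batch's
  # levels of the four score-associated compounds (standardized across
  # batches), truncated to the attainable score range.
  cc <- effects$sensory$coupled_compounds
  vol_b <- batch_level(volatile)
  non_b <- batch_level(nonvolatile)
  lev <- cbind(
    as.matrix(log(vol_b[, intersect(cc, names(vol_b)), drop = FALSE])),
    as.matrix(log(non_b[, intersect(cc, names(non_b)), drop = FALSE]))
  )
  # within-group standardisation: the coupling adds batch-level association
  # on top of the group base targets instead of re-encoding the group pattern
  z <- apply(lev, 2, function(x) {
    r <- x - stats::ave(x, batches$group)
    r / stats::sd(r)
  })
  zbar <- rowMeans(z)
  base <- effects$sensory$base_targets[batches$group]
  targets <- pmin(pmax(base + effects$sensory$kappa * zbar, 32), 88)
  names(targets) <- batches$batch_id
  counts <- generate_evaluator_counts(
    design, batch_targets = targets,
    seed = substream_seed(design$seed, "sensory-counts")
  )

  structure(list(
    volatile = volatile, nonvolatile = nonvolatile,
    enose = enose, etongue = etongue,
    evaluator_counts = counts,
    truth = list(effects = effects, batch_targets = targets,
                 pooled_sd = pooled_sd(noise)),
    design = design, noise = noise
  ), class = "amr_dataset")
}

#' @export
print.amr_dataset <- function(x, ...) {
  cat("Synthetic AMR grading dataset\n")
  cat(sprintf("  %d batches x %d replicates = %d observations per platform\n",
              sum(x$design$groups$n_batches), x$design$replicates,
              nrow(x$volatile)))
  cat(sprintf("  volatile: %d compounds | nonvolatile: %d | E-nose: %d sensors | E-tongue: %d\n",
              ncol(x$volatile) - 4L, ncol(x$nonvolatile) - 4L,
              ncol(x$enose) - 4L, ncol(x$etongue) - 4L))
  invisible(x)
}
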