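# Dataset-level differential screening: pairwise compound models against the
# genuine-origin reference group, multiclass sensor models, and the Spearman
# maps linking sensors, compounds and sensory scores.

#' Extract a model-ready feature matrix from a dataset platform
#'
#' Compound platforms are analysed at batch level (replicates averaged, one
#' row per batch); sensor platforms at replicate level.
#'
#' @param dataset An `amr_dataset`.
#' @param platform One of `"volatile"`, `"nonvolatile"`, `"enose"`,
#'   `"etongue"`.
#' @param level `"batch"` or `"replicate"`; defaults to the platform's
#'   convention.
#' @param ion_mode For the non-volatile platform, restrict to `"positive"`
#'   or `"negative"` mode columns.
#' @return List with matrix `X` and metadata tibble `meta`.
#' @export
platform_matrix <- function(dataset,
                            platform = c("volatile", "nonvolatile",
                                         "enose", "etongue"),
                            level = NULL, ion_mode = NULL) {
  platform <- match.arg(platform)
  level <- level %||%
    if (platform %in% c("volatile", "nonvolatile")) "batch" else "replicate"
  tbl <- dataset[[platform]]
  if (!is.null(ion_mode)) {
    if (platform != "nonvolatile") {
      stop("ion_mode only applies to the non-volatile platform",
           call. = FALSE)
    }
    panel <- dataset$truth$effects$panel$nonvolatile
    keep <- panel$id[panel$ion_mode == ion_mode]
    tbl <- tbl[, c(META_COLS, intersect(names(tbl), keep))]
  }
  if (level == "batch") {
    tbl <- batch_level(tbl)
    meta <- tbl[, c("batch_id", "group", "grade")]
    X <- as.matrix(tbl[, setdiff(names(tbl), c("batch_id", "group", "grade"))])
    rownames(X) <- tbl$batch_id
  } else {
    meta <- tbl[, META_COLS]
    X <- feature_matrix(tbl)
  }
  list(X = X, meta = meta)
}

#' Screen one pairwise contrast against the reference group
#'
#' Fits a two-class OPLS-DA for `reference` vs `group`, optionally validates
#' it with a permutation test, and flags VIP > threshold variables. When
#' gating is on and the permutation verdict is "not valid", the returned
#' differential set is empty.
#'
#' @inheritParams platform_matrix
#' @param group Group contrasted against the reference.
#' @param reference Reference group (default `"ZJ"`).
#' @param n_ortho Orthogonal components (default 1).
#' @param threshold VIP threshold (default 1).
#' @param gate_permutation Gate the set on permutation validity
#'   (default TRUE).
#' @param n_perm Permutations for the gate (default 200; 0 skips the test
#'   and the gate).
#' @param seed Seed for cross-validation folds and permutations.
#' @return List with `set` (a `differential_set`), `model`, and `permutation`
#'   (a `permutation_summary` or NULL).
#' @export
screen_contrast <- function(dataset, platform, group, reference = "ZJ",
                            ion_mode = NULL, n_ortho = 1L, threshold = 1,
                            gate_permutation = TRUE, n_perm = 200L,
                            seed = 1L) {
  pm <- platform_matrix(dataset, platform, ion_mode = ion_mode)
  keep <- pm$meta$group %in% c(reference, group)
  X <- pm$X[keep, , drop = FALSE]
  cls <- factor(pm$meta$group[keep], levels = c(reference, group))
  comparison <- paste(reference, "vs", group)
  model <- fit_opls_da(X, cls, n_ortho = n_ortho,
                       platform = paste(c(platform, ion_mode), collapse = "."),
                       comparison = comparison)
  perm <- NULL
  valid <- TRUE
  if (n_perm > 0L) {
    perm <- permutation_test(X, cls, n_perm = n_perm, n_ortho = n_ortho,
                             seed = substream_seed(seed, comparison))
    if (gate_permutation) valid <- perm$verdict == "valid"
  }
  set <- screen_differentials(model, threshold)
  if (!valid) set$table <- set$table[0, ]
  set$platform <- platform # union over ion modes shares one platform tag
  list(set = set, model = model, permutation = perm)
}

# Merge differential sets (e.g. positive + negative ion mode) into one.
union_sets <- function(sets, platform, comparison) {
  tab <- dplyr::bind_rows(lapply(sets, function(s) s$table))
  tab <- dplyr::arrange(tab[!duplicated(tab$variable), ], dplyr::desc(.data$vip))
  structure(list(table = tab, platform = platform, comparison = comparison,
                 threshold = sets[[1]]$threshold), class = "differential_set")
}

#' Differential screening of a compound platform across all ZJ contrasts
#'
#' Runs the pairwise OPLS-DA screenings of the reference group against every
#' other group. The non-volatile platform is modelled per ion mode (positive
#' and negative) and each contrast's set is the union over modes, mirroring
#' the separate pos/neg LC-MS models.
#'
#' @inheritParams screen_contrast
#' @param platform `"volatile"` or `"nonvolatile"`.
#' @return List with `sets` (one `differential_set` per contrast), `shared`
#'   (their intersection), `union` (all flagged ids), `models` and
#'   `permutations`.
#' @export
differential_screening <- function(dataset,
                                   platform = c("volatile", "nonvolatile"),
                                   reference = "ZJ", n_ortho = 1L,
                                   threshold = 1, gate_permutation = TRUE,
                                   n_perm = 200L, seed = 1L) {
  platform <- match.arg(platform)
  groups <- setdiff(dataset$design$groups$group, reference)
  modes <- if (platform == "nonvolatile") c("positive", "negative") else NA
  sets <- list()
  models <- list()
  perms <- list()
  for (g in groups) {
    comparison <- paste(reference, "vs", g)
    parts <- lapply(modes, function(m) {
      screen_contrast(dataset, platform, g, reference,
                      ion_mode = if (is.na(m)) NULL else m,
                      n_ortho = n_ortho, threshold = threshold,
                      gate_permutation = gate_permutation,
                      n_perm = n_perm, seed = seed)
    })
    names(parts) <- if (all(is.na(modes))) "all" else modes
    sets[[comparison]] <- if (length(parts) == 1L) {
      parts[[1]]$set
    } else {
      union_sets(lapply(parts, `[[`, "set"), platform, comparison)
    }
    models[[comparison]] <- lapply(parts, `[[`, "model")
    perms[[comparison]] <- lapply(parts, `[[`, "permutation")
  }
  list(sets = sets, shared = shared_differentials(sets),
       union = sort(unique(unlist(lapply(sets, function(s) s$table$variable)))),
       models = models, permutations = perms)
}

#' Multiclass sensor screening of an E-nose or E-tongue table
#'
#' Fits a four-grade multiclass OPLS-DA on the replicate-level sensor table
#' and flags sensors with VIP > threshold, optionally gated on the
#' permutation verdict.
#'
#' @inheritParams screen_contrast
#' @param platform `"enose"` or `"etongue"`.
#' @return List with `set`, `model` and `permutation`.
#' @export
sensor_screening <- function(dataset, platform = c("enose", "etongue"),
                             n_ortho = 1L, threshold = 1,
                             gate_permutation = TRUE, n_perm = 200L,
                             seed = 1L) {
  platform <- match.arg(platform)
  pm <- platform_matrix(dataset, platform)
  cls <- factor(pm$meta$group,
                levels = dataset$design$groups$group)
  model <- fit_opls_da(pm$X, cls, n_ortho = n_ortho, platform = platform,
                       comparison = "multiclass")
  perm <- NULL
  valid <- TRUE
  if (n_perm > 0L) {
    # replicate rows of one batch are not exchangeable across batches:
    # permute whole batches
    perm <- permutation_test(pm$X, cls, n_perm = n_perm, n_ortho = n_ortho,
                             seed = substream_seed(seed, platform),
                             blocks = pm$meta$batch_id)
    if (gate_permutation) valid <- perm$verdict == "valid"
  }
  set <- screen_differentials(model, threshold)
  if (!valid) set$table <- set$table[0, ]
  list(set = set, model = model, permutation = perm)
}

#' Spearman map between flagged sensors and differential compounds
#'
#' Correlates batch-level responses of the flagged sensors with batch-level
#' contents of the differential compounds (E-nose against the volatile
#' platform, E-tongue against the non-volatile platform).
#'
#' @param dataset An `amr_dataset`.
#' @param sensor_set `differential_set` of flagged sensors.
#' @param compound_set Character vector of differential compound ids.
#' @param alpha Significance level.
#' @return A `correlation_map` (sensors x compounds).
#' @export
sensor_compound_map <- function(dataset, sensor_set, compound_set,
                                alpha = 0.05) {
  sensor_platform <- sensor_set$platform
  compound_platform <- if (sensor_platform == "enose") "volatile" else "nonvolatile"
  sm <- platform_matrix(dataset, sensor_platform, level = "batch")
  cm <- platform_matrix(dataset, compound_platform, level = "batch")
  stopifnot(identical(sm$meta$batch_id, cm$meta$batch_id))
  spearman_matrix(sm$X[, sensor_set$table$variable, drop = FALSE],
                  cm$X[, compound_set, drop = FALSE], alpha = alpha)
}

#' Spearman map between batch sensory scores and compound contents
#'
#' @param dataset An `amr_dataset`.
#' @param scores Per-batch score tibble from [score_batches()]; computed from
#'   the dataset's evaluator counts when omitted.
#' @param compounds Compound ids (volatile or non-volatile) to correlate.
#' @param alpha Significance level.
#' @return A `correlation_map` (score x compounds).
#' @export
sensory_compound_map <- function(dataset, scores = NULL,
                                 compounds = NULL, alpha = 0.05) {
  scores <- scores %||% score_batches(dataset$evaluator_counts)
  compounds <- compounds %||% dataset$truth$effects$sensory$coupled_compounds
  vm <- platform_matrix(dataset, "volatile", level = "batch")
  nm <- platform_matrix(dataset, "nonvolatile", level = "batch")
  stopifnot(identical(vm$meta$batch_id, nm$meta$batch_id))
  X <- cbind(vm$X, nm$X)
  scores <- scores[match(vm$meta$batch_id, scores$batch_id), ]
  spearman_matrix(matrix(scores$score, ncol = 1,
                         dimnames = list(NULL, "sensory_score")),
                  X[, compounds, drop = FALSE], alpha = alpha)
}
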