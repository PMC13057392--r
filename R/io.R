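# Readers, writers, configuration and the end-to-end pipeline.

#' Read a platform feature table from CSV or TSV
#'
#' The delimiter is sniffed from the header line (tab wins over comma when
#' both occur, tabs being rarer in compound names). The four metadata columns
#' `batch_id`, `group`, `grade`, `replicate` are required; all remaining
#' columns must parse as numbers; duplicate (batch_id, replicate) keys are
#' rejected.
#'
#' @param path File path.
#' @param platform Optional platform tag attached to the result.
#' @return Tibble with metadata then feature columns, attribute `platform`.
#' @export
read_feature_table <- function(path, platform = NULL) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_meta <- setdiff(META_COLS, names(tbl))
  if (length(missing_meta)) {
    stop("missing metadata column(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(tbl$batch_id, tbl$replicate, sep = ".")
  if (anyDuplicated(key)) {
    stop("duplicate (batch_id, replicate) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  vars <- setdiff(names(tbl), META_COLS)
  for (v in vars) {
    if (!is.numeric(tbl[[v]])) {
      suppressWarnings(num <- as.numeric(tbl[[v]]))
      bad <- which(is.na(num) & !is.na(tbl[[v]]))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                     v, bad[1], tbl[[v]][bad[1]]), call. = FALSE)
      }
      tbl[[v]] <- num
    }
  }
  attr(tbl, "platform") <- platform
  tbl
}

#' Write a platform feature table as CSV
#'
#' @param tbl Feature table (metadata columns first).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(tbl, path) {
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' One CSV per platform, the evaluator counts in long format, and the planted
#' truth record as JSON.
#'
#' @param dataset An `amr_dataset`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    volatile = file.path(dir, "volatile.csv"),
    nonvolatile = file.path(dir, "nonvolatile.csv"),
    enose = file.path(dir, "enose.csv"),
    etongue = file.path(dir, "etongue.csv")
  )
  for (p in names(paths)) write_feature_table(dataset[[p]], paths[[p]])
  counts_path <- file.path(dir, "evaluator_counts.csv")
  readr::write_csv(dataset$evaluator_counts, counts_path, progress = FALSE)
  truth_path <- file.path(dir, "truth.json")
  eff <- dataset$truth$effects
  truth <- list(
    effect_scale = eff$effect_scale,
    volatile_sets = eff$volatile_sets,
    nonvolatile_sets = eff$nonvolatile_sets,
    volatile_effects = eff$volatile_effects,
    nonvolatile_effects = eff$nonvolatile_effects,
    informative_enose = eff$informative_enose,
    informative_etongue = eff$informative_etongue,
    batch_targets = as.list(dataset$truth$batch_targets),
    pooled_sd = dataset$truth$pooled_sd
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(c(paths, counts = counts_path, truth = truth_path))
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Unknown keys are rejected so
#' configs round-trip losslessly through YAML.
#'
#' @param seed Master seed; each stage draws from a named substream of it.
#' @param replicates Replicates per batch.
#' @param effect_scale Multiplier on all planted effects.
#' @param n_ortho Orthogonal components of every OPLS-DA model.
#' @param n_perm Permutations for model validation (0 skips the stage).
#' @param vip_threshold VIP screening threshold.
#' @param alpha Significance level of the correlation maps.
#' @param cv_folds Cross-validation folds.
#' @param train_frac,study_size,group_by_batch Split settings.
#' @param cum_var PCA cumulative-variance cutoff.
#' @param out_dir Output directory.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed = 42L, replicates = 5L, effect_scale = 1,
                            n_ortho = 1L, n_perm = 200L, vip_threshold = 1,
                            alpha = 0.05, cv_folds = 7L, train_frac = 0.7,
                            study_size = TRUE, group_by_batch = FALSE,
                            cum_var = 0.95, out_dir = "results") {
  structure(list(
    seed = as.integer(seed), replicates = as.integer(replicates),
    effect_scale = effect_scale, n_ortho = as.integer(n_ortho),
    n_perm = as.integer(n_perm), vip_threshold = vip_threshold,
    alpha = alpha, cv_folds = as.integer(cv_folds),
    train_frac = train_frac, study_size = study_size,
    group_by_batch = group_by_batch, cum_var = cum_var, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read and write pipeline configurations as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns a validated `pipeline_config`;
#'   `write_config` returns the path invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full grading pipeline
#'
#' Executes, in order: synthetic-data simulation, fuzzy sensory grading,
#' pairwise OPLS-DA screening of both compound platforms with shared-set
#' intersections, multiclass sensor screening, sensor-compound and
#' sensory-compound Spearman maps, and fused grade classification. All
#' artifacts are written under `config$out_dir` together with a run manifest.
#' The run is fully deterministic at a fixed seed; any stage error aborts
#' with the stage name after writing a partial manifest.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list of class `run_manifest`), invisibly
#'   returning all stage results in its `results` element.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    version = as.character(utils::packageVersion("amrgrade")),
    stages = list(), files = character(0)
  )
  results <- list()
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    value <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest(manifest, out, partial = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    value
  }
  add_files <- function(paths) {
    manifest$files <<- c(manifest$files, unname(paths))
  }

  ds <- run_stage("simulate", function() {
    design <- study_design(replicates = config$replicates,
                           seed = substream_seed(config$seed, "simulate"))
    generate_dataset(design, effect_spec(effect_scale = config$effect_scale),
                     noise_model())
  })
  add_files(run_stage("write-data", function() {
    write_dataset(ds, file.path(out, "data"))
  }))

  results$sensory <- run_stage("sensory-grading", function() {
    sc <- score_batches(ds$evaluator_counts)
    readr::write_csv(sc, file.path(out, "sensory_scores.csv"),
                     progress = FALSE)
    sc
  })
  add_files(file.path(out, "sensory_scores.csv"))

  seed_screen <- substream_seed(config$seed, "screening")
  for (pf in c("volatile", "nonvolatile")) {
    results[[paste0("screen_", pf)]] <- run_stage(
      paste0("screen-", pf), function() {
        ds_res <- differential_screening(
          ds, platform = pf, n_ortho = config$n_ortho,
          threshold = config$vip_threshold, n_perm = config$n_perm,
          gate_permutation = config$n_perm > 0L, seed = seed_screen
        )
        tab <- dplyr::bind_rows(lapply(names(ds_res$sets), function(cmp) {
          dplyr::mutate(ds_res$sets[[cmp]]$table, comparison = cmp,
                        platform = pf)
        }))
        readr::write_csv(tab, file.path(out, paste0(pf, "_differentials.csv")),
                         progress = FALSE)
        ds_res
      })
    add_files(file.path(out, paste0(pf, "_differentials.csv")))
  }
  if (config$n_perm == 0L) {
    manifest$stages[["permutation-validation"]] <-
      list(status = "skipped", message = "n_perm = 0")
  }

  for (pf in c("enose", "etongue")) {
    results[[paste0("screen_", pf)]] <- run_stage(
      paste0("screen-", pf), function() {
        sr <- sensor_screening(ds, platform = pf, n_ortho = config$n_ortho,
                               threshold = config$vip_threshold,
                               n_perm = config$n_perm,
                               gate_permutation = config$n_perm > 0L,
                               seed = seed_screen)
        readr::write_csv(sr$set$table,
                         file.path(out, paste0(pf, "_sensors.csv")),
                         progress = FALSE)
        sr
      })
    add_files(file.path(out, paste0(pf, "_sensors.csv")))
  }

  results$correlations <- run_stage("spearman-maps", function() {
    maps <- list()
    if (nrow(results$screen_enose$set$table)) {
      maps$enose <- sensor_compound_map(
        ds, results$screen_enose$set,
        results$screen_volatile$union, alpha = config$alpha)
    }
    if (nrow(results$screen_etongue$set$table)) {
      maps$etongue <- sensor_compound_map(
        ds, results$screen_etongue$set,
        results$screen_nonvolatile$union, alpha = config$alpha)
    }
    maps$sensory <- sensory_compound_map(ds, results$sensory,
                                         alpha = config$alpha)
    for (nm in names(maps)) {
      utils::write.csv(maps[[nm]]$rho,
                       file.path(out, paste0("spearman_", nm, "_rho.csv")))
      utils::write.csv(maps[[nm]]$p,
                       file.path(out, paste0("spearman_", nm, "_p.csv")))
    }
    maps
  })
  cor_names <- names(results$correlations)
  add_files(file.path(out, c(paste0("spearman_", cor_names, "_rho.csv"),
                             paste0("spearman_", cor_names, "_p.csv"))))

  results$classification <- run_stage("fusion-classification", function() {
    cmp <- compare_sources(
      ds,
      classifier_config(seed = substream_seed(config$seed, "classifiers")),
      split_spec(train_frac = config$train_frac,
                 seed = substream_seed(config$seed, "split"),
                 study_size = config$study_size,
                 group_by_batch = config$group_by_batch),
      cum_var = config$cum_var
    )
    readr::write_csv(cmp$report, file.path(out, "classification_report.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      lapply(cmp$confusion, function(src) lapply(src, unclass)),
      file.path(out, "confusion_matrices.json"), digits = NA
    )
    cmp
  })
  add_files(file.path(out, c("classification_report.csv",
                             "confusion_matrices.json")))

  manifest$results <- results
  manifest$dataset <- ds
  write_manifest(manifest, out, partial = FALSE)
  manifest$files <- c(manifest$files, file.path(out, "manifest.json"))
  structure(manifest, class = "run_manifest")
}

write_manifest <- function(manifest, out, partial = FALSE) {
  keep <- manifest[c("config", "config_hash", "seed", "version", "stages",
                     "files")]
  keep$partial <- partial
  keep$files <- as.list(keep$files)
  jsonlite::write_json(keep, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(keep)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run", x$config_hash, "\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-24s %s%s\n", nm, s$status,
                if (!is.null(s$seconds)) sprintf(" (%.1fs)", s$seconds) else ""))
  }
  cat(length(x$files), "files under", x$config$out_dir, "\n")
  invisible(x)
}
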