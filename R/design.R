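#' Study design for the four-grade AMR batch structure
#'
#' The default design mirrors the commercial grading study the package
#' emulates: 39 batches of dried Atractylodis Macrocephalae Rhizoma in four
#' specification groups -- the Zhejiang genuine-origin specification (ZJ,
#' grade 1, 10 batches), two Anhui/Henan grades (AH-HN-1, grade 2, 13 batches;
#' AH-HN-2, grade 3, 7 batches) and the Hebei specification (HB, grade 4,
#' 9 batches) -- each observed as 5 replicate preparations, for 195
#' observations per platform.
#'
#' @param groups A data frame with columns `group`, `grade`, `n_batches`.
#' @param replicates Replicate observations per batch (default 5).
#' @param seed Integer seed controlling every random draw of the generator.
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups = NULL, replicates = 5L, seed = 42L) {
  if (is.null(groups)) {
    groups <- tibble::tibble(
      group = c("ZJ", "AH-HN-1", "AH-HN-2", "HB"),
      grade = c("grade-1", "grade-2", "grade-3", "grade-4"),
      n_batches = c(10L, 13L, 7L, 9L)
    )
  }
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("group", "grade", "n_batches") %in% names(groups)))
  if (any(groups$n_batches < 1L)) {
    stop("every group needs at least one batch", call. = FALSE)
  }
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  structure(
    list(groups = groups, replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", sum(x$groups$n_batches), "batches x",
      x$replicates, "replicates (seed", paste0(x$seed, ")\n"))
  print(x$groups)
  invisible(x)
}

# Batch metadata table implied by a design: batch_id, group, grade.
design_batches <- function(design) {
  g <- design$groups
  tibble::tibble(
    batch_id = unlist(lapply(seq_len(nrow(g)), function(i) {
      sprintf("%s-%02d", g$group[i], seq_len(g$n_batches[i]))
    })),
    group = rep(g$group, g$n_batches),
    grade = rep(g$grade, g$n_batches)
  )
}

#' Default compound panel for the volatile and non-volatile platforms
#'
#' 49 volatile constituents (HS-GC-MS relative-content variables, 22 of them
#' shared peaks across grades) and 51 non-volatile constituents (LC-MS
#' peak-area variables with an ion-mode annotation, 31 positive / 20
#' negative). The ten compounds with documented grade behaviour carry their
#' real names; the remainder are synthetic placeholders (`V..`/`N..`) whose
#' identity is irrelevant to the computations.
#'
#' @return A list with tibbles `volatile` (id, name, class, shared_peak) and
#'   `nonvolatile` (id, name, ion_mode).
#' @export
compound_panel <- function() {
  named_v <- tibble::tibble(
    id = c("caryophyllene", "gamma_elemene", "aromadendrene", "atractylone"),
    name = c("caryophyllene", "γ-elemene", "aromadendrene", "atractylone"),
    class = c("sesquiterpene", "sesquiterpene", "sesquiterpene",
              "oxygenated_sesquiterpene")
  )
  other_v_id <- sprintf("V%02d", 5:49)
  classes <- c("sesquiterpene", "oxygenated_sesquiterpene", "monoterpene",
               "ester", "alkane")
  volatile <- dplyr::bind_rows(
    named_v,
    tibble::tibble(id = other_v_id, name = other_v_id,
                   class = classes[(seq_along(other_v_id) - 1L) %% 5L + 1L])
  )
  # 22 shared peaks: the four majors plus 18 placeholders.
  volatile$shared_peak <- volatile$id %in% c(named_v$id, sprintf("V%02d", 5:22))

  named_n <- tibble::tibble(
    id = c("isoatractylode_A", "beta_sitosterol", "atractylenolide_I",
           "maltose", "sucrose", "dihydroxy_atractylenolide_III"),
    name = c("isoatractylode A", "β-sitosterol", "atractylenolide I",
             "maltose", "sucrose",
             "6,9-dihydroxy-3,3a-dihydro atractylenolide III"),
    ion_mode = c("positive", "positive", "positive", "negative", "negative",
                 "positive")
  )
  other_n_id <- sprintf("N%02d", 7:51)
  # Positive mode: N07..N14 (A-set), N19..N23 (B-set), N26..N39 (nulls);
  # with the 4 named positives that makes 31 positive / 20 negative.
  pos <- c(sprintf("N%02d", 7:14), sprintf("N%02d", 19:23),
           sprintf("N%02d", 26:39))
  nonvolatile <- dplyr::bind_rows(
    named_n,
    tibble::tibble(id = other_n_id, name = other_n_id,
                   ion_mode = ifelse(other_n_id %in% pos,
                                     "positive", "negative"))
  )
  list(volatile = volatile, nonvolatile = nonvolatile)
}

#' Sensor panels of the electronic nose and tongue
#'
#' @return A list with character vectors `enose` (18 metal-oxide sensors,
#'   S1..S18) and `etongue` (7 taste sensors).
#' @export
sensor_panel <- function() {
  list(
    enose = paste0("S", 1:18),
    etongue = c("AHS", "PKS", "CTS", "NMS", "CPS", "ANS", "SCS")
  )
}

#' Planted effect specification for the synthetic generator
#'
#' Encodes, per platform, which variables differ between grade groups and by
#' how much, in units of the pooled within-group log-scale standard deviation
#' of a single replicate observation:
#'
#' * Volatile: the four shared majors (atractylone, aromadendrene,
#'   \eqn{\gamma}-elemene, caryophyllene) follow the grade ordering
#'   AH-HN-1 > AH-HN-2 > ZJ > HB; 12 further compounds shift equally in both
#'   AH-HN groups and 9 only in HB, so each ZJ contrast flags a clean set and
#'   the three-way intersection is exactly the four majors (union 25).
#' * Non-volatile: six named compounds differ from ZJ in every contrast
#'   (isoatractylode A and atractylenolide I higher in ZJ than HB, sucrose
#'   higher in HB than ZJ); 12 AH-shifted and 7 HB-shifted placeholders bring
#'   the union to 25 (17 positive / 8 negative mode) with the six named
#'   compounds as the three-way intersection.
#' * E-nose: responses mix three grade-varying odor latents (terpenoid,
#'   oxygenated, ester) and one grade-constant background latent through a
#'   fixed non-negative loading matrix; 9 of 18 sensors load on the grade
#'   latents.
#' * E-tongue: one grade-varying taste latent read by PKS and ANS plus a
#'   grade-constant background latent read by all sensors.
#' * Sensory coupling: batch score targets couple positively to the batch's
#'   caryophyllene, \eqn{\gamma}-elemene, aromadendrene and atractylenolide I
#'   levels on top of group base targets.
#'
#' @param panel Compound panel, see [compound_panel()].
#' @param effect_scale Multiplier on every planted group effect; 0 gives a
#'   fully null dataset (group means identical, no informative sensors).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(panel = compound_panel(), effect_scale = 1) {
  stopifnot(is.numeric(effect_scale), length(effect_scale) == 1L,
            effect_scale >= 0)
  groups <- c("ZJ", "AH-HN-1", "AH-HN-2", "HB")

  v_ids <- panel$volatile$id
  n_ids <- panel$nonvolatile$id

  shared_v <- c("atractylone", "aromadendrene", "gamma_elemene",
                "caryophyllene")
  ah_v <- sprintf("V%02d", 5:16)   # shifted equally in AH-HN-1 and AH-HN-2
  hb_v <- sprintf("V%02d", 17:25)  # shifted in HB only
  check_ids(c(shared_v, ah_v, hb_v), v_ids, "volatile")

  volatile_effects <- matrix(0, length(v_ids), 4,
                             dimnames = list(v_ids, groups))
  # Grade ordering for the shared majors, adjacent gaps of 2 pooled SD.
  volatile_effects[shared_v, ] <- matrix(rep(c(0, 4, 2, -2), each = 4), 4, 4)
  volatile_effects[ah_v, "AH-HN-1"] <-
    volatile_effects[ah_v, "AH-HN-2"] <- rep(c(2.5, -2.5), c(8, 4))
  volatile_effects[hb_v, "HB"] <- rep(c(2.5, -2.5), c(5, 4))

  shared_n <- c("isoatractylode_A", "beta_sitosterol", "atractylenolide_I",
                "maltose", "sucrose", "dihydroxy_atractylenolide_III")
  ah_n <- sprintf("N%02d", 7:18)   # 8 positive + 4 negative mode
  hb_n <- sprintf("N%02d", 19:25)  # 5 positive + 2 negative mode
  check_ids(c(shared_n, ah_n, hb_n), n_ids, "non-volatile")

  nonvolatile_effects <- matrix(0, length(n_ids), 4,
                                dimnames = list(n_ids, groups))
  nonvolatile_effects["isoatractylode_A", ] <- c(2.5, 0, 0, -2)
  nonvolatile_effects["atractylenolide_I", ] <- c(2.5, 0, 0, -2)
  nonvolatile_effects["beta_sitosterol", ] <- c(2.5, 0, 0, 0)
  nonvolatile_effects["dihydroxy_atractylenolide_III", ] <- c(2.5, 0, 0, 0)
  nonvolatile_effects["maltose", ] <- c(-2.5, 0, 0, 0)
  nonvolatile_effects["sucrose", ] <- c(-2, 0, 0, 2.5)
  nonvolatile_effects[ah_n, "AH-HN-1"] <-
    nonvolatile_effects[ah_n, "AH-HN-2"] <- rep(c(2.5, -2.5), c(8, 4))
  nonvolatile_effects[hb_n, "HB"] <- rep(c(2.5, -2.5), c(4, 3))

  sensors <- sensor_panel()
  # E-nose odor latents: rows = latents, cols = groups (log abundances).
  enose_latent_means <- matrix(
    c(0.0, 0.9, 0.60, -0.6,   # terpenoid: tracks the volatile grade ordering
      1.0, 0.1, 0.00,  0.2,   # oxygenated sesquiterpenes: high in smoke-dried ZJ
      0.2, 0.5, 0.35,  1.0,   # esters: high in HB
      0.0, 0.0, 0.00,  0.0),  # grade-constant odor background
    nrow = 4, byrow = TRUE,
    dimnames = list(c("terpenoid", "oxygenated", "ester", "background"),
                    groups)
  )
  informative_enose <- c("S17", "S11", "S1", "S18", "S13", "S12", "S14",
                         "S5", "S7")
  enose_loadings <- matrix(
    0, 18, 4,
    dimnames = list(sensors$enose,
                    c("terpenoid", "oxygenated", "ester", "background"))
  )
  enose_loadings[informative_enose, 1:3] <- matrix(
    c(1.2, 0.8, 0.3,
      1.0, 0.2, 0.8,
      0.2, 1.0, 0.3,
      0.8, 0.9, 0.2,
      0.9, 0.5, 0.9,
      1.1, 0.1, 0.5,
      1.0, 0.9, 0.9,
      1.0, 0.4, 0.1,
      0.5, 0.7, 0.9),
    ncol = 3, byrow = TRUE
  )
  enose_loadings[informative_enose, "background"] <- 0.5
  uninformative <- setdiff(sensors$enose, informative_enose)
  enose_loadings[uninformative, "background"] <-
    seq(0.7, 1.5, length.out = length(uninformative))

  etongue_latent_means <- matrix(
    c(0.8, 0.25, 0.2, -0.4,  # sweetness/umami latent read by PKS and ANS
      0.0, 0.00, 0.0,  0.0), # grade-constant taste background
    nrow = 2, byrow = TRUE,
    dimnames = list(c("sweet", "background"), groups)
  )
  informative_etongue <- c("PKS", "ANS")
  etongue_loadings <- matrix(
    c(0.0, 1.0,
      1.3, 0.6,
      0.0, 0.8,
      0.0, 1.2,
      0.0, 0.9,
      0.9, 0.6,
      0.0, 1.1),
    ncol = 2, byrow = TRUE,
    dimnames = list(sensors$etongue, c("sweet", "background"))
  )

  # Baselines and shared-factor loadings are fixed panel attributes, drawn
  # once from a panel-internal stream so they do not depend on the dataset
  # seed.
  base <- with_seed(193547L, list(
    volatile_mu = stats::rnorm(length(v_ids), mean = 1.0, sd = 0.8),
    nonvolatile_mu = stats::rnorm(length(n_ids), mean = 2.0, sd = 0.8),
    volatile_lambda = stats::runif(length(v_ids), 0.8, 1.2),
    nonvolatile_lambda = stats::runif(length(n_ids), 0.8, 1.2)
  ))
  names(base$volatile_mu) <- names(base$volatile_lambda) <- v_ids
  names(base$nonvolatile_mu) <- names(base$nonvolatile_lambda) <- n_ids

  if (effect_scale != 1) {
    volatile_effects <- volatile_effects * effect_scale
    nonvolatile_effects <- nonvolatile_effects * effect_scale
    # grade-varying latents collapse onto their group means' average
    enose_latent_means <- sweep(enose_latent_means, 1,
                                rowMeans(enose_latent_means)) * effect_scale +
      rowMeans(enose_latent_means)
    etongue_latent_means <- sweep(etongue_latent_means, 1,
                                  rowMeans(etongue_latent_means)) * effect_scale +
      rowMeans(etongue_latent_means)
  }
  if (effect_scale == 0) {
    informative_enose <- character(0)
    informative_etongue <- character(0)
  }

  structure(list(
    panel = panel,
    effect_scale = effect_scale,
    volatile_sets = list(
      "ZJ_vs_AH-HN-1" = sort(c(shared_v, ah_v)),
      "ZJ_vs_AH-HN-2" = sort(c(shared_v, ah_v)),
      "ZJ_vs_HB" = sort(c(shared_v, hb_v))
    ),
    nonvolatile_sets = list(
      "ZJ_vs_AH-HN-1" = sort(c(shared_n, ah_n)),
      "ZJ_vs_AH-HN-2" = sort(c(shared_n, ah_n)),
      "ZJ_vs_HB" = sort(c(shared_n, hb_n))
    ),
    volatile_effects = volatile_effects,
    nonvolatile_effects = nonvolatile_effects,
    enose_latent_means = enose_latent_means,
    enose_loadings = enose_loadings,
    informative_enose = informative_enose,
    etongue_latent_means = etongue_latent_means,
    etongue_loadings = etongue_loadings,
    informative_etongue = informative_etongue,
    sensory = list(
      base_targets = c("ZJ" = 75, "AH-HN-1" = 68, "AH-HN-2" = 52, "HB" = 46),
      coupled_compounds = c("caryophyllene", "gamma_elemene", "aromadendrene",
                            "atractylenolide_I"),
      kappa = 3.5
    ),
    baselines = base
  ), class = "effect_spec")
}

check_ids <- function(ids, universe, what) {
  unknown <- setdiff(ids, universe)
  if (length(unknown)) {
    stop(sprintf("unknown %s compound id(s): %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Noise model of the synthetic generator
#'
#' All noise is multiplicative (additive on the log scale):
#' * `sigma_shared`: batch-level shared abundance factor per compound platform
#'   (sample amount / matrix effect), loading on every compound.
#' * `sigma_batch`: independent per-compound batch-level biological noise.
#' * `sigma_replicate`: per-replicate preparation noise (separate powder
#'   portions/extracts).
#' * `sigma_acquisition`: per-acquisition technical noise, calibrated so the
#'   relative standard deviation of six repeated acquisitions of one sample
#'   stays below the 3 % repeatability bound.
#' * `sensor_latent_sd` / `sensor_background_sd`: batch-level spread of the
#'   grade-varying and grade-constant sensor latents.
#'
#' Negative or missing sigmas are rejected; zero is allowed (degenerate,
#' noise-free draws).
#'
#' @param sigma_shared,sigma_batch,sigma_replicate,sigma_acquisition,
#'   sensor_latent_sd,sensor_background_sd Non-negative standard deviations on
#'   the log scale.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_shared = 0.4, sigma_batch = 0.08,
                        sigma_replicate = 0.10, sigma_acquisition = 0.012,
                        sensor_latent_sd = 0.15,
                        sensor_background_sd = 0.5) {
  vals <- c(sigma_shared = sigma_shared, sigma_batch = sigma_batch,
            sigma_replicate = sigma_replicate,
            sigma_acquisition = sigma_acquisition,
            sensor_latent_sd = sensor_latent_sd,
            sensor_background_sd = sensor_background_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    bad <- names(vals)[!is.finite(vals) | vals < 0]
    stop("noise sigmas must be finite and non-negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(as.list(vals), class = "noise_model")
}

# Pooled within-group SD of one replicate observation on the log scale (the
# unit in which planted effects are expressed).
pooled_sd <- function(noise) {
  sqrt(noise$sigma_shared^2 + noise$sigma_batch^2 +
         noise$sigma_replicate^2 + noise$sigma_acquisition^2)
}
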