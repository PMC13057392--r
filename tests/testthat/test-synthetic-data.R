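test_that("default design and panels match the study structure", {
  d <- study_design()
  expect_equal(sum(d$groups$n_batches), 39L)
  expect_equal(d$groups$n_batches[d$groups$group == "ZJ"], 10L)
  expect_equal(d$replicates, 5L)

  pan <- compound_panel()
  expect_equal(nrow(pan$volatile), 49L)
  expect_equal(sum(pan$volatile$shared_peak), 22L)
  expect_equal(nrow(pan$nonvolatile), 51L)
  expect_true(all(named_volatile_shared %in% pan$volatile$id))
  expect_true(all(named_nonvolatile_shared %in% pan$nonvolatile$id))
  expect_equal(length(sensor_panel()$enose), 18L)
  expect_equal(length(sensor_panel()$etongue), 7L)
})

test_that("effect spec encodes the planted contrast structure", {
  eff <- effect_spec()
  expect_equal(length(unique(unlist(eff$volatile_sets))), 25L)
  expect_equal(sort(Reduce(intersect, eff$volatile_sets)),
               sort(named_volatile_shared))
  expect_equal(length(unique(unlist(eff$nonvolatile_sets))), 25L)
  expect_equal(sort(Reduce(intersect, eff$nonvolatile_sets)),
               sort(named_nonvolatile_shared))
  pan <- eff$panel$nonvolatile
  un <- unique(unlist(eff$nonvolatile_sets))
  expect_equal(sum(pan$ion_mode[match(un, pan$id)] == "positive"), 17L)
  expect_equal(sum(pan$ion_mode[match(un, pan$id)] == "negative"), 8L)
  expect_equal(sort(eff$informative_enose),
               sort(c("S17", "S11", "S1", "S18", "S13", "S12", "S14",
                      "S5", "S7")))
  expect_equal(sort(eff$informative_etongue), c("ANS", "PKS"))
  # planted ordering for the shared volatiles, AH-HN-1 > AH-HN-2 > ZJ > HB
  for (cpd in named_volatile_shared) {
    e <- eff$volatile_effects[cpd, ]
    expect_true(e["AH-HN-1"] > e["AH-HN-2"])
    expect_true(e["AH-HN-2"] > e["ZJ"])
    expect_true(e["ZJ"] > e["HB"])
  }
  expect_gt(eff$nonvolatile_effects["isoatractylode_A", "ZJ"],
            eff$nonvolatile_effects["isoatractylode_A", "HB"])
  expect_gt(eff$nonvolatile_effects["atractylenolide_I", "ZJ"],
            eff$nonvolatile_effects["atractylenolide_I", "HB"])
  expect_gt(eff$nonvolatile_effects["sucrose", "HB"],
            eff$nonvolatile_effects["sucrose", "ZJ"])
  # planted differentials are at least 2 pooled SD from the reference
  for (cmp in names(eff$volatile_sets)) {
    g <- sub("ZJ_vs_", "", cmp)
    gaps <- abs(eff$volatile_effects[eff$volatile_sets[[cmp]], g] -
                  eff$volatile_effects[eff$volatile_sets[[cmp]], "ZJ"])
    expect_true(all(gaps >= 2))
  }
})

test_that("generated dataset satisfies the structural invariants", {
  ds <- default_dataset()
  for (pf in c("volatile", "nonvolatile", "enose", "etongue")) {
    tbl <- ds[[pf]]
    expect_equal(nrow(tbl), 195L)
    expect_equal(length(unique(tbl$batch_id)), 39L)
    expect_identical(names(tbl)[1:4],
                     c("batch_id", "group", "grade", "replicate"))
    expect_identical(tbl[, 1:4], ds$volatile[, 1:4]) # row alignment
    vals <- as.matrix(tbl[, -(1:4)])
    expect_true(all(vals > 0))
  }
  expect_equal(ncol(ds$volatile) - 4L, 49L)
  expect_equal(ncol(ds$nonvolatile) - 4L, 51L)
  expect_equal(ncol(ds$enose) - 4L, 18L)
  expect_equal(ncol(ds$etongue) - 4L, 7L)
})

test_that("identical seeds give bit-identical datasets", {
  d1 <- generate_dataset(study_design(seed = 7L))
  d2 <- generate_dataset(study_design(seed = 7L))
  expect_identical(d1$volatile, d2$volatile)
  expect_identical(d1$nonvolatile, d2$nonvolatile)
  expect_identical(d1$enose, d2$enose)
  expect_identical(d1$etongue, d2$etongue)
  expect_identical(d1$evaluator_counts, d2$evaluator_counts)
  d3 <- generate_dataset(study_design(seed = 8L))
  expect_false(identical(d1$volatile, d3$volatile))
})

test_that("zero effect scale yields identical group means", {
  e0 <- effect_spec(effect_scale = 0)
  expect_true(all(e0$volatile_effects == 0))
  expect_true(all(e0$nonvolatile_effects == 0))
  expect_true(all(apply(e0$enose_latent_means, 1,
                        function(x) diff(range(x)) == 0)))
  expect_length(e0$informative_enose, 0)
  expect_length(e0$informative_etongue, 0)
})

test_that("planted orderings are recovered in the sample means", {
  ok <- 0L
  n_seeds <- 15L
  for (s in seq_len(n_seeds)) {
    ds <- generate_dataset(study_design(seed = s))
    vb <- dplyr::summarise(
      dplyr::group_by(ds$volatile, group),
      dplyr::across(dplyr::all_of(named_volatile_shared), mean)
    )
    good <- TRUE
    for (cpd in named_volatile_shared) {
      m <- setNames(vb[[cpd]], vb$group)
      good <- good && m["AH-HN-1"] > m["AH-HN-2"] &&
        m["AH-HN-2"] > m["ZJ"] && m["ZJ"] > m["HB"]
    }
    nb <- dplyr::summarise(
      dplyr::group_by(ds$nonvolatile, group),
      iso = mean(isoatractylode_A), atr = mean(atractylenolide_I),
      suc = mean(sucrose)
    )
    m <- function(col, g) nb[[col]][nb$group == g]
    good <- good && m("iso", "ZJ") > m("iso", "HB") &&
      m("atr", "ZJ") > m("atr", "HB") && m("suc", "HB") > m("suc", "ZJ")
    ok <- ok + good
  }
  expect_gte(ok, n_seeds - 1L)
})

test_that("acquisition protocols discard conditioning runs", {
  eff <- effect_spec()
  nm <- noise_model()
  lat <- c(terpenoid = 0.2, oxygenated = 0.5, ester = 0.3, background = 0.1)
  set.seed(1)
  acq <- simulate_enose_acquisition(lat, eff$enose_loadings, nm,
                                    n_injections = 4)
  expect_equal(nrow(acq), 3L)
  expect_equal(ncol(acq), 18L)
  expect_error(simulate_enose_acquisition(lat, eff$enose_loadings, nm,
                                          n_injections = 1),
               "n_injections")
  # zero technical sigma: all retained vectors identical and equal to the
  # noiseless loading-matrix response
  nm0 <- noise_model(sigma_acquisition = 0)
  acq0 <- simulate_enose_acquisition(lat, eff$enose_loadings, nm0,
                                     n_injections = 5)
  expect_equal(acq0[1, ], acq0[4, ])
  expect_equal(unname(acq0[1, ]),
               unname(drop(eff$enose_loadings %*% exp(lat[colnames(eff$enose_loadings)]))))

  tl <- c(sweet = 0.4, background = 0.2)
  avg0 <- simulate_etongue_acquisition(tl, eff$etongue_loadings, nm0)
  expect_equal(unname(avg0),
               unname(drop(eff$etongue_loadings %*% exp(tl[colnames(eff$etongue_loadings)]))))
  expect_error(simulate_etongue_acquisition(tl, eff$etongue_loadings, nm,
                                            n_measurements = 4, n_discard = 4),
               "n_measurements > n_discard")
  set.seed(9)
  a1 <- simulate_etongue_acquisition(tl, eff$etongue_loadings, nm)
  set.seed(9)
  a2 <- simulate_etongue_acquisition(tl, eff$etongue_loadings, nm)
  expect_identical(a1, a2)
})

test_that("six repeated acquisitions of one sample stay under 3% RSD", {
  eff <- effect_spec()
  nm <- noise_model()
  lat <- c(terpenoid = 0.2, oxygenated = 0.5, ester = 0.3, background = 0.1)
  worst <- 0
  for (s in 1:10) {
    set.seed(s)
    acq <- simulate_enose_acquisition(lat, eff$enose_loadings, nm,
                                      n_injections = 7)
    rsd <- apply(acq, 2, function(x) 100 * sd(x) / mean(x))
    worst <- max(worst, rsd)
  }
  expect_lt(worst, 3)
})

test_that("evaluator counts sum to the panel size and hit the target bands", {
  design <- study_design(seed = 5L)
  counts <- generate_evaluator_counts(design)
  sums <- tapply(counts$count, list(counts$batch_id, counts$criterion), sum)
  expect_true(all(sums == 10L))
  # degenerate concentration puts every evaluator on one level
  deg <- generate_evaluator_counts(design, concentration = Inf)
  expect_true(all(deg$count %in% c(0L, 10L)))
  # targets outside the level range are rejected
  expect_error(generate_evaluator_counts(design,
                                         score_targets = c("ZJ" = 95,
                                                           "AH-HN-1" = 68,
                                                           "AH-HN-2" = 52,
                                                           "HB" = 46)),
               "outside the attainable range")
  # ZJ batches score mostly in the 70-80 band on the default dataset
  sc <- score_batches(default_dataset()$evaluator_counts)
  zj <- sc$score[grepl("^ZJ", sc$batch_id)]
  expect_gte(mean(zj >= 70 & zj <= 80), 0.7)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(noise_model(sigma_batch = -1), "non-negative")
  eff <- effect_spec()
  eff$volatile_sets[["ZJ_vs_HB"]] <- c(eff$volatile_sets[["ZJ_vs_HB"]],
                                       "not_a_compound")
  expect_error(generate_dataset(study_design(), eff), "not_a_compound")
  expect_error(study_design(groups = data.frame(group = "A", grade = "g",
                                                n_batches = 0)),
               "at least one batch")
})
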