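# Drift correction, CV filtering, dilution linearity, normalization,
# name parsing, aggregation, differential abundance.

test_that("constant QC areas give a unit correction factor everywhere", {
  tab <- make_lipid_tab(area = function(f, i) 100)
  m <- fit_drift(tab, "F1")
  expect_true(m$correctable)
  expect_equal(drift_factor(m, 1:21), rep(1, 21), tolerance = 1e-12)
})

test_that("noiseless linear drift is inverted up to fit tolerance", {
  tab <- make_lipid_tab(area = function(f, i) 100 * (1 + i / 21)) # 2x across run
  corr <- apply_drift_correction(tab, list(F1 = fit_drift(tab, "F1")))
  qc <- corr$peak_area[corr$sample_type == "qc"]
  expect_lt(sd(qc) / mean(qc) * 100, 1e-6)
  expect_true("peak_area_raw" %in% colnames(corr))
  # second pass is a no-op: refitted factors within 2% of 1
  m2 <- fit_drift(corr, "F1")
  expect_true(all(abs(drift_factor(m2, 1:21) - 1) < 0.02))
})

test_that("features with too few QCs are flagged uncorrectable and pass through", {
  tab <- make_lipid_tab(qc_at = c(1, 11, 21), area = function(f, i) 100 + i)
  m <- fit_drift(tab, "F1")
  expect_false(m$correctable)
  corr <- apply_drift_correction(tab, list(F1 = m))
  expect_equal(corr$peak_area, tab$peak_area)
  expect_true(all(corr$qc_flag[corr$feature_id == "F1"] == "uncorrectable"))
  expect_error(
    fit_drift(make_lipid_tab(area = function(f, i) 0), "F1"),
    "all QC areas are zero"
  )
})

test_that("a missing model for a correctable feature is an error", {
  tab <- make_lipid_tab(features = c("F1", "F2"), area = function(f, i) 100)
  expect_error(
    apply_drift_correction(tab, list(F1 = fit_drift(tab, "F1"))),
    "no drift model.*F2"
  )
})

test_that("drift correction preserves within-injection sample rank order", {
  # one multiplicative factor per (feature, injection): ranks across features
  # at the same injection must be preserved per feature across injections
  set.seed(3)
  tab <- make_lipid_tab(area = function(f, i) exp(rnorm(1, 5)) * (1 + i / 30))
  corr <- apply_drift_correction(tab, list(F1 = fit_drift(tab, "F1")))
  s_raw <- tab$peak_area[tab$sample_type == "sample"]
  s_corr <- corr$peak_area[corr$sample_type == "sample"]
  expect_true(all(s_corr > 0))
  # factors are positive, so any same-index comparison keeps its sign
  f <- drift_factor(fit_drift(tab, "F1"), tab$injection_index)
  expect_true(all(f > 0))
})

test_that("CV filter applies the strict 30% rule on sample SD", {
  qc_areas <- list(F1 = c(100, 100, 100), F2 = c(50, 100, 150), F3 = c(70, 100, 130))
  tab <- make_lipid_tab(
    features = names(qc_areas), qc_at = c(1, 8, 15), n_inj = 15,
    area = function(f, i) {
      k <- sum(c(1, 8, 15) <= i)
      if (i %in% c(1, 8, 15)) qc_areas[[f]][k] else 100
    }
  )
  res <- cv_filter(tab, threshold_percent = 30)
  expect_equal(res$removed$feature_id, "F2") # CV 50%
  expect_equal(res$removed$cv_percent, 50)
  f3 <- res$cv$cv_percent[res$cv$feature_id == "F3"]
  expect_equal(f3, 30) # exactly at threshold: retained
  expect_true("F3" %in% res$retained$feature_id)
})

test_that("CV filter is monotone in its threshold", {
  set.seed(21)
  run <- gen_lipid_run(
    n_samples_per_group = 4, panel = default_lipid_panel()[1:40, ],
    drift_amplitude = 1, noise_cv = 0.15, frac_irreproducible = 0.2, seed = 77
  )
  kept <- lapply(c(10, 20, 30, 50), function(th) {
    unique(cv_filter(run$table, th)$retained$feature_id)
  })
  for (i in 1:3) expect_true(all(kept[[i]] %in% kept[[i + 1]]))
})

test_that("dilution linearity passes proportional series and fails flat/insufficient ones", {
  dil <- c(1, 0.5, 0.25, 0.125, 0.0625)
  prop <- make_lipid_tab(
    dilution = dil,
    area = function(f, i) if (i > 21) 1000 * dil[i - 21] else 100
  )
  res <- dilution_linearity(prop, "F1")
  expect_equal(res$verdict, "pass")
  expect_equal(res$r, 1, tolerance = 1e-9)
  flat <- make_lipid_tab(dilution = dil, area = function(f, i) 100)
  expect_equal(dilution_linearity(flat, "F1")$verdict, "fail")
  few <- make_lipid_tab(dilution = c(1, 0.5, 0.25), area = function(f, i) 100)
  expect_equal(dilution_linearity(few, "F1")$verdict, "insufficient")
})

test_that("a saturating dilution response is judged by the hand-computed r", {
  dil <- c(1, 0.5, 0.25, 0.125, 0.0625)
  areas <- c(100, 99, 95, 60, 35)
  sat <- make_lipid_tab(
    dilution = dil,
    area = function(f, i) if (i > 21) areas[i - 21] else 100
  )
  res <- dilution_linearity(sat, "F1", min_r = 0.9)
  r_hand <- oracle_pearson(dil, areas)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$verdict, if (r_hand >= 0.9) "pass" else "fail")
})

test_that("protein normalization divides sample rows only and demands protein values", {
  tab <- make_lipid_tab(area = function(f, i) 100, protein = 2)
  norm <- protein_normalize(tab)
  s <- norm$sample_type == "sample"
  expect_equal(norm$peak_area[s], rep(50, sum(s)))
  expect_equal(norm$peak_area[!s], tab$peak_area[!s])
  unit <- protein_normalize(make_lipid_tab(area = function(f, i) 100, protein = 1))
  expect_equal(unit$peak_area, tab$peak_area)
  bad <- tab
  bad$protein_ug[bad$sample_type == "sample"][1] <- NA
  expect_error(protein_normalize(bad), "protein_ug")
})

test_that("protein normalization and drift correction commute", {
  set.seed(5)
  tab <- make_lipid_tab(
    area = function(f, i) rlnorm(1, 5) * (1 + i / 25),
    protein = 3.7
  )
  models <- list(F1 = fit_drift(tab, "F1"))
  a <- protein_normalize(apply_drift_correction(tab, models))
  b <- apply_drift_correction(protein_normalize(tab), models)
  # the drift models were fitted on QC rows, untouched by protein normalization
  expect_equal(a$peak_area, b$peak_area, tolerance = 1e-12)
})

test_that("lipid names parse per the shorthand grammar", {
  p <- parse_lipid_name("PI 38:4")
  expect_equal(p$lipid_class, "PI")
  expect_equal(p$total_carbons, 38)
  expect_equal(p$total_double_bonds, 4)
  expect_null(p$chains)
  q <- parse_lipid_name("PI(18:0/20:4)")
  expect_equal(unname(q$chains[, "carbons"]), c(18, 20))
  expect_equal(q$total_carbons, 38)
  expect_equal(q$total_double_bonds, 4)
  expect_error(parse_lipid_name("XYZ 1:2"), "unknown lipid class")
  expect_error(parse_lipid_name("PI 38;4"), "malformed")
})

test_that("class aggregation sums member species and conserves totals", {
  tab <- make_lipid_tab(features = c("F1", "F2"), area = function(f, i) {
    if (f == "F1") 10 else 15
  })
  tab$lipid_name[tab$feature_id == "F2"] <- "PI 34:1"
  agg <- aggregate_by_class(tab)
  expect_true(all(agg$total_area == 25))
  expect_true(all(agg$n_species == 2))
  # conservation on a random table
  set.seed(15)
  run <- gen_lipid_run(
    n_samples_per_group = 3, panel = default_lipid_panel()[seq(1, 273, 9), ],
    drift_amplitude = 1, noise_cv = 0.1, frac_irreproducible = 0, seed = 9
  )
  agg2 <- aggregate_by_class(run$table)
  s <- run$table[run$table$sample_type == "sample", ]
  expect_equal(sum(agg2$total_area), sum(s$peak_area), tolerance = 1e-9)
})

test_that("differential abundance recovers constructed folds and summaries", {
  # two PI species with per-species folds 1.5 and 2.0, no noise
  mk <- function(fold1, fold2) {
    base <- expand.grid(rep = 1:3, group = c("CA", "CA_AD"), feature = c("P1", "P2"))
    base$area <- ifelse(base$feature == "P1", 10, 20)
    base$area <- base$area * ifelse(base$group == "CA_AD",
      ifelse(base$feature == "P1", fold1, fold2), 1
    )
    base$area <- base$area * rep(c(1, 1.01, 0.99), nrow(base) / 3) # tiny spread
    lipid_feature_table(data.frame(
      feature_id = base$feature,
      lipid_name = ifelse(base$feature == "P1", "PI 34:1", "PI 38:4"),
      injection_index = seq_len(nrow(base)), sample_id = paste0("s", seq_len(nrow(base))),
      sample_type = "sample", dilution_fraction = 1, peak_area = base$area,
      protein_ug = 1, group = as.character(base$group)
    ))
  }
  tab <- mk(1.5, 2.0)
  sp <- differential_abundance(tab, "CA", "CA_AD", level = "species")
  expect_equal(sort(sp$mean_fold), c(1.5, 2.0), tolerance = 1e-12)
  cl <- differential_abundance(tab, "CA", "CA_AD", level = "class")
  expect_equal(cl$avg_species_percent_change, 75, tolerance = 1e-9) # mean of 50%, 100%
  expect_equal(cl$n_species, 2L)
  expect_equal(cl$n_species_increased, 2L)
  expect_true(cl$q_value >= cl$p_value)

  # identical groups: fold 1, p = 1
  same <- mk(1, 1)
  sp0 <- differential_abundance(same, "CA", "CA_AD", level = "species")
  expect_equal(sp0$mean_fold, c(1, 1), tolerance = 1e-12)
  expect_equal(sp0$percent_change, c(0, 0), tolerance = 1e-9)
  expect_true(all(sp0$p_value == 1))
})
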