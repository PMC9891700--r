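# Seeded lipidomics run simulator: pooled-QC schedule, smooth drift,
# multiplicative lognormal noise, planted group effects — ground truth for
# every stage of the QC chain.

#' Default targeted lipid panel (273 species)
#'
#' A deterministic species panel spanning the usual targeted classes, sized
#' to a typical high-coverage targeted assay (273 species), including seven
#' phosphatidylinositol (PI) species.
#'
#' @return `data.frame` with columns `feature_id`, `lipid_name`,
#'   `lipid_class`.
#' @export
default_lipid_panel <- function() {
  mk <- function(class, carbons, dbs, n) {
    grid <- expand.grid(db = dbs, c = carbons)
    grid <- grid[seq_len(n), , drop = FALSE]
    sprintf("%s %d:%d", class, grid$c, grid$db)
  }
  names <- c(
    mk("PC", seq(30, 44, 2), 0:7, 60),
    mk("PE", seq(30, 44, 2), 0:5, 40),
    mk("PS", seq(32, 42, 2), 0:4, 15),
    mk("PG", seq(32, 40, 2), 0:3, 10),
    mk("PA", seq(32, 38, 2), 0:3, 8),
    c("PI 32:1", "PI 34:1", "PI 34:2", "PI 36:1", "PI 36:2", "PI 38:3", "PI 38:4"),
    mk("LPC", seq(14, 24, 2), 0:2, 15),
    mk("LPE", seq(16, 24, 2), 0:2, 10),
    mk("TG", seq(44, 60, 2), 0:7, 60),
    mk("DG", seq(30, 40, 2), 0:3, 18),
    mk("SM", seq(32, 42, 2), 0:3, 20),
    mk("CE", seq(14, 22, 2), 0:3, 10)
  )
  stopifnot(!anyDuplicated(names))
  data.frame(
    feature_id = gsub("[ :]", "_", names),
    lipid_name = names,
    lipid_class = sub(" .*$", "", names),
    stringsAsFactors = FALSE
  )
}

#' Simulate a targeted-lipidomics injection sequence
#'
#' Emulates a pooled-QC run design: biological samples in randomized
#' injection order, a pooled QC at the run start, after every `qc_every`
#' samples, and at the run end, followed by a diluted-QC series. The pooled
#' QC's true value is the mean of the pooled samples' true extract amounts.
#' Observed peak area = truth × drift(injection index) × lognormal noise.
#' Per-feature drift is a linear ramp plus one low-frequency sinusoid, with
#' max/min ratio equal to `drift_amplitude`. A chosen set of features is
#' generated irreproducible: their QC areas carry an extra multiplicative
#' pattern with log-scale SD set so the QC coefficient of variation is
#' `cv_irreproducible` (far above the 30% filter threshold by construction).
#'
#' True per-microgram abundances are per (feature, sample); biological sample
#' extracts scale with the sample's protein amount, which
#' [protein_normalize()] later divides out.
#'
#' @param n_samples_per_group Biological replicates per group (>= 2).
#' @param panel Species panel `data.frame` (`feature_id`, `lipid_name`), see
#'   [default_lipid_panel()].
#' @param groups Two group labels; the second carries the planted folds.
#' @param class_folds Named vector of per-class true fold changes
#'   (group 2 / group 1); classes not named fold 1.
#' @param species_folds Named per-feature folds overriding `class_folds`.
#' @param drift_amplitude Max/min drift ratio across the run, >= 1. Default 2.
#' @param noise_cv Multiplicative measurement noise CV. Default 0.05.
#' @param qc_every Pooled QC every this many samples; 5 or 6.
#' @param dilution_fractions Diluted-QC series, default
#'   `c(1, 0.5, 0.25, 0.125, 0.0625)`.
#' @param frac_irreproducible Fraction of features generated irreproducible.
#' @param cv_irreproducible Constructed QC CV of irreproducible features.
#' @param protected_features Feature ids excluded from the irreproducible
#'   draw (e.g. species whose recovery a study design guarantees).
#' @param protein_range Uniform range (µg) for per-sample protein content.
#' @param seed Integer seed; the run is a pure function of the arguments.
#' @return List with `table` (a `lipid_feature_table`) and `truth` (class
#'   `lipid_sim_truth`): `per_ug` truth matrix, `qc_true`, `expected_area`
#'   (noise-free, drift-free area per table row), `drift` (per-feature ×
#'   injection factor matrix), `species_folds`, `irreproducible_features`,
#'   `schedule`, `noise_cv`, `qc_every`, `seed`.
#' @examples
#' run <- gen_lipid_run(n_samples_per_group = 3, panel = default_lipid_panel()[1:5, ], seed = 1)
#' table(run$table$sample_type)
#' @export
gen_lipid_run <- function(n_samples_per_group = 6L,
                          panel = default_lipid_panel(),
                          groups = c("CA", "CA_AD"),
                          class_folds = NULL,
                          species_folds = NULL,
                          drift_amplitude = 2,
                          noise_cv = 0.05,
                          qc_every = 5L,
                          dilution_fractions = c(1, 0.5, 0.25, 0.125, 0.0625),
                          frac_irreproducible = 0.05,
                          cv_irreproducible = 0.5,
                          protected_features = character(0),
                          protein_range = c(40, 60),
                          seed = 1L) {
  assert_scalar_number(n_samples_per_group, "n_samples_per_group", lower = 2)
  assert_scalar_number(drift_amplitude, "drift_amplitude", lower = 1)
  assert_scalar_number(noise_cv, "noise_cv", lower = 0)
  assert_scalar_number(frac_irreproducible, "frac_irreproducible", lower = 0, upper = 1)
  assert_scalar_number(cv_irreproducible, "cv_irreproducible", lower = 0)
  if (!qc_every %in% c(5L, 6L)) {
    stop("`qc_every` must be 5 or 6", call. = FALSE)
  }
  if (length(groups) != 2L || anyDuplicated(groups)) {
    stop("`groups` must be two distinct labels", call. = FALSE)
  }
  if (any(dilution_fractions <= 0 | dilution_fractions > 1)) {
    stop("dilution fractions must lie in (0, 1]", call. = FALSE)
  }
  n_samples_per_group <- as.integer(n_samples_per_group)
  nf <- nrow(panel)
  feats <- panel$feature_id
  lipid_class <- sub(" .*$", "", panel$lipid_name)

  # Planted per-feature fold changes.
  folds <- rep(1, nf)
  names(folds) <- feats
  if (!is.null(class_folds)) {
    hit <- lipid_class %in% names(class_folds)
    folds[hit] <- class_folds[lipid_class[hit]]
  }
  if (!is.null(species_folds)) {
    unknown <- setdiff(names(species_folds), feats)
    if (length(unknown) > 0L) {
      stop("species_folds name features not in the panel: ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    folds[names(species_folds)] <- species_folds
  }
  if (any(folds <= 0)) stop("fold changes must be positive", call. = FALSE)

  n_samples <- 2L * n_samples_per_group
  samp_ids <- sprintf("%s_%02d", rep(groups, each = n_samples_per_group),
    rep(seq_len(n_samples_per_group), times = 2L)
  )
  samp_group <- rep(groups, each = n_samples_per_group)

  with_rng_seed(seed, {
    # --- truth -------------------------------------------------------------
    base <- stats::rlnorm(nf, meanlog = log(1e5), sdlog = 1)
    per_ug <- base %o% rep(1, n_samples)
    per_ug[, samp_group == groups[2L]] <-
      per_ug[, samp_group == groups[2L], drop = FALSE] * folds
    dimnames(per_ug) <- list(feats, samp_ids)
    protein <- stats::runif(n_samples, protein_range[1L], protein_range[2L])
    names(protein) <- samp_ids
    sample_area <- sweep(per_ug, 2L, protein, `*`) # extract amount per sample
    qc_true <- rowMeans(sample_area)

    # --- injection schedule -------------------------------------------------
    order_ids <- sample(samp_ids)
    sched_type <- "qc"
    sched_id <- "QC"
    since_qc <- 0L
    for (sid in order_ids) {
      sched_type <- c(sched_type, "sample")
      sched_id <- c(sched_id, sid)
      since_qc <- since_qc + 1L
      if (since_qc == qc_every) {
        sched_type <- c(sched_type, "qc")
        sched_id <- c(sched_id, "QC")
        since_qc <- 0L
      }
    }
    if (sched_type[length(sched_type)] != "qc") { # bracketing QC at run end
      sched_type <- c(sched_type, "qc")
      sched_id <- c(sched_id, "QC")
    }
    n_dil <- length(dilution_fractions)
    sched_type <- c(sched_type, rep("dilution_qc", n_dil))
    sched_id <- c(sched_id, sprintf("DQC_%02d", seq_len(n_dil)))
    sched_frac <- rep(1, length(sched_type))
    sched_frac[sched_type == "dilution_qc"] <- dilution_fractions
    n_inj <- length(sched_type)
    qc_idx <- which(sched_type == "qc")
    sched_id[qc_idx] <- sprintf("QC_%02d", seq_along(qc_idx))
    schedule <- data.frame(
      injection_index = seq_len(n_inj), sample_id = sched_id,
      sample_type = sched_type, dilution_fraction = sched_frac,
      stringsAsFactors = FALSE
    )

    # --- drift curves -------------------------------------------------------
    # Linear ramp plus one low-frequency (one cycle per run) sinusoid on a
    # fixed exponent scale, so `drift_amplitude` bounds the max/min ratio and
    # every curve stays smooth at the QC sampling density.
    drift <- matrix(1, nrow = nf, ncol = n_inj, dimnames = list(feats, NULL))
    if (drift_amplitude > 1) {
      idx <- seq_len(n_inj) / n_inj
      g_max <- 0.5 + 0.3 # |slope * (idx - 0.5)| <= 0.5, |sinusoid| <= 0.3
      for (i in seq_len(nf)) {
        slope <- stats::runif(1, -1, 1)
        phase <- stats::runif(1, 0, 2 * pi)
        g <- slope * (idx - 0.5) + 0.3 * sin(2 * pi * idx + phase)
        drift[i, ] <- drift_amplitude^((g + g_max) / (2 * g_max))
      }
    }

    # --- irreproducible features --------------------------------------------
    eligible <- setdiff(feats, protected_features)
    n_irr <- min(length(eligible), round(frac_irreproducible * nf))
    irr <- if (n_irr > 0L) sample(eligible, n_irr) else character(0)
    sdlog_irr <- sqrt(log(1 + cv_irreproducible^2))

    # --- observed areas -----------------------------------------------------
    truth_area <- matrix(NA_real_, nrow = nf, ncol = n_inj)
    for (j in seq_len(n_inj)) {
      truth_area[, j] <- switch(schedule$sample_type[j],
        sample = sample_area[, schedule$sample_id[j]],
        qc = qc_true,
        dilution_qc = qc_true * schedule$dilution_fraction[j]
      )
    }
    noise <- matrix(rlnorm_cv(nf * n_inj, noise_cv), nrow = nf)
    observed <- truth_area * drift * noise
    if (length(irr) > 0L && cv_irreproducible > 0) {
      # Irreproducibility is injected as an alternating multiplicative
      # pattern over the QC injections, standardized to log-scale SD
      # log(1 + cv^2)^(1/2). Alternation is orthogonal to any smooth drift
      # curve, so no drift model can explain it away — the QC CV stays near
      # `cv_irreproducible` by construction, before and after correction.
      for (f in irr) {
        i <- match(f, feats)
        pat <- sample(c(-1, 1), 1) * (-1)^seq_along(qc_idx)
        pat <- (pat - mean(pat)) / stats::sd(pat)
        observed[i, qc_idx] <- observed[i, qc_idx] * exp(pat * sdlog_irr)
      }
    }

    # --- long table ---------------------------------------------------------
    tab <- data.frame(
      feature_id = rep(feats, times = n_inj),
      lipid_name = rep(panel$lipid_name, times = n_inj),
      injection_index = rep(schedule$injection_index, each = nf),
      sample_id = rep(schedule$sample_id, each = nf),
      sample_type = rep(schedule$sample_type, each = nf),
      dilution_fraction = rep(schedule$dilution_fraction, each = nf),
      peak_area = as.vector(observed),
      protein_ug = rep(
        ifelse(schedule$sample_type == "sample",
          protein[schedule$sample_id], NA_real_
        ),
        each = nf
      ),
      group = rep(
        ifelse(schedule$sample_type == "sample",
          samp_group[match(schedule$sample_id, samp_ids)], "QC"
        ),
        each = nf
      ),
      stringsAsFactors = FALSE
    )
    table <- lipid_feature_table(tab)

    truth <- structure(
      list(
        per_ug = per_ug, qc_true = qc_true,
        expected_area = as.vector(truth_area),
        drift = drift,
        species_folds = folds, lipid_class = stats::setNames(lipid_class, feats),
        irreproducible_features = irr,
        cv_irreproducible = cv_irreproducible,
        protein_ug = protein,
        schedule = schedule,
        groups = groups,
        drift_amplitude = drift_amplitude,
        noise_cv = noise_cv, qc_every = as.integer(qc_every),
        seed = as.integer(seed)
      ),
      class = "lipid_sim_truth"
    )
    list(table = table, truth = truth)
  })
}

#' Lipidomics run preset mirroring an androgen-deprivation experiment
#'
#' The `"lncap-lipid-like"` preset generates the full 273-species panel with
#' six replicates per condition (`CA`: complete medium; `CA_AD`: androgen
#' deprivation), QCs every 5 samples, 2x drift and 5% measurement noise.
#' Planted effects: six of the seven PI species increase under deprivation
#' and one decreases, with per-species folds whose percent changes average
#' +141% across the class; all other species fold 1. The seven PI species
#' are excluded from the irreproducible draw — the emulated study design has
#' all assessed PI species surviving QC.
#'
#' @param preset Preset name, currently `"lncap-lipid-like"`.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [gen_lipid_run()].
#' @return As [gen_lipid_run()].
#' @export
lipid_preset <- function(preset = "lncap-lipid-like", seed = 1L, ...) {
  preset <- match.arg(preset)
  panel <- default_lipid_panel()
  pi_feats <- panel$feature_id[panel$lipid_class == "PI"]
  pi_folds <- stats::setNames(
    c(0.85, 2.2, 2.4, 2.6, 2.8, 3.0, 3.02), # mean percent change = +141%
    pi_feats
  )
  gen_lipid_run(
    n_samples_per_group = 6L, panel = panel, groups = c("CA", "CA_AD"),
    species_folds = pi_folds, drift_amplitude = 2, noise_cv = 0.05,
    qc_every = 5L, frac_irreproducible = 0.05, cv_irreproducible = 0.5,
    protected_features = pi_feats, seed = seed, ...
  )
}
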