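# Seeded latent-factor expression simulator: ground truth for the scoring
# and association layers.

#' Bundled synthetic AR signature fixture
#'
#' A 30-gene synthetic stand-in for an androgen-stimulated reference profile:
#' androgen-induced genes (KLK3, KLK2, TMPRSS2, FKBP5, ...) carry positive
#' reference values, androgen-repressed genes (e.g. OPRK1) negative ones.
#' The gene symbols are real AR-regulated genes; the reference values are
#' synthetic and documented as such — they are not any published vector.
#'
#' @return A [gene_signature()] with 30 genes.
#' @export
example_ar_signature <- function() {
  read_signature(
    system.file("extdata", "ar_signature_synthetic.tsv",
      package = "siglip",
      mustWork = TRUE
    ),
    name = "AR_synthetic"
  )
}

#' Bundled synthetic mTOR up/down gene sets
#'
#' Synthetic stand-in gene sets for mTORC1 activation: an up set of
#' growth/biosynthesis genes and a down set of autophagy/lysosomal (TFEB
#' program) genes. Membership is plausible but synthetic — not any published
#' gene set.
#'
#' @return A [pathway_gene_sets()].
#' @export
example_mtor_sets <- function() {
  sets <- read_gmt(system.file("extdata", "mtor_sets_synthetic.gmt",
    package = "siglip", mustWork = TRUE
  ))
  pathway_gene_sets(sets$MTOR_UP, sets$MTOR_DOWN, name = "MTOR_synthetic")
}

#' Simulate a log2 expression matrix with latent AR and mTOR activities
#'
#' Generative model (all on log2 scale): each sample i carries latent
#' activities `a_i ~ N(0,1)` (AR) and `m_i ~ N(0,1)` (mTOR). A signature
#' gene g takes value `mu_g + load_g * a_i + e`, with `load_g` proportional
#' to the signature's reference entry, so the reference vector is the
#' noiseless activated profile and the per-sample correlation score is a
#' strictly increasing function of `a_i` in the noiseless limit. mTOR
#' up-genes load `+1` and down-genes `-1` on `m_i`. The focal gene (default
#' `"PIP4K2A"`) takes `mu - gamma * a_i + e`: a planted negative coupling to
#' AR activity. Background genes are baseline plus noise. `e ~ N(0,
#' noise_sd^2)` throughout; baselines `mu_g ~ N(baseline_mean, baseline_sd^2)`.
#'
#' @param n_samples Number of samples (>= 10).
#' @param signature A [gene_signature()] (default [example_ar_signature()]).
#' @param mtor_sets A [pathway_gene_sets()] (default [example_mtor_sets()]).
#' @param gamma Magnitude of the focal gene's negative loading on latent AR
#'   activity (log2 units per SD of activity), >= 0. Default 0.8.
#' @param noise_sd Gene-level noise SD in log2 units, >= 0. Default 0.5.
#' @param n_background_genes Pure-noise genes appended to the matrix.
#' @param focal_gene Focal gene symbol. Default `"PIP4K2A"`.
#' @param mtor_loading Loading magnitude of mTOR set genes on latent mTOR
#'   activity. Default 1.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution (log2
#'   units). Defaults 5 and 1.
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @return List with `expr` (an [expression_matrix()]) and `truth` (class
#'   `expression_sim_truth`): `latent_ar`, `latent_mtor`,
#'   `signature_loadings`, `focal_gene`, `gamma`, `noise_sd`, `seed`.
#' @examples
#' sim <- gen_expression(n_samples = 20, seed = 1)
#' dim(sim$expr)
#' @export
gen_expression <- function(n_samples,
                           signature = example_ar_signature(),
                           mtor_sets = example_mtor_sets(),
                           gamma = 0.8, noise_sd = 0.5,
                           n_background_genes = 100L,
                           focal_gene = "PIP4K2A",
                           mtor_loading = 1,
                           baseline_mean = 5, baseline_sd = 1,
                           seed = 1L) {
  assert_scalar_number(n_samples, "n_samples", lower = 10)
  assert_scalar_number(gamma, "gamma", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(n_background_genes, "n_background_genes", lower = 0)
  stopifnot(inherits(signature, "gene_signature"), inherits(mtor_sets, "pathway_gene_sets"))
  focal_gene <- toupper(trimws(focal_gene))
  n_samples <- as.integer(n_samples)
  n_background_genes <- as.integer(n_background_genes)

  sig_genes <- signature$genes
  up <- mtor_sets$up_genes
  down <- mtor_sets$down_genes
  bg <- if (n_background_genes > 0L) {
    sprintf("BG%04d", seq_len(n_background_genes))
  } else {
    character(0)
  }
  all_genes <- c(sig_genes, up, down, focal_gene, bg)
  if (anyDuplicated(all_genes)) {
    stop("signature, mTOR sets, focal and background gene names must be disjoint",
      call. = FALSE
    )
  }

  with_rng_seed(seed, {
    latent_ar <- stats::rnorm(n_samples)
    latent_mtor <- stats::rnorm(n_samples)
    baselines <- stats::rnorm(length(all_genes), baseline_mean, baseline_sd)
    names(baselines) <- all_genes

    # Loadings proportional to the reference entries, scaled to unit SD so
    # `noise_sd` is interpretable relative to the signal.
    sig_load <- signature$reference / stats::sd(signature$reference)
    names(sig_load) <- sig_genes

    vals <- matrix(NA_real_, nrow = length(all_genes), ncol = n_samples,
      dimnames = list(all_genes, sprintf("S%04d", seq_len(n_samples)))
    )
    noise <- function() stats::rnorm(n_samples, 0, noise_sd)
    for (g in sig_genes) {
      vals[g, ] <- baselines[g] + sig_load[g] * latent_ar + noise()
    }
    for (g in up) {
      vals[g, ] <- baselines[g] + mtor_loading * latent_mtor + noise()
    }
    for (g in down) {
      vals[g, ] <- baselines[g] - mtor_loading * latent_mtor + noise()
    }
    vals[focal_gene, ] <- baselines[focal_gene] - gamma * latent_ar + noise()
    for (g in bg) {
      vals[g, ] <- baselines[g] + noise()
    }

    truth <- structure(
      list(
        latent_ar = latent_ar, latent_mtor = latent_mtor,
        signature_loadings = sig_load,
        baselines = baselines,
        focal_gene = focal_gene, focal_gene_coupling = gamma,
        mtor_loading = mtor_loading,
        noise_sd = noise_sd, seed = as.integer(seed),
        sample_ids = colnames(vals)
      ),
      class = "expression_sim_truth"
    )
    list(expr = expression_matrix(vals, is_log2 = TRUE), truth = truth)
  })
}

#' Expression simulation presets mirroring common cohort sizes
#'
#' `"tcga-like"` (n = 333) and `"su2c-like"` (n = 149) reproduce the sample
#' sizes of the primary and metastatic prostate cohorts the scoring method is
#' typically applied to; all other parameters are the [gen_expression()]
#' defaults.
#'
#' @param preset `"tcga-like"` or `"su2c-like"`.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [gen_expression()].
#' @return As [gen_expression()].
#' @export
expression_preset <- function(preset = c("tcga-like", "su2c-like"), seed = 1L, ...) {
  preset <- match.arg(preset)
  n <- switch(preset,
    "tcga-like" = 333L,
    "su2c-like" = 149L
  )
  gen_expression(n_samples = n, seed = seed, ...)
}
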