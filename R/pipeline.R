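# Config-driven end-to-end runs with reproducibility manifests.

manifest_input_digest <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    unname(tools::md5sum(x))
  } else {
    "<in-memory>"
  }
}

write_manifest <- function(path, stage, parameters, inputs, counts, seed = NULL) {
  manifest <- list(
    tool = "siglip",
    version = as.character(utils::packageVersion("siglip")),
    manifest_schema = "1.0",
    stage = stage,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = parameters,
    inputs = inputs,
    counts = counts
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the transcriptomic scoring pipeline
#'
#' Loads (or accepts) an expression matrix, a gene signature and up/down
#' pathway gene sets; emits per-sample AR and mTOR score tables, focal-gene
#' association reports (Pearson and Spearman against both scores), an
#' optional two-group score comparison, and a JSON run manifest. All outputs
#' are deterministic functions of the inputs.
#'
#' @param config Named list:
#'   \describe{
#'     \item{expr}{Path to a TSV/GCT file or an [expression_matrix()].}
#'     \item{signature}{Path to a signature TSV or a [gene_signature()].}
#'     \item{gene_sets}{Path to a GMT or a [pathway_gene_sets()].}
#'     \item{up, down}{Set names in the GMT (required when `gene_sets` is a
#'       GMT path). }
#'     \item{focal_genes}{Character vector of genes to associate with the
#'       scores (may be empty).}
#'     \item{groups}{Optional named character vector mapping sample id to a
#'       two-level group label, for a group comparison of each score.}
#'     \item{variant, absolute, min_genes_present, pseudocount,
#'       already_log2}{Optional overrides of the scoring defaults.}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `ar_scores`, `mtor_scores`, `associations`,
#'   `group_comparisons`, `manifest`.
#' @export
run_transcriptomic_pipeline <- function(config, out_dir) {
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  expr <- resolve_input(config$expr, function(p) {
    read_expression_matrix(p,
      pseudocount = config$pseudocount %||% 1,
      already_log2 = config$already_log2 %||% FALSE
    )
  })
  sig <- resolve_input(config$signature, read_signature)
  sets <- config$gene_sets
  if (is.character(sets)) {
    gmt <- read_gmt(sets)
    if (is.null(config$up) || is.null(config$down)) {
      stop("config must name `up` and `down` sets when gene_sets is a GMT path",
        call. = FALSE
      )
    }
    sets <- pathway_gene_sets(gmt[[config$up]], gmt[[config$down]],
      name = paste0(config$up, "/", config$down)
    )
  }

  ar <- ar_signature_score(expr, sig,
    min_genes_present = config$min_genes_present %||% NULL
  )
  mtor <- mtor_activation_score(expr, sets,
    variant = config$variant %||% "pooled",
    absolute = config$absolute %||% TRUE
  )
  write_scores(ar, file.path(out_dir, "ar_scores.tsv"))
  write_scores(mtor, file.path(out_dir, "mtor_scores.tsv"))

  focal <- toupper(config$focal_genes %||% character(0))
  assoc <- NULL
  if (length(focal) > 0L) {
    missing <- setdiff(focal, gene_ids(expr))
    if (length(missing) > 0L) {
      stop("focal gene(s) absent from the matrix: ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    rows <- list()
    for (g in focal) {
      gv <- expr$values[g, ]
      for (sc in list(
        list(name = "ar_signature_score", values = ar$score),
        list(name = "mtor_score", values = mtor$score)
      )) {
        for (m in c("pearson", "spearman")) {
          rows[[length(rows) + 1L]] <- correlate(gv, sc$values,
            method = m,
            x_name = g, y_name = sc$name
          )
        }
      }
    }
    assoc <- do.call(rbind, rows)
    utils::write.table(assoc, file.path(out_dir, "associations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }

  grp_cmp <- NULL
  if (!is.null(config$groups)) {
    gmap <- config$groups[ar$sample_id]
    grp_cmp <- rbind(
      cbind(score = "ar_signature_score", group_ttest(ar$score, gmap)),
      cbind(score = "mtor_score", group_ttest(mtor$score, gmap))
    )
    utils::write.table(grp_cmp, file.path(out_dir, "group_comparisons.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }

  manifest <- write_manifest(
    file.path(out_dir, "manifest.json"),
    stage = "transcriptomic_pipeline",
    parameters = list(
      variant = config$variant %||% "pooled",
      absolute = config$absolute %||% TRUE,
      min_genes_present = config$min_genes_present %||% ceiling(0.8 * length(sig)),
      pseudocount = config$pseudocount %||% 1,
      focal_genes = as.list(focal)
    ),
    inputs = list(
      expr = manifest_input_digest(config$expr),
      signature = manifest_input_digest(config$signature),
      gene_sets = manifest_input_digest(config$gene_sets)
    ),
    counts = list(
      n_genes = nrow(expr$values),
      n_samples = ncol(expr$values),
      n_signature_genes_used = ar$n_genes_used[1L],
      n_mtor_genes_used = mtor$n_genes_used[1L],
      n_associations = if (is.null(assoc)) 0L else nrow(assoc)
    )
  )
  invisible(list(
    ar_scores = ar, mtor_scores = mtor, associations = assoc,
    group_comparisons = grp_cmp, manifest = manifest
  ))
}

#' Run the lipidomics QC and differential-abundance pipeline
#'
#' Fixed stage order: fit and apply pooled-QC drift correction, CV filter,
#' dilution-linearity report, protein normalization, class aggregation and
#' species/class differential abundance. Writes the corrected table, the
#' removal and linearity reports, both differential tables and a JSON
#' manifest with per-stage feature counts.
#'
#' @param config Named list:
#'   \describe{
#'     \item{table}{Path to a long-format CSV or a `lipid_feature_table`.}
#'     \item{group_a, group_b}{Group labels for differential abundance
#'       (default: the two non-QC groups, in order of appearance).}
#'     \item{smoother, span, cv_threshold, min_dilution_r, variant}{Optional
#'       overrides (defaults `"lowess"`, 0.5, 30, 0.9, `"pooled"`).}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `corrected`, `retained`, `cv_report`,
#'   `linearity`, `species_diff`, `class_diff`, `manifest`.
#' @export
run_lipidomics_pipeline <- function(config, out_dir) {
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- resolve_input(config$table, read_lipid_table)
  smoother <- config$smoother %||% "lowess"
  span <- config$span %||% 0.5
  cv_threshold <- config$cv_threshold %||% 30
  min_dilution_r <- config$min_dilution_r %||% 0.9
  variant <- config$variant %||% "pooled"

  models <- fit_drift_models(tab, smoother = smoother, span = span)
  corrected <- apply_drift_correction(tab, models)
  filt <- cv_filter(corrected, threshold_percent = cv_threshold)
  linearity <- dilution_linearity_report(filt$retained, min_r = min_dilution_r)
  normalized <- protein_normalize(filt$retained)

  grps <- sort(unique(normalized$group[normalized$sample_type == "sample"]))
  group_a <- config$group_a %||% grps[1L]
  group_b <- config$group_b %||% grps[2L]
  species_diff <- differential_abundance(normalized, group_a, group_b,
    level = "species", variant = variant
  )
  class_diff <- differential_abundance(normalized, group_a, group_b,
    level = "class", variant = variant
  )

  write_lipid_table(corrected, file.path(out_dir, "corrected_table.csv"))
  utils::write.csv(filt$cv, file.path(out_dir, "cv_report.csv"), row.names = FALSE)
  utils::write.csv(filt$removed, file.path(out_dir, "cv_removals.csv"), row.names = FALSE)
  utils::write.csv(linearity, file.path(out_dir, "dilution_linearity.csv"),
    row.names = FALSE
  )
  utils::write.csv(as.data.frame(species_diff),
    file.path(out_dir, "differential_species.csv"),
    row.names = FALSE
  )
  utils::write.csv(as.data.frame(class_diff),
    file.path(out_dir, "differential_class.csv"),
    row.names = FALSE
  )

  n_uncorrectable <- sum(vapply(models, function(m) !m$correctable, logical(1)))
  manifest <- write_manifest(
    file.path(out_dir, "manifest.json"),
    stage = "lipidomics_pipeline",
    parameters = list(
      smoother = smoother, span = span, cv_threshold = cv_threshold,
      min_dilution_r = min_dilution_r, variant = variant,
      group_a = group_a, group_b = group_b
    ),
    inputs = list(table = manifest_input_digest(config$table)),
    counts = list(
      n_features_input = length(unique(tab$feature_id)),
      n_uncorrectable = n_uncorrectable,
      n_removed_cv = nrow(filt$removed),
      n_features_retained = length(unique(filt$retained$feature_id)),
      n_linearity_pass = sum(linearity$verdict == "pass"),
      n_species_tested = sum(!is.na(species_diff$p_value)),
      n_classes_tested = sum(!is.na(class_diff$p_value))
    )
  )
  invisible(list(
    corrected = corrected, retained = filt$retained, cv_report = filt$cv,
    linearity = linearity, species_diff = species_diff,
    class_diff = class_diff, manifest = manifest
  ))
}
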