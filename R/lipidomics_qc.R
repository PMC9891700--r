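# Post-acquisition processing of targeted MRM peak-area tables.
#
# Fixed pipeline order: fit/apply drift -> CV filter -> dilution linearity
# report -> protein normalize -> aggregate / differential abundance.

#' Fit a pooled-QC drift-correction model for one feature
#'
#' Pooled QC samples injected periodically through the run track instrument
#' signal drift. A smoother (LOWESS by default, cubic smoothing spline as
#' alternative) is fitted to QC peak area versus injection index; the
#' correction factor at index i is `fitted(i) / median(qc_areas)`. Outside
#' the first/last QC the nearest fitted value is held constant (no
#' extrapolation). Features with fewer than `min_qc` QC injections are marked
#' uncorrectable and pass through unchanged.
#'
#' @param table A `lipid_feature_table`.
#' @param feature Feature identifier.
#' @param smoother `"lowess"` (default) or `"spline"`.
#' @param span LOWESS span (fraction of QC points in each local fit),
#'   default 0.5.
#' @param epsilon Positive floor applied to correction factors.
#' @param min_qc Minimum QC injections required to fit (default 4).
#' @return An object of class `qc_drift_model`; see [drift_factor()].
#' @export
fit_drift <- function(table, feature, smoother = c("lowess", "spline"),
                      span = 0.5, epsilon = 1e-6, min_qc = 4L) {
  smoother <- match.arg(smoother)
  assert_scalar_number(span, "span", lower = .Machine$double.eps, upper = 1)
  assert_scalar_number(epsilon, "epsilon", lower = .Machine$double.xmin)
  qc <- table[table$feature_id == feature & table$sample_type == "qc", , drop = FALSE]
  qc <- qc[order(qc$injection_index), , drop = FALSE]
  model <- list(
    feature_id = feature,
    qc_injection_indices = qc$injection_index,
    qc_areas = qc$peak_area,
    smoother = smoother, span = span, epsilon = epsilon,
    correctable = nrow(qc) >= min_qc
  )
  if (!model$correctable) {
    model$flag <- "uncorrectable"
    class(model) <- "qc_drift_model"
    return(model)
  }
  if (all(qc$peak_area == 0)) {
    stop(sprintf("all QC areas are zero for feature '%s'", feature), call. = FALSE)
  }
  # Local fits must span at least 4 QC points: with fewer, the smoother
  # interpolates QC measurement noise and drift correction silently erases
  # the very irreproducibility the CV filter is meant to catch. Robustness
  # iterations are off for the same reason in reverse — at these window
  # widths they misread genuine drift curvature as outliers; screening
  # irreproducible features is the CV filter's job, not the smoother's.
  f_eff <- max(span, min(1, 4 / nrow(qc)))
  fitted <- if (smoother == "lowess") {
    stats::lowess(qc$injection_index, qc$peak_area, f = f_eff, iter = 0L)$y
  } else {
    sp <- stats::smooth.spline(qc$injection_index, qc$peak_area,
      cv = FALSE,
      all.knots = TRUE
    )
    stats::predict(sp, qc$injection_index)$y
  }
  model$fitted <- fitted
  model$median_qc <- stats::median(qc$peak_area)
  class(model) <- "qc_drift_model"
  model
}

#' Evaluate a drift model's correction factor at injection indices
#'
#' @param model A `qc_drift_model` from [fit_drift()].
#' @param injection_index Integer vector of injection indices.
#' @return Positive correction factors (1 for uncorrectable models); observed
#'   areas are divided by these.
#' @export
drift_factor <- function(model, injection_index) {
  stopifnot(inherits(model, "qc_drift_model"))
  if (!model$correctable) {
    return(rep(1, length(injection_index)))
  }
  f <- stats::approx(
    x = model$qc_injection_indices, y = model$fitted,
    xout = injection_index, rule = 2
  )$y / model$median_qc
  pmax(f, model$epsilon)
}

#' @export
print.qc_drift_model <- function(x, ...) {
  cat(sprintf(
    "<qc_drift_model> %s: %s, %d QCs%s\n", x$feature_id, x$smoother,
    length(x$qc_injection_indices),
    if (x$correctable) "" else " (uncorrectable)"
  ))
  invisible(x)
}

#' Fit drift models for every feature in a run
#'
#' @inheritParams fit_drift
#' @param features Features to fit (default: all in `table`).
#' @return Named list of `qc_drift_model` objects.
#' @export
fit_drift_models <- function(table, features = unique(table$feature_id),
                             smoother = c("lowess", "spline"), span = 0.5,
                             epsilon = 1e-6, min_qc = 4L) {
  smoother <- match.arg(smoother)
  models <- lapply(features, function(f) {
    fit_drift(table, f, smoother = smoother, span = span, epsilon = epsilon, min_qc = min_qc)
  })
  names(models) <- features
  models
}

#' Apply drift correction to a run table
#'
#' Divides each row's peak area (QC, sample and dilution rows alike) by the
#' feature's correction factor at that row's injection index. Original areas
#' are retained in the audit column `peak_area_raw`; uncorrectable features
#' pass through with `qc_flag = "uncorrectable"`.
#'
#' @param table A `lipid_feature_table`.
#' @param models Named list of `qc_drift_model`s covering every correctable
#'   feature (from [fit_drift_models()]).
#' @return The corrected table.
#' @export
apply_drift_correction <- function(table, models) {
  features <- unique(table$feature_id)
  qc_counts <- table(table$feature_id[table$sample_type == "qc"])
  out <- table
  out$peak_area_raw <- out$peak_area
  if (!"qc_flag" %in% colnames(out)) out$qc_flag <- ""
  for (f in features) {
    model <- models[[f]]
    if (is.null(model)) {
      n_qc <- if (f %in% names(qc_counts)) qc_counts[[f]] else 0L
      if (n_qc >= 4L) {
        stop(sprintf("no drift model supplied for correctable feature '%s'", f),
          call. = FALSE
        )
      }
      out$qc_flag[out$feature_id == f] <- "uncorrectable"
      next
    }
    rows <- which(out$feature_id == f)
    if (!model$correctable) {
      out$qc_flag[rows] <- "uncorrectable"
      next
    }
    out$peak_area[rows] <- out$peak_area[rows] /
      drift_factor(model, out$injection_index[rows])
  }
  out
}

#' Remove features with poor pooled-QC reproducibility
#'
#' Per feature, CV = sample standard deviation / mean of QC peak areas, in
#' percent, on the raw (not log) scale. Features whose QC CV strictly exceeds
#' `threshold_percent` are removed; CV exactly at the threshold is retained.
#' Features with fewer than 2 QC rows cannot be assessed: they are retained
#' and flagged.
#'
#' @param table A (drift-corrected) `lipid_feature_table`.
#' @param threshold_percent Removal threshold, default 30 (%).
#' @return List with `retained` (filtered table), `removed` (`data.frame` of
#'   `feature_id`, `cv_percent`), `cv` (per-feature CV report) and `flagged`
#'   (features with < 2 QCs, not filtered).
#' @export
cv_filter <- function(table, threshold_percent = 30) {
  assert_scalar_number(threshold_percent, "threshold_percent", lower = 0)
  qc <- table[table$sample_type == "qc", , drop = FALSE]
  features <- unique(table$feature_id)
  n_qc <- vapply(features, function(f) sum(qc$feature_id == f), integer(1))
  cv <- vapply(features, function(f) {
    a <- qc$peak_area[qc$feature_id == f]
    if (length(a) < 2L) NA_real_ else cv_percent(a)
  }, numeric(1))
  report <- data.frame(
    feature_id = features, n_qc = n_qc, cv_percent = cv,
    removed = !is.na(cv) & cv > threshold_percent,
    stringsAsFactors = FALSE, row.names = NULL
  )
  removed <- report[report$removed, c("feature_id", "cv_percent")]
  flagged <- features[n_qc < 2L]
  retained <- table[!table$feature_id %in% removed$feature_id, , drop = FALSE]
  list(
    retained = retained,
    removed = removed,
    cv = report,
    flagged = flagged
  )
}

#' Assess dilution linearity of a feature's response
#'
#' The diluted-QC series (100, 50, 25, 12.5, 6.25% pooled QC) probes whether
#' a feature's peak area responds linearly to analyte amount. The subjective
#' visual check is operationalized as: Pearson r between dilution fraction
#' and peak area at least `min_r`, with positive slope.
#'
#' @param table A `lipid_feature_table`.
#' @param feature Feature identifier.
#' @param min_r Minimum Pearson r to pass, default 0.9.
#' @return List with `feature_id`, `verdict` (`"pass"`, `"fail"`, or
#'   `"insufficient"` for < 4 dilution points), `r`, `slope`, `n`.
#' @export
dilution_linearity <- function(table, feature, min_r = 0.9) {
  assert_scalar_number(min_r, "min_r", lower = -1, upper = 1)
  d <- table[table$feature_id == feature & table$sample_type == "dilution_qc", ,
    drop = FALSE
  ]
  if (nrow(d) < 4L) {
    return(list(
      feature_id = feature, verdict = "insufficient",
      r = NA_real_, slope = NA_real_, n = nrow(d)
    ))
  }
  r <- pearson_r(d$dilution_fraction, d$peak_area)
  slope <- unname(stats::coef(stats::lm(peak_area ~ dilution_fraction, data = d))[2L])
  verdict <- if (!is.na(r) && r >= min_r && slope > 0) "pass" else "fail"
  list(feature_id = feature, verdict = verdict, r = r, slope = slope, n = nrow(d))
}

#' Dilution-linearity report for all features
#'
#' @inheritParams dilution_linearity
#' @return `data.frame` with one row per feature: `feature_id`, `verdict`,
#'   `r`, `slope`, `n`.
#' @export
dilution_linearity_report <- function(table, min_r = 0.9) {
  features <- unique(table$feature_id)
  rows <- lapply(features, function(f) {
    as.data.frame(dilution_linearity(table, f, min_r = min_r),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Normalize sample peak areas by total protein content
#'
#' Biological sample rows are divided by their sample's protein amount
#' (units become area per microgram); QC and dilution rows are exempt, since
#' pooled QCs have no per-sample protein measurement.
#'
#' @param table A `lipid_feature_table`.
#' @return The normalized table.
#' @export
protein_normalize <- function(table) {
  s <- table$sample_type == "sample"
  prot <- table$protein_ug[s]
  if (any(is.na(prot) | prot <= 0)) {
    bad <- unique(table$sample_id[s][is.na(prot) | prot <= 0])
    stop("missing or non-positive protein_ug for sample(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  table$peak_area[s] <- table$peak_area[s] / prot
  table
}

#' Aggregate species-level areas into per-class, per-sample totals
#'
#' Sums the (normalized) peak areas of all member species of each lipid class
#' within each biological sample. Only `sample` rows contribute.
#'
#' @param table A `lipid_feature_table` with parseable `lipid_name`s.
#' @param classes Accepted class vocabulary for [parse_lipid_name()].
#' @return `data.frame` with columns `lipid_class`, `sample_id`, `group`,
#'   `total_area`, `n_species`.
#' @export
aggregate_by_class <- function(table, classes = lipid_classes()) {
  s <- table[table$sample_type == "sample", , drop = FALSE]
  if (nrow(s) == 0L) {
    return(data.frame(
      lipid_class = character(0), sample_id = character(0),
      group = character(0), total_area = numeric(0), n_species = integer(0)
    ))
  }
  name_map <- unique(s[, c("feature_id", "lipid_name")])
  parsed <- parse_lipid_names(name_map$lipid_name, classes = classes)
  name_map$lipid_class <- parsed$lipid_class
  s$lipid_class <- name_map$lipid_class[match(s$feature_id, name_map$feature_id)]
  agg <- stats::aggregate(peak_area ~ lipid_class + sample_id + group,
    data = s,
    FUN = sum
  )
  nsp <- stats::aggregate(feature_id ~ lipid_class + sample_id + group,
    data = s,
    FUN = function(x) length(unique(x))
  )
  out <- merge(agg, nsp, by = c("lipid_class", "sample_id", "group"))
  names(out)[names(out) == "peak_area"] <- "total_area"
  names(out)[names(out) == "feature_id"] <- "n_species"
  out[order(out$lipid_class, out$sample_id), , drop = FALSE]
}

#' Differential lipid abundance between two groups
#'
#' At `level = "species"`, each feature's per-sample (normalized) areas are
#' compared between groups with a two-sided t test; the fold change is the
#' ratio of group means (`group_b / group_a`), percent change is
#' `(fold - 1) * 100`, and Benjamini–Hochberg q-values are computed across
#' all tested keys. At `level = "class"`, per-class totals from
#' [aggregate_by_class()] are tested the same way, and each class row also
#' summarizes its member species: the average percent change across species
#' and the count of species with fold > 1.
#'
#' @param table A processed `lipid_feature_table` (drift-corrected, filtered,
#'   protein-normalized).
#' @param group_a,group_b Group labels; fold changes are `b` over `a`.
#' @param level `"species"` or `"class"`.
#' @param variant t-test variant, `"pooled"` (default, plain Student t) or
#'   `"welch"`.
#' @param classes Class vocabulary for name parsing.
#' @return `data.frame` (class `lipid_differential`) with one row per key:
#'   `key`, `level`, `group_a`, `group_b`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `mean_fold`, `percent_change`, `t_stat`, `df`, `p_value`, `q_value`,
#'   plus at class level `n_species`, `n_species_increased`,
#'   `avg_species_percent_change`.
#' @export
differential_abundance <- function(table, group_a, group_b,
                                   level = c("species", "class"),
                                   variant = c("pooled", "welch"),
                                   classes = lipid_classes()) {
  level <- match.arg(level)
  variant <- match.arg(variant)
  s <- table[table$sample_type == "sample" & table$group %in% c(group_a, group_b), ,
    drop = FALSE
  ]
  if (nrow(s) == 0L) {
    stop(sprintf("no sample rows for groups '%s'/'%s'", group_a, group_b),
      call. = FALSE
    )
  }

  test_keys <- function(values_by_key) {
    rows <- lapply(names(values_by_key), function(k) {
      va <- values_by_key[[k]]$a
      vb <- values_by_key[[k]]$b
      if (length(va) < 2L || length(vb) < 2L) {
        return(data.frame(
          key = k, mean_a = NA_real_, mean_b = NA_real_,
          n_a = length(va), n_b = length(vb), mean_fold = NA_real_,
          percent_change = NA_real_, t_stat = NA_real_, df = NA_real_,
          p_value = NA_real_, flag = "insufficient_replicates",
          stringsAsFactors = FALSE
        ))
      }
      gt <- group_ttest(
        c(va, vb),
        factor(rep(c("a", "b"), c(length(va), length(vb))), levels = c("a", "b")),
        variant = variant
      )
      data.frame(
        key = k, mean_a = gt$mean_a, mean_b = gt$mean_b,
        n_a = gt$n_a, n_b = gt$n_b, mean_fold = gt$fold_change,
        percent_change = (gt$fold_change - 1) * 100,
        t_stat = gt$t_stat, df = gt$df, p_value = gt$p_value, flag = "",
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out$q_value <- NA_real_
    tested <- !is.na(out$p_value)
    out$q_value[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
    out
  }

  split_values <- function(df, key_col, value_col) {
    keys <- unique(df[[key_col]])
    vals <- lapply(keys, function(k) {
      rows <- df[[key_col]] == k
      list(
        a = df[[value_col]][rows & df$group == group_a],
        b = df[[value_col]][rows & df$group == group_b]
      )
    })
    names(vals) <- keys
    vals
  }

  if (level == "species") {
    res <- test_keys(split_values(s, "feature_id", "peak_area"))
    name_map <- unique(s[, c("feature_id", "lipid_name")])
    res$lipid_name <- name_map$lipid_name[match(res$key, name_map$feature_id)]
  } else {
    cls <- aggregate_by_class(s, classes = classes)
    res <- test_keys(split_values(cls, "lipid_class", "total_area"))
    # Per-class species summaries from the species-level comparison.
    sp <- differential_abundance(table, group_a, group_b,
      level = "species",
      variant = variant, classes = classes
    )
    sp$lipid_class <- parse_lipid_names(sp$lipid_name, classes = classes)$lipid_class
    res$n_species <- NA_integer_
    res$n_species_increased <- NA_integer_
    res$avg_species_percent_change <- NA_real_
    for (i in seq_len(nrow(res))) {
      member <- sp[sp$lipid_class == res$key[i] & !is.na(sp$mean_fold), , drop = FALSE]
      res$n_species[i] <- nrow(member)
      res$n_species_increased[i] <- sum(member$mean_fold > 1)
      res$avg_species_percent_change[i] <- mean(member$percent_change)
    }
  }
  res$level <- level
  res$group_a <- group_a
  res$group_b <- group_b
  class(res) <- c("lipid_differential", "data.frame")
  res
}
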