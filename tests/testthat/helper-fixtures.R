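# In-code fixture builders shared across test files.

make_expr <- function(values) {
  expression_matrix(values, is_log2 = TRUE)
}

# Single-sample matrix over named gene values.
one_sample_expr <- function(gene_values, sample_id = "s1") {
  m <- matrix(gene_values, ncol = 1, dimnames = list(names(gene_values), sample_id))
  expression_matrix(m, is_log2 = TRUE)
}

# Minimal lipid run: one or more features, QC rows at given injections,
# optional sample/dilution rows. `area` is a function(feature, injection).
make_lipid_tab <- function(features = "F1", n_inj = 21,
                           qc_at = c(1, 6, 11, 16, 21),
                           dilution = NULL,
                           area = function(f, i) 100,
                           protein = 50, groups = c("CA", "CA_AD")) {
  rows <- list()
  for (f in features) {
    type <- rep("sample", n_inj)
    type[qc_at] <- "qc"
    frac <- rep(1, n_inj)
    sid <- sprintf("S%02d", seq_len(n_inj))
    sid[qc_at] <- sprintf("QC_%02d", seq_along(qc_at))
    if (!is.null(dilution)) {
      type <- c(type, rep("dilution_qc", length(dilution)))
      frac <- c(frac, dilution)
      sid <- c(sid, sprintf("DQC_%02d", seq_along(dilution)))
    }
    ni <- length(type)
    grp <- ifelse(type == "sample",
      rep(groups, length.out = ni), "QC"
    )
    rows[[f]] <- data.frame(
      feature_id = f, lipid_name = "PI 38:4",
      injection_index = seq_len(ni), sample_id = sid, sample_type = type,
      dilution_fraction = frac,
      peak_area = vapply(seq_len(ni), function(i) area(f, i), numeric(1)),
      protein_ug = ifelse(type == "sample", protein, NA_real_),
      group = grp, stringsAsFactors = FALSE
    )
  }
  lipid_feature_table(do.call(rbind, rows))
}

write_tempfile <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
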