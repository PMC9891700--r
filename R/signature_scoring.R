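# Per-sample pathway-activity scores.
#
# Both statistics are computed from their definition formulas (explicit sums)
# rather than through cor()/t.test(): the tests hold them against independent
# oracles, so the implementation must not be the oracle.

# Pearson product-moment correlation by explicit sums.
pearson_r <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) {
    return(NA_real_)
  }
  sum(dx * dy) / den
}

# Two-sample t statistic (x vs y), pooled or Welch, with df.
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  n1 <- length(x)
  n2 <- length(y)
  m1 <- mean(x)
  m2 <- mean(y)
  v1 <- sum((x - m1)^2) / (n1 - 1)
  v2 <- sum((y - m2)^2) / (n2 - 1)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (v1 == 0 && v2 == 0) {
      n1 + n2 - 2
    } else {
      (v1 / n1 + v2 / n2)^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
  }
  t <- if (se == 0) {
    if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    (m1 - m2) / se
  }
  list(t = t, df = df, se = se, mean_x = m1, mean_y = m2, var_x = v1, var_y = v2)
}

#' AR signaling score: per-sample correlation to a reference vector
#'
#' For each sample, the score is the Pearson correlation coefficient between
#' the sample's log2 expression values over the signature genes (in signature
#' order) and the signature's reference vector. High scores mean the sample's
#' expression profile over AR-regulated genes resembles the androgen-stimulated
#' reference; scores lie in \[-1, 1\].
#'
#' Signature genes absent from the matrix are dropped pairwise (gene and
#' reference entry together) and recorded in `flags`; fewer than
#' `min_genes_present` intersecting genes is an error.
#'
#' @param expr An [expression_matrix()] on log2 scale.
#' @param sig A [gene_signature()].
#' @param min_genes_present Minimum number of signature genes that must be
#'   present in `expr`. Default: 80% of the signature (rounded up), i.e. 24
#'   of a 30-gene signature; a 25-of-30 floor can be requested explicitly.
#' @return A `data.frame` (class `score_vector`) with columns `sample_id`,
#'   `score`, `n_genes_used`, `flags`. A sample with zero variance over the
#'   signature genes gets `NA` with flag `zero_variance`.
#' @examples
#' sig <- gene_signature(c("A", "B", "C", "D", "E"), c(1, 2, 3, 4, 5))
#' m <- matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(sig$genes, "s1"))
#' ar_signature_score(expression_matrix(m), sig)$score # 1
#' @export
ar_signature_score <- function(expr, sig, min_genes_present = NULL) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sig, "gene_signature"))
  if (!expr$is_log2) {
    stop("expression matrix must be log2 scale (is_log2 = TRUE)", call. = FALSE)
  }
  n_sig <- length(sig$genes)
  min_genes_present <- min_genes_present %||% ceiling(0.8 * n_sig)
  assert_scalar_number(min_genes_present, "min_genes_present", lower = 3)

  present <- sig$genes %in% gene_ids(expr)
  missing <- sig$genes[!present]
  if (sum(present) < min_genes_present) {
    stop(sprintf(
      "only %d of %d signature genes present (need >= %d); missing: %s",
      sum(present), n_sig, min_genes_present, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  genes_used <- sig$genes[present]
  ref <- sig$reference[present]
  if (stats::var(ref) == 0) {
    stop("reference vector is constant over the intersecting genes", call. = FALSE)
  }
  sub <- expr$values[genes_used, , drop = FALSE]

  base_flag <- if (length(missing) > 0L) {
    paste0("missing_genes:", paste(missing, collapse = "|"))
  } else {
    ""
  }
  scores <- vapply(seq_len(ncol(sub)), function(j) pearson_r(sub[, j], ref), numeric(1))
  flags <- rep(base_flag, ncol(sub))
  zv <- is.na(scores)
  flags[zv] <- paste0(ifelse(nzchar(flags[zv]), paste0(flags[zv], ";"), ""), "zero_variance")

  out <- data.frame(
    sample_id = sample_ids(expr),
    score = scores,
    n_genes_used = length(genes_used),
    flags = flags,
    stringsAsFactors = FALSE
  )
  attr(out, "score_name") <- paste0("ar_signature:", sig$name)
  class(out) <- c("score_vector", "data.frame")
  out
}

#' mTOR activation score: per-sample up-versus-down gene-set t statistic
#'
#' For each sample, a two-sample t test is computed between the sample's log2
#' expression values of genes up-regulated on mTOR pathway activation and
#' those down-regulated on activation — the genes, not the samples, are the
#' observations. The absolute value of the t statistic is the mTOR score
#' (the signed statistic is always retained in `signed_score`).
#'
#' @param expr An [expression_matrix()] on log2 scale.
#' @param sets A [pathway_gene_sets()]; at least 2 up and 2 down genes must be
#'   present in `expr`.
#' @param variant `"pooled"` (Student, default) or `"welch"`.
#' @param absolute If `TRUE` (default) `score = |t|`; the signed t is kept in
#'   `signed_score` either way.
#' @return A `data.frame` (class `score_vector`) with columns `sample_id`,
#'   `score`, `signed_score`, `n_genes_used`, `flags`. Degenerate samples
#'   (both gene groups constant and equal) score 0 with flag
#'   `degenerate_variance`; a single constant group falls back to the Welch
#'   statistic with flag `one_group_constant_welch`.
#' @examples
#' m <- matrix(c(2, 4, 6, 1, 2, 3), 6, 1,
#'   dimnames = list(c("U1", "U2", "U3", "D1", "D2", "D3"), "s1")
#' )
#' sets <- pathway_gene_sets(c("U1", "U2", "U3"), c("D1", "D2", "D3"))
#' mtor_activation_score(expression_matrix(m), sets)$score # 2/sqrt(5/3)
#' @export
mtor_activation_score <- function(expr, sets, variant = c("pooled", "welch"),
                                  absolute = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sets, "pathway_gene_sets"))
  variant <- match.arg(variant)
  if (!expr$is_log2) {
    stop("expression matrix must be log2 scale (is_log2 = TRUE)", call. = FALSE)
  }
  up <- intersect(sets$up_genes, gene_ids(expr))
  down <- intersect(sets$down_genes, gene_ids(expr))
  if (length(up) < 2L || length(down) < 2L) {
    stop(sprintf(
      "need >= 2 up and >= 2 down genes in the matrix (found %d up, %d down)",
      length(up), length(down)
    ), call. = FALSE)
  }
  missing <- setdiff(c(sets$up_genes, sets$down_genes), gene_ids(expr))
  base_flag <- if (length(missing) > 0L) {
    paste0("missing_genes:", paste(missing, collapse = "|"))
  } else {
    ""
  }
  upv <- expr$values[up, , drop = FALSE]
  downv <- expr$values[down, , drop = FALSE]

  n <- ncol(expr$values)
  signed <- numeric(n)
  flags <- rep(base_flag, n)
  add_flag <- function(f, new) ifelse(nzchar(f), paste0(f, ";", new), new)
  for (j in seq_len(n)) {
    x <- upv[, j]
    y <- downv[, j]
    vx <- stats::var(x)
    vy <- stats::var(y)
    if (vx == 0 && vy == 0) {
      if (mean(x) == mean(y)) {
        signed[j] <- 0
        flags[j] <- add_flag(flags[j], "degenerate_variance")
      } else {
        signed[j] <- sign(mean(x) - mean(y)) * Inf
        flags[j] <- add_flag(flags[j], "degenerate_variance")
      }
    } else if (vx == 0 || vy == 0) {
      signed[j] <- two_sample_t(x, y, "welch")$t
      if (variant == "pooled") {
        flags[j] <- add_flag(flags[j], "one_group_constant_welch")
      }
    } else {
      signed[j] <- two_sample_t(x, y, variant)$t
    }
  }
  out <- data.frame(
    sample_id = sample_ids(expr),
    score = if (absolute) abs(signed) else signed,
    signed_score = signed,
    n_genes_used = length(up) + length(down),
    flags = flags,
    stringsAsFactors = FALSE
  )
  attr(out, "score_name") <- paste0(
    "mtor_activation:", sets$name, ":", variant,
    if (absolute) ":absolute" else ":signed"
  )
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Write a score vector as TSV
#'
#' @param scores A `score_vector` from [ar_signature_score()] or
#'   [mtor_activation_score()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
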