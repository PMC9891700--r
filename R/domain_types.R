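#' Construct an expression matrix container
#'
#' Wraps a numeric gene-by-sample matrix of log2-scale expression values
#' (conventionally log2(FPKM + pseudocount)) with validated identifiers.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Rownames
#'   are gene identifiers, colnames are sample identifiers.
#' @param is_log2 Logical flag recording that `values` are on log2 scale.
#'   Scoring functions require `TRUE`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `is_log2`. Gene identifiers are uppercased.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("KLK3", "TMPRSS2", "FKBP5"), c("s1", "s2")))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values, is_log2 = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  rownames(values) <- toupper(trimws(rownames(values)))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers: ",
      paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers: ",
      paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  structure(list(values = values, is_log2 = isTRUE(is_log2)), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples (%s scale)\n",
    nrow(x$values), ncol(x$values), if (x$is_log2) "log2" else "linear"
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(expr) rownames(expr$values)
sample_ids <- function(expr) colnames(expr$values)

#' Construct a gene signature
#'
#' A gene signature pairs an ordered gene list with a numeric reference
#' vector: the expression profile of a pathway-stimulated reference condition.
#' Per-sample activity is scored as the Pearson correlation of a sample's
#' expression over these genes against the reference ([ar_signature_score()]).
#'
#' @param genes Character vector of unique gene identifiers (uppercased on
#'   construction), length >= 3.
#' @param reference Numeric reference vector, same length as `genes`, not
#'   constant (the correlation is otherwise undefined).
#' @param name Signature label.
#' @return An object of class `gene_signature`.
#' @examples
#' gene_signature(c("KLK3", "TMPRSS2", "OPRK1"), c(2, 1.5, -1), name = "AR")
#' @export
gene_signature <- function(genes, reference, name = "signature") {
  genes <- toupper(trimws(as.character(genes)))
  reference <- as.numeric(reference)
  if (length(genes) != length(reference)) {
    stop("`genes` and `reference` must have equal length", call. = FALSE)
  }
  if (length(genes) < 3L) {
    stop("a signature needs at least 3 genes", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate signature genes: ",
      paste(unique(genes[duplicated(genes)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(is.finite(reference))) {
    stop("reference values must be finite", call. = FALSE)
  }
  if (stats::var(reference) == 0) {
    stop("reference vector is constant; correlation against it is undefined", call. = FALSE)
  }
  structure(list(name = name, genes = genes, reference = reference),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' Construct an up/down pathway gene-set pair
#'
#' Holds the genes up-regulated and down-regulated on activation of a pathway,
#' the two observation groups contrasted by [mtor_activation_score()].
#'
#' @param up_genes,down_genes Character vectors of gene identifiers
#'   (uppercased; each set >= 2 genes; sets disjoint).
#' @param name Pathway label.
#' @return An object of class `pathway_gene_sets`.
#' @examples
#' pathway_gene_sets(c("SLC7A5", "PSAT1"), c("CTSD", "NEU1"), name = "MTOR")
#' @export
pathway_gene_sets <- function(up_genes, down_genes, name = "pathway") {
  up_genes <- unique(toupper(trimws(as.character(up_genes))))
  down_genes <- unique(toupper(trimws(as.character(down_genes))))
  if (length(up_genes) < 2L || length(down_genes) < 2L) {
    stop("both up and down sets need at least 2 genes", call. = FALSE)
  }
  both <- intersect(up_genes, down_genes)
  if (length(both) > 0L) {
    stop("up and down sets must be disjoint; shared: ",
      paste(both, collapse = ", "),
      call. = FALSE
    )
  }
  structure(list(name = name, up_genes = up_genes, down_genes = down_genes),
    class = "pathway_gene_sets"
  )
}

#' @export
print.pathway_gene_sets <- function(x, ...) {
  cat(sprintf(
    "<pathway_gene_sets> '%s': %d up, %d down\n",
    x$name, length(x$up_genes), length(x$down_genes)
  ))
  invisible(x)
}
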