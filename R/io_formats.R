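# Readers and writers for every external format the pipeline touches.
# Strict validation here means downstream modules never see malformed input.

lipid_required_cols <- c(
  "feature_id", "lipid_name", "injection_index", "sample_id", "sample_type",
  "dilution_fraction", "peak_area", "protein_ug", "group"
)

#' Read a gene-by-sample expression matrix (TSV or GCT 1.2)
#'
#' Accepts either a tab-delimited table with gene identifiers in the first
#' column and one header row of sample identifiers, or a GCT 1.2 file.
#' FPKM-scale input is log2-transformed with a pseudocount; duplicate gene
#' rows (after case normalization) are collapsed by their mean with a warning.
#'
#' @param path Path to the file.
#' @param pseudocount Non-negative value added before log2 when
#'   `already_log2 = FALSE`. Default 1, the usual choice for FPKM so that
#'   zeros map to zero.
#' @param already_log2 If `TRUE`, values are taken as log2-scale as-is.
#' @return An [expression_matrix()] object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "KLK3\t1\t3", "FKBP5\t7\t0"), tf)
#' read_expression_matrix(tf) # log2(x + 1)
#' @export
read_expression_matrix <- function(path, pseudocount = 1, already_log2 = FALSE) {
  assert_scalar_number(pseudocount, "pseudocount", lower = 0)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.2")) {
    tab <- read_gct_1_2(path)
  } else {
    tab <- utils::read.delim(path,
      header = TRUE, sep = "\t", check.names = FALSE,
      colClasses = "character", quote = ""
    )
    if (ncol(tab) < 2L) {
      stop("expression table needs a gene column plus at least one sample column",
        call. = FALSE
      )
    }
  }
  genes <- toupper(trimws(tab[[1L]]))
  samples <- colnames(tab)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ",
      paste(unique(samples[duplicated(samples)]), collapse = ", "),
      call. = FALSE
    )
  }
  vals <- matrix(NA_real_, nrow = nrow(tab), ncol = length(samples))
  for (j in seq_along(samples)) {
    col <- tab[[j + 1L]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !is.na(col) & trimws(col) != "" & toupper(trimws(col)) != "NA")
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-numeric value '%s' at gene row '%s', sample column '%s'",
        col[bad[1L]], genes[bad[1L]], samples[j]
      ), call. = FALSE)
    }
    vals[, j] <- v
  }
  if (anyNA(vals)) {
    stop("expression table contains missing values", call. = FALSE)
  }
  # Collapse duplicate gene rows (case-insensitive) by mean.
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing duplicate gene rows by mean: ", paste(dup, collapse = ", "),
      call. = FALSE
    )
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  if (!already_log2) {
    vals <- log2(vals + pseudocount)
  }
  rownames(vals) <- genes
  colnames(vals) <- samples
  expression_matrix(vals, is_log2 = TRUE)
}

# GCT 1.2: "#1.2" / "<n_genes>\t<n_samples>" / header Name Description s1.. /
# data rows. Returns a data.frame shaped like the plain-TSV branch.
read_gct_1_2 <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GCT file", call. = FALSE)
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\t")[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2])) {
    stop("GCT line 2 must declare '<n_genes>\\t<n_samples>'", call. = FALSE)
  }
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L) {
    stop("GCT header must be 'Name\\tDescription\\t<samples...>'", call. = FALSE)
  }
  samples <- header[-(1:2)]
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != dims[1L]) {
    stop(sprintf(
      "GCT declares %d genes but has %d data rows", dims[1L], length(body)
    ), call. = FALSE)
  }
  if (length(samples) != dims[2L]) {
    stop(sprintf(
      "GCT declares %d samples but header has %d", dims[2L], length(samples)
    ), call. = FALSE)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header))) {
    stop("GCT data row ", which(nf != length(header))[1L], " has wrong field count",
      call. = FALSE
    )
  }
  m <- do.call(rbind, parts)
  out <- data.frame(gene = m[, 1L], check.names = FALSE)
  for (j in seq_along(samples)) out[[samples[j]]] <- m[, j + 2L]
  out
}

#' Write an expression matrix as tab-delimited text
#'
#' @param expr An [expression_matrix()].
#' @param path Output path. UTF-8, LF line endings, genes in rows.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(
    c(
      paste(c("gene", colnames(expr$values)), collapse = "\t"),
      vapply(seq_len(nrow(expr$values)), function(i) {
        paste(c(
          rownames(expr$values)[i],
          formatC(expr$values[i, ], format = "g", digits = 15)
        ), collapse = "\t")
      }, character(1))
    ),
    con = con, sep = "\n", useBytes = TRUE
  )
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' gene identifiers. Order within a set is preserved.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene identifiers.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("MTOR_UP\tna\tA\tB\tC", tf)
#' read_gmt(tf)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]), call. = FALSE)
  }
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set names: ",
      paste(unique(nms[duplicated(nms)]), collapse = ", "),
      call. = FALSE
    )
  }
  sets <- lapply(parts, function(p) {
    g <- trimws(p[-(1:2)])
    g[nzchar(g)]
  })
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named", call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(
    vapply(seq_along(sets), function(i) {
      paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
    }, character(1)),
    con = con, sep = "\n", useBytes = TRUE
  )
  invisible(path)
}

#' Read a gene signature from a two-column table
#'
#' Tab-delimited, two columns: gene identifier and numeric reference value.
#' A header row is detected (and skipped) when the second field of the first
#' line is non-numeric.
#'
#' @param path Path to the signature file.
#' @param name Signature label (defaults to the file name).
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("signature file must have two tab-separated columns", call. = FALSE)
  }
  if (length(parts) > 0L && is.na(suppressWarnings(as.numeric(parts[[1L]][2L])))) {
    parts <- parts[-1L] # header row
  }
  genes <- vapply(parts, `[[`, character(1), 1L)
  refs <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  bad <- which(is.na(refs))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric reference value for gene '%s'", genes[bad[1L]]),
      call. = FALSE
    )
  }
  gene_signature(genes, refs, name = name)
}

#' Write a gene signature as a two-column TSV
#'
#' @param sig A [gene_signature()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(
    c(
      "gene\treference",
      paste(sig$genes, formatC(sig$reference, format = "g", digits = 15), sep = "\t")
    ),
    con = con, sep = "\n", useBytes = TRUE
  )
  invisible(path)
}

#' Read a long-format targeted-lipidomics feature table
#'
#' CSV with columns `feature_id, lipid_name, injection_index, sample_id,
#' sample_type, dilution_fraction, peak_area, protein_ug, group`. Extra
#' columns are ignored with a warning. `sample_type` is normalized to
#' lowercase and must be one of `sample`, `qc`, `dilution_qc`. Features with
#' fewer than 3 QC rows are retained but flagged `insufficient_qc` (see the
#' `insufficient_qc` attribute of the result).
#'
#' @param path Path to the CSV file.
#' @return A validated `data.frame` (class `lipid_feature_table`).
#' @export
read_lipid_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(lipid_required_cols, colnames(tab))
  if (length(missing_cols) > 0L) {
    stop("lipid table is missing mandatory columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(colnames(tab), lipid_required_cols)
  if (length(extra) > 0L) {
    warning("ignoring extra lipid-table columns: ", paste(extra, collapse = ", "),
      call. = FALSE
    )
    tab <- tab[lipid_required_cols]
  }
  lipid_feature_table(tab)
}

#' Validate (and type) a lipid feature table
#'
#' Used by [read_lipid_table()] and by the simulator; validates the invariants
#' of the long-format table directly on an in-memory `data.frame`.
#'
#' @param tab `data.frame` with the mandatory lipidomics columns.
#' @return The validated table, class `c("lipid_feature_table", "data.frame")`,
#'   with attribute `insufficient_qc` listing features having < 3 QC rows.
#' @export
lipid_feature_table <- function(tab) {
  missing_cols <- setdiff(lipid_required_cols, colnames(tab))
  if (length(missing_cols) > 0L) {
    stop("lipid table is missing mandatory columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  tab$feature_id <- as.character(tab$feature_id)
  tab$lipid_name <- as.character(tab$lipid_name)
  tab$sample_id <- as.character(tab$sample_id)
  tab$group <- as.character(tab$group)
  tab$sample_type <- tolower(trimws(as.character(tab$sample_type)))
  tab$injection_index <- as.integer(tab$injection_index)
  tab$dilution_fraction <- as.numeric(tab$dilution_fraction)
  tab$peak_area <- as.numeric(tab$peak_area)
  tab$protein_ug <- as.numeric(tab$protein_ug)

  bad_type <- setdiff(unique(tab$sample_type), c("sample", "qc", "dilution_qc"))
  if (length(bad_type) > 0L) {
    stop("unknown sample_type values: ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(tab$injection_index) | tab$injection_index < 1L)) {
    stop("injection_index must be a positive integer", call. = FALSE)
  }
  if (any(is.na(tab$peak_area) | tab$peak_area < 0)) {
    stop("peak_area must be non-negative", call. = FALSE)
  }
  dq <- tab$sample_type == "dilution_qc"
  if (any(is.na(tab$dilution_fraction[dq]) | tab$dilution_fraction[dq] <= 0 |
    tab$dilution_fraction[dq] > 1)) {
    stop("dilution_fraction must lie in (0, 1] for dilution_qc rows", call. = FALSE)
  }
  tab$dilution_fraction[!dq] <- 1
  # injection_index unique per feature x injection
  key <- paste(tab$feature_id, tab$injection_index)
  if (anyDuplicated(key)) {
    stop("duplicate (feature_id, injection_index) rows", call. = FALSE)
  }
  qc_counts <- table(tab$feature_id[tab$sample_type == "qc"])
  feats <- unique(tab$feature_id)
  n_qc <- as.integer(qc_counts[feats])
  n_qc[is.na(n_qc)] <- 0L
  attr(tab, "insufficient_qc") <- feats[n_qc < 3L]
  class(tab) <- c("lipid_feature_table", "data.frame")
  tab
}

#' Write a lipid feature table as CSV
#'
#' @param tab A `lipid_feature_table` (or compatible `data.frame`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lipid_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a qPCR cycle-threshold table
#'
#' CSV with columns `gene, sample, condition, ct`; triplicate rows per
#' (gene, sample, condition) are the expected layout but any replicate count
#' >= 1 is accepted.
#'
#' @param path Path to the CSV file.
#' @return A validated `data.frame` of Ct values.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "condition", "ct")
  missing_cols <- setdiff(need, colnames(tab))
  if (length(missing_cols) > 0L) {
    stop("Ct table is missing mandatory columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(colnames(tab), need)
  if (length(extra) > 0L) {
    warning("ignoring extra Ct-table columns: ", paste(extra, collapse = ", "),
      call. = FALSE
    )
    tab <- tab[need]
  }
  tab$ct <- as.numeric(tab$ct)
  if (any(!is.finite(tab$ct))) {
    stop("all Ct values must be finite", call. = FALSE)
  }
  if (any(tab$ct <= 0 | tab$ct >= 45)) {
    warning("Ct values outside the typical (0, 45) cycle range", call. = FALSE)
  }
  tab
}
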