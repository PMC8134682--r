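#' Construct an expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns) carrying an explicit scale tag, either `"linear"` (e.g. FPKM/TPM)
#' or `"log2"` (e.g. normalized microarray intensities). All downstream
#' operations that care about scale check this tag rather than guessing.
#'
#' @param values Numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids). All values must be finite; linear-scale values
#'   must be non-negative.
#' @param scale `"linear"` or `"log2"`.
#' @return A matrix of class `expr_matrix` with an `expr_scale` attribute.
#' @export
expr_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale expression values must be >= 0")
  structure(values, expr_scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
expr_scale <- function(m) {
  s <- attr(m, "expr_scale")
  if (is.null(s)) "linear" else s
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod()
  if (is.matrix(out)) {
    attr(out, "expr_scale") <- attr(x, "expr_scale")
    class(out) <- class(x)
  }
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), expr_scale(x)))
  y <- unclass(x)
  print(y[seq_len(min(5L, nrow(y))), seq_len(min(5L, ncol(y))), drop = FALSE], ...)
  invisible(x)
}

# Collapse duplicate gene ids, keeping the row with the highest mean
# expression (common microarray multi-probe convention).
collapse_duplicate_genes <- function(values) {
  ids <- rownames(values)
  if (!anyDuplicated(ids)) return(values)
  means <- rowMeans(values)
  ord <- order(ids, -means)
  keep <- ord[!duplicated(ids[ord])]
  values[sort(keep), , drop = FALSE]
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV layout: header row of sample ids, first column gene ids. GCT files
#' (first line `#1.2`, second line dimensions, `Name`/`Description` columns)
#' are detected automatically. Duplicate gene rows are collapsed by keeping
#' the row with the highest mean expression; duplicate sample ids are an
#' error.
#'
#' @param path File path.
#' @param scale Scale tag to record (`"linear"` or `"log2"`). A heuristic
#'   warning is emitted when the tag looks inconsistent with the values
#'   (max value below 30 suggests log2).
#' @return An [expr_matrix].
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  first <- readLines(path, n = 1L)
  is_gct <- startsWith(first, "#1.2")
  skip <- if (is_gct) 2L else 0L
  df <- utils::read.delim(path, skip = skip, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (is_gct) {
    desc <- tolower(names(df)) == "description"
    df <- df[, !desc, drop = FALSE]
  }
  gene_ids <- as.character(df[[1L]])
  sample_ids <- names(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s) in header of ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric value %s at row %d (gene %s), column %s",
                     dQuote(col[bad[1L]]), bad[1L], gene_ids[bad[1L]],
                     sample_ids[j]))
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  m <- collapse_duplicate_genes(m)
  if (scale == "linear" && max(m) < 30)
    warning("max value < 30: values look log2-scaled but scale = 'linear'")
  expr_matrix(m, scale)
}

#' Write an expression matrix as TSV
#' @param m An [expr_matrix] or plain matrix.
#' @param path Output path.
#' @param gene_col Name of the gene-id column.
#' @export
write_expression_matrix <- function(m, path, gene_col = "gene_id") {
  df <- data.frame(rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert FPKM to TPM
#'
#' Per sample j, `TPM_ij = FPKM_ij / sum_i(FPKM_ij) * 1e6`, so every column
#' sums to one million. Requires linear scale and at least one positive value
#' per sample.
#'
#' @param m Linear-scale [expr_matrix].
#' @return An [expr_matrix] whose columns each sum to 1e6.
#' @export
fpkm_to_tpm <- function(m) {
  if (expr_scale(m) != "linear")
    stop("fpkm_to_tpm requires linear-scale input")
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero))
    stop("all-zero sample column(s): ", paste(colnames(m)[zero], collapse = ", "))
  out <- sweep(unclass(m), 2L, cs, "/") * 1e6
  expr_matrix(out, "linear")
}

#' Log2-transform a linear expression matrix
#' @param m Linear-scale [expr_matrix].
#' @param pseudocount Offset added before taking log2.
#' @export
to_log2 <- function(m, pseudocount = 1) {
  if (expr_scale(m) != "linear") stop("input is already log2-scale")
  expr_matrix(log2(unclass(m) + pseudocount), "log2")
}
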