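#' Validate a genes-by-samples expression matrix
#'
#' An expression matrix is a base `matrix` of finite log2-scale values with
#' unique gene identifiers as row names and unique sample identifiers as
#' column names. All downstream functions consume this container.
#'
#' @param x A numeric matrix with gene row names and sample column names.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expression matrix must be a numeric matrix")
  }
  genes <- rownames(x)
  samples <- colnames(x)
  if (is.null(genes) || is.null(samples)) {
    abort("expression matrix must have gene row names and sample column names")
  }
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g) > 0) {
    abort(paste0("duplicated gene id(s): ", paste(head(dup_g, 5), collapse = ", ")))
  }
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0) {
    abort(paste0("duplicated sample id(s): ", paste(head(dup_s, 5), collapse = ", ")))
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-finite expression value at gene '%s', sample '%s' (missing values are rejected, not imputed)",
      genes[bad[1]], samples[bad[2]]
    ))
  }
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample identifiers and
#' whose first column holds gene identifiers; cells are log2-scale expression
#' values. Row and column order are preserved.
#'
#' @param path Path to a TSV file.
#' @return A validated genes-by-samples numeric matrix.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  if (length(lines) < 2) abort(paste0("expression TSV needs a header and at least one gene row: ", path))
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  ncell <- length(header)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != ncell)) {
    bad <- which(widths != ncell)[1] + 1L
    abort(sprintf("ragged row at line %d: expected %d fields, found %d", bad, ncell, widths[bad - 1L]))
  }
  genes <- vapply(rows, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1]), numeric(length(samples)))
  )
  # vapply over rows gives samples x genes; transpose to genes x samples
  m <- if (length(samples) == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-numeric cell at line %d (gene '%s', sample '%s')",
      bad[1] + 1L, genes[bad[1]], samples[bad[2]]
    ))
  }
  dimnames(m) <- list(genes, samples)
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix to TSV
#'
#' @param x A validated expression matrix.
#' @param path Output path.
#' @param id_column Name used for the gene-identifier column header.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, id_column = "gene_id") {
  validate_expression_matrix(x)
  header <- paste(c(id_column, colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
      collapse = "\t"
    )
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
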