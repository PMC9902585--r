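#' Coerce an expression tibble to a numeric gene-by-sample matrix
#'
#' Expression data travels through the package as a tibble whose first column
#' (`gene`) holds gene symbols and whose remaining columns are numeric
#' per-sample values. This helper converts that layout to a base matrix with
#' gene symbols as rownames; matrices are passed through unchanged.
#'
#' @param x A gene-by-sample expression tibble/data frame (first column
#'   `gene`), or a numeric matrix with gene rownames.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
as_expr_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("expression matrix must have gene rownames")
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort("expression data must be a data frame with a `gene` column and >=1 sample column")
  }
  genes <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("all sample columns must be numeric")
  rownames(m) <- genes
  m
}

#' Convert a gene-by-sample matrix to an expression tibble
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @return A tibble with first column `gene` and one numeric column per sample.
#' @export
as_expr_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene = rownames(m)), out)
}

# Integer in [0, 2^31): deterministic per-label RNG substream offsets.
hash_label <- function(label, seed) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147480009
  as.integer((h + (seed %% 2147480009)) %% 2147480009)
}

check_cpm <- function(m, tol = 1e-6) {
  cs <- colSums(m)
  ok <- abs(cs - 1e6) <= tol * 1e6
  if (!all(ok)) {
    abort(paste0(
      "matrix does not look counts-per-million normalized (column sums != 1e6); ",
      "run cpm_normalize() first. Offending samples: ",
      paste(head(colnames(m)[!ok], 5), collapse = ", ")
    ))
  }
  invisible(m)
}
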