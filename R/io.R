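validation_error <- function(msg) abort(msg, class = "coassoc_validation_error")

#' Read a gene-by-sample expression matrix
#'
#' Accepts plain or gzip-compressed tab-delimited text (genes in rows, header
#' row of sample IDs, first column gene symbols) or a MatrixMarket triplet
#' file with companion gene/sample label files. Gene symbols are uppercased
#' on ingest; duplicated symbols are collapsed by summing their rows, with a
#' warning.
#'
#' @param path Path to the `.tsv`/`.tsv.gz` or `.mtx` file.
#' @param gene_file,sample_file Sidecar label files for MatrixMarket input
#'   (one label per line). Default: `path` with `.mtx[.gz]` replaced by
#'   `.genes.txt` / `.samples.txt`.
#' @return An expression tibble (first column `gene`).
#' @export
read_expression <- function(path, gene_file = NULL, sample_file = NULL) {
  if (!file.exists(path)) validation_error(paste0("file not found: ", path))
  if (grepl("\\.mtx(\\.gz)?$", path)) {
    stem <- sub("\\.mtx(\\.gz)?$", "", path)
    if (is.null(gene_file)) gene_file <- paste0(stem, ".genes.txt")
    if (is.null(sample_file)) sample_file <- paste0(stem, ".samples.txt")
    for (f in c(gene_file, sample_file)) {
      if (!file.exists(f)) validation_error(paste0("missing sidecar label file: ", f))
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- toupper(readr::read_lines(gene_file))
    samples <- readr::read_lines(sample_file)
    if (length(genes) != nrow(m) || length(samples) != ncol(m)) {
      validation_error("sidecar label lengths do not match matrix dimensions")
    }
    dimnames(m) <- list(genes, samples)
  } else {
    tb <- suppressWarnings(
      readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                      progress = FALSE, name_repair = "minimal")
    )
    pr <- readr::problems(tb)
    if (nrow(pr) > 0) {
      validation_error(paste0(
        "malformed matrix file ", path, " at row(s): ",
        paste(head(unique(pr$row), 10), collapse = ", ")
      ))
    }
    if (ncol(tb) < 2) validation_error("matrix file needs a gene column and >=1 sample column")
    num <- vapply(tb[-1], is.numeric, logical(1))
    if (!all(num)) {
      validation_error(paste0("non-numeric sample column(s): ",
                              paste(names(tb)[-1][!num], collapse = ", ")))
    }
    if (anyNA(tb)) {
      bad <- which(rowSums(is.na(tb[-1])) > 0)
      validation_error(paste0("missing/non-numeric cells at data row(s): ",
                              paste(head(bad, 10), collapse = ", ")))
    }
    m <- as.matrix(tb[-1])
    rownames(m) <- toupper(as.character(tb[[1]]))
  }
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    warn(paste0("collapsing duplicated gene symbol(s) by sum: ",
                paste(head(dup, 10), collapse = ", ")))
    m <- rowsum(m, group = rownames(m))
  }
  as_expr_tbl(m)
}

#' Write an expression matrix as TSV or MatrixMarket
#'
#' @param x Expression tibble or matrix.
#' @param path Output path; `.gz` suffix gzip-compresses TSV output, `.mtx`
#'   selects MatrixMarket triplets with `.genes.txt`/`.samples.txt` sidecars.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  m <- as_expr_matrix(x)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    readr::write_lines(rownames(m), paste0(stem, ".genes.txt"))
    readr::write_lines(colnames(m), paste0(stem, ".samples.txt"))
  } else {
    readr::write_tsv(as_expr_tbl(m), path, progress = FALSE)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated dialect: field 1 set name, field 2 description, fields 3+
#' gene symbols (uppercased). Lines with fewer than 3 fields are rejected
#' with their line number.
#'
#' @param path Path to a `.gmt` file (plain or gzipped).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) validation_error(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) validation_error(paste0("empty GMT file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    validation_error(paste0("malformed GMT line(s) (need >=3 tab-separated fields): ",
                            paste(head(bad, 10), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  lines <- mapply(function(nm, g) paste(c(nm, description, g), collapse = "\t"),
                  names(sets), sets)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a receptor annotation
#'
#' One receptor gene symbol per line (first tab-separated field used; `#`
#' comment lines ignored); symbols are uppercased and deduplicated.
#'
#' @param path Path to the annotation file.
#' @return Character vector of receptor symbols.
#' @export
read_receptors <- function(path) {
  if (!file.exists(path)) validation_error(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sym <- unique(toupper(vapply(strsplit(lines, "\t", fixed = TRUE),
                               `[`, character(1), 1)))
  sym <- sym[!sym %in% c("GENE", "SYMBOL", "RECEPTOR")]  # tolerate a header
  if (length(sym) == 0) validation_error(paste0("no receptor symbols in ", path))
  sym
}

write_tsv_prov <- function(df, path, prov) {
  writeLines(paste0("# ", prov), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

prov_line <- function(params) {
  paste0("coassoc v", as.character(utils::packageVersion("coassoc")), " | ",
         paste(names(params), unlist(params), sep = "=", collapse = " "))
}

#' Write the tables of a screen result to a directory
#'
#' Emits `gene_stats.tsv`, one TSV per significant set, `intersection.tsv`
#' and `receptors_ranked.tsv`, each with a `#` provenance header carrying
#' version, seed and parameters.
#'
#' @param result A [run_screen()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_screen <- function(result, dir) {
  stopifnot(inherits(result, "screen_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- prov_line(result$params)
  paths <- c(
    gene_stats = file.path(dir, "gene_stats.tsv"),
    set_emt = file.path(dir, "set_emt.tsv"),
    set_cycle = file.path(dir, "set_cycle.tsv"),
    set_joint = file.path(dir, "set_joint.tsv"),
    intersection = file.path(dir, "intersection.tsv"),
    receptors_ranked = file.path(dir, "receptors_ranked.tsv")
  )
  write_tsv_prov(result$gene_stats, paths["gene_stats"], prov)
  write_tsv_prov(tibble(gene = result$sets$emt), paths["set_emt"], prov)
  write_tsv_prov(tibble(gene = result$sets$cycle), paths["set_cycle"], prov)
  write_tsv_prov(tibble(gene = result$sets$joint), paths["set_joint"], prov)
  write_tsv_prov(tibble(gene = result$intersection), paths["intersection"], prov)
  write_tsv_prov(rank_receptors(result), paths["receptors_ranked"], prov)
  invisible(paths)
}
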