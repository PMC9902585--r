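#' Counts-per-million normalization
#'
#' Scales every sample column so it sums to one million, preserving gene and
#' sample labels.
#'
#' @param x Expression tibble (first column `gene`) or matrix of raw counts;
#'   all entries must be non-negative and no sample may be all-zero.
#' @return A tibble in the same layout, each sample column summing to 1e6.
#' @examples
#' x <- tibble::tibble(gene = c("A", "B", "C"), s1 = c(2, 3, 5))
#' cpm_normalize(x)
#' @export
cpm_normalize <- function(x) {
  m <- as_expr_matrix(x)
  if (any(m < 0)) abort("expression values must be non-negative")
  cs <- colSums(m)
  if (any(cs == 0)) {
    abort(paste0("all-zero sample column(s): ",
                 paste(colnames(m)[cs == 0], collapse = ", ")))
  }
  as_expr_tbl(sweep(m, 2, 1e6 / cs, `*`))
}

#' Select highly variable genes by CV residual over a mean trend
#'
#' Ranks genes by how far their coefficient of variation (CV = sd/mean across
#' samples) sits above the typical CV of genes with similar mean expression.
#' The trend is a rolling median of CV within 20 mean-quantile windows; the
#' selection statistic is `CV - window median`. Deterministic; ties broken by
#' gene symbol.
#'
#' @param x CPM-normalized expression tibble or matrix (see [cpm_normalize()]).
#' @param top_n Number of genes to return.
#' @param n_windows Number of mean-quantile windows for the CV trend.
#' @return A tibble with columns `gene`, `mean`, `cv`, `cv_residual`, sorted
#'   by decreasing residual, `top_n` rows.
#' @export
select_variable_genes <- function(x, top_n, n_windows = 20) {
  m <- as_expr_matrix(x)
  check_cpm(m)
  mu <- rowMeans(m)
  keep <- mu > 0
  if (sum(keep) < top_n) {
    abort(sprintf("only %d genes have a computable CV; top_n = %d requested",
                  sum(keep), top_n))
  }
  g <- rownames(m)[keep]
  mu <- mu[keep]
  cv <- apply(m[keep, , drop = FALSE], 1, sd) / mu
  ord <- order(mu, g)  # ascending mean, symbol tie-break
  win <- ceiling(seq_along(ord) / (length(ord) / n_windows))
  trend <- stats::ave(cv[ord], win, FUN = median)
  resid <- numeric(length(cv))
  resid[ord] <- cv[ord] - trend
  out <- tibble(gene = g, mean = mu, cv = cv, cv_residual = resid)
  out <- dplyr::arrange(out, dplyr::desc(.data$cv_residual), .data$gene)
  out[seq_len(top_n), ]
}

#' Assign genes to contiguous expression-rank bins
#'
#' Genes are ranked by mean expression across samples (highest first, ties by
#' gene symbol) and split into `n_bins` contiguous rank intervals whose sizes
#' differ by at most one (earlier bins take the remainder).
#'
#' @param x CPM-normalized expression tibble or matrix.
#' @param n_bins Number of rank intervals (default 25).
#' @return A tibble with columns `gene`, `mean_expr`, `rank`, `bin`.
#' @export
assign_rank_bins <- function(x, n_bins = 25) {
  m <- as_expr_matrix(x)
  ng <- nrow(m)
  stopifnot(n_bins >= 1)
  if (n_bins > ng) abort("n_bins exceeds the number of genes")
  mu <- rowMeans(m)
  ord <- order(-mu, rownames(m))
  base <- ng %/% n_bins
  extra <- ng %% n_bins
  sizes <- rep(base, n_bins) + rep(c(1L, 0L), c(extra, n_bins - extra))
  bins <- rep(seq_len(n_bins), sizes)
  tibble(
    gene = rownames(m)[ord],
    mean_expr = mu[ord],
    rank = seq_len(ng),
    bin = bins
  )
}

#' Per-sample program activity scores against rank-matched control genes
#'
#' For a program (functional attribute) gene set, the score of a sample is the
#' mean expression of the program genes minus the mean expression of a control
#' pool of expression-matched background genes: genes are binned into
#' `n_bins` rank intervals by mean expression, and from every bin containing a
#' program gene the top `n_control_per_bin` non-program genes (by the same
#' expression ranking) enter the pool. Scores are computed on log2(CPM + 1).
#' The default control pool is deterministic; set `resample_controls = TRUE`
#' to draw the per-bin controls at random instead (seeded).
#'
#' @param x CPM-normalized expression tibble or matrix.
#' @param program Character vector of program gene symbols.
#' @param attribute Name of the functional attribute (e.g. `"EMT"`).
#' @param n_bins Number of expression-rank bins (default 25).
#' @param n_control_per_bin Control genes taken per program-occupied bin
#'   (default 100).
#' @param seed Integer seed; only consulted when `resample_controls = TRUE`.
#' @param resample_controls Draw controls at random within each bin instead of
#'   taking the top-ranked ones.
#' @param log_transform Compute differential means on log2(CPM + 1)
#'   (default) rather than raw CPM.
#' @return A tibble of class `coassoc_activity` with columns `sample`,
#'   `attribute`, `score`; the control-pool record is attached as attributes
#'   `controls` (tibble of bin, gene) and `program`.
#' @export
score_activity <- function(x, program, attribute = "activity",
                           n_bins = 25, n_control_per_bin = 100,
                           seed = 1, resample_controls = FALSE,
                           log_transform = TRUE) {
  m <- as_expr_matrix(x)
  check_cpm(m)
  program <- toupper(program)
  missing <- setdiff(program, rownames(m))
  present <- intersect(program, rownames(m))
  if (length(present) == 0) {
    abort(paste0("no program gene found in the matrix; missing: ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  bins <- assign_rank_bins(m, n_bins = n_bins)
  occupied <- sort(unique(bins$bin[bins$gene %in% present]))
  pick <- function(b) {
    eligible <- bins$gene[bins$bin == b & !(bins$gene %in% present)]
    if (length(eligible) == 0) return(character(0))
    if (resample_controls) {
      withr::with_seed(hash_label(paste0("bin", b), seed), {
        eligible[sort(sample.int(length(eligible),
                                 min(n_control_per_bin, length(eligible))))]
      })
    } else {
      head(eligible, n_control_per_bin)  # already in expression-rank order
    }
  }
  controls <- lapply(occupied, pick)
  empty <- occupied[lengths(controls) == 0]
  if (length(empty) > 0) {
    warn(sprintf("bin(s) %s contain only program genes; no controls drawn there",
                 paste(empty, collapse = ", ")))
  }
  control_tbl <- tibble(
    bin = rep(occupied, lengths(controls)),
    gene = unlist(controls, use.names = FALSE)
  )
  if (nrow(control_tbl) == 0) {
    abort("control pool is empty: program genes exhaust every occupied bin")
  }
  vals <- if (log_transform) log2(m + 1) else m
  score <- colMeans(vals[present, , drop = FALSE]) -
    colMeans(vals[control_tbl$gene, , drop = FALSE])
  out <- tibble(sample = colnames(m), attribute = attribute, score = unname(score))
  attr(out, "controls") <- control_tbl
  attr(out, "program") <- present
  class(out) <- c("coassoc_activity", class(out))
  out
}

#' @describeIn score_activity Histogram of per-sample activity scores.
#' @param object A `coassoc_activity` tibble.
#' @param ... Ignored.
#' @export
autoplot.coassoc_activity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::facet_wrap(~attribute) +
    ggplot2::labs(x = "activity score (program - matched controls, log2 CPM)",
                  y = "samples")
}
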