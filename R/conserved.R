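#' Cross-dataset conserved correlation with a focal gene
#'
#' Within each dataset, computes the Spearman correlation between the focal
#' gene and every other gene across samples, with a two-sided p-value
#' (t approximation) and BH adjustment within the dataset. A gene is
#' significant in a dataset when its adjusted p (or raw p, if
#' `adjust = "none"`) is `<= alpha`; the conserved set contains the genes
#' significant in at least `k` datasets (default 2, the
#' "at least two of N independent datasets" rule).
#'
#' @param datasets Named list of expression tibbles/matrices (or
#'   `synthetic_dataset` objects); genes in rows, samples in columns.
#' @param focal_gene Focal gene symbol; must be present in every dataset.
#' @param alpha Per-dataset significance level (default 0.05).
#' @param k Minimum number of datasets with significant correlation
#'   (default 2).
#' @param adjust `"BH"` (default) or `"none"` for the per-dataset p-values.
#' @return An object of class `conservation_result`: list with `per_dataset`
#'   (long tibble: dataset, gene, rho, p, q, significant), `summary`
#'   (per-gene `n_significant_datasets`, `conserved`), `conserved_genes`,
#'   and `params`.
#' @export
correlate_focal <- function(datasets, focal_gene, alpha = 0.05, k = 2,
                            adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1, k >= 1)
  if (length(datasets) == 0) abort("datasets must be a nonempty list")
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  focal_gene <- toupper(focal_gene)

  per <- purrr::imap(datasets, function(d, nm) {
    if (inherits(d, "synthetic_dataset")) d <- d$expression
    m <- as_expr_matrix(d)
    if (!(focal_gene %in% rownames(m))) {
      abort(sprintf("focal gene %s missing in dataset '%s'", focal_gene, nm))
    }
    n <- ncol(m)
    rk <- t(apply(m, 1, rank))
    rho <- suppressWarnings(as.numeric(cor(t(rk), rk[focal_gene, ])))
    rho[is.na(rho)] <- 0
    rc <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
    p <- 2 * pt(-abs(rc * sqrt((n - 2) / (1 - rc^2))), df = n - 2)
    out <- tibble(dataset = nm, gene = rownames(m), rho = rho, p = p) |>
      dplyr::filter(.data$gene != focal_gene)
    out$q <- p.adjust(out$p, "BH")
    out$significant <- (if (adjust == "BH") out$q else out$p) <= alpha
    out
  })
  long <- dplyr::bind_rows(per)
  summary <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_significant_datasets = sum(.data$significant),
                     .groups = "drop") |>
    dplyr::mutate(conserved = .data$n_significant_datasets >= k) |>
    dplyr::arrange(dplyr::desc(.data$n_significant_datasets), .data$gene)
  structure(
    list(
      per_dataset = long,
      summary = summary,
      conserved_genes = summary$gene[summary$conserved],
      params = list(focal_gene = focal_gene, alpha = alpha, k = k,
                    adjust = adjust, n_datasets = length(datasets))
    ),
    class = "conservation_result"
  )
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf(
    "<conservation_result> focal %s | %d datasets | %d conserved genes (k >= %d, alpha %.3g, %s)\n",
    x$params$focal_gene, x$params$n_datasets, length(x$conserved_genes),
    x$params$k, x$params$alpha, x$params$adjust
  ))
  invisible(x)
}

#' Tidy a conserved-correlation result
#'
#' @param x A `conservation_result`.
#' @param ... Ignored.
#' @return For `tidy()`: the per-gene summary tibble. For `glance()`: one row
#'   of counts and parameters. For `autoplot()`: a bar chart of how many
#'   genes reach each dataset count.
#' @export
tidy.conservation_result <- function(x, ...) x$summary

#' @rdname tidy.conservation_result
#' @export
glance.conservation_result <- function(x, ...) {
  tibble(
    focal_gene = x$params$focal_gene,
    n_datasets = x$params$n_datasets,
    n_genes = nrow(x$summary),
    n_conserved = length(x$conserved_genes),
    k = x$params$k, alpha = x$params$alpha, adjust = x$params$adjust
  )
}

#' @rdname tidy.conservation_result
#' @param object A `conservation_result`.
#' @export
autoplot.conservation_result <- function(object, ...) {
  df <- dplyr::count(object$summary, .data$n_significant_datasets)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_significant_datasets, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$params$k - 0.5, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "datasets with significant focal-gene correlation",
                  y = "genes")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each pathway for over-representation of the selected gene set within
#' a stated universe: one-sided hypergeometric tail
#' `P(overlap >= observed)`, BH-adjusted across pathways. Pathways are
#' intersected with the universe first; pathways disjoint from the universe
#' are dropped with a warning.
#'
#' @param selected Character vector of selected genes (subset of `universe`).
#' @param pathways Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector, the gene universe.
#' @return Tibble: `pathway`, `overlap`, `pathway_size`, `selected_size`,
#'   `universe_size`, `p_value`, `q_value`, sorted by p.
#' @examples
#' ora(paste0("G", 1:5), list(hit = paste0("G", 1:5)), paste0("G", 1:20))
#' @export
ora <- function(selected, pathways, universe) {
  selected <- unique(toupper(selected))
  universe <- unique(toupper(universe))
  if (length(universe) == 0) abort("universe must be nonempty")
  if (length(selected) == 0) abort("selected gene set must be nonempty")
  if (!all(selected %in% universe)) {
    abort("selected genes must be a subset of the universe")
  }
  pw <- lapply(pathways, function(g) intersect(unique(toupper(g)), universe))
  drop <- lengths(pw) == 0
  if (any(drop)) {
    warn(paste0("dropping pathway(s) disjoint from the universe: ",
                paste(names(pw)[drop], collapse = ", ")))
    pw <- pw[!drop]
  }
  if (length(pw) == 0) abort("no pathway overlaps the universe")
  N <- length(universe)
  n_sel <- length(selected)
  out <- purrr::imap(pw, function(g, nm) {
    K <- length(g)
    ov <- length(intersect(g, selected))
    tibble(
      pathway = nm, overlap = ov, pathway_size = K,
      selected_size = n_sel, universe_size = N,
      p_value = phyper(ov - 1, K, N - K, n_sel, lower.tail = FALSE)
    )
  }) |> dplyr::bind_rows()
  out$q_value <- p.adjust(out$p_value, "BH")
  dplyr::arrange(out, .data$p_value, .data$pathway)
}
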