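#' Screen genes co-associated with EMT and mitotic activity
#'
#' For every gene, estimates (i) pairwise mutual information against the EMT
#' activity score, (ii) pairwise MI against the mitotic activity score, and
#' (iii) the three-way co-information with both scores, each with a
#' permutation p-value (gene labels permuted; absolute value of the signed
#' co-information). Within each of the three statistic families, p-values are
#' BH-adjusted across genes and the significant set is `q <= q_threshold`.
#' The screen reports the three sets, their intersection, the receptors in
#' the intersection, and the Spearman correlation (on the untransformed
#' values) of every gene with each score for directionality.
#'
#' Internally samples are put in sample-ID order and each gene gets its own
#' RNG substream derived from `seed` and the gene symbol, so results are
#' exactly invariant to row and column reordering of the input.
#'
#' @param x Expression tibble or matrix (counts or normalized; values must be
#'   non-negative). Expression vectors are total-normalized/log2-transformed
#'   (zeros to 1) and quantile-binned before entropy estimation.
#' @param emt_scores,cycle_scores Activity-score tibbles from
#'   [score_activity()] (or any tibble with `sample` and `score` columns)
#'   covering exactly the matrix samples.
#' @param receptors Character vector of receptor gene symbols (or a data
#'   frame whose first column holds them).
#' @param n_perm Permutations per gene and statistic (default 999).
#' @param q_threshold BH-FDR threshold defining the significant sets.
#' @param n_levels Quantile-binning levels for discretization (default 10).
#' @param seed Master seed for the permutation streams.
#' @return An object of class `screen_result`: list with `gene_stats`
#'   (per-gene tibble of MI/NMI/p/q/rho columns), `sets` (named list
#'   `emt`, `cycle`, `joint`), `intersection`, `receptors_in_intersection`,
#'   and `params`. See [tidy.screen_result()], [rank_receptors()].
#' @export
run_screen <- function(x, emt_scores, cycle_scores, receptors,
                       n_perm = 999, q_threshold = 0.05, n_levels = 10,
                       seed = 1) {
  stopifnot(q_threshold > 0, q_threshold < 1)
  m <- as_expr_matrix(x)
  if (any(m < 0)) abort("expression values must be non-negative")
  if (is.data.frame(receptors)) receptors <- receptors[[1]]
  receptors <- toupper(as.character(receptors))

  grab <- function(s, label) {
    if (!is.data.frame(s) || !all(c("sample", "score") %in% names(s))) {
      abort(sprintf("%s must be a tibble with columns sample, score", label))
    }
    setNames(s$score, s$sample)
  }
  emt <- grab(emt_scores, "emt_scores")
  cyc <- grab(cycle_scores, "cycle_scores")
  for (lab in list(c("emt_scores", "emt"), c("cycle_scores", "cyc"))) {
    sc <- if (lab[2] == "emt") emt else cyc
    miss <- setdiff(colnames(m), names(sc))
    extra <- setdiff(names(sc), colnames(m))
    if (length(miss) || length(extra)) {
      abort(sprintf(
        "sample mismatch between matrix and %s: missing [%s], extra [%s]",
        lab[1], paste(head(miss, 5), collapse = ", "),
        paste(head(extra, 5), collapse = ", ")
      ))
    }
  }

  # canonical order: samples by ID, genes by symbol
  samp <- sort(colnames(m))
  m <- m[order(rownames(m)), samp, drop = FALSE]
  emt <- emt[samp]
  cyc <- cyc[samp]

  d_emt <- discretize(emt, n_levels)
  d_cyc <- discretize(cyc, n_levels)
  L1 <- n_levels_of(d_emt)
  L2 <- n_levels_of(d_cyc)

  genes <- rownames(m)
  ng <- length(genes)
  cols <- c("mi_emt", "mi_cycle", "mi_joint", "nmi_emt", "nmi_cycle",
            "nmi_joint", "p_emt", "p_cycle", "p_joint")
  st <- matrix(NA_real_, ng, length(cols), dimnames = list(genes, cols))
  for (i in seq_len(ng)) {
    dg <- discretize(preprocess_for_entropy(m[i, ]), n_levels)
    res <- withr::with_seed(
      hash_label(genes[i], seed),
      perm_coassoc_cpp(as.integer(dg), n_levels_of(dg),
                       as.integer(d_emt), L1, as.integer(d_cyc), L2,
                       as.integer(n_perm))
    )
    st[i, ] <- c(
      res$mi1, res$mi2, res$ci,
      normalized_mi(res$mi1, c(res$h_target, res$h1)),
      normalized_mi(res$mi2, c(res$h_target, res$h2)),
      normalized_mi(res$ci, c(res$h_target, res$h1, res$h2)),
      (1 + res$exceed1) / (1 + n_perm),
      (1 + res$exceed2) / (1 + n_perm),
      (1 + res$exceed3) / (1 + n_perm)
    )
  }

  gs <- as_tibble(st) |> dplyr::mutate(gene = genes, .before = 1)
  gs$q_emt <- p.adjust(gs$p_emt, "BH")
  gs$q_cycle <- p.adjust(gs$p_cycle, "BH")
  gs$q_joint <- p.adjust(gs$p_joint, "BH")

  # Spearman directionality on the values as supplied
  rk <- t(apply(m, 1, rank))
  rho_emt <- suppressWarnings(as.numeric(cor(t(rk), rank(emt))))
  rho_cyc <- suppressWarnings(as.numeric(cor(t(rk), rank(cyc))))
  nsamp <- ncol(m)
  rho_p <- function(r) {
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    2 * pt(-abs(r * sqrt((nsamp - 2) / (1 - r^2))), df = nsamp - 2)
  }
  gs$rho_emt <- ifelse(is.na(rho_emt), 0, rho_emt)
  gs$rho_cycle <- ifelse(is.na(rho_cyc), 0, rho_cyc)
  gs$rho_p_emt <- rho_p(gs$rho_emt)
  gs$rho_p_cycle <- rho_p(gs$rho_cycle)
  gs$rho_q_emt <- p.adjust(gs$rho_p_emt, "BH")
  gs$rho_q_cycle <- p.adjust(gs$rho_p_cycle, "BH")

  sets <- list(
    emt = gs$gene[gs$q_emt <= q_threshold],
    cycle = gs$gene[gs$q_cycle <= q_threshold],
    joint = gs$gene[gs$q_joint <= q_threshold]
  )
  intersection <- Reduce(intersect, sets)
  rec_in_matrix <- intersect(receptors, genes)
  if (length(rec_in_matrix) == 0) {
    warn("no receptor annotation gene is present in the matrix")
  }
  structure(
    list(
      gene_stats = gs,
      sets = sets,
      intersection = intersection,
      receptors_in_intersection = intersect(intersection, rec_in_matrix),
      receptors = rec_in_matrix,
      params = list(n_perm = n_perm, q_threshold = q_threshold,
                    n_levels = n_levels, seed = seed)
    ),
    class = "screen_result"
  )
}

#' Rank screened receptors by Spearman directionality
#'
#' Orders the receptors found in the screen intersection by their signed
#' Spearman correlation with the EMT score (most negative first — the
#' inversely co-correlated receptors lead), breaking ties by the correlation
#' with the mitotic score and then by symbol.
#'
#' @param result A [run_screen()] result.
#' @return Tibble of receptors with their MI, rho and q statistics, ordered.
#' @export
rank_receptors <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  result$gene_stats |>
    dplyr::filter(.data$gene %in% result$receptors_in_intersection) |>
    dplyr::arrange(.data$rho_emt, .data$rho_cycle, .data$gene)
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    paste0("<screen_result> %d genes | significant: EMT %d, cycle %d, ",
           "joint %d | intersection %d (receptors %d)\n"),
    nrow(x$gene_stats), length(x$sets$emt), length(x$sets$cycle),
    length(x$sets$joint), length(x$intersection),
    length(x$receptors_in_intersection)
  ))
  invisible(x)
}

#' Tidy a co-association screen result
#'
#' @param x A `screen_result`.
#' @param ... Ignored.
#' @return The per-gene statistics tibble with logical membership columns
#'   `sig_emt`, `sig_cycle`, `sig_joint`, `in_intersection`, `is_receptor`.
#' @export
tidy.screen_result <- function(x, ...) {
  x$gene_stats |>
    dplyr::mutate(
      sig_emt = .data$gene %in% x$sets$emt,
      sig_cycle = .data$gene %in% x$sets$cycle,
      sig_joint = .data$gene %in% x$sets$joint,
      in_intersection = .data$gene %in% x$intersection,
      is_receptor = .data$gene %in% x$receptors
    )
}

#' @rdname tidy.screen_result
#' @return For `glance()`: a one-row tibble of set sizes and parameters.
#' @export
glance.screen_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x$gene_stats),
    n_sig_emt = length(x$sets$emt),
    n_sig_cycle = length(x$sets$cycle),
    n_sig_joint = length(x$sets$joint),
    n_intersection = length(x$intersection),
    n_receptors_in_intersection = length(x$receptors_in_intersection),
    q_threshold = x$params$q_threshold,
    n_perm = x$params$n_perm
  )
}

#' @rdname tidy.screen_result
#' @param object A `screen_result`.
#' @return For `autoplot()`: a ggplot of per-gene Spearman directionality,
#'   highlighting the intersection and its receptors.
#' @export
autoplot.screen_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho_emt, y = .data$rho_cycle)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_intersection),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$gene %in% object$receptors_in_intersection),
      shape = 21, size = 2.6, stroke = 0.8, colour = "black"
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Spearman rho vs EMT score", y = "Spearman rho vs mitotic score",
                  colour = "in intersection")
}
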