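#' Preprocess a non-negative vector for entropy estimation
#'
#' Zero values are replaced by 1, the vector is normalized to its total, and
#' the result is log2-transformed. This is the standard preparation applied to
#' expression vectors before discretization; it is monotone except for the
#' zero-to-one replacement, which merges zeros with ones (a deliberate tie).
#'
#' @param values Non-negative numeric vector with at least one positive entry.
#' @return Finite numeric vector, `log2(values' / sum(values'))`.
#' @examples
#' preprocess_for_entropy(c(0, 2, 2))  # log2(c(0.2, 0.4, 0.4))
#' @export
preprocess_for_entropy <- function(values) {
  if (any(values < 0)) abort("values must be non-negative")
  if (all(values == 0)) abort("all-zero input cannot be preprocessed")
  values[values == 0] <- 1
  log2(values / sum(values))
}

#' Discretize a numeric vector into equal-frequency levels
#'
#' Quantile (equal-frequency) binning: breaks are the `n_levels + 1` sample
#' quantiles, tied values always share a level, and the assignment is
#' monotone (x <= y implies bin(x) <= bin(y)), hence invariant to strictly
#' increasing transforms of the input. Duplicate quantiles (heavy ties)
#' collapse levels; a constant vector yields a single level.
#'
#' @param values Numeric vector.
#' @param n_levels Requested number of levels (default 10).
#' @return Integer vector of 1-based level labels with attributes `n_levels`
#'   (levels actually used) and `constant` (logical flag).
#' @export
discretize <- function(values, n_levels = 10) {
  stopifnot(n_levels >= 1)
  if (length(unique(values)) == 1) {
    out <- rep(1L, length(values))
    attr(out, "n_levels") <- 1L
    attr(out, "constant") <- TRUE
    return(out)
  }
  br <- unique(quantile(values, probs = seq(0, 1, length.out = n_levels + 1),
                        names = FALSE, type = 7))
  out <- as.integer(cut(values, breaks = br, include.lowest = TRUE, labels = FALSE))
  attr(out, "n_levels") <- length(br) - 1L
  attr(out, "constant") <- FALSE
  out
}

n_levels_of <- function(v) {
  L <- attr(v, "n_levels")
  if (is.null(L)) L <- max(as.integer(v))
  as.integer(L)
}

joint_code <- function(vars) {
  code <- as.integer(vars[[1]]) - 1L
  L <- n_levels_of(vars[[1]])
  if (length(vars) > 1) {
    for (v in vars[-1]) {
      Lv <- n_levels_of(v)
      code <- code * Lv + (as.integer(v) - 1L)
      L <- L * Lv
    }
  }
  list(code = code + 1L, n_levels = L)
}

#' Plugin Shannon entropy of one or more discretized variables
#'
#' Joint entropy in bits from empirical cell frequencies, with `0 log 0`
#' treated as 0. Pass a single discretized vector or a list of equal-length
#' vectors (joint entropy).
#'
#' @param vars An integer vector from [discretize()], or a list of them.
#' @return Entropy in bits (non-negative scalar).
#' @examples
#' shannon_entropy(rep(1:4, 25))  # uniform 4-level: 2 bits
#' @export
shannon_entropy <- function(vars) {
  if (!is.list(vars)) vars <- list(vars)
  n <- unique(lengths(vars))
  if (length(n) != 1) abort("variables must have the same number of samples")
  jc <- joint_code(vars)
  p <- tabulate(jc$code, nbins = jc$n_levels)
  p <- p[p > 0] / n
  -sum(p * log2(p))
}

#' Multivariate mutual information by inclusion-exclusion
#'
#' For two variables this is the usual mutual information
#' `H(X) + H(Y) - H(X,Y)`; for three it is the co-information
#' `H(X)+H(Y)+H(Z) - H(XY) - H(XZ) - H(YZ) + H(XYZ)`, the alternating-sign
#' sum of joint entropies over all nonempty variable subsets. Pairwise MI is
#' non-negative (up to rounding); co-information is signed — positive for
#' redundant, negative for synergistic dependence.
#'
#' @param x,y,z Discretized variables ([discretize()]); `z` optional.
#' @return A list of class `mi_value` with elements `k`, `mi` (bits), `nmi`
#'   (normalized by the square root of the product of marginal entropies; 0
#'   when any marginal entropy is 0) and `entropies` (the marginals).
#' @examples
#' v <- discretize(rnorm(100), 4)
#' mutual_information(v, v)$mi  # equals H(v)
#' @export
mutual_information <- function(x, y, z = NULL) {
  vars <- if (is.null(z)) list(x, y) else list(x, y, z)
  k <- length(vars)
  n <- unique(lengths(vars))
  if (length(n) != 1) abort("variables must have the same number of samples")
  idx <- seq_len(k)
  mi <- 0
  for (size in idx) {
    for (sub in utils::combn(idx, size, simplify = FALSE)) {
      mi <- mi - (-1)^size * shannon_entropy(vars[sub])
    }
  }
  h <- vapply(vars, shannon_entropy, numeric(1))
  structure(
    list(k = k, mi = mi, nmi = normalized_mi(mi, h), entropies = h),
    class = "mi_value"
  )
}

#' Normalize a mutual-information value by its marginal entropies
#'
#' `mi / sqrt(prod(h))`, the square-root-of-entropies normalization; defined
#' as 0 whenever any marginal entropy is 0 (a constant variable carries no
#' information).
#'
#' @param mi Mutual information in bits (scalar, may be negative for
#'   co-information).
#' @param h Numeric vector of marginal entropies of all variables involved.
#' @return Dimensionless normalized MI.
#' @export
normalized_mi <- function(mi, h) {
  if (any(h <= 0)) return(0)
  mi / sqrt(prod(h))
}

#' @export
print.mi_value <- function(x, ...) {
  cat(sprintf("<mi_value k=%d> mi = %.6g bits, nmi = %.6g\n", x$k, x$mi, x$nmi))
  invisible(x)
}

#' Permutation p-value for mutual information
#'
#' Permutes the target variable's sample labels `n_perm` times, recomputing
#' the statistic each time, and returns `p = (1 + #{perm >= observed}) /
#' (1 + n_perm)`. With one anchor the statistic is the pairwise MI; with two
#' anchors it is the absolute three-way co-information (which is signed, so
#' both synergy and redundancy count as association).
#'
#' @param target Discretized target variable.
#' @param anchor1 First discretized anchor variable.
#' @param anchor2 Optional second anchor (triple statistic).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @return One-row tibble: `statistic`, `mi`, `nmi`, `p_value`, `n_perm`.
#' @export
permutation_pvalue <- function(target, anchor1, anchor2 = NULL,
                               n_perm = 999, seed = 1) {
  if (n_perm < 99) abort("n_perm must be at least 99")
  a2 <- if (is.null(anchor2)) integer(0) else as.integer(anchor2)
  res <- withr::with_seed(seed,
    perm_coassoc_cpp(as.integer(target), n_levels_of(target),
                     as.integer(anchor1), n_levels_of(anchor1),
                     a2, if (is.null(anchor2)) 1L else n_levels_of(anchor2),
                     as.integer(n_perm))
  )
  if (is.null(anchor2)) {
    tibble(statistic = "pairwise_mi", mi = res$mi1,
           nmi = normalized_mi(res$mi1, c(res$h_target, res$h1)),
           p_value = (1 + res$exceed1) / (1 + n_perm), n_perm = n_perm)
  } else {
    tibble(statistic = "co_information", mi = res$ci,
           nmi = normalized_mi(res$ci, c(res$h_target, res$h1, res$h2)),
           p_value = (1 + res$exceed3) / (1 + n_perm), n_perm = n_perm)
  }
}
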