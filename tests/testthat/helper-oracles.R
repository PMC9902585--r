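# Independent plugin oracles computed straight from the empirical joint
# distribution (structurally different from the inclusion-exclusion path in
# the package: pairwise MI from the ratio form, co-information as
# I(X;Y) - I(X;Y|Z)).

oracle_mi2 <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  unname(s)
}

oracle_coinfo <- function(x, y, z) {
  # I(X;Y;Z) = I(X;Y) - I(X;Y|Z)
  zl <- sort(unique(z))
  cond <- 0
  for (v in zl) {
    w <- z == v
    cond <- cond + mean(w) * oracle_mi2(x[w], y[w])
  }
  unname(oracle_mi2(x, y) - cond)
}

# exhaustive hypergeometric tail by enumerating all draws of size n from the
# universe (small universes only)
oracle_hyper_tail <- function(overlap, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K items are the pathway
  mean(hits >= overlap)
}

as_disc <- function(v, L = max(v)) {
  v <- as.integer(v)
  attr(v, "n_levels") <- as.integer(L)
  v
}

# small deterministic count tibble for IO / normalization tests
toy_counts <- function() {
  tibble::tibble(
    gene = c("A", "B", "C"),
    s1 = c(2, 3, 5),
    s2 = c(10, 30, 60)
  )
}

quick_sim <- function(seed = 1, n_genes = 200, n_samples = 120, ...) {
  simulate_bulk(sim_config(n_genes = n_genes, n_samples = n_samples,
                           seed = seed, ...))
}
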