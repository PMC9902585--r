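#' Simulation configuration for synthetic expression data
#'
#' Describes a synthetic gene-by-sample count experiment with two latent
#' per-sample program activities (EMT-like and mitotic-like), program gene
#' sets tracking the latents, receptor genes with calibrated monotone
#' (saturating, hence nonlinear) dependence on one or both latents, and null
#' genes independent of everything. Counts are negative binomial with
#' library-size variation, emulating bulk RNA-seq.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of samples.
#' @param n_program_genes_emt,n_program_genes_cycle Sizes of the two planted
#'   program gene sets.
#' @param receptor_effects Data frame with one row per planted receptor:
#'   columns `target` (one of `"emt"`, `"cycle"`, `"both"`), `direction`
#'   (`"+"` or `"-"`), and `rho_target` (absolute Spearman correlation with
#'   the designated latent(s), in `[0, 1)`). Use [receptor_effects()] to
#'   build one. May have zero rows.
#' @param library_size_mean Mean library size (total counts per sample).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be > 0.
#' @param latent_correlation Gaussian-copula correlation between the two
#'   latent program activities (default 0.4): EMT and mitotic activity
#'   co-vary across tumors, and the three-way statistic of the screen is
#'   built around that co-variation.
#' @param seed Master integer seed; all randomness derives from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 1000, n_samples = 300,
                       n_program_genes_emt = 50, n_program_genes_cycle = 50,
                       receptor_effects = coassoc::receptor_effects(),
                       library_size_mean = 1e5, dispersion = 0.3,
                       latent_correlation = 0.4, seed = 1) {
  receptor_effects <- as_tibble(receptor_effects)
  stopifnot(
    n_genes >= 1, n_samples >= 2,
    n_program_genes_emt >= 0, n_program_genes_cycle >= 0,
    library_size_mean > 0, dispersion > 0,
    latent_correlation >= -1, latent_correlation <= 1
  )
  if (nrow(receptor_effects) > 0) {
    if (!all(c("target", "direction", "rho_target") %in% names(receptor_effects))) {
      abort("receptor_effects needs columns target, direction, rho_target")
    }
    if (!all(receptor_effects$target %in% c("emt", "cycle", "both"))) {
      abort("receptor_effects$target must be 'emt', 'cycle' or 'both'")
    }
    if (!all(receptor_effects$direction %in% c("+", "-"))) {
      abort("receptor_effects$direction must be '+' or '-'")
    }
    rt <- receptor_effects$rho_target
    if (any(rt < 0 | rt > 1)) abort("rho_target must lie in [0, 1]")
    if (any(rt >= 1)) {
      abort("rho_target = 1 is unattainable under negative-binomial noise (dispersion > 0); lower rho_target")
    }
  }
  n_receptors <- nrow(receptor_effects)
  if (n_program_genes_emt + n_program_genes_cycle + n_receptors > n_genes) {
    abort("n_program_genes + n_receptors exceeds n_genes")
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
      n_program_genes_emt = as.integer(n_program_genes_emt),
      n_program_genes_cycle = as.integer(n_program_genes_cycle),
      n_receptors = as.integer(n_receptors),
      receptor_effects = receptor_effects,
      library_size_mean = library_size_mean,
      dispersion = dispersion,
      latent_correlation = latent_correlation, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Build a receptor effect table for the simulator
#'
#' @param target Character vector over `{"emt", "cycle", "both"}`, recycled.
#' @param direction `"+"` or `"-"`, recycled.
#' @param rho_target Target absolute Spearman correlation with the designated
#'   latent(s), recycled.
#' @return A tibble with columns `target`, `direction`, `rho_target`.
#' @export
receptor_effects <- function(target = character(), direction = "+", rho_target = 0.5) {
  if (length(target) == 0) {
    return(tibble(target = character(), direction = character(), rho_target = double()))
  }
  tibble(target = target, direction = direction, rho_target = rho_target)
}

# Saturating monotone transform of a positive latent, standardized.
saturating_std <- function(latent) {
  u <- latent / (1 + latent)
  (u - mean(u)) / sd(u)
}

# Bisection on the link strength b so that NB counts with mean
# libsize * base * exp(b*u) / total_scale achieve the target absolute
# Spearman correlation against `target_vec` (a vector, or a list of vectors
# whose realized |rho| values are averaged). Monotone in b; averaged over
# nrep draws to tame Monte-Carlo noise.
calibrate_link <- function(u_std, base_rel, total_scale, libsizes, size,
                           target_vec, rho_target, sign = 1,
                           nrep = 4, b_max = 12, tol = 0.1) {
  if (!is.list(target_vec)) target_vec <- list(target_vec)
  realized <- function(b) {
    link <- exp(sign * b * u_std)
    link <- link / mean(link)  # hold the gene's average abundance fixed
    mu <- libsizes * base_rel * link / total_scale
    mean(vapply(seq_len(nrep), function(i) {
      cts <- rnbinom(length(mu), mu = mu, size = size)
      mean(vapply(target_vec, function(tv) {
        r <- suppressWarnings(cor(cts, tv, method = "spearman"))
        if (is.na(r)) 0 else abs(r)
      }, numeric(1)))
    }, numeric(1)))
  }
  # |rho|(b) climbs, then degrades once extreme links flood the gene with
  # zeros, so scan a grid and take the first crossing of the target
  grid <- seq(0, b_max, length.out = 25)
  rho_grid <- vapply(grid, realized, numeric(1))
  cross <- which(rho_grid >= rho_target)
  if (length(cross) == 0) {
    abort(sprintf(
      "cannot calibrate rho_target = %.2f: maximum achievable |rho| under this noise model is ~%.2f",
      rho_target, max(rho_grid)
    ))
  }
  i <- cross[1]
  if (i == 1) return(grid[1])
  # linear interpolation between the bracketing grid points
  w <- (rho_target - rho_grid[i - 1]) / (rho_grid[i] - rho_grid[i - 1])
  grid[i - 1] + w * (grid[i] - grid[i - 1])
}

# Core generator shared by simulate_bulk() and simulate_multidataset().
# `extra` optionally plants a focal-gene module (see simulate_multidataset).
simulate_core <- function(config, extra = NULL) {
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- config$n_samples
  ng <- config$n_genes
  eff <- config$receptor_effects
  n_emt <- config$n_program_genes_emt
  n_cyc <- config$n_program_genes_cycle
  n_rec <- config$n_receptors
  n_null <- ng - n_emt - n_cyc - n_rec

  genes <- c(
    sprintf("EMT%03d", seq_len(n_emt)),
    sprintf("CCG%03d", seq_len(n_cyc)),
    sprintf("RCP%03d", seq_len(n_rec)),
    sprintf("NUL%04d", seq_len(n_null))
  )
  role <- rep(c("program_emt", "program_cycle", "receptor", "null"),
              c(n_emt, n_cyc, n_rec, n_null))
  samples <- sprintf("S%03d", seq_len(n))

  # lognormal latents through a Gaussian copula so the two program
  # activities co-vary at the configured strength
  rl <- config$latent_correlation
  z1 <- stats::rnorm(n)
  z2 <- rl * z1 + sqrt(1 - rl^2) * stats::rnorm(n)
  latent_emt <- exp(0.6 * z1)
  latent_cycle <- exp(0.6 * z2)
  g_emt <- saturating_std(latent_emt)
  g_cyc <- saturating_std(latent_cycle)

  base <- rlnorm(ng, meanlog = log(50), sdlog = 1)
  libsizes <- config$library_size_mean * rlnorm(n, -0.045, 0.3)
  size <- 1 / config$dispersion

  # relative expression: base * link(latent); program genes use a fixed
  # moderate link, receptors a calibrated one
  link <- matrix(1, ng, n)
  b_prog <- 1.5
  prog_link <- function(g) { l <- exp(b_prog * g); l / mean(l) }
  if (n_emt > 0) link[role == "program_emt", ] <-
    rep(prog_link(g_emt), each = n_emt)
  if (n_cyc > 0) link[role == "program_cycle", ] <-
    rep(prog_link(g_cyc), each = n_cyc)

  # Per-gene means are scaled by a single global constant (not per-sample
  # column totals), so genes without a planted link stay exactly independent
  # of the latents; library-size variation enters only through `libsizes`.
  total_scale <- mean(colSums(base * link))

  rec_rows <- which(role == "receptor")
  rec_meta <- tibble(gene = genes[rec_rows],
                     target = character(n_rec), direction = character(n_rec),
                     rho_target = double(n_rec), b = double(n_rec))
  if (n_rec > 0) {
    for (k in seq_len(n_rec)) {
      tg <- eff$target[k]
      sgn <- if (eff$direction[k] == "+") 1 else -1
      u <- switch(tg,
        emt = g_emt, cycle = g_cyc,
        both = (g_emt + g_cyc) / sqrt(2)
      )
      tv <- switch(tg, emt = latent_emt, cycle = latent_cycle,
                   both = list(latent_emt, latent_cycle))
      i <- rec_rows[k]
      b <- calibrate_link(u, base[i], total_scale, libsizes, size,
                          target_vec = tv, rho_target = eff$rho_target[k],
                          sign = sgn)
      l <- exp(sgn * b * u)
      link[i, ] <- l / mean(l)
      rec_meta$target[k] <- tg
      rec_meta$direction[k] <- eff$direction[k]
      rec_meta$rho_target[k] <- eff$rho_target[k]
      rec_meta$b[k] <- b
    }
  }

  # optional planted focal-gene module on null-gene slots
  focal_counts <- NULL
  if (!is.null(extra)) {
    null_rows <- which(role == "null")
    need <- 1 + length(extra$module)
    if (length(null_rows) < need) abort("not enough null genes to host focal gene and module")
    genes[null_rows[1]] <- extra$focal_gene
    role[null_rows[1]] <- "focal"
    f <- rlnorm(n, 0, 0.6)
    gf <- saturating_std(f)
    i_f <- null_rows[1]
    lf <- exp(2.5 * gf)
    link[i_f, ] <- lf / mean(lf)
    mu_f <- libsizes * base[i_f] * link[i_f, ] / total_scale
    focal_counts <- rnbinom(n, mu = mu_f, size = size)
    mod_rows <- null_rows[1 + seq_along(extra$module)]
    genes[mod_rows] <- extra$module
    role[mod_rows] <- "module"
    if (extra$with_signal) {
      for (j in seq_along(mod_rows)) {
        i <- mod_rows[j]
        b <- calibrate_link(gf, base[i], total_scale, libsizes, size,
                            target_vec = focal_counts,
                            rho_target = extra$rho_target, sign = 1)
        l <- exp(b * gf)
        link[i, ] <- l / mean(l)
      }
    }
  }

  mu <- sweep(base * link, 2, libsizes, `*`) / total_scale
  counts <- matrix(rnbinom(ng * n, mu = mu, size = size), ng, n,
                   dimnames = list(genes, samples))
  if (!is.null(focal_counts)) counts[extra$focal_gene, ] <- focal_counts

  truth <- tibble(gene = genes, role = role) |>
    dplyr::left_join(rec_meta[, c("gene", "target", "direction", "rho_target")],
                     by = "gene")
  structure(
    list(
      expression = as_expr_tbl(counts),
      latent = tibble(sample = samples, emt = latent_emt, cycle = latent_cycle),
      truth = truth,
      config = config
    ),
    class = "synthetic_dataset"
  )
}

#' Simulate a bulk expression dataset with planted program and receptor genes
#'
#' Draws a negative-binomial count matrix in which program genes increase with
#' their matching latent activity, receptor genes follow a saturating
#' (nonlinear, monotone) link of the designated latent(s) with the designated
#' sign — calibrated by bisection so the realized Spearman correlation with
#' the latent hits `rho_target` within about 0.1 — and null genes are
#' independent of both latents. Identical seeds give identical datasets.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_dataset`: list with `expression` (count tibble),
#'   `latent` (per-sample activities), `truth` (gene labels and planted
#'   directions), and `config`.
#' @examples
#' d <- simulate_bulk(sim_config(n_genes = 60, n_samples = 40, seed = 7))
#' d$expression
#' @export
simulate_bulk <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  simulate_core(config)
}

#' Simulate multiple datasets sharing a planted focal-gene module
#'
#' Generates `n_datasets` independent synthetic datasets over a shared gene
#' universe. In exactly `datasets_with_signal` of them (the first ones), the
#' `conserved_module` genes are calibrated to correlate with the focal gene at
#' `rho_target`; elsewhere they are independent null genes. Per-dataset seeds
#' are `config$seed + dataset index`.
#'
#' @param config A [sim_config()] (its `seed` is the master seed).
#' @param n_datasets Number of datasets.
#' @param focal_gene Symbol for the focal gene (hosted on a null-gene slot).
#' @param conserved_module Character vector of module gene symbols.
#' @param datasets_with_signal How many datasets carry the planted module.
#' @param rho_target Target Spearman correlation between module genes and the
#'   focal gene in signal datasets.
#' @return A named list of `synthetic_dataset` objects (`dataset1`, ...).
#' @export
simulate_multidataset <- function(config, n_datasets, focal_gene,
                                  conserved_module, datasets_with_signal,
                                  rho_target = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  if (length(conserved_module) == 0) abort("conserved_module must be nonempty")
  if (datasets_with_signal < 0 || datasets_with_signal > n_datasets) {
    abort("datasets_with_signal must lie in [0, n_datasets]")
  }
  if (focal_gene %in% conserved_module) abort("focal_gene cannot be in conserved_module")
  out <- lapply(seq_len(n_datasets), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    simulate_core(cfg, extra = list(
      focal_gene = toupper(focal_gene),
      module = toupper(conserved_module),
      with_signal = i <= datasets_with_signal,
      rho_target = rho_target
    ))
  })
  names(out) <- paste0("dataset", seq_len(n_datasets))
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d genes x %d samples (seed %d)\n",
    x$config$n_genes, x$config$n_samples, x$config$seed
  ))
  print(dplyr::count(x$truth, .data$role))
  invisible(x)
}
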