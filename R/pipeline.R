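#' Load and validate a pipeline configuration
#'
#' Configuration may be a YAML or JSON file, or an equivalent named list.
#' Required fields: `matrix` (expression file), `programs_gmt` (GMT with the
#' two program sets), `emt_program` and `cycle_program` (set names in the
#' GMT), `receptors` (annotation file), `out_dir`, `seed`. Optional `params`
#' (n_bins, n_control_per_bin, n_levels, n_perm, q_threshold, k, alpha) and
#' `conserved` (`datasets`: list of matrix paths, `focal_gene`). All
#' referenced files must exist and parameters must be in range; violations
#' raise a validation error before any stage runs.
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @return The validated configuration list (class `pipeline_config`).
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) validation_error(paste0("config file not found: ", config))
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) validation_error("config must be a file path or a named list")
  req <- c("matrix", "programs_gmt", "emt_program", "cycle_program",
           "receptors", "out_dir", "seed")
  missing <- setdiff(req, names(config))
  if (length(missing) > 0) {
    validation_error(paste0("config missing field(s): ", paste(missing, collapse = ", ")))
  }
  for (f in c("matrix", "programs_gmt", "receptors")) {
    if (!file.exists(config[[f]])) {
      validation_error(sprintf("config field '%s': file not found: %s", f, config[[f]]))
    }
  }
  defaults <- list(n_bins = 25, n_control_per_bin = 100, n_levels = 10,
                   n_perm = 999, q_threshold = 0.05, k = 2, alpha = 0.05)
  p <- utils::modifyList(defaults, as.list(config$params %||% list()))
  if (p$n_bins < 1 || p$n_levels < 2 || p$n_perm < 99 ||
      p$q_threshold <= 0 || p$q_threshold >= 1 ||
      p$alpha <= 0 || p$alpha >= 1 || p$k < 1) {
    validation_error("config parameter out of documented range")
  }
  config$params <- p
  config$seed <- as.integer(config$seed)
  if (!is.null(config$conserved)) {
    cc <- config$conserved
    if (is.null(cc$datasets) || is.null(cc$focal_gene)) {
      validation_error("conserved block needs 'datasets' and 'focal_gene'")
    }
    for (f in unlist(cc$datasets)) {
      if (!file.exists(f)) validation_error(paste0("conserved dataset not found: ", f))
    }
  }
  structure(config, class = c("pipeline_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full co-association pipeline
#'
#' Executes normalize -> activity scoring (EMT and mitotic) -> MI screen ->
#' receptor ranking, and optionally the conserved-correlation stage, all
#' driven by one master seed. Every output table carries a provenance header;
#' a `manifest.tsv` records each output file's MD5 checksum, so two runs of
#' the same configuration produce identical manifests.
#'
#' @param config A [load_config()] result, a config file path, or a list.
#' @return The manifest tibble (`file`, `md5`), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else load_config(config)
  p <- cfg$params
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }

  message("reading inputs")
  x <- stage("read", read_expression(cfg$matrix))
  sets <- stage("read", read_gmt(cfg$programs_gmt))
  for (nm in c(cfg$emt_program, cfg$cycle_program)) {
    if (!nm %in% names(sets)) {
      validation_error(paste0("program set not in GMT: ", nm))
    }
  }
  receptors <- stage("read", read_receptors(cfg$receptors))

  message("normalizing and scoring")
  cpm <- stage("normalize", cpm_normalize(x))
  emt <- stage("score", score_activity(
    cpm, sets[[cfg$emt_program]], attribute = "EMT",
    n_bins = p$n_bins, n_control_per_bin = p$n_control_per_bin, seed = cfg$seed))
  cyc <- stage("score", score_activity(
    cpm, sets[[cfg$cycle_program]], attribute = "mitotic",
    n_bins = p$n_bins, n_control_per_bin = p$n_control_per_bin, seed = cfg$seed))

  message("running MI screen")
  scr <- stage("screen", run_screen(
    x, emt, cyc, receptors, n_perm = p$n_perm,
    q_threshold = p$q_threshold, n_levels = p$n_levels, seed = cfg$seed))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- prov_line(c(list(seed = cfg$seed), p))
  paths <- c(
    file.path(cfg$out_dir, "scores_emt.tsv"),
    file.path(cfg$out_dir, "scores_mitotic.tsv")
  )
  write_tsv_prov(as_tibble(emt), paths[1], prov)
  write_tsv_prov(as_tibble(cyc), paths[2], prov)
  paths <- c(paths, write_screen(scr, cfg$out_dir))

  if (!is.null(cfg$conserved)) {
    message("conserved-correlation stage")
    ds <- stage("conserved", lapply(unlist(cfg$conserved$datasets), read_expression))
    names(ds) <- basename(unlist(cfg$conserved$datasets))
    cons <- stage("conserved", correlate_focal(
      ds, cfg$conserved$focal_gene, alpha = p$alpha, k = p$k))
    cons_path <- file.path(cfg$out_dir, "conserved_genes.tsv")
    write_tsv_prov(tidy(cons), cons_path, prov)
    paths <- c(paths, cons_path)
  }

  manifest <- tibble(
    file = basename(unname(paths)),
    md5 = unname(tools::md5sum(unname(paths)))
  ) |> dplyr::arrange(.data$file)
  readr::write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"), progress = FALSE)
  invisible(manifest)
}
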