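.stack_roles <- c("dmso_control", "pos_titration", "pos_top", "compound",
                  "dmso_plate")

#' Screen configuration
#'
#' Bundles every tunable of the pipeline: the assay concentration series,
#' the classification and hit-calling thresholds, the synthetic-generator
#' block and the sample manifest. Configurations round-trip losslessly
#' through YAML via [write_config()] / [read_config()].
#'
#' @param series Assay series: list with `top` (uM), `factor`, `n_points`.
#' @param thresholds Named list of analysis thresholds; see Defaults.
#' @param generator Named list of synthetic-screen settings.
#' @param samples List with `n_cll` and `n_normal`.
#' @param seed Integer master seed.
#' @return An object of class `screen_config` (a named list).
#' @details Default thresholds: efficacy for the active call 60%, high-
#'   efficacy class boundary 80%, significant-response threshold 25 points,
#'   consensus IC50 gate 30 uM, selectivity fold-shift gate 5, efficacy-
#'   difference gate 40 points, minimum r2 0.3, plateau tolerance 0.05,
#'   minimum Hill slope 0.3, flat-span 5 points.
#' @export
screen_config <- function(series = list(top = 57, factor = 5, n_points = 8L),
                          thresholds = list(),
                          generator = list(),
                          samples = list(n_cll = 6L, n_normal = 5L),
                          seed = 1L) {
  th <- utils::modifyList(list(
    efficacy_active = 60, efficacy_high = 80, act_threshold = 25,
    ic50_gate = 30, fold_shift_gate = 5, efficacy_diff_gate = 40,
    r2_min = 0.3, plateau_tol = 0.05, hill_min = 0.3, flat_span = 5
  ), thresholds)
  gen <- utils::modifyList(list(
    n_compounds = 2816L, fractions = as.list(default_archetype_mix()),
    sigma_log10 = 0.3, selective_fold = 30,
    plate_baseline = 3000, sb_ratio = 11.2, well_cv = 0.05,
    spatial_amplitude = 0.10
  ), generator)
  if (any(unlist(th) <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  structure(
    list(series = series, thresholds = th, generator = gen,
         samples = samples, seed = as.integer(seed)),
    class = "screen_config"
  )
}

#' Mini screen configuration for desk-scale runs
#'
#' A 64-compound screen with an archetype mix rich enough to exercise
#' every pipeline stage: 32 inactive, 16 pan-cytotoxic, 6 partial,
#' 4 top-concentration-only and 6 selective compounds, over the default
#' 6 CLL + 5 normal manifest.
#'
#' @param ... Overrides forwarded to [screen_config()].
#' @return A `screen_config`.
#' @export
mini_screen_config <- function(...) {
  base <- screen_config(
    generator = list(
      n_compounds = 64L,
      fractions = list(inactive = 0.5, pan_cytotoxic = 0.25,
                       partial = 3 / 32, top_only = 1 / 16,
                       selective = 3 / 32)
    )
  )
  utils::modifyList(base, rlang::list2(...))
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf(
    "<screen_config> %d compounds, %d-pt 1:%g series from %g uM, %d CLL + %d normal samples, seed %d\n",
    x$generator$n_compounds, x$series$n_points, x$series$factor,
    x$series$top, x$samples$n_cll, x$samples$n_normal, x$seed
  ))
  invisible(x)
}

#' Read / write a screen configuration
#'
#' @param config A [screen_config()].
#' @param path YAML file path.
#' @return `read_config()` returns a `screen_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  screen_config(series = raw$series, thresholds = raw$thresholds,
                generator = raw$generator, samples = raw$samples,
                seed = raw$seed)
}

#' Write a raw plate stack as long-format CSV
#'
#' One row per well: `plate_id, stack_index, row, col, role, compound_id,
#' conc_uM, value` (plus `sample_id` and `stack` when present).
#'
#' @param stack A plate-stack tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_raw_stack <- function(stack, path) {
  .check_stack(stack)
  readr::write_csv(stack, path)
  invisible(path)
}

#' Read and validate a raw plate stack
#'
#' Reads the long-format well CSV and validates the schema: required
#' columns, well addresses within the 32 x 48 plate, known roles, and no
#' duplicate wells within a plate. Violations are reported with the
#' offending file row numbers. Plates are ordered by `stack_index`;
#' compound-free DMSO-only plates are the ones whose `role` is
#' `"dmso_plate"`.
#'
#' @param path CSV path.
#' @return A validated plate-stack tibble.
#' @export
read_raw_stack <- function(path) {
  stack <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("plate_id", "stack_index", "row", "col", "role", "compound_id",
           "conc_uM", "value")
  missing <- setdiff(req, names(stack))
  if (length(missing) > 0) {
    stop("raw stack is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_addr <- which(stack$row < 1 | stack$row > 32 |
                      stack$col < 1 | stack$col > 48)
  if (length(bad_addr) > 0) {
    stop("well address out of range (rows ",
         paste(utils::head(bad_addr, 5), collapse = ", "),
         if (length(bad_addr) > 5) ", ..." else "",
         "): row must be 1-32, col 1-48", call. = FALSE)
  }
  bad_role <- which(!stack$role %in% .stack_roles)
  if (length(bad_role) > 0) {
    stop("unknown role (rows ",
         paste(utils::head(bad_role, 5), collapse = ", "),
         if (length(bad_role) > 5) ", ..." else "", ")", call. = FALSE)
  }
  key <- paste(stack$plate_id, stack$row, stack$col)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate wells within a plate (rows ",
         paste(utils::head(dup, 5), collapse = ", "),
         if (length(dup) > 5) ", ..." else "", ")", call. = FALSE)
  }
  dplyr::arrange(stack, dplyr::across(dplyr::any_of(c("sample_id", "stack"))),
                 .data$stack_index, .data$row, .data$col)
}

#' Run the full screen analysis pipeline
#'
#' Executes simulate (or load) -> pattern-correct -> QC -> normalize ->
#' fit -> classify -> consensus/selectivity -> summary -> cluster, writing
#' every stage artifact into `out_dir`: `truth.csv` (simulated runs),
#' `qc.csv`, `normalized.csv`, `fits.csv`, `consensus_hits.csv`,
#' `selectivity.csv`, `summary.json`, `heatmap.tsv` (integer codes, rows in
#' dendrogram order), `dendrogram.nwk` and `pipeline.log`. Deterministic
#' given the config (including its seed).
#'
#' @param config A [screen_config()].
#' @param out_dir Output directory (created if needed).
#' @param raw Optional raw stack tibble (e.g. from [read_raw_stack()]) with
#'   a `sample_id` column; when `NULL` a synthetic screen is generated from
#'   the config's generator block.
#' @param truth Optional truth table matching `raw` (for provenance only).
#' @param write_normalized Write the (large) normalized well-level CSV.
#' @return Invisibly, a list with the main in-memory results: `qc`,
#'   `fits`, `matrix`, `consensus`, `selectivity`, `summary`, `clustering`.
#' @export
run_pipeline <- function(config, out_dir, raw = NULL, truth = NULL,
                         write_normalized = TRUE) {
  stopifnot(inherits(config, "screen_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(config))
  ver <- as.character(utils::packageVersion("qhtscreen"))
  log_path <- file.path(out_dir, "pipeline.log")
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] config=%s version=%s seed=%d %s\n",
                stage, cfg_hash, ver, config$seed, msg),
        file = log_path, append = TRUE)
  }
  unlink(log_path)
  th <- config$thresholds
  series <- make_series(config$series$top, config$series$factor,
                        config$series$n_points)
  manifest <- sample_manifest(config$samples$n_cll, config$samples$n_normal)
  cll <- manifest$sample_id[manifest$group == "cll"]
  nrm <- manifest$sample_id[manifest$group == "normal"]

  if (is.null(raw)) {
    gen <- config$generator
    truth <- generate_library(
      gen$n_compounds, fractions = unlist(gen$fractions),
      samples = manifest, seed = config$seed,
      sigma_log10 = gen$sigma_log10, selective_fold = gen$selective_fold
    )
    noise <- noise_model(gen$plate_baseline, gen$sb_ratio, gen$well_cv,
                         gen$spatial_amplitude)
    raw <- generate_screen(truth, noise = noise, series = series,
                           seed = config$seed)
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
    log_line("simulate", sprintf("%d compounds x %d samples",
                                 gen$n_compounds, nrow(manifest)))
  }

  corrected <- pattern_correct(raw)
  log_line("pattern_correct", sprintf("%d wells", nrow(corrected)))

  stats <- control_stats(corrected)
  qc <- qc_report(corrected, stats)
  readr::write_csv(qc, file.path(out_dir, "qc.csv"))
  log_line("qc", sprintf("%d plates, mean Z' %.3f", nrow(qc),
                         mean(qc$z_factor)))

  norm <- normalize_stack(corrected, stats)
  if (write_normalized) {
    readr::write_csv(norm, file.path(out_dir, "normalized.csv"))
  }
  log_line("normalize", sprintf("%d wells", nrow(norm)))

  fits <- fit_screen(norm, flat_span = th$flat_span)
  log_line("fit", sprintf("%d curves, %d converged", nrow(fits),
                          sum(fits$converged)))

  fits <- classify_screen(
    fits, norm,
    act_threshold = th$act_threshold, r2_min = th$r2_min,
    plateau_tol = th$plateau_tol, hill_min = th$hill_min,
    active_efficacy = th$efficacy_active
  )
  readr::write_csv(fits, file.path(out_dir, "fits.csv"))
  log_line("classify", sprintf("%d active calls",
                               sum(fits$category == "active")))

  mat <- activity_matrix(fits, samples = manifest$sample_id)
  hits <- consensus_hits(mat, cll, ic50_gate = th$ic50_gate)
  readr::write_csv(hits, file.path(out_dir, "consensus_hits.csv"))
  sel <- call_selectivity(mat, hits, cll, nrm, data = norm,
                          fold_gate = th$fold_shift_gate,
                          eff_gate = th$efficacy_diff_gate)
  readr::write_csv(sel, file.path(out_dir, "selectivity.csv"))
  log_line("hits", sprintf("%d consensus, %d selective", nrow(hits),
                           sum(sel$selective)))

  summary <- summarize_screen(mat, hits, sel, cll_samples = cll)
  jsonlite::write_json(
    list(meta = list(package = "qhtscreen", version = ver,
                     config_hash = cfg_hash, seed = config$seed),
         per_sample = summary$per_sample, totals = summary$totals),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  encoded <- encode_outcomes(mat)
  clustering <- cluster_profiles(encoded)
  heat <- tibble::as_tibble(encoded[clustering$order, , drop = FALSE],
                            rownames = "compound_id")
  readr::write_tsv(heat, file.path(out_dir, "heatmap.tsv"))
  if (!is.null(clustering$hclust)) {
    write_dendrogram(clustering, file.path(out_dir, "dendrogram.nwk"))
  }
  log_line("report", sprintf("summary + heatmap for %d compounds",
                             nrow(encoded)))

  invisible(list(qc = qc, fits = fits, matrix = mat, consensus = hits,
                 selectivity = sel, summary = summary,
                 clustering = clustering, truth = truth))
}
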