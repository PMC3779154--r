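#' Compound x sample activity matrix (long form)
#'
#' Reshapes a classified fit table into the long activity matrix that feeds
#' consensus hit calling, selectivity and clustering: one row per compound
#' and sample with its activity category, curve class, IC50 (the fitted
#' AC50 of a converged cytotoxic fit, otherwise `NA`) and efficacy.
#' Compound-sample combinations absent from the fit table are filled in as
#' `"untested"`.
#'
#' @param classified Output of [classify_screen()].
#' @param samples Optional character vector of all screened samples, used
#'   to materialize untested cells; defaults to the samples present.
#' @return A tibble with columns `compound_id`, `sample_id`, `category`,
#'   `curve_class`, `ic50`, `efficacy`.
#' @export
activity_matrix <- function(classified, samples = NULL) {
  req <- c("compound_id", "sample_id", "category", "curve_class",
           "ac50", "efficacy", "converged")
  stopifnot(all(req %in% names(classified)))
  out <- tibble::tibble(
    compound_id = classified$compound_id,
    sample_id = classified$sample_id,
    category = classified$category,
    curve_class = classified$curve_class,
    ic50 = ifelse(classified$converged, classified$ac50, NA_real_),
    efficacy = classified$efficacy
  )
  samples <- samples %||% unique(out$sample_id)
  out <- tidyr::complete(
    out,
    compound_id = unique(out$compound_id),
    sample_id = samples,
    fill = list(category = "untested", curve_class = NA_character_,
                ic50 = NA_real_, efficacy = NA_real_)
  )
  dplyr::arrange(out, .data$compound_id, .data$sample_id)
}

#' Consensus hits across CLL samples
#'
#' A consensus hit is a compound called active (high-confidence curve
#' class with efficacy above threshold) in *every* listed CLL sample, with
#' each per-sample IC50 below `ic50_gate` (default 30 uM). Potency across
#' samples is aggregated by the geometric mean, appropriate for
#' log-distributed IC50s.
#'
#' @param matrix An [activity_matrix()].
#' @param cll_samples Character vector of CLL sample ids; all must be
#'   present in the matrix.
#' @param ic50_gate Per-sample IC50 ceiling (uM).
#' @return A tibble of hits sorted by ascending geometric-mean IC50:
#'   `compound_id`, `ic50_gm`, `ic50_min`, `ic50_max`, `n_samples`.
#' @export
consensus_hits <- function(matrix, cll_samples, ic50_gate = 30) {
  missing <- setdiff(cll_samples, unique(matrix$sample_id))
  if (length(missing) > 0) {
    stop("sample(s) not in activity matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- matrix[matrix$sample_id %in% cll_samples, ]
  agg <- dplyr::summarise(
    dplyr::group_by(m, .data$compound_id),
    hit = dplyr::n() == length(cll_samples) &&
      all(.data$category == "active") &&
      all(!is.na(.data$ic50) & .data$ic50 < ic50_gate),
    ic50_gm = exp(mean(log(.data$ic50))),
    ic50_min = min(.data$ic50),
    ic50_max = max(.data$ic50),
    n_samples = dplyr::n(),
    .groups = "drop"
  )
  hits <- agg[agg$hit, c("compound_id", "ic50_gm", "ic50_min",
                         "ic50_max", "n_samples")]
  dplyr::arrange(hits, .data$ic50_gm, .data$compound_id)
}

#' Potency fold shift between normal and CLL cells
#'
#' Ratio of the normal-donor IC50 (or geometric mean thereof) to the CLL
#' IC50; values above 1 mean the compound is more potent against the
#' leukemic cells.
#'
#' @param ic50_cll,ic50_normal Positive IC50s (uM).
#' @return Dimensionless fold shift.
#' @examples
#' fold_shift(0.1, 3.2) # 32-fold CLL-selective
#' @export
fold_shift <- function(ic50_cll, ic50_normal) {
  if (any(ic50_cll <= 0) || any(ic50_normal <= 0)) {
    stop("IC50s must be strictly positive", call. = FALSE)
  }
  ic50_normal / ic50_cll
}

#' Efficacy difference at the top tested concentrations
#'
#' Differential efficacy between the CLL and normal groups, measured on the
#' normalized responses at the two highest tested concentrations (19 and
#' 57 uM in the default series): the mean over those two concentrations of
#' (mean CLL kill magnitude - mean normal kill magnitude), in percentage
#' points.
#'
#' @param data Normalized long table with `compound_id`, `sample_id`,
#'   `conc_uM`, `value_norm`.
#' @param compound One compound id.
#' @param cll_samples,normal_samples Sample id vectors.
#' @param n_top Number of top concentrations to average over.
#' @return Percentage-point difference (positive = stronger kill in CLL).
#' @export
efficacy_difference <- function(data, compound, cll_samples, normal_samples,
                                n_top = 2L) {
  d <- data[!is.na(data$compound_id) & data$compound_id == compound &
              data$sample_id %in% c(cll_samples, normal_samples) &
              !is.na(data$conc_uM) & !is.na(data$value_norm), ]
  if (nrow(d) == 0) {
    stop("no response rows for compound `", compound, "`", call. = FALSE)
  }
  top_concs <- sort(unique(d$conc_uM), decreasing = TRUE)[seq_len(n_top)]
  d <- d[d$conc_uM %in% top_concs, ]
  per_conc <- dplyr::summarise(
    dplyr::group_by(d, .data$conc_uM),
    diff = mean(-.data$value_norm[.data$sample_id %in% cll_samples]) -
      mean(-.data$value_norm[.data$sample_id %in% normal_samples]),
    .groups = "drop"
  )
  if (nrow(per_conc) < n_top || any(!is.finite(per_conc$diff))) {
    stop("responses at the top concentrations are incomplete for `",
         compound, "`", call. = FALSE)
  }
  mean(per_conc$diff)
}

#' Tumor-versus-normal selectivity of consensus hits
#'
#' Flags a consensus hit as CLL-selective when any of three clauses holds:
#' a potency fold shift above `fold_gate` (normal over CLL geometric-mean
#' IC50, default > 5-fold), an efficacy difference above `eff_gate`
#' percentage points at the two top concentrations (default > 40), or
#' inactivity in a majority (at least half, rounded up) of the normal
#' samples. Each clause is reported separately.
#'
#' @param matrix An [activity_matrix()] covering normal samples.
#' @param consensus Output of [consensus_hits()].
#' @param cll_samples,normal_samples Sample id vectors.
#' @param data Optional normalized long table for
#'   [efficacy_difference()]; without it the efficacy clause is `NA` and
#'   does not fire.
#' @param fold_gate,eff_gate Clause thresholds.
#' @return A tibble with one row per consensus compound: `compound_id`,
#'   `ic50_gm_cll`, `ic50_gm_normal`, `fold_shift`, `efficacy_diff`,
#'   `n_normal_inactive`, `n_normal`, and the `selective` flag.
#' @export
call_selectivity <- function(matrix, consensus, cll_samples, normal_samples,
                             data = NULL, fold_gate = 5, eff_gate = 40) {
  stopifnot(nrow(consensus) >= 0, length(normal_samples) >= 1)
  norm <- matrix[matrix$sample_id %in% normal_samples &
                   matrix$compound_id %in% consensus$compound_id, ]
  agg <- dplyr::summarise(
    dplyr::group_by(norm, .data$compound_id),
    ic50_gm_normal = if (any(!is.na(.data$ic50))) {
      exp(mean(log(.data$ic50[!is.na(.data$ic50)])))
    } else NA_real_,
    n_normal_inactive = sum(.data$category == "inactive"),
    n_normal = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::left_join(
    consensus[, c("compound_id", "ic50_gm")], agg, by = "compound_id"
  )
  out <- dplyr::rename(out, ic50_gm_cll = "ic50_gm")
  out$fold_shift <- ifelse(
    is.na(out$ic50_gm_normal), NA_real_,
    fold_shift(out$ic50_gm_cll, out$ic50_gm_normal)
  )
  out$efficacy_diff <- if (is.null(data)) NA_real_ else {
    vapply(out$compound_id, function(cmp) {
      tryCatch(
        efficacy_difference(data, cmp, cll_samples, normal_samples),
        error = function(e) NA_real_
      )
    }, numeric(1))
  }
  out$selective <- (!is.na(out$fold_shift) & out$fold_shift > fold_gate) |
    (!is.na(out$efficacy_diff) & out$efficacy_diff > eff_gate) |
    out$n_normal_inactive >= ceiling(out$n_normal / 2)
  dplyr::arrange(out, dplyr::desc(.data$selective), .data$compound_id)
}

#' Screen-level summary
#'
#' Per-sample active counts and percentages plus the screen totals:
#' compounds inactive in every CLL sample, consensus hits, and consensus
#' hits that are also toxic to normal cells (non-selective). Percentages
#' use the number of tested compounds as denominator and are reported to
#' one decimal.
#'
#' @param matrix An [activity_matrix()].
#' @param consensus Output of [consensus_hits()].
#' @param selectivity Output of [call_selectivity()] (optional).
#' @param cll_samples CLL sample ids.
#' @return An object of class `screen_summary`: a list with tibbles
#'   `per_sample` and `totals`.
#' @export
summarize_screen <- function(matrix, consensus, selectivity = NULL,
                             cll_samples = unique(matrix$sample_id)) {
  tested <- matrix[matrix$category != "untested", ]
  per_sample <- dplyr::summarise(
    dplyr::group_by(tested, .data$sample_id),
    n_tested = dplyr::n(),
    n_active = sum(.data$category == "active"),
    n_inconclusive = sum(.data$category == "inconclusive"),
    n_inactive = sum(.data$category == "inactive"),
    pct_active = round(100 * sum(.data$category == "active") / dplyr::n(), 1),
    .groups = "drop"
  )
  n_compounds <- dplyr::n_distinct(tested$compound_id)
  cll <- tested[tested$sample_id %in% cll_samples, ]
  all_inactive <- sum(dplyr::summarise(
    dplyr::group_by(cll, .data$compound_id),
    ii = all(.data$category == "inactive"),
    .groups = "drop"
  )$ii)
  any_active <- sum(dplyr::summarise(
    dplyr::group_by(cll, .data$compound_id),
    aa = any(.data$category == "active"),
    .groups = "drop"
  )$aa)
  n_sel <- if (is.null(selectivity)) NA_integer_ else sum(selectivity$selective)
  totals <- tibble::tibble(
    n_compounds = n_compounds,
    n_active_any = any_active,
    pct_active_any = round(100 * any_active / n_compounds, 1),
    n_inactive_all = all_inactive,
    pct_inactive_all = round(100 * all_inactive / n_compounds, 1),
    n_consensus = nrow(consensus),
    pct_consensus = round(100 * nrow(consensus) / n_compounds, 1),
    n_selective = n_sel,
    n_consensus_toxic_normal = nrow(consensus) - n_sel,
    pct_consensus_toxic_normal =
      round(100 * (nrow(consensus) - n_sel) / max(nrow(consensus), 1), 1)
  )
  structure(list(per_sample = per_sample, totals = totals),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("<screen_summary>\n")
  cat(sprintf(
    "  %d compounds; %d (%.1f%%) active in >=1 CLL sample; %d (%.1f%%) inactive in all\n",
    x$totals$n_compounds, x$totals$n_active_any, x$totals$pct_active_any,
    x$totals$n_inactive_all, x$totals$pct_inactive_all
  ))
  cat(sprintf("  %d (%.1f%%) consensus hits; %s selective\n",
              x$totals$n_consensus, x$totals$pct_consensus,
              ifelse(is.na(x$totals$n_selective), "?",
                     x$totals$n_selective)))
  print(x$per_sample)
  invisible(x)
}

#' Encode activity outcomes as integers
#'
#' Heatmap/clustering encoding of the activity matrix: active = 1,
#' inconclusive = 2, inactive = 3, untested = 4.
#'
#' @param matrix An [activity_matrix()].
#' @return An integer matrix, rows = compounds (rownames), columns =
#'   samples (colnames).
#' @export
encode_outcomes <- function(matrix) {
  codes <- c(active = 1L, inconclusive = 2L, inactive = 3L, untested = 4L)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(matrix[, c("compound_id", "sample_id", "category")],
                  code = codes[.data$category]),
    id_cols = "compound_id", names_from = "sample_id", values_from = "code",
    values_fill = 4L
  )
  out <- as.matrix(wide[, -1, drop = FALSE])
  storage.mode(out) <- "integer"
  rownames(out) <- wide$compound_id
  out[order(rownames(out)), , drop = FALSE]
}

#' Cluster compound activity profiles
#'
#' Hierarchical clustering (average linkage) of integer-coded activity
#' profiles. The distance between two compounds is the fraction of assays
#' tested in both where their codes differ; untested cells are
#' non-informative and excluded (pairs with no shared tested assay get the
#' maximal distance 1). Rows are ordered by compound id before clustering
#' so the leaf order is deterministic.
#'
#' @param encoded Integer matrix from [encode_outcomes()], >= 2 rows.
#' @param k Optional number of flat clusters to cut.
#' @return An object of class `activity_clustering`: list with `hclust`,
#'   `order` (compound ids in dendrogram order), `dist` (the distance
#'   matrix) and, when `k` is given, `clusters` (named integer vector).
#' @export
cluster_profiles <- function(encoded, k = NULL) {
  stopifnot(is.matrix(encoded))
  encoded <- encoded[order(rownames(encoded)), , drop = FALSE]
  if (nrow(encoded) < 2) {
    return(structure(
      list(hclust = NULL, order = rownames(encoded), dist = NULL,
           clusters = NULL),
      class = "activity_clustering"
    ))
  }
  tested <- encoded != 4L
  both <- tcrossprod(tested * 1)
  matches <- matrix(0, nrow(encoded), nrow(encoded))
  for (v in 1:3) {
    a <- (encoded == v & tested) * 1
    matches <- matches + tcrossprod(a)
  }
  d <- ifelse(both > 0, (both - matches) / both, 1)
  diag(d) <- 0
  dimnames(d) <- list(rownames(encoded), rownames(encoded))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  structure(
    list(hclust = hc, order = rownames(encoded)[hc$order], dist = d,
         clusters = clusters),
    class = "activity_clustering"
  )
}

#' @export
print.activity_clustering <- function(x, ...) {
  cat(sprintf("<activity_clustering> %d compounds%s\n",
              length(x$order),
              if (is.null(x$clusters)) "" else
                sprintf(", %d flat clusters", max(x$clusters))))
  invisible(x)
}

#' Export a clustering dendrogram as newick
#'
#' @param clustering An [cluster_profiles()] result with >= 2 compounds.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(clustering, path) {
  stopifnot(inherits(clustering, "activity_clustering"),
            !is.null(clustering$hclust))
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}
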