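#' Per-plate control-well statistics
#'
#' Summarizes the DMSO-only wells (columns 1 and 3; basal, 0% anchor) and
#' the fixed-dose positive-control wells (column 4, doxorubicin full kill,
#' -100% anchor) of every assay plate. The titration column is excluded.
#' Medians and MADs are carried alongside means and SDs: normalization
#' anchors use the robust estimates (dead or skipped wells happen on
#' 1536-well plates), while the Z'-factor uses means and SDs per the
#' standard screening-window formula.
#'
#' @param stack A raw plate-stack tibble (see [generate_sample_screen()] or
#'   [read_raw_stack()]). Compound-free DMSO-only plates are skipped.
#' @return A tibble with one row per assay plate: `plate_id`, and for each
#'   control group (`dmso`, `pos`) the n, mean, sd, median and mad of raw
#'   values.
#' @export
control_stats <- function(stack) {
  .check_stack(stack)
  assay <- stack[stack$role != "dmso_plate", ]
  ctl <- assay[assay$role %in% c("dmso_control", "pos_top"), ]
  grp <- dplyr::ungroup(dplyr::summarise(
    dplyr::group_by(ctl, .data$plate_id, .data$role),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    median = stats::median(.data$value),
    mad = stats::mad(.data$value),
    .groups = "drop"
  ))
  if (any(grp$n < 2)) {
    stop("control statistics need >= 2 wells per control group per plate",
         call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    grp,
    names_from = "role",
    values_from = c("n", "mean", "sd", "median", "mad"),
    names_glue = "{.value}_{ifelse(role == 'dmso_control', 'dmso', 'pos')}"
  )
  dplyr::arrange(wide, .data$plate_id)
}

#' Normalize raw luminescence to percent activity
#'
#' Affine normalization anchored at the DMSO basal level (0%) and the
#' doxorubicin full-kill level (-100%):
#' `100 * (raw - mu_dmso) / (mu_dmso - mu_pos)`. Cell killing is therefore
#' negative, with -100 meaning kill equal to the positive control.
#'
#' @param raw Raw luminescence values.
#' @param mu_dmso,mu_pos Plate anchors (typically the medians of the DMSO
#'   and positive-control wells). They must differ.
#' @return Normalized percent activity.
#' @examples
#' normalize_activity(c(1120, 100, 610), mu_dmso = 1120, mu_pos = 100)
#' @export
normalize_activity <- function(raw, mu_dmso, mu_pos) {
  if (any(mu_dmso == mu_pos)) {
    stop("degenerate controls: DMSO and positive-control anchors coincide",
         call. = FALSE)
  }
  100 * (raw - mu_dmso) / (mu_dmso - mu_pos)
}

#' Normalize every assay plate of a stack
#'
#' Applies [normalize_activity()] per plate using that plate's own control
#' anchors (medians from [control_stats()]). DMSO-only pattern-correction
#' plates have no positive controls and get `NA` normalized values; they
#' should be consumed by [pattern_correct()] before this step.
#'
#' @param stack A raw plate-stack tibble.
#' @param stats Optional precomputed [control_stats()]; recomputed from
#'   `stack` when missing (use this after pattern correction).
#' @return `stack` with an added `value_norm` column (% activity).
#' @export
normalize_stack <- function(stack, stats = control_stats(stack)) {
  .check_stack(stack)
  out <- dplyr::left_join(
    stack,
    stats[, c("plate_id", "median_dmso", "median_pos")],
    by = "plate_id"
  )
  ok <- !is.na(out$median_dmso) & !is.na(out$median_pos)
  out$value_norm <- NA_real_
  out$value_norm[ok] <- normalize_activity(out$value[ok], out$median_dmso[ok],
                                           out$median_pos[ok])
  out$median_dmso <- NULL
  out$median_pos <- NULL
  out
}

#' Correct spatial plate patterns using bracketing DMSO-only plates
#'
#' Compound-free DMSO-only plates at the beginning and end of each plate
#' stack expose the systematic spatial response of the instrument and
#' dispense path. For each DMSO plate `k` the relative background is
#' `b_k(w) = value_k(w) / median(value_k)`; for an assay plate at stack
#' position `x` the field is interpolated linearly in `x` between the
#' bracketing DMSO plates, and every raw value is divided by it. A purely
#' multiplicative artifact identical across the stack is removed exactly;
#' the median of each DMSO plate is unchanged, and re-running the
#' correction on its own output is the identity.
#'
#' @param stack A raw plate-stack tibble containing, per sample and stack,
#'   at least one DMSO-only plate (`role == "dmso_plate"`) before the first
#'   and after the last assay plate.
#' @return The stack with `value` replaced by corrected values.
#' @export
pattern_correct <- function(stack) {
  .check_stack(stack)
  keys <- intersect(c("sample_id", "stack"), names(stack))
  if (length(keys) == 0) {
    return(.pattern_correct_stack(stack))
  }
  stack <- dplyr::group_modify(
    dplyr::group_by(stack, dplyr::across(dplyr::all_of(keys))),
    function(df, key) .pattern_correct_stack(df)
  )
  dplyr::ungroup(stack)
}

.pattern_correct_stack <- function(df) {
  plates <- sort(unique(df$stack_index))
  is_dmso <- vapply(
    plates,
    function(k) all(df$role[df$stack_index == k] == "dmso_plate"),
    logical(1)
  )
  dmso_idx <- plates[is_dmso]
  assay_idx <- plates[!is_dmso]
  if (length(assay_idx) > 0 &&
      (length(dmso_idx) == 0 ||
       min(dmso_idx) > min(assay_idx) || max(dmso_idx) < max(assay_idx))) {
    stop("pattern correction needs DMSO-only plates bracketing the stack",
         call. = FALSE)
  }
  # relative background field per DMSO plate, wells in (row, col) order
  df <- dplyr::arrange(df, .data$stack_index, .data$row, .data$col)
  n_wells <- sum(df$stack_index == plates[1])
  bmat <- vapply(dmso_idx, function(k) {
    v <- df$value[df$stack_index == k]
    v / stats::median(v)
  }, numeric(n_wells))
  corrected <- df$value
  for (x in plates) {
    sel <- df$stack_index == x
    if (length(dmso_idx) == 1L) {
      b <- bmat[, 1]
    } else {
      k2 <- findInterval(x, dmso_idx, rightmost.closed = TRUE) # left bracket
      k1 <- max(k2, 1L)
      k2 <- min(k1 + 1L, length(dmso_idx))
      if (dmso_idx[k2] == dmso_idx[k1]) {
        b <- bmat[, k1]
      } else {
        t <- (x - dmso_idx[k1]) / (dmso_idx[k2] - dmso_idx[k1])
        t <- min(max(t, 0), 1)
        b <- (1 - t) * bmat[, k1] + t * bmat[, k2]
      }
    }
    corrected[sel] <- df$value[sel] / b
  }
  df$value <- corrected
  df
}

#' Z'-factor of a plate
#'
#' The screening-window coefficient
#' `1 - 3 * (sd_pos + sd_dmso) / |mean_pos - mean_dmso|`. Values approaching
#' 1 indicate well-separated controls; below 0 the assay window is unusable.
#'
#' @param mu_dmso,sd_dmso Mean and SD of the negative (DMSO) control wells.
#' @param mu_pos,sd_pos Mean and SD of the positive (full-kill) control wells.
#' @return The Z'-factor (dimensionless, <= 1).
#' @examples
#' z_factor(100, 5, 10, 2.5) # 0.75
#' @export
z_factor <- function(mu_dmso, sd_dmso, mu_pos, sd_pos) {
  if (any(mu_dmso == mu_pos)) {
    stop("Z'-factor undefined: control means coincide", call. = FALSE)
  }
  1 - 3 * (sd_pos + sd_dmso) / abs(mu_pos - mu_dmso)
}

#' Signal-to-background ratio of a plate
#'
#' Ratio of the DMSO (full signal) level to the positive-control
#' (background after full kill) level.
#'
#' @param mu_dmso DMSO control level (> 0 expected).
#' @param mu_pos Positive-control level; must be > 0.
#' @return Dimensionless ratio.
#' @export
signal_background <- function(mu_dmso, mu_pos) {
  if (any(mu_pos <= 0)) {
    stop("signal/background undefined for non-positive background",
         call. = FALSE)
  }
  mu_dmso / mu_pos
}

#' Plate-level quality-control report
#'
#' Computes, per assay plate, the Z'-factor, signal-to-background ratio and
#' DMSO-well coefficient of variation. Use [glance()] on the result for the
#' screen-aggregate view.
#'
#' @param stack A raw plate-stack tibble.
#' @param stats Optional precomputed [control_stats()].
#' @return A tibble of class `qc_report` with columns `plate_id`,
#'   `z_factor`, `sb_ratio`, `cv_dmso`, `n_dmso`, `n_pos`.
#' @export
qc_report <- function(stack, stats = control_stats(stack)) {
  out <- tibble::tibble(
    plate_id = stats$plate_id,
    z_factor = z_factor(stats$mean_dmso, stats$sd_dmso,
                        stats$mean_pos, stats$sd_pos),
    sb_ratio = signal_background(stats$median_dmso, stats$median_pos),
    cv_dmso = stats$sd_dmso / stats$mean_dmso,
    n_dmso = stats$n_dmso,
    n_pos = stats$n_pos
  )
  class(out) <- c("qc_report", class(out))
  out
}

#' @rdname qc_report
#' @param x A `qc_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    n_plates = nrow(x),
    z_factor_mean = mean(x$z_factor),
    z_factor_min = min(x$z_factor),
    sb_ratio_mean = mean(x$sb_ratio),
    cv_dmso_mean = mean(x$cv_dmso)
  )
}

# schema check shared by stack-consuming functions
.check_stack <- function(stack) {
  req <- c("plate_id", "stack_index", "row", "col", "role", "value")
  missing <- setdiff(req, names(stack))
  if (length(missing) > 0) {
    stop("plate stack is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(stack)
}
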