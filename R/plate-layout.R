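#' Geometric concentration series
#'
#' Construct the descending geometric dilution series used throughout the
#' screen: `values[i] = top / factor^(i-1)`. The default assay series is an
#' 8-point 1:5 titration from 57 uM down to about 0.7 nM; confirmation
#' screens use a 12-point 1:3 series and compound stock plates a 15-step
#' 1:2.236 series (2.236^2 is approximately 5, so alternate stock plates are
#' 1:5 apart).
#'
#' @param top Top (highest) concentration in uM. Must be positive.
#' @param factor Dilution factor between consecutive points; must be > 1.
#' @param n_points Number of concentrations; must be >= 1.
#'
#' @return An object of class `conc_series`: a list with elements `top`,
#'   `factor`, `n_points` and `values` (descending concentrations, uM).
#' @examples
#' s <- make_series(57, 5, 8)
#' s$values      # 57, 11.4, ... down to ~7.3e-4 uM (0.7 nM)
#' @export
make_series <- function(top, factor, n_points) {
  stopifnot(is.numeric(top), is.numeric(factor), is.numeric(n_points))
  if (length(top) != 1L || !is.finite(top) || top <= 0) {
    stop("`top` must be a single positive concentration (uM)", call. = FALSE)
  }
  if (length(factor) != 1L || !is.finite(factor) || factor <= 1) {
    stop("`factor` must be a single dilution ratio > 1", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  if (length(n_points) != 1L || is.na(n_points) || n_points < 1L) {
    stop("`n_points` must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      top = top,
      factor = factor,
      n_points = n_points,
      values = top / factor^(seq_len(n_points) - 1)
    ),
    class = "conc_series"
  )
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf(
    "<conc_series> %d points, 1:%g from %g uM to %g uM\n",
    x$n_points, x$factor, x$top, x$values[x$n_points]
  ))
  invisible(x)
}

#' @export
length.conc_series <- function(x) x$n_points

#' Final concentration after a pintool transfer
#'
#' Concentration of compound in the assay well after transferring
#' `v_transfer` nL of stock into `v_assay` uL of medium:
#' `stock * v_transfer / (v_assay * 1000 + v_transfer)`.
#' A 23 nL transfer of a 10 mM stock into a 4 uL assay volume gives the
#' screen's 57 uM top concentration.
#'
#' @param stock Stock concentration (uM), >= 0.
#' @param v_transfer Transferred volume (nL), > 0.
#' @param v_assay Assay volume before transfer (uL), > 0.
#' @return Final concentration in uM.
#' @examples
#' transfer_concentration(10000, 23, 4) # ~57.2 uM
#' @export
transfer_concentration <- function(stock, v_transfer, v_assay) {
  stopifnot(is.numeric(stock), is.numeric(v_transfer), is.numeric(v_assay))
  if (any(stock < 0) || any(v_transfer <= 0) || any(v_assay <= 0)) {
    stop("`stock` must be >= 0 and volumes strictly positive", call. = FALSE)
  }
  stock * v_transfer / (v_assay * 1000 + v_transfer)
}

#' 1536-well plate specification
#'
#' The screening plate format: 32 rows x 48 columns. Columns 1 and 3 carry
#' DMSO-only wells (basal control), column 2 a doxorubicin titration (1:2
#' from 10 uM to 5 nM, the 12-point block cycled down the 32 rows), column 4
#' doxorubicin at the fixed top dose of 10 uM (full-kill control), and
#' columns 5-48 the library compounds (32 x 44 = 1408 compound wells).
#'
#' @param pos_top_conc Concentration (uM) of the fixed positive-control
#'   column (column 4).
#' @param titration_top,titration_factor,titration_points The column-2
#'   positive-control titration series (defaults: 1:2 from 10 uM, 12 points,
#'   ending at ~5 nM).
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(pos_top_conc = 10,
                       titration_top = 10,
                       titration_factor = 2,
                       titration_points = 12L) {
  structure(
    list(
      n_rows = 32L,
      n_cols = 48L,
      dmso_cols = c(1L, 3L),
      pos_titration_col = 2L,
      pos_top_col = 4L,
      compound_cols = 5:48,
      pos_top_conc = pos_top_conc,
      titration = make_series(titration_top, titration_factor, titration_points)
    ),
    class = "plate_spec"
  )
}

#' @export
print.plate_spec <- function(x, ...) {
  cat(sprintf(
    "<plate_spec> %d x %d wells; DMSO cols %s; titration col %d (1:%g from %g uM, %d pts); pos col %d (%g uM); %d compound wells\n",
    x$n_rows, x$n_cols, paste(x$dmso_cols, collapse = ","),
    x$pos_titration_col, x$titration$factor, x$titration$top,
    x$titration$n_points, x$pos_top_col, x$pos_top_conc,
    x$n_rows * length(x$compound_cols)
  ))
  invisible(x)
}

#' Control layout of a screening plate
#'
#' Expand a [plate_spec()] into one row per well with its role and, for
#' control wells, the expected compound concentration. Column-2 wells carry
#' the doxorubicin titration down the rows; because a 1:2 series from 10 uM
#' reaches the stated 5 nM floor after 12 points, the 12-point block is
#' cycled over the 32 rows rather than extended below the floor.
#'
#' @param spec A [plate_spec()].
#' @return A tibble with columns `row`, `col`, `role` (one of
#'   `"dmso_control"`, `"pos_titration"`, `"pos_top"`, `"compound"`) and
#'   `conc_uM` (`NA` for compound wells, whose concentration is set per
#'   plate in the stack).
#' @export
control_layout <- function(spec = plate_spec()) {
  stopifnot(inherits(spec, "plate_spec"))
  grid <- tidyr::expand_grid(row = seq_len(spec$n_rows), col = seq_len(spec$n_cols))
  role <- dplyr::case_when(
    grid$col %in% spec$dmso_cols ~ "dmso_control",
    grid$col == spec$pos_titration_col ~ "pos_titration",
    grid$col == spec$pos_top_col ~ "pos_top",
    TRUE ~ "compound"
  )
  tit <- spec$titration$values
  conc <- rep(NA_real_, nrow(grid))
  conc[role == "dmso_control"] <- 0
  conc[role == "pos_top"] <- spec$pos_top_conc
  i <- role == "pos_titration"
  conc[i] <- tit[(grid$row[i] - 1L) %% length(tit) + 1L]
  dplyr::mutate(grid, role = role, conc_uM = conc)
}

#' Assign a compound library to plate wells
#'
#' Lay out a compound library over the compound area of the plate
#' (columns 5-48, row-major). Each block of 1408 compounds occupies one
#' well-set; every compound keeps its well across all concentration plates
#' of its stack (inter-plate titration), so a 2816-compound library needs
#' two plate stacks.
#'
#' @param compound_ids Character vector of unique compound identifiers.
#' @param spec A [plate_spec()].
#' @return A tibble with columns `compound_id`, `stack` (1-based well-set
#'   index), `row`, `col`.
#' @export
assign_compounds <- function(compound_ids, spec = plate_spec()) {
  stopifnot(is.character(compound_ids), !anyDuplicated(compound_ids))
  wells_per_plate <- spec$n_rows * length(spec$compound_cols)
  idx <- seq_along(compound_ids) - 1L
  within <- idx %% wells_per_plate
  tibble::tibble(
    compound_id = compound_ids,
    stack = idx %/% wells_per_plate + 1L,
    row = within %/% length(spec$compound_cols) + 1L,
    col = spec$compound_cols[within %% length(spec$compound_cols) + 1L]
  )
}
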