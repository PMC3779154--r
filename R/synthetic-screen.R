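#' Sample manifest for a synthetic screen
#'
#' Donor samples screened in parallel: leukemic (CLL) lymphocyte
#' preparations and lymphocytes from unaffected (normal) donors. The
#' default manifest mirrors a primary screen of six CLL and five normal
#' donors on cryopreserved cells.
#'
#' @param n_cll Number of CLL-like samples.
#' @param n_normal Number of normal-donor-like samples.
#' @param material Cell material, `"frozen"` or `"fresh"` (metadata only).
#' @return A tibble with columns `sample_id`, `group` (`"cll"` or
#'   `"normal"`) and `material`.
#' @export
sample_manifest <- function(n_cll = 6L, n_normal = 5L, material = "frozen") {
  stopifnot(n_cll >= 0, n_normal >= 0, n_cll + n_normal >= 1)
  tibble::tibble(
    sample_id = c(sprintf("CLL%02d", seq_len(n_cll)),
                  sprintf("NRM%02d", seq_len(n_normal))),
    group = rep(c("cll", "normal"), c(n_cll, n_normal)),
    material = material
  )
}

#' Noise model for synthetic plate reads
#'
#' Describes the stochastic and systematic components of the simulated
#' luminescence readout. Raw counts are
#' `plate_baseline * viability * spatial(well) * lognormal(1, well_cv)`,
#' where viability is floored at `1 / sb_ratio`: even fully killed wells
#' retain background luminescence, which is what gives the assay its finite
#' signal-to-background ratio (11.2 on average in the screen this emulates).
#'
#' @param plate_baseline Expected raw counts of an untreated (DMSO) well.
#' @param sb_ratio Signal-to-background ratio: DMSO signal over full-kill
#'   signal. Must be > 1.
#' @param well_cv Fractional coefficient of variation of the multiplicative
#'   log-normal well noise; >= 0.
#' @param spatial_amplitude Amplitude of the systematic spatial field
#'   (corner-to-corner gradient plus edge depression), as a fraction of
#'   signal; 0 disables it. The field is normalized to mean 1 over a plate.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(plate_baseline = 3000,
                        sb_ratio = 11.2,
                        well_cv = 0.05,
                        spatial_amplitude = 0.10) {
  stopifnot(plate_baseline > 0, sb_ratio > 1, well_cv >= 0, spatial_amplitude >= 0)
  structure(
    list(plate_baseline = plate_baseline, sb_ratio = sb_ratio,
         well_cv = well_cv, spatial_amplitude = spatial_amplitude),
    class = "noise_model"
  )
}

#' Systematic spatial field of a plate
#'
#' Deterministic multiplicative per-well field emulating dispense and
#' evaporation artifacts: a smooth corner-to-corner gradient of the given
#' amplitude plus a depression of the edge rows and columns, normalized so
#' the plate-wide mean is exactly 1.
#'
#' @param amplitude Fractional amplitude; 0 returns a field of ones.
#' @param n_rows,n_cols Plate dimensions.
#' @return An `n_rows` x `n_cols` numeric matrix with mean 1.
#' @export
spatial_field <- function(amplitude = 0.10, n_rows = 32L, n_cols = 48L) {
  stopifnot(amplitude >= 0)
  r <- (seq_len(n_rows) - 1) / (n_rows - 1)
  c_ <- (seq_len(n_cols) - 1) / (n_cols - 1)
  g <- 1 + amplitude * (outer(r, c_, `+`) - 1)      # -a at one corner, +a at the other
  g[c(1L, n_rows), ] <- g[c(1L, n_rows), ] * (1 - amplitude / 2)
  g[, c(1L, n_cols)] <- g[, c(1L, n_cols)] * (1 - amplitude / 2)
  g / mean(g)
}

# archetype labels in deterministic order
.archetypes <- c("inactive", "pan_cytotoxic", "partial", "top_only", "selective")

#' Default archetype mix of the synthetic library
#'
#' Roughly 5 in 6 compounds inactive, matching the inactive fraction seen
#' in primary-cell cytotoxicity screens of approved-drug libraries, with the
#' remainder split between full cytotoxics, partial-efficacy compounds,
#' top-concentration-only actives and CLL-selective compounds.
#'
#' @return Named numeric vector of archetype fractions summing to 1.
#' @export
default_archetype_mix <- function() {
  c(inactive = 0.80, pan_cytotoxic = 0.09, partial = 0.04,
    top_only = 0.04, selective = 0.03)
}

# deterministic integer counts from fractions (largest-remainder method)
.archetype_counts <- function(fractions, n) {
  if (!all(names(fractions) %in% .archetypes) || anyDuplicated(names(fractions))) {
    stop("archetype fractions must be named from: ",
         paste(.archetypes, collapse = ", "), call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop("archetype fractions must be non-negative and sum to 1", call. = FALSE)
  }
  full <- stats::setNames(rep(0, length(.archetypes)), .archetypes)
  full[names(fractions)] <- fractions
  k <- floor(full * n)
  rem <- full * n - k
  short <- n - sum(k)
  if (short > 0) {
    top_up <- order(rem, decreasing = TRUE)[seq_len(short)]
    k[top_up] <- k[top_up] + 1
  }
  as.integer(k)
}

#' Generate a synthetic compound library with ground-truth pharmacology
#'
#' Draws, for each compound and each sample, the true four-parameter
#' logistic curve the generator will realize on plates. Per-sample AC50s
#' scatter log-normally around a compound-level center to emulate
#' inter-patient potency spread; selective compounds carry a planted
#' CLL-versus-normal separation, either a potency shift (default 30-fold,
#' emulating the auranofin/dimercaprol pattern) or an efficacy gap (normal
#' cells barely respond, emulating the azacitidine/podofilox pattern).
#'
#' @param n_compounds Library size, >= 1.
#' @param fractions Named archetype fractions summing to 1; see
#'   [default_archetype_mix()].
#' @param samples A [sample_manifest()] tibble.
#' @param seed Integer seed; the truth table is deterministic given it.
#' @param sigma_log10 SD (log10 units) of the per-sample AC50 scatter
#'   around the compound center.
#' @param selective_fold Planted potency shift of shift-type selective
#'   compounds (normal AC50 over CLL AC50).
#' @return A `truth_table`: a tibble with one row per compound x sample
#'   (`compound_id`, `archetype`, `sample_id`, `group`, `y0_true`,
#'   `yinf_true`, `ac50_true`, `hill_true`), with the seed and generator
#'   configuration stored in attributes `seed` and `config`.
#' @export
generate_library <- function(n_compounds,
                             fractions = default_archetype_mix(),
                             samples = sample_manifest(),
                             seed = 1L,
                             sigma_log10 = 0.3,
                             selective_fold = 30) {
  stopifnot(n_compounds >= 1, nrow(samples) >= 1)
  counts <- .archetype_counts(fractions, n_compounds)
  set.seed(seed)
  archetype <- sample(rep(.archetypes, counts))
  compound_id <- sprintf("CMPD-%04d", seq_len(n_compounds))
  n <- n_compounds

  # compound-level curve centers
  yinf <- numeric(n); log_ac50 <- numeric(n); hill <- numeric(n)
  is <- archetype == "inactive"
  yinf[is] <- stats::runif(sum(is), -4, 0)
  log_ac50[is] <- 1; hill[is] <- 1
  ip <- archetype == "pan_cytotoxic"
  yinf[ip] <- stats::runif(sum(ip), -100, -85)
  log_ac50[ip] <- stats::runif(sum(ip), -1.5, 0.5)
  hill[ip] <- stats::runif(sum(ip), 1, 2)
  ir <- archetype == "partial"
  yinf[ir] <- stats::runif(sum(ir), -70, -45)
  log_ac50[ir] <- stats::runif(sum(ir), -1, 0.5)
  hill[ir] <- stats::runif(sum(ir), 1, 2)
  it <- archetype == "top_only"
  yinf[it] <- stats::runif(sum(it), -100, -80)
  # steep curves with midpoints just under the 57 uM top dose: appreciable
  # kill at the top concentration, essentially none one 1:5 step below
  log_ac50[it] <- log10(stats::runif(sum(it), 25, 60))
  hill[it] <- stats::runif(sum(it), 4, 6)
  il <- archetype == "selective"
  yinf[il] <- stats::runif(sum(il), -100, -85)
  log_ac50[il] <- stats::runif(sum(il), -1, 0)
  hill[il] <- stats::runif(sum(il), 1, 2)
  # alternate selective mechanism: potency shift vs efficacy gap
  sel_type <- character(n)
  sel_type[il] <- rep_len(c("shift", "efficacy"), sum(il))

  truth <- tidyr::expand_grid(
    tibble::tibble(compound_id, archetype, yinf0 = yinf,
                   log_ac50, hill_true = hill, sel_type),
    samples[, c("sample_id", "group")]
  )
  m <- nrow(truth)
  # top_only compounds get a tighter per-sample spread: their defining
  # feature (kill appearing only at the top dose) sits in a narrow potency
  # window and should persist across samples
  sig <- ifelse(truth$archetype == "top_only",
                pmin(sigma_log10, 0.1), sigma_log10)
  truth$ac50_true <- 10^(truth$log_ac50 + stats::rnorm(m, 0, sig))
  truth$y0_true <- 0
  truth$yinf_true <- truth$yinf0
  sel_norm <- truth$archetype == "selective" & truth$group == "normal"
  shift <- sel_norm & truth$sel_type == "shift"
  effgap <- sel_norm & truth$sel_type == "efficacy"
  truth$ac50_true[shift] <- truth$ac50_true[shift] * selective_fold
  truth$ac50_true[effgap] <- truth$ac50_true[effgap] * 3
  truth$yinf_true[effgap] <- stats::runif(sum(effgap), -20, -10)

  out <- truth[, c("compound_id", "archetype", "sel_type", "sample_id", "group",
                   "y0_true", "yinf_true", "ac50_true", "hill_true")]
  attr(out, "seed") <- seed
  attr(out, "config") <- list(
    n_compounds = n_compounds, fractions = fractions,
    sigma_log10 = sigma_log10, selective_fold = selective_fold,
    samples = samples
  )
  class(out) <- c("truth_table", class(out))
  out
}

# doxorubicin positive-control curve used for titration-column wells
.dox_truth <- function(group) {
  list(y0 = 0, yinf = -100, ac50 = if (identical(group, "cll")) 4.5 else 14.4,
       hill = 1.5)
}

#' Generate the raw plate stack of one sample's screen
#'
#' Realizes the assay architecture on 1536-well plates: each compound sits
#' in a fixed well across a stack of concentration plates (inter-plate
#' titration, one plate per concentration, highest first), with DMSO and
#' doxorubicin control columns on every plate and one compound-free
#' DMSO-only plate at the beginning and end of each stack. Raw counts
#' follow the [noise_model()]: baseline times true viability times the
#' spatial field times log-normal well noise, with viability floored at
#' `1 / sb_ratio`.
#'
#' @param truth A [generate_library()] truth table.
#' @param sample_id One sample present in `truth`.
#' @param noise A [noise_model()].
#' @param series The assay [make_series()] (default 8-point 1:5 from 57 uM).
#' @param seed Integer seed for the well noise.
#' @param spec A [plate_spec()].
#' @return A raw plate-stack tibble with columns `sample_id`, `plate_id`,
#'   `stack`, `stack_index`, `row`, `col`, `role`, `compound_id`, `conc_uM`,
#'   `value`. DMSO-only plates carry role `"dmso_plate"` in every well.
#' @export
generate_sample_screen <- function(truth, sample_id,
                                   noise = noise_model(),
                                   series = make_series(57, 5, 8),
                                   seed = 1L,
                                   spec = plate_spec()) {
  stopifnot(inherits(truth, "truth_table"), inherits(noise, "noise_model"))
  tr <- truth[truth$sample_id == sample_id, ]
  if (nrow(tr) == 0) {
    stop("sample `", sample_id, "` not found in truth table", call. = FALSE)
  }
  group <- tr$group[[1]]
  set.seed(seed)

  layout <- control_layout(spec)
  placement <- assign_compounds(unique(tr$compound_id), spec)
  n_stacks <- max(placement$stack)
  field <- spatial_field(noise$spatial_amplitude, spec$n_rows, spec$n_cols)
  dox <- .dox_truth(group)
  sdlog <- sqrt(log1p(noise$well_cv^2))

  plates <- list()
  for (s in seq_len(n_stacks)) {
    pl <- dplyr::left_join(
      layout,
      dplyr::select(placement[placement$stack == s, ], "compound_id", "row", "col"),
      by = c("row", "col")
    )
    pl <- dplyr::left_join(
      pl,
      tr[, c("compound_id", "y0_true", "yinf_true", "ac50_true", "hill_true")],
      by = "compound_id"
    )
    n_plates <- series$n_points + 2L
    for (k in seq_len(n_plates)) {
      p <- pl
      if (k == 1L || k == n_plates) {
        p$role <- "dmso_plate"
        p$compound_id <- NA_character_
        p$conc_uM <- 0
        y <- rep(0, nrow(p))
      } else {
        conc <- series$values[k - 1L]
        cmp <- p$role == "compound" & !is.na(p$compound_id)
        p$conc_uM[p$role == "compound"] <- ifelse(
          is.na(p$compound_id[p$role == "compound"]), NA_real_, conc
        )
        y <- rep(0, nrow(p))
        y[cmp] <- fourpl(conc, p$y0_true[cmp], p$yinf_true[cmp],
                         p$ac50_true[cmp], p$hill_true[cmp])
        tit <- p$role == "pos_titration"
        y[tit] <- fourpl(p$conc_uM[tit], dox$y0, dox$yinf, dox$ac50, dox$hill)
        y[p$role == "pos_top"] <- -100
      }
      # planted responses live on the normalized scale: 0 is the DMSO level
      # and -100 the full-kill background floor, so the expected signal
      # interpolates between those anchors and normalization inverts the
      # generator exactly (full kill still leaves 1/sb_ratio of signal)
      viability <- pmax(1 + (y / 100) * (1 - 1 / noise$sb_ratio),
                        1 / noise$sb_ratio)
      noise_fac <- if (noise$well_cv > 0) {
        stats::rlnorm(nrow(p), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else 1
      plates[[length(plates) + 1L]] <- tibble::tibble(
        sample_id = sample_id,
        plate_id = sprintf("%s-S%d-P%02d", sample_id, s, k),
        stack = s,
        stack_index = k,
        row = p$row, col = p$col, role = p$role,
        compound_id = p$compound_id, conc_uM = p$conc_uM,
        value = noise$plate_baseline * viability *
          field[cbind(p$row, p$col)] * noise_fac
      )
    }
  }
  dplyr::bind_rows(plates)
}

#' Generate a full multi-sample synthetic screen
#'
#' Runs [generate_sample_screen()] for every sample in the truth table,
#' with per-sample seeds derived deterministically from `seed`.
#'
#' @inheritParams generate_sample_screen
#' @param seed Integer master seed.
#' @return One long raw-stack tibble over all samples.
#' @export
generate_screen <- function(truth,
                            noise = noise_model(),
                            series = make_series(57, 5, 8),
                            seed = 1L,
                            spec = plate_spec()) {
  ids <- unique(truth$sample_id)
  dplyr::bind_rows(purrr::map(seq_along(ids), function(i) {
    generate_sample_screen(truth, ids[i], noise = noise, series = series,
                           seed = seed + 7919L * i, spec = spec)
  }))
}
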