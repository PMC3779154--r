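test_that("normalization is anchored at DMSO (0%) and full kill (-100%)", {
  expect_equal(normalize_activity(1120, 1120, 100), 0)
  expect_equal(normalize_activity(100, 1120, 100), -100)
  expect_equal(normalize_activity((1120 + 100) / 2, 1120, 100), -50)
  expect_error(normalize_activity(5, 10, 10), "degenerate")
})

test_that("normalization is affine and order-preserving", {
  raw <- sort(runif(50, 50, 2000))
  norm <- normalize_activity(raw, mu_dmso = 1500, mu_pos = 120)
  expect_true(all(diff(norm) > 0))
  # affine: second differences of equally spaced inputs vanish
  norm2 <- normalize_activity(seq(100, 1000, by = 100), 1500, 120)
  expect_equal(diff(norm2, differences = 2), rep(0, 8), tolerance = 1e-12)
})

test_that("Z'-factor follows the screening-window formula", {
  expect_equal(z_factor(100, 0, 10, 0), 1)
  expect_equal(z_factor(100, 5, 10, 2.5), 0.75)
  expect_lt(z_factor(100, 40, 10, 2.5), 0)    # noise swamps the window
  expect_error(z_factor(10, 1, 10, 1), "coincide")
})

test_that("signal/background is the DMSO-to-floor ratio", {
  expect_equal(signal_background(1120, 100), 11.2)
  expect_equal(signal_background(500, 500), 1)
  expect_error(signal_background(100, 0), "non-positive")
})

test_that("pattern correction is the identity on uniform DMSO plates", {
  truth <- generate_library(6, fractions = c(pan_cytotoxic = 1),
                            samples = sample_manifest(1, 0), seed = 21)
  raw <- generate_sample_screen(
    truth, "CLL01", noise = noise_model(well_cv = 0, spatial_amplitude = 0),
    seed = 21
  )
  corrected <- pattern_correct(raw)
  expect_equal(corrected$value[order(corrected$stack_index, corrected$row,
                                     corrected$col)],
               raw$value[order(raw$stack_index, raw$row, raw$col)],
               tolerance = 1e-12)
})

test_that("a planted multiplicative gradient is removed exactly", {
  truth <- generate_library(6, fractions = c(pan_cytotoxic = 1),
                            samples = sample_manifest(1, 0), seed = 22)
  raw <- generate_sample_screen(
    truth, "CLL01",
    noise = noise_model(well_cv = 0, spatial_amplitude = 0.10), seed = 22
  )
  corrected <- pattern_correct(raw)
  # corrected DMSO-plate wells all equal the plate median
  for (k in unique(corrected$stack_index[corrected$role == "dmso_plate"])) {
    v <- corrected$value[corrected$stack_index == k &
                           corrected$role == "dmso_plate"]
    expect_equal(v, rep(median(v), length(v)), tolerance = 1e-9)
  }
  # compound-plate control wells are flat again (field divided out; the
  # common level is baseline times the field's median)
  ctl <- corrected[corrected$role == "dmso_control", ]
  expect_equal(ctl$value, rep(ctl$value[1], nrow(ctl)), tolerance = 1e-9)
})

test_that("the correction field interpolates across stack position", {
  # hand-built 3-plate stack: a flat leading DMSO plate, a trailing DMSO
  # plate with a median-1 gradient of amplitude 0.1, and one assay plate
  # carrying exactly the midpoint (amplitude 0.05) field. Interpolation
  # must reconstruct that midpoint field, leaving the assay plate flat.
  lay <- control_layout(plate_spec())
  grad <- outer((1:32 - 16.5) / 31, (1:48 - 24.5) / 47, `+`)
  g1 <- 1 + 0.1 * grad
  expect_equal(median(g1), 1)   # construction guarantee
  gm <- 1 + 0.05 * grad
  mk <- function(idx, role, field) {
    tibble::tibble(
      plate_id = paste0("P", idx), stack_index = idx,
      row = lay$row, col = lay$col,
      role = if (is.na(role)) lay$role else role,
      compound_id = NA_character_, conc_uM = NA_real_,
      value = 1000 * field[cbind(lay$row, lay$col)]
    )
  }
  stack <- dplyr::bind_rows(
    mk(1, "dmso_plate", matrix(1, 32, 48)),
    mk(2, NA_character_, gm),
    mk(3, "dmso_plate", g1)
  )
  corrected <- pattern_correct(stack)
  mid <- corrected$value[corrected$stack_index == 2]
  expect_equal(mid, rep(1000, length(mid)), tolerance = 1e-9)
})

test_that("pattern correction is idempotent", {
  truth <- generate_library(6, samples = sample_manifest(1, 0), seed = 23)
  raw <- generate_sample_screen(
    truth, "CLL01",
    noise = noise_model(well_cv = 0.05, spatial_amplitude = 0.10), seed = 23
  )
  once <- pattern_correct(raw)
  twice <- pattern_correct(once)
  expect_equal(twice$value, once$value, tolerance = 1e-12)
})

test_that("missing bracketing DMSO plates are a configuration error", {
  truth <- generate_library(4, samples = sample_manifest(1, 0), seed = 24)
  raw <- generate_sample_screen(truth, "CLL01", seed = 24)
  no_tail <- raw[raw$stack_index < max(raw$stack_index), ]
  expect_error(pattern_correct(no_tail), "bracketing")
})

test_that("QC on the synthetic screen reproduces the configured assay stats", {
  truth <- generate_library(32, samples = sample_manifest(2, 0), seed = 25)
  raw <- generate_screen(truth, noise = noise_model(well_cv = 0.05), seed = 25)
  qc <- qc_report(pattern_correct(raw))
  expect_true(all(qc$z_factor > 0.5 & qc$z_factor < 1))
  agg <- glance(qc)
  expect_equal(agg$sb_ratio_mean, 11.2, tolerance = 0.05)
})
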