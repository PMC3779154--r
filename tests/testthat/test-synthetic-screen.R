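test_that("library generation respects the archetype mix and seed", {
  # degenerate mix: all inactive, and every entry satisfies the
  # inactive contract (|yinf - y0| < 5)
  t1 <- generate_library(10, fractions = c(inactive = 1),
                         samples = sample_manifest(1, 1), seed = 1)
  expect_true(all(t1$archetype == "inactive"))
  expect_true(all(abs(t1$yinf_true - t1$y0_true) < 5))

  # seed determinism
  t2a <- generate_library(200, seed = 7)
  t2b <- generate_library(200, seed = 7)
  expect_identical(t2a, t2b)
  expect_false(identical(t2a$ac50_true,
                         generate_library(200, seed = 8)$ac50_true))

  # requested selective count lands exactly
  mix <- c(inactive = 0.75, selective = 0.25)
  t3 <- generate_library(20, fractions = mix, seed = 42)
  expect_equal(sum(t3$archetype == "selective") / nrow(sample_manifest()), 5)

  expect_error(generate_library(10, fractions = c(inactive = 0.4)), "sum to 1")
})

test_that("one row exists per compound x sample", {
  truth <- generate_library(30, seed = 2)
  expect_equal(nrow(truth), 30 * 11)
  expect_equal(anyDuplicated(truth[, c("compound_id", "sample_id")]), 0)
  expect_equal(attr(truth, "seed"), 2)
})

test_that("selective compounds carry the planted CLL/normal separation", {
  truth <- generate_library(40, fractions = c(selective = 1), seed = 9)
  per_cmp <- dplyr::summarise(
    dplyr::group_by(truth, compound_id),
    fold = exp(mean(log(ac50_true[group == "normal"]))) /
      exp(mean(log(ac50_true[group == "cll"]))),
    eff_gap = mean(abs(yinf_true[group == "cll"])) -
      mean(abs(yinf_true[group == "normal"]))
  )
  expect_true(all(per_cmp$fold > 5 | per_cmp$eff_gap > 40))
})

test_that("zero-noise wells hit the exact anchor levels", {
  truth <- generate_library(8, fractions = c(inactive = 1),
                            samples = sample_manifest(1, 0), seed = 3)
  # force exactly flat truth so compound wells sit at baseline
  truth$yinf_true <- 0
  nm <- noise_model(plate_baseline = 2000, sb_ratio = 11.2,
                    well_cv = 0, spatial_amplitude = 0)
  raw <- generate_sample_screen(truth, "CLL01", noise = nm, seed = 3)
  cmp <- raw$value[raw$role == "compound" & !is.na(raw$compound_id)]
  expect_equal(cmp, rep(2000, length(cmp)))
  # full-kill positive controls at the background floor
  pos <- raw$value[raw$role == "pos_top"]
  expect_equal(pos, rep(2000 / 11.2, length(pos)))
  # DMSO-only bracketing plates at each end of the stack
  idx <- sort(unique(raw$stack_index))
  expect_true(all(raw$role[raw$stack_index == min(idx)] == "dmso_plate"))
  expect_true(all(raw$role[raw$stack_index == max(idx)] == "dmso_plate"))
})

test_that("a planted curve normalizes back to its 4PL midpoint", {
  truth <- generate_library(4, fractions = c(pan_cytotoxic = 1),
                            samples = sample_manifest(1, 0), seed = 5)
  truth$ac50_true <- 57 / 5^4   # put the midpoint exactly on a tested dose
  truth$hill_true <- 1
  truth$yinf_true <- -100
  nm <- noise_model(well_cv = 0, spatial_amplitude = 0)
  raw <- generate_sample_screen(truth, "CLL01", noise = nm, seed = 5)
  norm <- normalize_stack(raw)
  mid <- norm[!is.na(norm$compound_id) & !is.na(norm$conc_uM) &
                abs(norm$conc_uM - 57 / 5^4) < 1e-9, ]
  expect_equal(mid$value_norm, rep(-50, nrow(mid)), tolerance = 1e-6)
})

test_that("unknown samples are rejected", {
  truth <- generate_library(4, seed = 1)
  expect_error(generate_sample_screen(truth, "nope"), "not found")
})

test_that("the spatial field has mean one and vanishing amplitude is flat", {
  f <- spatial_field(0.1)
  expect_equal(mean(f), 1, tolerance = 1e-12)
  expect_gt(diff(range(f)), 0.1)
  expect_equal(spatial_field(0), matrix(1, 32, 48))
})

test_that("screen generation is deterministic under a fixed seed", {
  truth <- generate_library(8, samples = sample_manifest(2, 1), seed = 4)
  a <- generate_screen(truth, seed = 4)
  b <- generate_screen(truth, seed = 4)
  expect_identical(a, b)
})
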