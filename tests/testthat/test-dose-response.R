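test_that("noiseless curves are recovered to high precision", {
  conc <- rev(assay_series()$values)
  cases <- list(
    c(y0 = 0, yinf = -100, ac50 = 1, hill = 1.5),
    c(y0 = 5, yinf = -90, ac50 = 0.2, hill = 1),
    c(y0 = -2, yinf = -60, ac50 = 5, hill = 2.5)
  )
  for (p in cases) {
    fit <- fit_4pl(conc, fourpl(conc, p["y0"], p["yinf"], p["ac50"], p["hill"]))
    expect_true(fit$converged)
    expect_equal(fit$ac50, unname(p["ac50"]), tolerance = 1e-6)
    expect_equal(fit$hill, unname(p["hill"]), tolerance = 1e-6)
    expect_equal(fit$yinf, unname(p["yinf"]), tolerance = 1e-4)
    expect_equal(fit$y0, unname(p["y0"]), tolerance = 1e-4)
  }
})

test_that("flat data yield an unconverged fit with zero efficacy", {
  conc <- rev(assay_series()$values)
  fit <- fit_4pl(conc, rep(0, 8))
  expect_false(fit$converged)
  expect_equal(fit$efficacy, 0)
  expect_error(predict(fit, 1), "unconverged")
})

test_that("the fitted curve honours the 4PL identities", {
  conc <- rev(assay_series()$values)
  fit <- fit_4pl(conc, fourpl(conc, 0, -100, 1, 1.2))
  # midpoint identity: y(ac50) is halfway between the asymptotes
  expect_equal(predict(fit, fit$ac50), (fit$y0 + fit$yinf) / 2,
               tolerance = 1e-8)
  # asymptote limits
  expect_equal(predict(fit, 1e-9), fit$y0, tolerance = 1e-3)
  expect_equal(predict(fit, 1e9), fit$yinf, tolerance = 1e-3)
  # worked point: three-fold above the midpoint covers 3/4 of the span
  expect_equal(fourpl(3, 0, -100, 1, 1), -75, tolerance = 1e-12)
})

test_that("fitting is equivariant under concentration rescaling", {
  conc <- rev(assay_series()$values)
  resp <- fourpl(conc, 0, -95, 0.8, 1.7) + c(2, -1, 1, -2, 1, 0, -1, 2)
  f1 <- fit_4pl(conc, resp)
  for (k in c(10, 0.25)) {
    f2 <- fit_4pl(conc * k, resp)
    expect_equal(f2$ac50, f1$ac50 * k, tolerance = 1e-4)
    expect_equal(f2$hill, f1$hill, tolerance = 1e-4)
    expect_equal(f2$yinf, f1$yinf, tolerance = 1e-4)
  }
})

test_that("descending fits predict strictly decreasing responses", {
  conc <- rev(assay_series()$values)
  fit <- fit_4pl(conc, fourpl(conc, 0, -100, 1, 1.5))
  grid <- 10^seq(-4, 2, length.out = 200)
  expect_true(all(diff(predict(fit, grid)) < 0))
})

test_that("input contracts are enforced", {
  expect_error(fit_4pl(c(1, 2, 3), c(0, -10, -20)), "at least 4")
  expect_error(fit_4pl(c(-1, 1, 2, 3), rep(0, 4)), "positive")
  expect_error(fit_4pl(c(1, 2, 3, 4), c(0, NA, -10, -20)), "finite")
  expect_error(predict(fit_4pl(c(1, 2, 3, 4) / 2,
                               fourpl(c(1, 2, 3, 4) / 2, 0, -90, 1, 1)),
                       -1), "positive")
})

test_that("fit_screen matches fit_4pl curve by curve", {
  ns <- noiseless_screen()
  fits <- fit_screen(ns$norm)
  one <- fits[3, ]
  d <- ns$norm[!is.na(ns$norm$compound_id) &
                 ns$norm$compound_id == one$compound_id &
                 !is.na(ns$norm$value_norm), ]
  ref <- fit_4pl(d$conc_uM, d$value_norm)
  expect_equal(one$ac50, ref$ac50, tolerance = 1e-10)
  expect_equal(one$hill, ref$hill, tolerance = 1e-10)
  expect_equal(one$r2, ref$r2, tolerance = 1e-10)
})

test_that("log-AC50 error shrinks as well noise vanishes", {
  truth <- generate_library(24, fractions = c(pan_cytotoxic = 1),
                            samples = sample_manifest(1, 0), seed = 31)
  err_at <- function(cv) {
    raw <- generate_sample_screen(
      truth, "CLL01",
      noise = noise_model(well_cv = cv, spatial_amplitude = 0), seed = 31
    )
    fits <- fit_screen(normalize_stack(pattern_correct(raw)))
    m <- dplyr::inner_join(
      fits, dplyr::distinct(truth, compound_id, ac50_true),
      by = "compound_id"
    )
    median(abs(log10(m$ac50) - log10(m$ac50_true)))
  }
  errs <- vapply(c(0.10, 0.03, 0), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-6)
})

test_that("tidy and glance expose the fit in broom shape", {
  conc <- rev(assay_series()$values)
  fit <- fit_4pl(conc, fourpl(conc, 0, -100, 1, 1.5))
  td <- tidy(fit)
  expect_equal(td$term, c("y0", "yinf", "ac50", "hill"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$r2, 1, tolerance = 1e-9)
  expect_s3_class(autoplot(fit), "ggplot")
})
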