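.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Core bounded 4PL least-squares fit. Returns a named numeric vector so the
# screen-wide loop stays allocation-light; fit_4pl() wraps it in an object.
# Parametrized in log10(ac50); Levenberg-Marquardt with box bounds.
.fit_4pl_core <- function(conc, resp, flat_span = 5) {
  n <- length(conc)
  if (n < 4) {
    stop("4PL fit needs at least 4 concentration points", call. = FALSE)
  }
  if (length(resp) != n) {
    stop("`conc` and `resp` must have equal length", call. = FALSE)
  }
  if (any(conc <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (!all(is.finite(resp))) {
    stop("responses must be finite", call. = FALSE)
  }
  o <- order(conc)
  conc <- conc[o]
  resp <- resp[o]
  span <- diff(range(resp))
  if (span < flat_span) {
    # flat data: nothing to fit
    return(c(y0 = mean(resp), yinf = mean(resp), ac50 = NA_real_,
             hill = NA_real_, efficacy = 0, r2 = NA_real_,
             converged = 0, n_points = n))
  }
  cmin <- conc[1]
  cmax <- conc[n]
  lower <- c(-30, -120, log10(cmin) - 2, 0.3)
  upper <- c(30, 30, log10(cmax) + 2, 10)
  y0_i <- .clamp(mean(resp[1:2]), lower[1], upper[1])
  yinf_i <- .clamp(mean(resp[c(n - 1, n)]), lower[2], upper[2])
  # derivative-free start for ac50: best of a 20-point log-spaced grid
  grid <- seq(log10(cmin) - 1, log10(cmax) + 1, length.out = 20)
  rss <- vapply(grid, function(la) {
    sum((resp - (y0_i + (yinf_i - y0_i) / (1 + (10^la / conc)^1)))^2)
  }, numeric(1))
  start <- c(y0_i, yinf_i, grid[which.min(rss)], 1)
  fn <- function(p) resp - (p[1] + (p[2] - p[1]) / (1 + (10^p[3] / conc)^p[4]))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    p <- start
    ok <- FALSE
    res <- fn(p)
  } else {
    p <- fit$par
    ok <- fit$info %in% 1:4
    res <- fit$fvec
  }
  tss <- sum((resp - mean(resp))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  c(y0 = p[1], yinf = p[2], ac50 = 10^p[3], hill = p[4],
    efficacy = min(abs(p[2] - p[1]), 120), r2 = r2,
    converged = as.numeric(ok), n_points = n)
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Bounded least-squares fit of [fourpl()] to one compound-sample series,
#' yielding the midpoint concentration (AC50; reported as IC50 when the
#' response is loss of viability), the asymptotes, the Hill slope, the
#' efficacy (magnitude of the asymptote excursion, capped at 120 points)
#' and goodness of fit. Initialization is deterministic: asymptotes from
#' the two lowest/highest-concentration responses, Hill slope 1, and AC50
#' from a 20-point log-spaced grid search. Bounds (`hill` in [0.3, 10],
#' AC50 within two decades of the tested range, `yinf` in [-120, 30], `y0`
#' in [-30, 30]) keep incomplete curves from extrapolating pathologically.
#' Series whose response span is under `flat_span` points are declared flat
#' and returned unconverged with zero efficacy.
#'
#' @param conc Concentrations (uM), strictly positive, >= 4 points.
#' @param resp Normalized responses (% activity) of equal length.
#' @param flat_span Minimum response span (points) below which data are
#'   treated as flat.
#' @return An object of class `fit_4pl` with elements `y0`, `yinf`, `ac50`,
#'   `hill`, `efficacy`, `r2`, `converged`, `n_points`, `conc`, `resp`.
#' @examples
#' conc <- 57 / 5^(0:7)
#' fit <- fit_4pl(conc, fourpl(conc, 0, -100, 1, 1.5))
#' tidy(fit)
#' @export
fit_4pl <- function(conc, resp, flat_span = 5) {
  est <- .fit_4pl_core(conc, resp, flat_span = flat_span)
  o <- order(conc)
  structure(
    list(
      y0 = unname(est["y0"]), yinf = unname(est["yinf"]),
      ac50 = unname(est["ac50"]), hill = unname(est["hill"]),
      efficacy = unname(est["efficacy"]), r2 = unname(est["r2"]),
      converged = est["converged"] == 1, n_points = length(conc),
      conc = conc[o], resp = resp[o]
    ),
    class = "fit_4pl"
  )
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat("<fit_4pl>",
      if (x$converged) "" else "(not converged)",
      sprintf(
        "\n  y0 = %.2f  yinf = %.2f  ac50 = %.4g uM  hill = %.2f\n  efficacy = %.1f  r2 = %.3f  n = %d\n",
        x$y0, x$yinf, x$ac50, x$hill, x$efficacy,
        ifelse(is.na(x$r2), NA, x$r2), x$n_points
      ))
  invisible(x)
}

#' Predict from a fitted 4PL curve
#'
#' @param object A [fit_4pl()] object with `converged = TRUE`.
#' @param conc Concentrations (uM), strictly positive.
#' @param ... Unused.
#' @return Predicted % activity.
#' @export
predict.fit_4pl <- function(object, conc, ...) {
  if (!object$converged) {
    stop("cannot predict from an unconverged fit", call. = FALSE)
  }
  if (any(conc <= 0)) stop("`conc` must be strictly positive", call. = FALSE)
  fourpl(conc, object$y0, object$yinf, object$ac50, object$hill)
}

#' @exportS3Method generics::tidy
tidy.fit_4pl <- function(x, ...) {
  tibble::tibble(
    term = c("y0", "yinf", "ac50", "hill"),
    estimate = c(x$y0, x$yinf, x$ac50, x$hill)
  )
}

#' @exportS3Method generics::glance
glance.fit_4pl <- function(x, ...) {
  tibble::tibble(
    ac50 = x$ac50, efficacy = x$efficacy, r2 = x$r2,
    converged = x$converged, n_points = x$n_points
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.fit_4pl <- function(object, ...) {
  pts <- tibble::tibble(conc = object$conc, resp = object$resp)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$conc, y = .data$resp)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (uM)", y = "Activity (%)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- exp(seq(log(min(object$conc)), log(max(object$conc)),
                    length.out = 100))
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(conc = grid, resp = predict(object, grid)),
      colour = "#2c7fb8"
    )
  }
  p
}

#' Fit 4PL curves for every compound x sample series of a screen
#'
#' Vectorized driver over a normalized long plate table: compound wells are
#' grouped by compound and sample, concentration-response series assembled,
#' and each series fitted with the same bounded fitter as [fit_4pl()].
#'
#' @param data A normalized stack (see [normalize_stack()]) or any tibble
#'   with the grouping, concentration and response columns. Rows with
#'   missing compound, concentration or response are dropped; if a `role`
#'   column is present only `"compound"` wells are used.
#' @param by Grouping columns (default compound and sample).
#' @param conc,response Names of the concentration (uM) and normalized
#'   response columns.
#' @param flat_span Passed to the fitter.
#' @return A tibble with one row per group: the grouping columns plus
#'   `y0`, `yinf`, `ac50`, `hill`, `efficacy`, `r2`, `converged`,
#'   `n_points`.
#' @export
fit_screen <- function(data,
                       by = c("compound_id", "sample_id"),
                       conc = "conc_uM",
                       response = "value_norm",
                       flat_span = 5) {
  by <- intersect(by, names(data))
  stopifnot(length(by) >= 1, conc %in% names(data), response %in% names(data))
  d <- data
  if ("role" %in% names(d)) d <- d[d$role == "compound", ]
  keep <- !is.na(d[[conc]]) & !is.na(d[[response]])
  if ("compound_id" %in% by) keep <- keep & !is.na(d$compound_id)
  d <- d[keep, ]
  key <- do.call(paste, c(unname(d[by]), sep = "\r"))
  idx <- split(seq_len(nrow(d)), key)
  cc <- d[[conc]]
  rr <- d[[response]]
  est <- vapply(idx, function(i) .fit_4pl_core(cc[i], rr[i], flat_span),
                numeric(8))
  keys <- do.call(rbind, strsplit(names(idx), "\r", fixed = TRUE))
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(keys, stringsAsFactors = FALSE), by
  ))
  out <- dplyr::bind_cols(out, tibble::as_tibble(t(est)))
  out$converged <- out$converged == 1
  out$n_points <- as.integer(out$n_points)
  dplyr::arrange(out, dplyr::across(dplyr::all_of(by)))
}
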