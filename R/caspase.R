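#' Normalize caspase activation against DMSO control
#'
#' Caspase-3/7, -8 and -9 activation is expressed relative to the matched
#' DMSO-treated control: 0% is the DMSO level and 100% a two-fold
#' induction, i.e. `100 * (raw - mu_dmso) / mu_dmso`. The DMSO anchor
#' coincides with the viability normalization's basal anchor (both 0).
#'
#' @param raw Raw caspase assay signal.
#' @param mu_dmso DMSO control level; must be > 0.
#' @return Normalized activation (%).
#' @examples
#' normalize_caspase(c(1, 2, 3) * 500, mu_dmso = 500)
#' @export
normalize_caspase <- function(raw, mu_dmso) {
  if (any(mu_dmso <= 0)) {
    stop("`mu_dmso` must be strictly positive", call. = FALSE)
  }
  100 * (raw - mu_dmso) / mu_dmso
}

#' Fit a caspase activation curve, masking bell-shaped fall-off
#'
#' Cytotoxic compounds can produce bell-shaped caspase curves: activation
#' rises with concentration, then collapses at high doses because the cells
#' are dead before the readout. The fitter detects the peak response and,
#' if any point above the peak concentration falls below `mask_threshold`
#' (default 50%) of the peak, masks the entire post-peak tail (a suffix of
#' the concentration-ordered points, never the peak itself) and fits a
#' rising four-parameter logistic to the remainder. The EC50 is the fitted
#' midpoint of the ascending limb. Flat curves return an unconverged fit,
#' not an error.
#'
#' @param conc Concentrations (uM), strictly positive, >= 4 points.
#' @param resp Normalized activation (%) from [normalize_caspase()].
#' @param mask_threshold Fraction of the peak below which a post-peak point
#'   triggers masking.
#' @param flat_span Minimum response span (points) for a fit to be
#'   attempted.
#' @return A list of class `caspase_fit`: `fit` (a [fit_4pl()]-like object
#'   fitted on the unmasked points, with ascending-curve bounds), `ec50`,
#'   `masked` (integer indices of masked points in concentration order),
#'   `peak_conc`, `peak_resp`.
#' @export
fit_activation <- function(conc, resp, mask_threshold = 0.5, flat_span = 5) {
  n <- length(conc)
  stopifnot(length(resp) == n)
  if (n < 4) stop("activation fit needs at least 4 points", call. = FALSE)
  if (any(conc <= 0)) stop("`conc` must be strictly positive", call. = FALSE)
  o <- order(conc)
  conc <- conc[o]
  resp <- resp[o]
  peak <- which.max(resp)
  masked <- integer(0)
  if (peak < n && resp[peak] > 0) {
    post <- (peak + 1L):n
    if (any(resp[post] < mask_threshold * resp[peak])) {
      masked <- post
    }
  }
  keep <- setdiff(seq_len(n), masked)
  if (length(keep) < 4) {
    stop("bell too narrow: fewer than 4 points remain after masking",
         call. = FALSE)
  }
  fit <- .fit_rising_4pl(conc[keep], resp[keep], flat_span = flat_span)
  structure(
    list(fit = fit,
         ec50 = if (fit$converged) fit$ac50 else NA_real_,
         masked = masked, conc = conc, resp = resp,
         peak_conc = conc[peak], peak_resp = resp[peak]),
    class = "caspase_fit"
  )
}

# ascending 4PL: same machinery as the viability fitter but with bounds
# oriented for activation (yinf above y0, both allowed up to strong
# induction)
.fit_rising_4pl <- function(conc, resp, flat_span = 5) {
  n <- length(conc)
  span <- diff(range(resp))
  if (span < flat_span) {
    return(list(y0 = mean(resp), yinf = mean(resp), ac50 = NA_real_,
                hill = NA_real_, efficacy = 0, r2 = NA_real_,
                converged = FALSE, n_points = n, conc = conc, resp = resp))
  }
  cmin <- min(conc)
  cmax <- max(conc)
  lower <- c(-50, -50, log10(cmin) - 2, 0.3)
  upper <- c(100, 500, log10(cmax) + 2, 10)
  y0_i <- .clamp(mean(resp[1:2]), lower[1], upper[1])
  yinf_i <- .clamp(mean(resp[c(n - 1, n)]), lower[2], upper[2])
  grid <- seq(log10(cmin) - 1, log10(cmax) + 1, length.out = 20)
  rss <- vapply(grid, function(la) {
    sum((resp - (y0_i + (yinf_i - y0_i) / (1 + (10^la / conc)^1)))^2)
  }, numeric(1))
  fn <- function(p) resp - (p[1] + (p[2] - p[1]) / (1 + (10^p[3] / conc)^p[4]))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(y0_i, yinf_i, grid[which.min(rss)], 1),
      lower = lower, upper = upper, fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    p <- c(y0_i, yinf_i, grid[which.min(rss)], 1)
    ok <- FALSE
    res <- fn(p)
  } else {
    p <- fit$par
    ok <- fit$info %in% 1:4 && p[2] > p[1]   # must actually rise
    res <- fit$fvec
  }
  tss <- sum((resp - mean(resp))^2)
  structure(
    list(y0 = p[1], yinf = p[2], ac50 = 10^p[3], hill = p[4],
         efficacy = min(abs(p[2] - p[1]), 500),
         r2 = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
         converged = ok, n_points = n, conc = conc, resp = resp),
    class = "fit_4pl"
  )
}

#' @export
print.caspase_fit <- function(x, ...) {
  cat(sprintf(
    "<caspase_fit> EC50 = %s uM; %d/%d points masked (peak %.0f%% at %.3g uM)\n",
    ifelse(is.na(x$ec50), "NA", sprintf("%.3g", x$ec50)),
    length(x$masked), length(x$conc), x$peak_resp, x$peak_conc
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.caspase_fit <- function(x, ...) {
  tibble::tibble(
    term = c("y0", "yinf", "ec50", "hill"),
    estimate = c(x$fit$y0, x$fit$yinf, x$ec50, x$fit$hill)
  )
}

#' @exportS3Method generics::glance
glance.caspase_fit <- function(x, ...) {
  tibble::tibble(
    ec50 = x$ec50, efficacy = x$fit$efficacy, r2 = x$fit$r2,
    converged = x$fit$converged, n_masked = length(x$masked),
    n_points = length(x$conc)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.caspase_fit <- function(object, ...) {
  pts <- tibble::tibble(
    conc = object$conc, resp = object$resp,
    masked = seq_along(object$conc) %in% object$masked
  )
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$conc, y = .data$resp,
                                         shape = .data$masked)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(x = "Concentration (uM)", y = "Caspase activation (%)",
                  shape = "Masked") +
    ggplot2::theme_minimal()
  if (object$fit$converged) {
    keep <- !pts$masked
    grid <- exp(seq(log(min(pts$conc[keep])), log(max(pts$conc[keep])),
                    length.out = 100))
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(conc = grid,
                            resp = fourpl(grid, object$fit$y0,
                                          object$fit$yinf, object$fit$ac50,
                                          object$fit$hill),
                            masked = FALSE),
      colour = "#d95f02"
    )
  }
  p
}
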