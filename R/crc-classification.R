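.crc_active_classes <- c("1.1", "1.2", "2.1", "2.2")

# classification cascade shared by classify_crc() and classify_screen().
# All inputs are scalars except conc/resp; returns the class as character.
.classify_core <- function(y0, yinf, ac50, hill, efficacy, r2, converged,
                           conc, resp,
                           act_threshold = 25, r2_min = 0.3,
                           plateau_tol = 0.05, hill_min = 0.3) {
  kill <- -resp                                  # positive toward cell kill
  active_pts <- which(kill > act_threshold)
  if (length(active_pts) == 0) {
    return("4")                                  # no significant response
  }
  if (!converged) {
    return("3")                                  # responses but no usable fit
  }
  if (yinf >= y0) {
    return("4")                                  # excursion in the + direction
  }
  top_only <- length(active_pts) == 1 &&
    conc[active_pts] == max(conc)
  if (top_only || (!is.na(r2) && r2 < r2_min) || hill <= hill_min + 1e-9) {
    return("3")                                  # low-confidence active
  }
  complete <- abs(fourpl(max(conc), y0, yinf, ac50, hill) - yinf) <
    plateau_tol * efficacy
  if (complete) {
    if (efficacy >= 80) "1.1" else "1.2"
  } else {
    if (efficacy >= 80) "2.1" else "2.2"
  }
}

#' Classify a fitted concentration-response curve
#'
#' Assigns the qHTS concentration-response curve (CRC) class:
#' * **1.1 / 1.2** - complete curves with both asymptotes inside the tested
#'   range, efficacy >= 80% / < 80%;
#' * **2.1 / 2.2** - incomplete curves (lower plateau not reached),
#'   efficacy >= 80% / < 80%;
#' * **3** - low-confidence: kill only at the single highest concentration,
#'   a poorly fit curve (r2 below `r2_min`), a Hill slope stuck at its
#'   lower bound (shallow), or responses without a converged fit;
#' * **4** - inactive: no observed response beyond `act_threshold` points
#'   toward kill, or a fitted excursion in the signal-increase direction.
#'
#' Completeness is judged on the fitted curve: the prediction at the top
#' tested concentration must be within `plateau_tol` of the span from the
#' lower asymptote.
#'
#' @param fit A [fit_4pl()] object.
#' @param conc,resp The observed series the fit was made from (uM, %).
#' @param act_threshold Minimum kill (points toward -100) for a response to
#'   count as significant.
#' @param r2_min Minimum r-squared for a confident fit.
#' @param plateau_tol Fraction of efficacy within which the top-dose
#'   prediction must approach `yinf` to call the curve complete.
#' @param hill_min Hill slopes at or below this bound are treated as
#'   shallow (class 3).
#' @return The curve class as a character scalar
#'   (`"1.1"`, `"1.2"`, `"2.1"`, `"2.2"`, `"3"`, `"4"`).
#' @export
classify_crc <- function(fit, conc = fit$conc, resp = fit$resp,
                         act_threshold = 25, r2_min = 0.3,
                         plateau_tol = 0.05, hill_min = 0.3) {
  stopifnot(inherits(fit, "fit_4pl"))
  if (length(conc) != length(resp)) {
    stop("`conc` and `resp` must describe the same series", call. = FALSE)
  }
  .classify_core(fit$y0, fit$yinf, fit$ac50, fit$hill, fit$efficacy,
                 fit$r2, fit$converged, conc, resp,
                 act_threshold = act_threshold, r2_min = r2_min,
                 plateau_tol = plateau_tol, hill_min = hill_min)
}

#' Collapse curve classes into activity categories
#'
#' Three-way activity call used for hit aggregation: **active** compounds
#' have a curve class 1.1, 1.2, 2.1 or 2.2 *and* efficacy above
#' `active_efficacy`; **inactive** compounds are class 4; everything else
#' (class 3 and low-efficacy class 1-2 curves) is **inconclusive**.
#'
#' @param curve_class Character vector of CRC classes.
#' @param efficacy Efficacy values (%), same length.
#' @param active_efficacy Efficacy threshold for the active call.
#' @return Character vector: `"active"`, `"inconclusive"`, `"inactive"`.
#' @examples
#' categorize(c("1.2", "4", "2.2"), c(70, 0, 50))
#' @export
categorize <- function(curve_class, efficacy, active_efficacy = 60) {
  stopifnot(length(curve_class) == length(efficacy))
  dplyr::case_when(
    curve_class %in% .crc_active_classes & efficacy > active_efficacy ~ "active",
    curve_class == "4" ~ "inactive",
    TRUE ~ "inconclusive"
  )
}

#' Classify every fitted curve of a screen
#'
#' Joins the fit table from [fit_screen()] back to the observed normalized
#' series and adds `curve_class` and `category` columns.
#'
#' @param fits Output of [fit_screen()].
#' @param data The normalized long table the fits were made from.
#' @param by,conc,response As in [fit_screen()].
#' @param act_threshold,r2_min,plateau_tol,hill_min See [classify_crc()].
#' @param active_efficacy See [categorize()].
#' @return `fits` with added `curve_class` and `category` columns.
#' @export
classify_screen <- function(fits, data,
                            by = c("compound_id", "sample_id"),
                            conc = "conc_uM", response = "value_norm",
                            act_threshold = 25, r2_min = 0.3,
                            plateau_tol = 0.05, hill_min = 0.3,
                            active_efficacy = 60) {
  by <- intersect(by, names(fits))
  d <- data
  if ("role" %in% names(d)) d <- d[d$role == "compound", ]
  keep <- !is.na(d[[conc]]) & !is.na(d[[response]])
  if ("compound_id" %in% by) keep <- keep & !is.na(d$compound_id)
  d <- d[keep, ]
  key_d <- do.call(paste, c(unname(d[by]), sep = "\r"))
  idx <- split(seq_len(nrow(d)), key_d)
  key_f <- do.call(paste, c(unname(fits[by]), sep = "\r"))
  if (!all(key_f %in% names(idx))) {
    stop("`data` does not cover every fitted series", call. = FALSE)
  }
  cc <- d[[conc]]
  rr <- d[[response]]
  fits$curve_class <- vapply(seq_len(nrow(fits)), function(i) {
    j <- idx[[key_f[i]]]
    .classify_core(fits$y0[i], fits$yinf[i], fits$ac50[i], fits$hill[i],
                   fits$efficacy[i], fits$r2[i], fits$converged[i],
                   cc[j], rr[j],
                   act_threshold = act_threshold, r2_min = r2_min,
                   plateau_tol = plateau_tol, hill_min = hill_min)
  }, character(1))
  fits$category <- categorize(fits$curve_class, fits$efficacy,
                              active_efficacy = active_efficacy)
  fits
}
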