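#' Four-parameter logistic (Hill) model
#'
#' Evaluate `y(c) = y0 + (yinf - y0) / (1 + (ac50/c)^hill)`. With `yinf < y0`
#' and `hill > 0` this is the descending sigmoid describing loss of cell
#' viability with increasing compound concentration; at `c = ac50` the
#' response is halfway between the asymptotes.
#'
#' @param conc Concentrations (uM), strictly positive.
#' @param y0 Zero-dose asymptote (% activity).
#' @param yinf Infinite-dose asymptote (% activity).
#' @param ac50 Midpoint concentration (uM), > 0.
#' @param hill Hill slope, > 0.
#' @return Numeric vector of responses (% activity).
#' @examples
#' fourpl(c(0.1, 1, 10), y0 = 0, yinf = -100, ac50 = 1, hill = 1)
#' @export
fourpl <- function(conc, y0, yinf, ac50, hill) {
  if (any(conc <= 0)) stop("`conc` must be strictly positive", call. = FALSE)
  y0 + (yinf - y0) / (1 + (ac50 / conc)^hill)
}
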