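# Risk-of-overfishing curves: the posterior probability that recent catch
# exceeds MSY when the intrinsic growth rate suffers a sudden decline, as
# expected from coral-reef habitat loss. The reduction applies to r only;
# the risk metric is a static reference-point comparison per posterior
# draw, not a forward projection.

#' Mean catch over a recent window
#'
#' Arithmetic mean of annual catch over an inclusive year window (for
#' example the last three data years). Zero-catch years count as zeros.
#'
#' @param series a [cpue_series()].
#' @param window inclusive integer interval `c(first, last)`.
#' @return Mean catch (tonnes).
#' @export
recent_catch <- function(series, window) {
  window <- as.integer(window)
  if (window[1] < series$years[1] || window[2] > series$years[length(series$years)]) {
    stop("window lies outside the data span")
  }
  sel <- series$years >= window[1] & series$years <= window[2]
  mean(series$catch[sel])
}

#' MSY under a sudden reduction in intrinsic growth
#'
#' Schaefer MSY is `r*K/4`; a habitat-driven productivity decline of
#' `reduction_pct` percent scales r (not K), giving
#' `(r * (1 - reduction/100)) * K / 4`. Vectorised over draws.
#'
#' @param r,K posterior draws (or scalars) of growth rate and carrying
#'   capacity.
#' @param reduction_pct percent reduction in r, in \[0, 100\].
#' @return MSY (tonnes) at the reduced growth rate.
#' @export
msy_at_reduction <- function(r, K, reduction_pct) {
  if (any(reduction_pct < 0 | reduction_pct > 100)) {
    stop("reduction_pct must be in [0, 100]")
  }
  (r * (1 - reduction_pct / 100)) * K / 4
}

#' Posterior probability that recent catch exceeds reduced-r MSY
#'
#' Fraction of posterior draws for which `recent_catch` strictly exceeds
#' that draw's MSY at the given reduction. Ties (catch exactly at MSY) do
#' not count as overfishing.
#'
#' @param posterior an `spm_posterior` (draws must carry `r` and `K`).
#' @param recent_catch mean recent catch (tonnes), non-negative.
#' @param reduction_pct percent reduction in r.
#' @return Probability in \[0, 1\].
#' @export
overfishing_probability <- function(posterior, recent_catch, reduction_pct) {
  draws <- posterior$draws
  if (is.null(draws) || nrow(draws) == 0) stop("posterior has no draws")
  if (recent_catch < 0) stop("recent_catch must be non-negative")
  msy <- msy_at_reduction(draws$r, draws$K, reduction_pct)
  mean(recent_catch > msy)
}

#' Risk-of-overfishing curve over 0-100% productivity decline
#'
#' Evaluates [overfishing_probability()] at every integer reduction from 0
#' to 100 percent. Because each draw's exceedance indicator is monotone in
#' the reduction, the curve is non-decreasing; this is asserted after
#' construction. At 100% reduction MSY is zero, so any positive recent
#' catch gives probability 1.
#'
#' @param posterior an `spm_posterior`.
#' @param recent_catch mean recent catch (tonnes).
#' @param stock_id optional label; defaults to the fitted series' id.
#' @return Object of class `risk_curve`: tibble with `stock_id`,
#'   `reduction_pct` (0..100) and `probability`, plus the `recent_catch`
#'   attribute.
#' @export
risk_curve <- function(posterior, recent_catch,
                       stock_id = posterior$series$stock_id) {
  reductions <- 0:100
  probs <- vapply(
    reductions,
    function(p) overfishing_probability(posterior, recent_catch, p),
    numeric(1)
  )
  if (any(diff(probs) < 0)) {
    stop("internal error: risk curve is not monotone")
  }
  out <- tibble::tibble(
    stock_id = if (is.null(stock_id)) NA_character_ else stock_id,
    reduction_pct = reductions,
    probability = probs
  )
  attr(out, "recent_catch") <- recent_catch
  class(out) <- c("risk_curve", class(out))
  out
}
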