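#' Selection-altered sampling probability
#'
#' Maps the current relative frequency of variant A to the probability that a
#' member of the next generation adopts A, under a directional selection
#' pressure of strength `beta`. With `beta = 0` the map is the identity and
#' the model reduces to neutral drift. The boundaries 0 and 1 are absorbing
#' under both forms.
#'
#' Two functional forms are available:
#' \describe{
#'   \item{`"fitness"`}{the relative-fitness form
#'     \eqn{g(f) = f(1+\beta) / (1 + f\beta)}, i.e. variant A carries a
#'     multiplicative fitness advantage of \eqn{1+\beta};}
#'   \item{`"additive"`}{the additive logistic-increment form
#'     \eqn{g(f) = \mathrm{clip}(f + \beta f(1-f),\ 0,\ 1)}.}
#' }
#' Both are strictly increasing in `f`, weakly increasing in `beta` on (0, 1),
#' and fix the boundaries.
#'
#' @param f Numeric vector of frequencies in \[0, 1\].
#' @param beta Selection coefficient, a single non-negative number.
#' @param form Which pressure function to use; see Details.
#' @return Numeric vector of altered sampling probabilities, same length as `f`.
#' @examples
#' selection_pressure(0.5, 1)            # 2/3
#' selection_pressure(c(0, 0.3, 1), 0)   # identity under drift
#' @export
selection_pressure <- function(f, beta, form = c("fitness", "additive")) {
  form <- match.arg(form)
  if (!is.numeric(f) || anyNA(f) || any(f < 0 | f > 1)) {
    stop("`f` must be numeric in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("`beta` must be a single non-negative number", call. = FALSE)
  }
  switch(form,
    fitness = f * (1 + beta) / (1 + f * beta),
    additive = pmin(1, pmax(0, f + beta * f * (1 - f)))
  )
}
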