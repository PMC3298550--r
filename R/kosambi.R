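#' Kosambi map function
#'
#' Convert a recombination fraction to additive map distance (and back)
#' under the Kosambi mapping function, which allows for moderate crossover
#' interference: `d = 1/4 * log((1 + 2r) / (1 - 2r))` Morgans, reported in
#' centimorgans.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in centimorgans.
#' @examples
#' kosambi(0.2)            # 21.18 cM
#' kosambi_inverse(10)     # ~0.0987
#' @seealso [kosambi_inverse()]
#' @export
kosambi <- function(r) {
  if (!is.numeric(r)) stop("`r` must be numeric")
  if (any(is.na(r))) stop("`r` must not contain NA")
  if (any(r < 0)) stop("recombination fraction must be >= 0")
  if (any(r >= 0.5)) {
    stop("recombination fraction must be < 0.5 (map distance is infinite at r = 0.5)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi map function
#'
#' @param d Map distance(s) in centimorgans, `>= 0`.
#' @return Recombination fraction(s) `r = 1/2 * tanh(2d)` with `d` in Morgans.
#' @export
kosambi_inverse <- function(d) {
  if (!is.numeric(d)) stop("`d` must be numeric")
  if (any(is.na(d))) stop("`d` must not contain NA")
  if (any(d < 0)) stop("map distance must be >= 0")
  0.5 * tanh(d / 50)
}
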