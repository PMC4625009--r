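#' Convert recombination fractions to map distances
#'
#' `map_distance()` turns a recombination fraction into a genetic distance in
#' centiMorgans; `map_rf()` is its inverse. Two map functions are supported:
#' Haldane (crossovers as a Poisson process, no interference), where
#' \eqn{d = -50\,\ln(1 - 2r)} and \eqn{r = (1 - e^{-d/50})/2}, and Kosambi,
#' where \eqn{d = 25\,\ln[(1+2r)/(1-2r)]} and \eqn{r = \tanh(d/50)/2}.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Genetic distance(s) in centiMorgans, `>= 0`.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#'
#' @return A numeric vector of distances (cM) or recombination fractions.
#'
#' @examples
#' map_distance(0.0906)        # ~10 cM under Haldane
#' map_rf(10)                  # ~0.0906
#' @export
map_distance <- function(r, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5)) {
    stop("recombination fractions must lie in [0, 0.5); r = 0.5 maps to an infinite distance",
         call. = FALSE)
  }
  switch(map_function,
    haldane = -50 * log(1 - 2 * r),
    kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r))
  )
}

#' @rdname map_distance
#' @export
map_rf <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(is.na(d)) || any(d < 0)) {
    stop("map distances must be non-negative", call. = FALSE)
  }
  switch(map_function,
    haldane = 0.5 * (1 - exp(-d / 50)),
    kosambi = 0.5 * tanh(d / 50)
  )
}
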