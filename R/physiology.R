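#' Foraging return on investment
#'
#' Saturating (Michaelis-Menten) return on the amount `x` of resources a
#' cell invests into foraging: `f_max * x / (x + h)`. Monotone increasing
#' and concave, bounded above by `f_max`.
#'
#' @param x_alloc Non-negative investment into foraging (resources).
#' @param params A [model_params()] supplying `f_max` and `h`.
#' @return Foraging return (resources), same length as `x_alloc`.
#' @examples
#' p <- model_params()
#' foraging_return(0.3, p) # half-saturation: f_max / 2
#' @export
foraging_return <- function(x_alloc, params) {
  validate_params(params)
  if (any(!is.finite(x_alloc)) || any(x_alloc < 0))
    stop("foraging investment must be finite and >= 0", call. = FALSE)
  params$f_max * x_alloc / (x_alloc + params$h)
}

#' Stochastic damage increments
#'
#' Draws per-cycle cellular damage increments from an exponential
#' distribution with rate `lambda` (mean `1/lambda`).
#'
#' @param n Number of draws.
#' @param params A [model_params()] supplying `lambda`.
#' @return Non-negative numeric vector of length `n`.
#' @export
damage_increment <- function(n = 1L, params) {
  validate_params(params)
  stats::rexp(n, rate = params$lambda)
}

#' Damage remaining after repair
#'
#' Repair shrinks damage exponentially in the invested amount:
#' `d * exp(-a * y)`. Never increases damage; `y = 0` leaves it unchanged.
#'
#' @param d Non-negative damage before repair.
#' @param y_alloc Non-negative investment into repair (resources).
#' @param params A [model_params()] supplying `a`.
#' @return Damage after repair, in \[0, d\].
#' @export
repair_damage <- function(d, y_alloc, params) {
  validate_params(params)
  if (any(!is.finite(d)) || any(d < 0) ||
      any(!is.finite(y_alloc)) || any(y_alloc < 0))
    stop("damage and repair investment must be finite and >= 0",
         call. = FALSE)
  d * exp(-params$a * y_alloc)
}

#' Probability of producing a daughter cell
#'
#' `1 - exp(-b * z)` for an investment `z` into reproduction: zero at
#' `z = 0`, concave increasing, approaching one.
#'
#' @param z_alloc Non-negative investment into reproduction (resources).
#' @param params A [model_params()] supplying `b`.
#' @return Probability in \[0, 1).
#' @export
reproduction_probability <- function(z_alloc, params) {
  validate_params(params)
  if (any(!is.finite(z_alloc)) || any(z_alloc < 0))
    stop("reproduction investment must be finite and >= 0", call. = FALSE)
  -expm1(-params$b * z_alloc)
}

#' Intrinsic (damage-dependent) mortality
#'
#' Mixture of a linear and a quartic term in scaled damage `u = d / D`:
#' `(1 - c) * u + c * u^4`, clamped to \[0, 1\] (the raw expression
#' exceeds one for `d > D`). `c` tunes convexity; `D` sets the damage
#' scale, with small `D` meaning damage is strongly lethal.
#'
#' @param d Non-negative damage.
#' @param params A [model_params()] supplying `c` and `D`.
#' @return Death probability in \[0, 1\].
#' @export
intrinsic_mortality <- function(d, params) {
  validate_params(params)
  if (any(is.na(d)) || any(d < 0))
    stop("damage must be >= 0", call. = FALSE)
  u <- d / params$D
  pmin(1, pmax(0, (1 - params$c) * u + params$c * u^4))
}

#' Damage window expressed at a given damage level
#'
#' The viability loci partition the damage axis into `n_loci` half-open,
#' lower-inclusive windows `[d_{k-1}, d_k)` whose interior boundaries are
#' `params$damage_bins`; exactly one locus is expressed per cell per
#' cycle, the one whose window contains the cell's damage. Damage at or
#' beyond the last boundary expresses the final locus.
#'
#' @param d Non-negative damage (vectorised).
#' @param params A [model_params()].
#' @return Integer locus indices in `1:n_loci`.
#' @examples
#' expressed_locus(c(0, 0.374, 100), model_params())
#' @export
expressed_locus <- function(d, params) {
  validate_params(params)
  if (any(is.na(d)) || any(d < 0))
    stop("damage must be >= 0", call. = FALSE)
  findInterval(d, params$damage_bins, left.open = FALSE) + 1L
}

#' Viability-locus mortality round
#'
#' A cell whose damage expresses a locus carrying the deleterious allele
#' dies with probability `m2`; otherwise it survives this round.
#'
#' @param d Non-negative damage of the cell.
#' @param viability Integer vector of `n_loci` alleles (0/1) carried by
#'   the cell.
#' @param params A [model_params()].
#' @return Logical: `TRUE` if the cell dies in this round.
#' @export
viability_death <- function(d, viability, params) {
  validate_params(params)
  stopifnot(length(viability) == params$n_loci)
  k <- expressed_locus(d, params)
  if (viability[k] == 1L) stats::runif(1L) < params$m2 else FALSE
}
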