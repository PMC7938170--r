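#' Construct a genotype
#'
#' The heritable state of one individual: per-cell-type allocation genes
#' for foraging (`x`) and repair (`y`) on the real line, strictly positive
#' resource-need signals, damage-retention fractions in \[0, 1\] (the
#' share of her damage a mother cell keeps at division), and 16 bi-allelic
#' viability loci (0 = neutral, 1 = deleterious). `viability2` is the
#' type-2 cell's copy of the loci; it equals `viability` except under the
#' developmental extra-mutation variant.
#'
#' @param x,y Numeric length-2 vectors of allocation genes, indexed by
#'   cell type.
#' @param signal Positive length-2 vector of resource-need signals.
#' @param retention Length-2 vector of retention fractions in \[0, 1\].
#' @param viability Integer vector of 16 alleles, each 0 or 1.
#' @param viability2 Type-2 cell's allele vector (defaults to
#'   `viability`).
#' @return An object of class `genotype`.
#' @examples
#' g <- genotype()
#' softmax_allocations(g$x[1], g$y[1]) # (1/3, 1/3, 1/3)
#' @export
genotype <- function(x = c(0, 0), y = c(0, 0), signal = c(1, 1),
                     retention = c(0.5, 0.5),
                     viability = integer(16), viability2 = viability) {
  g <- structure(list(x = as.numeric(x), y = as.numeric(y),
                      signal = as.numeric(signal),
                      retention = as.numeric(retention),
                      viability = as.integer(viability),
                      viability2 = as.integer(viability2)),
                 class = "genotype")
  validate_genotype(g)
  g
}

validate_genotype <- function(g) {
  if (!(length(g$x) == 2L && length(g$y) == 2L &&
        all(is.finite(g$x)) && all(is.finite(g$y))))
    stop("invalid genotype: allocation genes must be two finite values per trait",
         call. = FALSE)
  if (!(length(g$signal) == 2L && all(is.finite(g$signal)) &&
        all(g$signal > 0)))
    stop("invalid genotype: signals must be strictly positive", call. = FALSE)
  if (!(length(g$retention) == 2L && all(!is.na(g$retention)) &&
        all(g$retention >= 0 & g$retention <= 1)))
    stop("invalid genotype: retention must lie in [0, 1]", call. = FALSE)
  for (nm in c("viability", "viability2"))
    if (!(length(g[[nm]]) == 16L && all(g[[nm]] %in% c(0L, 1L))))
      stop("invalid genotype: viability must be 16 alleles of 0/1",
           call. = FALSE)
  invisible(g)
}

#' Softmax transform of allocation genes to proportions
#'
#' Maps unbounded foraging and repair genes to the proportions of the
#' resource pool allocated to foraging (`p_x`), repair (`p_y`) and
#' reproduction (`p_z`):
#' \deqn{p_x = e^x / (1 + e^x + e^y),\quad p_y = e^y / (1 + e^x + e^y),}
#' and \eqn{p_z = 1 - p_x - p_y}. The three proportions are strictly
#' positive for finite genes and sum to one.
#'
#' @param x,y Finite numeric vectors (recycled to common length) of
#'   foraging and repair genes.
#' @return A data.frame with columns `p_x`, `p_y`, `p_z`.
#' @examples
#' softmax_allocations(0, 0)
#' @export
softmax_allocations <- function(x, y) {
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("invalid genotype: allocation genes must be finite", call. = FALSE)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  # subtract the max of (0, x, y) before exponentiating for stability
  m <- pmax(0, x, y)
  e0 <- exp(-m); ex <- exp(x - m); ey <- exp(y - m)
  den <- e0 + ex + ey
  data.frame(p_x = ex / den, p_y = ey / den, p_z = e0 / den)
}

#' Resource shares from the two cells' signals
#'
#' Cell 1 receives `s1 / (s1 + s2)` of the jointly foraged resources and
#' cell 2 the rest; the shares are invariant under a common rescaling of
#' the signals.
#'
#' @param s1,s2 Strictly positive numeric vectors of signals.
#' @return A data.frame with columns `share_1`, `share_2` summing to one.
#' @examples
#' resource_shares(3, 1) # 0.75, 0.25
#' @export
resource_shares <- function(s1, s2) {
  if (!all(is.finite(s1) & s1 > 0) || !all(is.finite(s2) & s2 > 0))
    stop("invalid genotype: signals must be strictly positive",
         call. = FALSE)
  tot <- s1 + s2
  data.frame(share_1 = s1 / tot, share_2 = s2 / tot)
}

#' Mutate the continuous reaction-norm genes
#'
#' Each allocation gene (`x`, `y` per type) mutates independently with
#' probability `mu` by an additive Gaussian(0, `sigma`) increment; the
#' signals mutate likewise on the log scale (keeping them positive); the
#' retention fractions mutate with probability `mu_d` on the log-odds
#' scale and are mapped back through the logistic function (keeping them
#' inside \[0, 1\]). The input genotype is not modified.
#'
#' @param g A [genotype()].
#' @param params A [model_params()] supplying `mu`, `sigma`, `mu_d` and
#'   the `evolvable_retention` switch.
#' @return A new `genotype`.
#' @export
mutate_continuous <- function(g, params) {
  validate_genotype(g)
  validate_params(params)
  mu <- params$mu; sigma <- params$sigma
  bump <- function(v) {
    hit <- stats::runif(length(v)) < mu
    v[hit] <- v[hit] + stats::rnorm(sum(hit), 0, sigma)
    v
  }
  out <- g
  if (mu > 0 && sigma >= 0) {
    out$x <- bump(g$x)
    out$y <- bump(g$y)
    out$signal <- exp(bump(log(g$signal)))
  }
  if (params$evolvable_retention && params$mu_d > 0) {
    hit <- stats::runif(2L) < params$mu_d
    q <- stats::qlogis(out$retention)
    q[hit] <- q[hit] + stats::rnorm(sum(hit), 0, sigma)
    out$retention <- stats::plogis(q)
  }
  out
}

#' Mutate the damage-gated viability loci
#'
#' Per round, every neutral allele flips to deleterious with probability
#' `mu_v0` and every deleterious allele back to neutral with probability
#' `mu_v1`, independently across the 16 loci. The bias `mu_v0 > mu_v1`
#' makes deleterious alleles accumulate under weak selection. Only the
#' shared (`viability`) copy is mutated; `rounds = 2` models the
#' developmental variant in which a lineage receives an extra round.
#'
#' @param g A [genotype()].
#' @param params A [model_params()] supplying `mu_v0`, `mu_v1`.
#' @param rounds Positive integer number of mutation rounds.
#' @return A new `genotype` with mutated `viability` (and `viability2`
#'   kept identical to it).
#' @export
mutate_viability <- function(g, params, rounds = 1L) {
  validate_genotype(g)
  validate_params(params)
  stopifnot(rounds >= 1L)
  v <- g$viability
  for (i in seq_len(rounds)) v <- flip_viability(v, params)
  out <- g
  out$viability <- v
  out$viability2 <- v
  out
}

# one biased mutation round over a 0/1 allele vector
flip_viability <- function(v, params) {
  u <- stats::runif(length(v))
  ifelse(v == 1L, ifelse(u < params$mu_v1, 0L, 1L),
         ifelse(u < params$mu_v0, 1L, 0L))
}
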