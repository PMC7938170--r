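#' Model parameters for the bicellular simulator
#'
#' Bundles every model parameter together with engine settings into a
#' validated `model_params` object. Defaults are the shared parameter
#' values used by all experiment presets; see [preset_params()] for the
#' per-experiment bindings.
#'
#' @param N Population size: number of bicellular adults after culling.
#' @param f_max Maximal foraging return (resources).
#' @param h Half-saturation constant of the foraging return (resources).
#' @param lambda Rate of the exponential distribution of per-cycle damage
#'   increments (1/damage); the mean increment is `1/lambda`.
#' @param a Rate at which repair decreases damage (1/resources).
#' @param b Rate at which reproduction probability increases with
#'   investment (1/resources).
#' @param c Convexity of the mortality-versus-damage curve, in \[0, 1\]
#'   (0 = linear, 1 = quartic).
#' @param D Inverse extrinsic mortality: damage scale of the intrinsic
#'   mortality curve. Small `D` makes damage strongly lethal. `Inf` is
#'   allowed and disables intrinsic mortality.
#' @param m2 Per-locus mortality probability when an expressed viability
#'   locus carries the deleterious allele.
#' @param r Regeneration probability: when exactly one cell of an
#'   individual dies, the survivor doubles and rebuilds the adult with
#'   probability `r`; otherwise the individual dies.
#' @param mu Mutation probability per continuous reaction-norm gene per
#'   offspring (allocation and signal genes).
#' @param sigma Standard deviation of the Gaussian mutation effect on the
#'   unconstrained gene scales.
#' @param mu_v0,mu_v1 Per-locus viability mutation probabilities, neutral
#'   to deleterious (`mu_v0`) and deleterious to neutral (`mu_v1`).
#' @param mu_d Mutation probability of the damage-retention genes
#'   (perturbed on the log-odds scale with the same `sigma`).
#' @param n_loci Number of damage-gated viability loci (16).
#' @param damage_bins Interior boundaries of the `n_loci` damage windows,
#'   strictly increasing, length `n_loci - 1`. Default: evenly spaced
#'   windows on \[0, 6\]; damage at or beyond the last boundary expresses
#'   the final locus.
#' @param cycles Number of population cycles to run.
#' @param init_resources Resource endowment per cell in the founding
#'   population (resources).
#' @param offspring_endowment Standard resource endowment of each newly
#'   formed cell of an offspring (resources). The default, 2, equals
#'   `init_resources`: every cell starts life with the same standard
#'   endowment, the smallest integer amount that keeps all experiment
#'   presets demographically viable. Set to 0 to switch to the
#'   proportional-inheritance variant in which the propagule instead
#'   receives `kappa * z` resources.
#' @param kappa Offspring resource constant of the proportional
#'   -inheritance variant (used only when `offspring_endowment = 0`): the
#'   propagule receives `kappa * z` resources, split between its two
#'   cells, where `z` was the mother cell's allocation to reproduction.
#' @param extra_mutation_type2 If `TRUE`, the type-2 cell's copy of the
#'   viability loci undergoes one extra round of mutation at offspring
#'   production (developmental mutation asymmetry).
#' @param evolvable_sharing If `FALSE`, foraged resources are always
#'   split 0.5/0.5 and the signal genes are inert (ablation control).
#' @param evolvable_retention If `FALSE`, retention genes never mutate
#'   regardless of `mu_d`.
#' @param max_age_class Oldest age class tracked separately in the
#'   death/exposure ledgers; older individuals are pooled into it.
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params(N = 100, cycles = 50)
#' p$damage_bins[1:3]
#' @export
model_params <- function(N = 1e5, f_max = 6, h = 0.3, lambda = 2, a = 0.5,
                         b = 0.1, c = 0.8, D = 1000, m2 = 0.05, r = 0,
                         mu = 0.05, sigma = 0.5, mu_v0 = 0.001, mu_v1 = 1e-4,
                         mu_d = 0, n_loci = 16L, damage_bins = NULL,
                         cycles = 10000L, init_resources = 2,
                         offspring_endowment = 2, kappa = 1,
                         extra_mutation_type2 = FALSE,
                         evolvable_sharing = TRUE,
                         evolvable_retention = TRUE,
                         max_age_class = 60L) {
  n_loci <- as.integer(n_loci)
  if (is.null(damage_bins))
    damage_bins <- seq(0, 6, length.out = n_loci + 1L)[-c(1L, n_loci + 1L)]
  p <- list(N = as.integer(N), f_max = f_max, h = h, lambda = lambda, a = a,
            b = b, c = c, D = D, m2 = m2, r = r, mu = mu, sigma = sigma,
            mu_v0 = mu_v0, mu_v1 = mu_v1, mu_d = mu_d, n_loci = n_loci,
            damage_bins = as.numeric(damage_bins),
            cycles = as.integer(cycles), init_resources = init_resources,
            offspring_endowment = offspring_endowment, kappa = kappa,
            extra_mutation_type2 = isTRUE(extra_mutation_type2),
            evolvable_sharing = isTRUE(evolvable_sharing),
            evolvable_retention = isTRUE(evolvable_retention),
            max_age_class = as.integer(max_age_class))
  class(p) <- "model_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  chk <- function(ok, msg) if (!ok) stop("invalid model_params: ", msg,
                                         call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  chk(num1(p$N) && p$N >= 1, "N must be a positive integer")
  chk(num1(p$f_max) && p$f_max >= 0, "f_max must be >= 0")
  chk(num1(p$h) && p$h > 0, "h must be > 0")
  chk(num1(p$lambda) && p$lambda > 0, "lambda must be > 0")
  chk(num1(p$a) && p$a >= 0, "a must be >= 0")
  chk(num1(p$b) && p$b >= 0, "b must be >= 0")
  chk(num1(p$c) && p$c >= 0 && p$c <= 1, "c must be in [0, 1]")
  chk(num1(p$D) && p$D > 0, "D must be > 0")
  for (nm in c("m2", "r", "mu", "mu_v0", "mu_v1", "mu_d"))
    chk(num1(p[[nm]]) && p[[nm]] >= 0 && p[[nm]] <= 1,
        paste(nm, "must be a probability in [0, 1]"))
  chk(num1(p$sigma) && p$sigma >= 0, "sigma must be >= 0")
  chk(num1(p$n_loci) && p$n_loci >= 1 && p$n_loci <= 30,
      "n_loci must be in 1..30")
  chk(length(p$damage_bins) == p$n_loci - 1L,
      "damage_bins must have n_loci - 1 interior boundaries")
  chk(all(is.finite(p$damage_bins)) && all(p$damage_bins > 0) &&
        !is.unsorted(p$damage_bins, strictly = TRUE),
      "damage_bins must be positive and strictly increasing")
  chk(num1(p$cycles) && p$cycles >= 0, "cycles must be >= 0")
  chk(num1(p$init_resources) && p$init_resources >= 0,
      "init_resources must be >= 0")
  chk(num1(p$offspring_endowment) && p$offspring_endowment >= 0,
      "offspring_endowment must be >= 0")
  chk(num1(p$kappa) && p$kappa >= 0, "kappa must be >= 0")
  chk(p$offspring_endowment > 0 || p$kappa > 0,
      "offspring cells need resources: offspring_endowment or kappa > 0")
  chk(num1(p$max_age_class) && p$max_age_class >= 1,
      "max_age_class must be >= 1")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Bicellular life-history model parameters\n")
  cat(sprintf("  population N = %d, cycles = %d\n", x$N, x$cycles))
  cat(sprintf("  foraging f_max = %g, h = %g; damage lambda = %g\n",
              x$f_max, x$h, x$lambda))
  cat(sprintf("  repair a = %g; fecundity b = %g\n", x$a, x$b))
  cat(sprintf("  mortality c = %g, D = %g, m2 = %g; regeneration r = %g\n",
              x$c, x$D, x$m2, x$r))
  cat(sprintf("  mutation mu = %g (sigma = %g), mu_v0 = %g, mu_v1 = %g, mu_d = %g\n",
              x$mu, x$sigma, x$mu_v0, x$mu_v1, x$mu_d))
  cat(sprintf("  %d viability loci, windows up to %g; sharing %s, retention %s%s\n",
              x$n_loci, max(x$damage_bins),
              if (x$evolvable_sharing) "evolvable" else "fixed 0.5/0.5",
              if (x$evolvable_retention) "evolvable" else "fixed",
              if (x$extra_mutation_type2) "; extra type-2 mutation round" else ""))
  invisible(x)
}
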