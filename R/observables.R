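#' Deleterious-allele frequency per viability locus
#'
#' Fraction of individuals (haploid clonal genotypes, counted once per
#' individual via the type-1 copy) carrying the deleterious allele at
#' each damage-gated locus.
#'
#' @param pop A population snapshot data.frame.
#' @param n_loci Number of loci encoded in the viability strings.
#' @return Numeric vector of `n_loci` frequencies in \[0, 1\].
#' @examples
#' allele_frequencies(make_fixture("one_carrier"))
#' @export
allele_frequencies <- function(pop, n_loci = 16L) {
  if (nrow(pop) == 0L)
    stop("undefined statistic: empty population", call. = FALSE)
  colMeans(viability_to_matrix(pop$viability_1, n_loci))
}

#' Empirical age-specific mortality
#'
#' Pools individual deaths (outside the random cull) and exposures over
#' the final `window` fraction of recorded cycles and reports the
#' per-age-class death probability `deaths / exposures`. Age classes with
#' zero exposure are omitted.
#'
#' @param sim A `bicellum_sim` from [run_simulation()].
#' @param window Fraction of the most recent cycles to pool (default the
#'   final 10 percent).
#' @return A data.frame with columns `age`, `deaths`, `exposures`,
#'   `mortality`.
#' @export
mortality_by_age <- function(sim, window = 0.1) {
  stopifnot(inherits(sim, "bicellum_sim"), window > 0, window <= 1)
  n <- nrow(sim$deaths)
  if (n == 0L) stop("undefined statistic: no cycles recorded", call. = FALSE)
  rows <- seq.int(max(1L, n - ceiling(window * n) + 1L), n)
  dd <- colSums(sim$deaths[rows, , drop = FALSE])
  ee <- colSums(sim$exposures[rows, , drop = FALSE])
  if (all(ee == 0))
    stop("undefined statistic: no exposures in the window", call. = FALSE)
  keep <- ee > 0
  data.frame(age = which(keep) - 1L, deaths = dd[keep],
             exposures = ee[keep], mortality = dd[keep] / ee[keep],
             row.names = NULL)
}

#' Damage by age: median and 10/90 percent quantiles
#'
#' Per age class in a population snapshot, the median and the 10th/90th
#' percentiles of per-individual mean damage (mean over the two cells),
#' i.e. the centre and an 80 percent interval of the damage-at-age
#' distribution.
#'
#' @param pop A population snapshot data.frame.
#' @return A data.frame with columns `age`, `n`, `q10`, `median`, `q90`.
#' @export
damage_by_age <- function(pop) {
  if (nrow(pop) == 0L)
    stop("undefined statistic: empty population", call. = FALSE)
  dmg <- (pop$damage_1 + pop$damage_2) / 2
  ages <- sort(unique(pop$age))
  out <- lapply(ages, function(a) {
    x <- dmg[pop$age == a]
    q <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
    data.frame(age = a, n = length(x), q10 = q[1], median = q[2], q90 = q[3])
  })
  do.call(rbind, out)
}

#' Division-of-labour index
#'
#' L1 distance between the two cell types' mean allocation profiles,
#' `|px_1 - px_2| + |py_1 - py_2| + |pz_1 - pz_2|`, in \[0, 2\]: zero iff
#' the types allocate identically, 2 for fully disjoint specialisation.
#'
#' @param profile_1,profile_2 Length-3 numeric vectors `(p_x, p_y, p_z)`
#'   or 3-column matrices/data.frames (rows compared pairwise).
#' @return Non-negative numeric vector of distances.
#' @examples
#' division_of_labour_index(c(0.5, 0, 0.5), c(1, 0, 0)) # 1
#' @export
division_of_labour_index <- function(profile_1, profile_2) {
  p1 <- as.matrix(profile_1); p2 <- as.matrix(profile_2)
  if (ncol(p1) == 1L) p1 <- t(p1)
  if (ncol(p2) == 1L) p2 <- t(p2)
  stopifnot(ncol(p1) == 3L, ncol(p2) == 3L, nrow(p1) == nrow(p2))
  rowSums(abs(p1 - p2))
}

# per-cycle division-of-labour index of a trajectory
dol_trajectory <- function(traj) {
  division_of_labour_index(traj[, c("px_1", "py_1", "pz_1")],
                           traj[, c("px_2", "py_2", "pz_2")])
}

#' Equilibrium (final-window) summary of a simulation
#'
#' Means of the per-cycle summaries over the final `window` fraction of
#' recorded cycles: allocation proportions, resource share, damage,
#' resource pool and retention per cell type, overall means across types,
#' the division-of-labour index of the window-mean profiles, and the
#' deleterious-allele frequency per locus.
#'
#' @param sim A `bicellum_sim`.
#' @param window Fraction of the most recent cycles to average (default
#'   the final 10 percent).
#' @return A one-row data.frame (allele frequencies in columns
#'   `vfreq_01` ... `vfreq_16`).
#' @export
equilibrium_summary <- function(sim, window = 0.1) {
  stopifnot(inherits(sim, "bicellum_sim"), window > 0, window <= 1)
  traj <- sim$trajectory
  n <- nrow(traj)
  if (n == 0L) stop("undefined statistic: no cycles recorded", call. = FALSE)
  rows <- seq.int(max(1L, n - ceiling(window * n) + 1L), n)
  m <- colMeans(traj[rows, setdiff(names(traj), "cycle"), drop = FALSE])
  out <- as.data.frame(as.list(m))
  out$pz_mean <- (out$pz_1 + out$pz_2) / 2
  out$px_mean <- (out$px_1 + out$px_2) / 2
  out$py_mean <- (out$py_1 + out$py_2) / 2
  out$dol <- division_of_labour_index(
    c(out$px_1, out$py_1, out$pz_1), c(out$px_2, out$py_2, out$pz_2))
  out$window_cycles <- length(rows)
  out
}

#' Which cell type is the germ line?
#'
#' Classifies a run's germ line as the cell type with the higher mean
#' allocation to reproduction over the final window, requiring a minimum
#' gap to avoid noise-driven labels.
#'
#' @param sim A `bicellum_sim`.
#' @param window Final fraction of cycles to average.
#' @param gap Minimum difference in mean `p_z` between the types; smaller
#'   gaps return `NA` (unclassified).
#' @return `1L`, `2L`, or `NA_integer_`.
#' @export
germline_type <- function(sim, window = 0.1, gap = 0.1) {
  s <- equilibrium_summary(sim, window)
  d <- s$pz_1 - s$pz_2
  if (abs(d) < gap) return(NA_integer_)
  if (d > 0) 1L else 2L
}
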