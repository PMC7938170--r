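# Population snapshots are plain data.frames, one row per individual:
# id, age, damage_1/2, resources_1/2, the continuous genes x_1, y_1, x_2,
# y_2, signal_gene_1/2 (signal = exp(gene)), retention_1/2, and the two
# 16-character viability strings. The compiled engine consumes a numeric
# state matrix plus two 0/1 locus matrices built from such a snapshot.

state_cols <- c("age", "damage_1", "damage_2", "resources_1", "resources_2",
                "x_1", "y_1", "x_2", "y_2", "g_1", "g_2", "q_1", "q_2")

#' Founding population
#'
#' The symmetric, senescence-free start: every individual carries the
#' ancestral genotype (all allocation genes 0, hence 1/3 allocations;
#' equal signals; retention 0.5; all viability loci neutral), zero damage
#' and `init_resources` per cell, age 0.
#'
#' @param params A [model_params()].
#' @return A population snapshot data.frame with `params$N` rows.
#' @export
init_population <- function(params) {
  validate_params(params)
  N <- params$N
  v <- strrep("0", params$n_loci)
  data.frame(id = seq_len(N), age = 0L,
             damage_1 = 0, damage_2 = 0,
             resources_1 = params$init_resources,
             resources_2 = params$init_resources,
             x_1 = 0, y_1 = 0, x_2 = 0, y_2 = 0,
             signal_gene_1 = 0, signal_gene_2 = 0,
             retention_1 = 0.5, retention_2 = 0.5,
             viability_1 = v, viability_2 = v,
             stringsAsFactors = FALSE)
}

viability_to_matrix <- function(strings, n_loci) {
  m <- matrix(0L, length(strings), n_loci)
  for (i in seq_along(strings)) {
    bits <- utf8ToInt(strings[[i]]) - utf8ToInt("0")
    if (length(bits) != n_loci || any(bits < 0L | bits > 1L))
      stop("viability strings must be ", n_loci, " characters of 0/1",
           call. = FALSE)
    m[i, ] <- bits
  }
  m
}

matrix_to_viability <- function(m) {
  apply(m, 1L, function(bits) paste(bits, collapse = ""))
}

snapshot_to_state <- function(pop, params) {
  need <- c("age", "damage_1", "damage_2", "resources_1", "resources_2",
            "x_1", "y_1", "x_2", "y_2", "signal_gene_1", "signal_gene_2",
            "retention_1", "retention_2", "viability_1", "viability_2")
  miss <- setdiff(need, names(pop))
  if (length(miss))
    stop("population snapshot lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  st <- cbind(pop$age, pop$damage_1, pop$damage_2,
              pop$resources_1, pop$resources_2,
              pop$x_1, pop$y_1, pop$x_2, pop$y_2,
              pop$signal_gene_1, pop$signal_gene_2,
              stats::qlogis(pop$retention_1), stats::qlogis(pop$retention_2))
  colnames(st) <- state_cols
  list(state = st,
       v1 = viability_to_matrix(pop$viability_1, params$n_loci),
       v2 = viability_to_matrix(pop$viability_2, params$n_loci))
}

state_to_snapshot <- function(state, v1, v2) {
  n <- nrow(state)
  if (n == 0L) {
    out <- init_population(model_params(N = 1, cycles = 0))[0, ]
    return(out)
  }
  data.frame(id = seq_len(n), age = as.integer(state[, 1]),
             damage_1 = state[, 2], damage_2 = state[, 3],
             resources_1 = state[, 4], resources_2 = state[, 5],
             x_1 = state[, 6], y_1 = state[, 7],
             x_2 = state[, 8], y_2 = state[, 9],
             signal_gene_1 = state[, 10], signal_gene_2 = state[, 11],
             retention_1 = stats::plogis(state[, 12]),
             retention_2 = stats::plogis(state[, 13]),
             viability_1 = matrix_to_viability(v1),
             viability_2 = matrix_to_viability(v2),
             stringsAsFactors = FALSE)
}

trajectory_names <- function(n_loci) {
  c("cycle", "px_1", "py_1", "pz_1", "px_2", "py_2", "pz_2",
    "share_1", "damage_1", "damage_2", "resources_1", "resources_2",
    "retention_1", "retention_2", "n", "births", "deaths",
    sprintf("vfreq_%02d", seq_len(n_loci)))
}

#' Run the evolutionary simulation
#'
#' Initialises (or takes) a population and iterates the full cycle —
#' allocation, foraging with redistribution, damage, repair, reproduction,
#' three mortality rounds (damage curve, expressed viability locus,
#' random cull to `N`), regeneration with probability `r` — for
#' `params$cycles` cycles in the compiled engine. Runs are exactly
#' reproducible for a fixed seed.
#'
#' @param params A [model_params()].
#' @param seed Optional integer seed passed to [set.seed()].
#' @param init Optional starting population snapshot (default
#'   [init_population()]).
#' @return An object of class `bicellum_sim`: a list with `trajectory`
#'   (data.frame of per-cycle summaries: mean allocation proportions,
#'   resource share, damage, pool, retention per cell type, counts, and
#'   the 16 deleterious-allele frequencies), `deaths` and `exposures`
#'   (cycle x age-class matrices of individual deaths outside the cull
#'   and individuals at risk), `final` (final population snapshot),
#'   `extinct`, `cycles_run`, `params` and `seed`.
#' @examples
#' sim <- run_simulation(model_params(N = 50, cycles = 20), seed = 1)
#' tail(sim$trajectory[, c("cycle", "pz_1", "pz_2")], 3)
#' @export
run_simulation <- function(params, seed = NULL, init = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- init_population(params)
  st <- snapshot_to_state(init, params)
  res <- run_engine(unclass(params), st$state, st$v1, st$v2, params$cycles)
  keep <- seq_len(res$cycles_run)
  traj <- as.data.frame(res$stats[keep, , drop = FALSE])
  names(traj) <- trajectory_names(params$n_loci)
  structure(list(trajectory = traj,
                 deaths = res$deaths[keep, , drop = FALSE],
                 exposures = res$exposures[keep, , drop = FALSE],
                 final = state_to_snapshot(res$final_state, res$final_v1,
                                           res$final_v2),
                 extinct = res$extinct, cycles_run = res$cycles_run,
                 params = params, seed = seed),
            class = "bicellum_sim")
}

#' @export
print.bicellum_sim <- function(x, ...) {
  cat(sprintf("Bicellular simulation: N = %d, %d/%d cycles run%s\n",
              x$params$N, x$cycles_run, x$params$cycles,
              if (x$extinct) " (EXTINCT)" else ""))
  if (x$cycles_run > 0) {
    s <- equilibrium_summary(x)
    cat(sprintf("  final-window allocations type 1 (x/y/z): %.3f/%.3f/%.3f\n",
                s$px_1, s$py_1, s$pz_1))
    cat(sprintf("  final-window allocations type 2 (x/y/z): %.3f/%.3f/%.3f\n",
                s$px_2, s$py_2, s$pz_2))
    cat(sprintf("  division-of-labour index: %.3f\n", s$dol))
  }
  invisible(x)
}

#' Develop a propagule into a bicellular adult
#'
#' A reproducing mother cell of type `t` keeps `retention[t]` of her
#' damage; the propagule receives the remaining `1 - retention[t]` share,
#' inherits the mother's genotype passed through [mutate_continuous()]
#' and [mutate_viability()] (with an extra viability round for the type-2
#' copy under the developmental asymmetry variant), and doubles once,
#' splitting damage equally between its type-1 and type-2 cells. Each new
#' cell starts with the standard resource endowment
#' (`offspring_endowment`); in the proportional-inheritance variant
#' (`offspring_endowment = 0`) the propagule instead carries
#' `kappa * z_alloc` resources, split equally.
#'
#' @param mother_cell List with `type` (1 or 2), `damage`, and `alive`.
#' @param g The mother's [genotype()].
#' @param z_alloc The mother cell's investment into reproduction this
#'   cycle (resources).
#' @param params A [model_params()].
#' @return List with `offspring` (an individual: `genotype`, `cells` of
#'   two lists with `type`, `damage`, `resources`, `alive`, and `age = 0`)
#'   and `mother_damage`, the damage the mother retains.
#' @export
develop_offspring <- function(mother_cell, g, z_alloc, params) {
  validate_params(params)
  validate_genotype(g)
  if (!isTRUE(mother_cell$alive))
    stop("engine invariant violation: dead mother cell cannot reproduce",
         call. = FALSE)
  t <- mother_cell$type
  stopifnot(t %in% c(1L, 2L), z_alloc >= 0, mother_cell$damage >= 0)
  ret <- g$retention[t]
  prop_damage <- (1 - ret) * mother_cell$damage
  cell_res <- if (params$offspring_endowment > 0) params$offspring_endowment
              else params$kappa * z_alloc / 2
  inherited <- g
  inherited$viability <- if (t == 1L) g$viability else g$viability2
  inherited$viability2 <- inherited$viability
  child <- mutate_viability(mutate_continuous(inherited, params), params)
  if (params$extra_mutation_type2)
    child$viability2 <- flip_viability(child$viability, params)
  cells <- list(
    list(type = 1L, damage = prop_damage / 2, resources = cell_res,
         alive = TRUE),
    list(type = 2L, damage = prop_damage / 2, resources = cell_res,
         alive = TRUE))
  list(offspring = list(genotype = child, cells = cells, age = 0L),
       mother_damage = ret * mother_cell$damage)
}

#' Regenerate a bicellular adult from a surviving cell
#'
#' When exactly one cell of an individual survives the first two
#' mortality rounds, the survivor doubles again (with probability `r` in
#' the engine): its resources and damage are split equally between new
#' type-1 and type-2 cells, the genotype is unchanged (no mutation at
#' regeneration) and the individual keeps its age.
#'
#' @param survivor List with `damage` and `resources` of the surviving
#'   cell.
#' @param n_survivors Number of surviving cells (must be exactly 1).
#' @return A list of two cells.
#' @export
regenerate <- function(survivor, n_survivors = 1L) {
  if (n_survivors != 1L)
    stop("engine invariant violation: regeneration needs exactly one survivor",
         call. = FALSE)
  stopifnot(survivor$damage >= 0, survivor$resources >= 0)
  half <- list(damage = survivor$damage / 2,
               resources = survivor$resources / 2, alive = TRUE)
  list(c(list(type = 1L), half), c(list(type = 2L), half))
}
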