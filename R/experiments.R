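# Experiment presets. All share the default parameter column (N = 1e5,
# f_max = 6, h = 0.3, lambda = 2, a = 0.5, b = 0.1, c = 0.8, m2 = 0.05,
# mu = 0.05, sigma = 0.5, mu_v0 = 0.001, mu_v1 = 1e-4) and differ in the
# damage scale D, the regeneration probability r, the damage-partition
# mutation rate mu_d, and the variant switches. In fig1 and fig2b/fig3b
# the death of one cell kills the individual (r = 0); in fig2a/fig3a the
# adult is always rebuilt from the surviving cell (r = 1), the regime in
# which somatic specialisation pays because a failed partner cell is
# replaceable.

preset_table <- function() {
  list(
    fig1 = list(D = 1000, r = 0, mu_d = 0,
                desc = "symmetric damage split, weak intrinsic mortality; senescence by mutation accumulation"),
    fig2a = list(D = 1, r = 1, mu_d = 0,
                 desc = "lethal damage, full regeneration; germ-line-soma division of labour"),
    fig2b = list(D = 1, r = 0, mu_d = 0,
                 desc = "lethal damage, no regeneration; partner-cell death is lethal"),
    fig3a = list(D = 1, r = 1, mu_d = 0.05,
                 desc = "evolvable damage partitioning, full regeneration"),
    fig3b = list(D = 1, r = 0, mu_d = 0.05,
                 desc = "evolvable damage partitioning, no regeneration"),
    no_share_ablation = list(D = 1, r = 1, mu_d = 0,
                             evolvable_sharing = FALSE,
                             desc = "fig2a without evolvable resource sharing (control)"),
    germline_symmetry = list(D = 1, r = 1, mu_d = 0,
                             desc = "fig2a conditions for the replicate germ-line identity experiment"),
    extra_mutation_type2 = list(D = 1, r = 1, mu_d = 0,
                                extra_mutation_type2 = TRUE,
                                desc = "fig2a with an extra type-2 viability mutation round in development")
  )
}

#' Names of the built-in experiment presets
#' @return Character vector of preset names.
#' @export
preset_names <- function() names(preset_table())

#' Parameters of a built-in experiment preset
#'
#' Binds the shared parameter column plus the preset's `D`, `r`, `mu_d`
#' and variant switches, optionally rescaled for desk-scale runs.
#'
#' @param name One of [preset_names()].
#' @param scale Multiplies the population size `N` (in (0, 1\]); cycle
#'   counts are set independently via `cycles`.
#' @param cycles Optional cycle count override (default 10000).
#' @param overrides Named list of [model_params()] arguments overriding
#'   the preset binding; unknown names are an error.
#' @return A [model_params()] object.
#' @examples
#' preset_params("fig1", scale = 0.05, cycles = 1000)$N
#' @export
preset_params <- function(name, scale = 1, cycles = NULL,
                          overrides = list()) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; see preset_names()", call. = FALSE)
  stopifnot(scale > 0, scale <= 1)
  args <- tab[[name]]
  args$desc <- NULL
  args$N <- max(1L, as.integer(round(1e5 * scale)))
  if (!is.null(cycles)) args$cycles <- as.integer(cycles)
  bad <- setdiff(names(overrides), names(formals(model_params)))
  if (length(bad))
    stop("invalid override key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args[names(overrides)] <- overrides
  do.call(model_params, args)
}

#' Run one preset experiment
#'
#' Runs the simulation under a preset's parameters and optionally writes
#' a run directory: `config.tsv` (the full parameter binding),
#' `trajectory.tsv`, `summary.tsv` (final-window summary),
#' `snapshot.tsv` (final population) and `manifest.txt` (seed, scale,
#' software version and the parameters needed to reproduce the run
#' byte-for-byte).
#'
#' @param name One of [preset_names()].
#' @param seed Integer seed.
#' @param scale,cycles,overrides Passed to [preset_params()].
#' @param out_dir Optional output directory (created if needed).
#' @return The `bicellum_sim`, invisibly when `out_dir` is given.
#' @export
run_preset <- function(name, seed = 1L, scale = 1, cycles = NULL,
                       overrides = list(), out_dir = NULL) {
  params <- preset_params(name, scale = scale, cycles = cycles,
                          overrides = overrides)
  sim <- run_simulation(params, seed = seed)
  if (is.null(out_dir)) return(sim)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(params, file.path(out_dir, "config.tsv"))
  write_tsv(sim$trajectory, file.path(out_dir, "trajectory.tsv"))
  write_tsv(equilibrium_summary(sim), file.path(out_dir, "summary.tsv"))
  write_tsv(sim$final, file.path(out_dir, "snapshot.tsv"))
  writeLines(c(
    sprintf("package: bicellum %s",
            as.character(utils::packageVersion("bicellum"))),
    sprintf("preset: %s", name),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("scale: %g", scale),
    sprintf("N: %d", params$N),
    sprintf("cycles: %d", params$cycles),
    sprintf("extinct: %s", sim$extinct),
    "config: config.tsv (re-run with read_config + run_simulation(seed))"),
    file.path(out_dir, "manifest.txt"))
  invisible(sim)
}

#' Replicate runs and germ-line identity tally
#'
#' Runs `n_reps` independent replicates of a preset under distinct seeds
#' (`base_seed + 0:(n_reps-1)`), classifies each run's germ line as the
#' cell type with the higher final mean allocation to reproduction
#' ([germline_type()], minimum gap 0.1), and tallies the outcomes.
#'
#' @param name One of [preset_names()].
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Seed of the first replicate.
#' @param scale,cycles,overrides Passed to [preset_params()].
#' @param gap Classification gap passed to [germline_type()].
#' @return List with `results` (data.frame: replicate, seed, germline,
#'   final mean `pz_1`, `pz_2`, extinct flag) and `tally` (named counts
#'   for type 1, type 2 and unclassified runs).
#' @export
replicate_experiment <- function(name, n_reps, base_seed = 1L, scale = 0.05,
                                 cycles = 5000L, overrides = list(),
                                 gap = 0.1) {
  stopifnot(n_reps >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_reps) - 1L
  rows <- lapply(seq_len(n_reps), function(i) {
    sim <- run_preset(name, seed = seeds[i], scale = scale, cycles = cycles,
                      overrides = overrides)
    s <- equilibrium_summary(sim)
    data.frame(replicate = i, seed = seeds[i],
               germline = germline_type(sim, gap = gap),
               pz_1 = s$pz_1, pz_2 = s$pz_2, extinct = sim$extinct)
  })
  results <- do.call(rbind, rows)
  tally <- c(type_1 = sum(results$germline == 1L, na.rm = TRUE),
             type_2 = sum(results$germline == 2L, na.rm = TRUE),
             unclassified = sum(is.na(results$germline)))
  list(results = results, tally = tally)
}

#' Tiny deterministic populations for tests and examples
#'
#' @param kind One of `"symmetric_start"` (four identical ancestral
#'   individuals, zero damage), `"one_carrier"` (four individuals, one
#'   carrying a single deleterious allele at locus 7), or
#'   `"specialized_pair"` (hand-set genes: type 1 allocates essentially
#'   everything to reproduction, type 2 to foraging).
#' @param seed Unused for these fully deterministic fixtures, kept for
#'   interface stability.
#' @return A population snapshot data.frame with at most 10 rows.
#' @export
make_fixture <- function(kind = c("symmetric_start", "one_carrier",
                                  "specialized_pair"), seed = 1L) {
  kind <- match.arg(kind)
  base <- init_population(model_params(N = 4, cycles = 0))
  switch(kind,
    symmetric_start = base,
    one_carrier = {
      v <- rep(0L, 16); v[7] <- 1L
      base$viability_1[1] <- base$viability_2[1] <- paste(v, collapse = "")
      base
    },
    specialized_pair = {
      pop <- base[1:2, ]
      pop$x_1 <- -8; pop$y_1 <- -8    # type 1: p_z ~ 1
      pop$x_2 <- 8;  pop$y_2 <- -8    # type 2: p_x ~ 1
      pop$id <- 1:2
      pop
    })
}
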