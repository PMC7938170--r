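# Small parameter sets and deterministic populations shared across tests.

tiny_params <- function(...) {
  args <- list(N = 50, cycles = 20)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(model_params, args)
}

# parameters with every mutation channel silenced
quiet_params <- function(...) {
  tiny_params(mu = 0, mu_v0 = 0, mu_v1 = 0, mu_d = 0, ...)
}

# deathless world: no intrinsic or viability mortality, regeneration certain
immortal_params <- function(...) {
  quiet_params(D = 1e12, m2 = 0, r = 1, ...)
}
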