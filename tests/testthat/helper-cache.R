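# Default trial and the 24 formulation x criterion cycle solutions are
# computed once per test run and shared across test files.
.kneeload_cache <- new.env(parent = emptyenv())

cached_trial <- function() {
  if (is.null(.kneeload_cache$trial)) .kneeload_cache$trial <- gen_trial()
  .kneeload_cache$trial
}

cached_solutions <- function() {
  if (is.null(.kneeload_cache$solutions)) {
    trial <- cached_trial()
    props <- muscle_properties()
    sols <- list()
    for (f in c("RM", "RML", "RFML")) {
      sols[[f]] <- list()
      for (obj in objective_ids()) {
        sols[[f]][[obj]] <- solve_cycle(trial, formulation(f),
                                        objective_spec(obj), props)
      }
    }
    .kneeload_cache$solutions <- sols
  }
  .kneeload_cache$solutions
}

# per-frame right-hand sides of the RFML system (R, M), unscaled
cached_rhs <- function() {
  trial <- cached_trial()
  as.matrix(trial$loads[, c("Rx", "Ry", "Rz", "Mx", "My", "Mz")])
}
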