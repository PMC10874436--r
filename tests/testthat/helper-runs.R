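# Reference-parameter scenario runs are expensive, so they are computed
# lazily and shared across test files within a run.

.run_cache <- new.env(parent = emptyenv())

ref_run <- function(name) {
  if (!is.null(.run_cache[[name]])) return(.run_cache[[name]])
  plan <- switch(name,
    intact_heaviside = list(mode = "heaviside", scenario = "intact"),
    intact_hill = list(mode = "hill", scenario = "intact"),
    ant_p2_heaviside = list(mode = "heaviside", scenario = "anterior_half", offset = 2L),
    ant_m2_heaviside = list(mode = "heaviside", scenario = "anterior_half", offset = -2L),
    ant_p2_hill = list(mode = "hill", scenario = "anterior_half", offset = 2L),
    ant_m2_hill = list(mode = "hill", scenario = "anterior_half", offset = -2L),
    ant_p1_heaviside = list(mode = "heaviside", scenario = "anterior_half", offset = 1L),
    ant_m1_heaviside = list(mode = "heaviside", scenario = "anterior_half", offset = -1L),
    ant_0_heaviside = list(mode = "heaviside", scenario = "anterior_half", offset = 0L),
    stop("unknown reference run: ", name))
  params <- reference_params(production_mode = plan$mode)
  config <- if (plan$scenario == "intact") {
    scenario_config("intact")
  } else {
    scenario_config("anterior_half", obliquity_offset = plan$offset)
  }
  rec <- suppressWarnings(simulate_ring(config, params))
  assign(name, rec, envir = .run_cache)
  rec
}

# Side helpers: the right edge of the cut segment is the first stored cell,
# the left edge the last.
edge_committed <- function(rec) {
  A <- rec$final$A
  c(right = A[1] == 1L, left = A[length(A)] == 1L)
}
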