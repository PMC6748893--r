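# small meshes and cached coupled runs shared across tests

small_mesh <- function(dx = 2) build_mesh(channel_geometry(), dx, dx)

# the four canonical coupled runs at desk scale; computed once per session
acceptance_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(stats::setNames(nm = canonical_conditions()$condition),
                       function(cond) {
        simulate_clot_growth(simulation_config(cond, t_end = 450,
                                               snapshot_times = 400))
      })
    }
    cache
  }
})

shell_height_at_400 <- function(sim) {
  sn <- sim$snapshots[["400"]]
  extract_shell(sn$bound, sim$mesh,
                phi_max = sim$config$platelet$phi_max)$height
}
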