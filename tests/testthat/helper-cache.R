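# Shared fixtures, computed once per test run. HJB solves are the expensive
# part, so value functions are cached by (nx, D) and reused across files.
.hh_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .hh_cache)) assign(key, force(expr), envir = .hh_cache)
  get(key, envir = .hh_cache)
}

cached_orbit <- function() cached("orbit", find_period())
cached_fp <- function() cached("fp", find_fixed_point())

cached_vf <- function(nx, D, store_dt = 0.01) {
  cached(sprintf("vf_%d_%g", nx, D),
         solve_hjb(grid = grid_spec(nx = nx, ny = nx), D = D,
                   store_dt = store_dt))
}

# deterministic-trajectory waveform for a given (nx, D)
cached_waveform <- function(nx, D) {
  cached(sprintf("wave_%d_%g", nx, D), {
    strat <- if (D == 0) "deterministic-on-deterministic"
             else "stochastic-on-deterministic"
    control_waveform(hh_policy(cached_vf(nx, D), strat),
                     z0 = cached_orbit()$spike_point)
  })
}
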