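# Shared fixtures: tiny deterministic problems used across test files.

sphere3 <- function(x) sum(x^2)

sphere_space <- function() search_space(rep(-5.12, 3), rep(5.11, 3))

quick_control <- function(...) {
  args <- list(...)
  defaults <- list(n_particles = 24L, n_subpopulations = 4L,
                   iterations = 40L, seed = 42L)
  do.call(swarm_control, utils::modifyList(defaults, args))
}

# Small asymmetric phantom spec for fast end-to-end checks.
small_phantom_spec <- function(size = c(32L, 32L, 9L), noise_sd = 0,
                               seed = 7L) {
  phantom_spec(size = size, spacing = c(2.59, 2.59, 8.0),
               noise_sd = noise_sd, seed = seed)
}

# A smooth (non-constant-patch) volume for interpolation round trips.
smooth_volume <- function(dims = c(24L, 24L, 10L), spacing = c(2, 2, 5)) {
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                   k = seq_len(dims[3]))
  vals <- sin(g$i / 3) * cos(g$j / 4) + 0.5 * sin(g$k / 2)
  volume3d(array(vals, dims), spacing = spacing)
}
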