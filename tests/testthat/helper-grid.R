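# The default 2 x 4 x 200 simulation grid is used by several acceptance
# checks; compute it once per test run.
.grid_cache <- new.env(parent = emptyenv())

default_grid <- function() {
  if (is.null(.grid_cache$g))
    .grid_cache$g <- run_grid(grid_spec(master_seed = 1))
  .grid_cache$g
}

# pooled 99% binomial band for a mean final-bin count under chance,
# over n_runs runs of bin_size trials each
chance_band <- function(n_runs, bin_size = 10L) {
  stats::qbinom(c(0.005, 0.995), n_runs * bin_size, 0.5) / n_runs
}
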