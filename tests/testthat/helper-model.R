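# Shared fixtures: baseline parameter sets and a tiny fast configuration.

baseline_params <- function(n = 8, ...) gc_parameters(n = n, ...)

toy_params <- function(n = 2, ...) gc_parameters(n = n, ...)

# quick settings for toy integrations that do not need the full horizon
toy_settings <- function(t_max = 30, ...) solver_settings(t_max = t_max, ...)

# a seeded-but-inert configuration: no selection, B-cells only decay
no_selection_params <- function(n = 2) {
  gc_parameters(n = n, sigma = 0, sigma_c = 0)
}

# relative difference with a one-cell absolute floor, so that compartments
# that have collapsed to < 1 cell are compared absolutely
rel_diff <- function(a, b) max(abs(a - b) / pmax(abs(b), 1))

# match stored time points between two trajectories (6-decimal rounding)
common_times <- function(t1, t2) {
  intersect(round(t1, 6), round(t2, 6))
}
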