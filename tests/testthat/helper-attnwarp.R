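# Shared test helpers: independent oracles and small fixture builders.

# Brute-force circular distance: shortest arc by explicit enumeration of
# both directions (independent of angular_distance's modular arithmetic).
bf_angular_distance <- function(a, b) {
  min(abs(a - b + c(-360, 0, 360)))
}

# Monte Carlo oracle for the 2AFC observer: sample the internal
# representation and apply the nearest-option rule directly.
mc_choose_target <- function(delta, direction, bias, noise, n = 2e5) {
  x <- rnorm(n, bias, noise)  # away side is the positive axis
  foil <- if (direction == "away") delta else -delta
  mean(abs(x) < abs(x - foil))
}

# Uniform search-accuracy map covering every distance of an experiment.
flat_search_accuracy <- function(experiment, p = 1) {
  D <- unique(experiment_cells(experiment)$target_distractor_distance)
  setNames(rep(p, length(D)), D)
}

# Binomial cell summaries drawn directly from the closed-form model:
# fast surrogate for a full simulated design at large trial counts.
simulate_summaries <- function(cells, params, n_per_cell, model = "linear") {
  p <- p_choose_target(cells$foil_distance, cells$foil_direction, params,
                       model = model, D = cells$target_distractor_distance)
  data.frame(cells,
             n_trials = n_per_cell,
             n_target_chosen = rbinom(nrow(cells), n_per_cell, p))
}

# The E2 cell grid (away foils only), handy for fitting tests.
e2_cells <- function() {
  cells <- expand.grid(target_distractor_distance = c(30, 60, 180),
                       foil_distance = c(10, 20, 60, 180),
                       KEEP.OUT.ATTRS = FALSE)
  cells$foil_direction <- "away"
  cells
}
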