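# Shared test objects.

# Soft bending model: closure events are common even for short fragments,
# which keeps Monte Carlo comparisons cheap; estimator properties hold for
# any elastic model.
soft_fluct <- function() {
  fluctuation_model(sigma_tilt = 15, sigma_roll = 15, sigma_twist = 4.09)
}

# A frozen (zero-fluctuation) model: the sampler degenerates to the
# minimum-energy chain.
frozen_fluct <- function() {
  fluctuation_model(sigma_tilt = 0, sigma_roll = 0, sigma_twist = 0)
}

poly_a <- function(n) strrep("A", n)

# Rotation angle of a 3x3 rotation matrix, used as the axis-angle oracle.
rotation_angle <- function(R) acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
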