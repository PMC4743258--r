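test_that("closure flags follow the nested conditional structure", {
  cfg <- sampler_config()
  # straight 10-step arm, ~31 A long: misses the capture radius
  far <- build_chain(matrix(rep(c(0, 0, 0, 0, 0, 3.1), 10), 6, 10))
  expect_equal(evaluate_closure(far, cfg),
               tibble::tibble(r_hit = FALSE, gamma_hit = NA,
                              phi_hit = NA))
  # coincident frames: perfect closure
  near <- build_chain(matrix(0, 6, 1))
  expect_equal(evaluate_closure(near, cfg),
               tibble::tibble(r_hit = TRUE, gamma_hit = TRUE,
                              phi_hit = TRUE))
  # close ends but bent normals (roll 37 deg => cos(gamma) ~ 0.8)
  bent <- build_chain(matrix(c(0, 37, 0, 0, 0, 1), 6, 1))
  expect_equal(evaluate_closure(bent, cfg),
               tibble::tibble(r_hit = TRUE, gamma_hit = FALSE,
                              phi_hit = NA))
  # close and coplanar but torsionally misaligned (twist 60 deg)
  twisted <- build_chain(matrix(c(0, 0, 60, 0, 0, 1), 6, 1))
  expect_equal(evaluate_closure(twisted, cfg),
               tibble::tibble(r_hit = TRUE, gamma_hit = TRUE,
                              phi_hit = FALSE))
})

test_that("counts convert to J factors with the documented normalization", {
  cfg <- sampler_config()
  # floor rule
  fl <- j_from_counts(closure_counts(1e6, 10, 2, 0), cfg)
  expect_true(fl$floored)
  expect_equal(fl$j, 1e-15)
  # explicit three-factor product equals the telescoped implementation
  cts <- closure_counts(2e6, 800, 90, 12)
  v_cap <- 4 / 3 * pi * 30^3
  manual <- 4 * pi / 6.02214076e23 * 1e27 *
    ((800 / 2e6) / v_cap) *
    ((90 / 800) / (1 - 0.86)) *
    ((12 / 90) / (2 * acos(0.86)))
  expect_equal(j_from_counts(cts, cfg)$j, manual, tolerance = 1e-12)
  # doubling the trials with fixed hits halves J
  cts2 <- closure_counts(4e6, 800, 90, 12)
  expect_equal(j_from_counts(cts2, cfg)$j, manual / 2, tolerance = 1e-12)
  # impossible states
  expect_error(closure_counts(100, 5, 10, 2), "n_total >= n_r")
  expect_error(j_from_counts(closure_counts(100, 0, 0, 0) |>
                               (\(x) { x$n_phi <- 3; x })(), cfg),
               "impossible")
})

test_that("a frozen model reproduces the minimum-energy chain exactly", {
  prof <- equilibrium_profile("XXXXXZZZZZ", builtin_curved())
  ch0 <- build_chain(prof)
  ch1 <- sample_chain(prof, frozen_fluct(), seed = 1)
  expect_equal(ch1$origins, ch0$origins, tolerance = 1e-12)
  expect_equal(ch1$triads, ch0$triads, tolerance = 1e-12)
})

test_that("estimators are bit-reproducible under a fixed seed", {
  prof <- equilibrium_profile(poly_a(60), builtin_straight())
  cfg <- sampler_config(max_chains = 2e4, batch_size = 1e3)
  e1 <- estimate_j_naive(prof, soft_fluct(), cfg, seed = 42)
  e2 <- estimate_j_naive(prof, soft_fluct(), cfg, seed = 42)
  expect_identical(glance(e1), glance(e2))
  cfgh <- sampler_config(half_chains = 2000)
  h1 <- estimate_j_halfchain(prof, soft_fluct(), cfgh, seed = 42)
  h2 <- estimate_j_halfchain(prof, soft_fluct(), cfgh, seed = 42)
  expect_identical(glance(h1), glance(h2))
  expect_false(identical(glance(h1)$j_M, glance(e1)$j_M))
})

test_that("counts are monotone and respect threshold monotonicity", {
  prof <- equilibrium_profile(poly_a(60), builtin_straight())
  est <- estimate_j_naive(prof, soft_fluct(),
                          sampler_config(max_chains = 2e4,
                                         batch_size = 1e3), seed = 3)
  cts <- est$counts
  expect_true(cts$n_total >= cts$n_r)
  expect_true(cts$n_r >= cts$n_gamma)
  expect_true(cts$n_gamma >= cts$n_phi)

  # identical ensemble under different thresholds
  ens <- make_known_density_ensemble(2e4, box_side = 120, seed = 5)
  base <- closure_counts_from_ensemble(ens, sampler_config())
  wider <- closure_counts_from_ensemble(
    ens, sampler_config(capture_radius = 45))
  expect_gte(wider$n_r, base$n_r)
  stricter <- closure_counts_from_ensemble(
    ens, sampler_config(cos_gamma_min = 0.95, cos_phi_min = 0.95))
  expect_lte(stricter$n_gamma, base$n_gamma)
  expect_lte(stricter$n_phi, base$n_phi)
})

test_that("the pair prefilter is exact: grid on and off give equal counts", {
  prof <- equilibrium_profile(poly_a(60), builtin_straight())
  cfg <- sampler_config(half_chains = 500)
  on <- estimate_j_halfchain(prof, soft_fluct(), cfg, seed = 7,
                             use_grid = TRUE)
  off <- estimate_j_halfchain(prof, soft_fluct(), cfg, seed = 7,
                              use_grid = FALSE)
  expect_identical(glance(on), glance(off))
  expect_gt(on$counts$n_r, 0)  # the comparison is not vacuous
})

test_that("one half-chain pair degenerates to a single full chain", {
  prof <- equilibrium_profile(poly_a(20), builtin_straight())
  est <- estimate_j_halfchain(prof, soft_fluct(),
                              sampler_config(half_chains = 1), seed = 9)
  expect_equal(est$counts$n_total, 1)
  expect_equal(est$n_half, 1)
})

test_that("tangent correlations start at one and decay", {
  prof <- equilibrium_profile(poly_a(121), builtin_straight())
  tc <- tangent_correlation(prof, n_chains = 500, seed = 15)
  expect_equal(nrow(tc), 121)
  expect_equal(tc$correlation[1], 1)
  expect_lt(tc$correlation[120], 1)
  expect_gt(persistence_length(tc), 0)
})

test_that("tidy and glance expose the three closure factors", {
  prof <- equilibrium_profile(poly_a(40), builtin_straight())
  est <- estimate_j_halfchain(prof, soft_fluct(),
                              sampler_config(half_chains = 1500), seed = 8)
  td <- tidy(est)
  expect_equal(td$factor, c("W", "Gamma", "Phi"))
  expect_equal(td$hits, c(est$counts$n_r, est$counts$n_gamma,
                          est$counts$n_phi))
  gl <- glance(est)
  expect_equal(gl$j_M, est$j)
  expect_equal(gl$method, "halfchain")
})
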