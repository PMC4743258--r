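test_that("step energy is the harmonic quadratic form", {
  fl <- default_fluctuations()
  expect_equal(step_energy(rep(0, 6), fl), 0)
  # a one-sigma deviation costs exactly half a kT
  expect_equal(step_energy(c(0, 4.84, 0, 0, 0, 0), fl), 0.5)
  expect_equal(step_energy(c(0, 0, 4.09, 0, 0, 0), fl), 0.5)
  # deviations along frozen coordinates carry no energy
  expect_equal(step_energy(c(0, 0, 0, 1, 1, 1), fl), 0)
})

test_that("general matrix energies match a brute-force double loop", {
  set.seed(19)
  for (i in 1:5) {
    M <- matrix(rnorm(36), 6, 6)
    F6 <- crossprod(M)  # symmetric PSD
    fl <- fluctuation_model(beta_F = F6)
    d <- rnorm(6)
    brute <- 0
    for (a in 1:6) for (b in 1:6) brute <- brute + F6[a, b] * d[a] * d[b]
    expect_equal(step_energy(d, fl, units = "radians"), brute / 2,
                 tolerance = 1e-10)
  }
  expect_error(fluctuation_model(beta_F = matrix(rnorm(36), 6, 6)),
               "symmetric")
})

test_that("total energy is additive over steps", {
  fl <- default_fluctuations()
  devs <- matrix(0, 6, 7)
  expect_equal(total_energy(devs, fl), 0)
  devs[2, ] <- 4.84  # unit-sigma roll on every step
  expect_equal(total_energy(devs, fl), 0.5 * 7)
  a <- matrix(rnorm(12), 6, 2)
  b <- matrix(rnorm(18), 6, 3)
  expect_equal(total_energy(cbind(a, b), fl),
               total_energy(a, fl) + total_energy(b, fl))
  expect_error(total_energy(a, rep(list(fl), 5)), "5.*2")
})

test_that("Boltzmann weights factorize over independent energies", {
  expect_equal(boltzmann_weight(0), 1)
  expect_equal(boltzmann_weight(0.5), exp(-0.5))
  expect_equal(boltzmann_weight(1.3 + 0.4),
               boltzmann_weight(1.3) * boltzmann_weight(0.4))
  expect_error(boltzmann_weight(Inf), "finite")
})

test_that("principal axes diagonalize the force matrix", {
  # diagonal model: eigenvalues are the diagonal stiffnesses
  fl <- default_fluctuations()
  pa <- principal_axes(fl)
  sig_rad <- c(4.84, 4.84, 4.09) * pi / 180
  expect_equal(sort(pa$D, decreasing = TRUE)[1:3],
               sort(1 / sig_rad^2, decreasing = TRUE), tolerance = 1e-10)
  expect_equal(sum(pa$D == 0), 3)  # frozen displacements
  expect_equal(sort(pa$sampling_sd[pa$sampling_sd > 0]),
               sort(sig_rad), tolerance = 1e-12)

  # coupled 2x2 tilt-roll block [[2,1],[1,2]]: eigenvalues 3 and 1 on the
  # (1,1)/sqrt(2) and (1,-1)/sqrt(2) axes
  F6 <- matrix(0, 6, 6)
  F6[1:2, 1:2] <- matrix(c(2, 1, 1, 2), 2, 2)
  pa2 <- principal_axes(fluctuation_model(beta_F = F6))
  expect_equal(sort(pa2$D[pa2$D > 1e-10]), c(1, 3), tolerance = 1e-10)
  v3 <- pa2$axes[, which.max(pa2$D)]
  expect_equal(abs(v3[1:2]), rep(1 / sqrt(2), 2), tolerance = 1e-10)

  expect_error(principal_axes(fluctuation_model(beta_F = -diag(6))),
               "negative eigenvalue")
})

test_that("eigendecomposition reconstructs random PSD matrices", {
  set.seed(23)
  for (i in 1:5) {
    F6 <- crossprod(matrix(rnorm(36), 6, 6))
    fl <- fluctuation_model(beta_F = F6)
    pa <- principal_axes(fl)
    expect_lt(max(abs(pa$axes %*% diag(pa$D) %*% t(pa$axes) - F6)), 1e-10)
    # energy is invariant under rotation into principal axes
    d <- rnorm(6)
    om <- drop(t(pa$axes) %*% d)
    expect_equal(0.5 * sum(pa$D * om^2),
                 step_energy(d, fl, units = "radians"), tolerance = 1e-10)
  }
})

test_that("sampled deviations recover the model's moments", {
  set.seed(29)
  dev <- sample_step_deviations(default_fluctuations(), 3e4)
  se_mean <- 4.84 / sqrt(3e4)
  expect_lt(abs(mean(dev["roll", ])), 3 * se_mean)
  expect_lt(abs(sd(dev["roll", ]) - 4.84), 3 * 4.84 / sqrt(2 * 3e4))
  expect_true(all(dev[c("shift", "slide", "rise"), ] == 0))
})
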