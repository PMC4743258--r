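test_that("zero-angle steps translate along the normal without rotating", {
  st <- step_transform(c(tilt = 0, roll = 0, twist = 0,
                         shift = 0, slide = 0, rise = 3.40))
  expect_equal(st$rotation, diag(3), tolerance = 1e-12)
  expect_equal(st$translation, c(0, 0, 3.40), tolerance = 1e-12)
})

test_that("ten 36-degree twists compose to the identity", {
  st <- step_transform(step_parameters(twist = 36))
  R10 <- Reduce(`%*%`, rep(list(st$rotation), 10))
  expect_lt(max(abs(R10 - diag(3))), 1e-9)
})

test_that("a single nonzero angle rotates by exactly that angle", {
  for (step in list(c(roll = 7.41), c(tilt = 3.2), c(twist = 21))) {
    st <- step_transform(c(step, rise = 3.4))
    expect_equal(rotation_angle(st$rotation) * 180 / pi,
                 unname(step[1]), tolerance = 1e-9)
  }
  # pure roll rotates about the long (y) axis
  st <- step_transform(c(roll = 7.41, rise = 3.4))
  expect_equal(drop(st$rotation %*% c(0, 1, 0)), c(0, 1, 0),
               tolerance = 1e-12)
})

test_that("a step transform composed with its inverse is the identity", {
  set.seed(11)
  for (i in 1:5) {
    st <- step_transform(c(tilt = rnorm(1, 0, 5), roll = rnorm(1, 0, 5),
                           twist = runif(1, 30, 40), shift = rnorm(1),
                           slide = rnorm(1), rise = 3.4))
    Rinv <- t(st$rotation)
    tinv <- -drop(Rinv %*% st$translation)
    expect_lt(max(abs(st$rotation %*% Rinv - diag(3))), 1e-12)
    expect_lt(max(abs(drop(st$rotation %*% tinv) + st$translation)), 1e-12)
  }
})

test_that("pure-twist chains are collinear with end-to-end = sum of rises", {
  prof <- equilibrium_profile(poly_a(150), builtin_straight())
  ch <- build_chain(prof)
  expect_equal(ch$n, 150)
  expect_lt(max(abs(ch$origins[, 1:2])), 1e-9)
  g <- closure_geometry(ch)
  expect_equal(g$r, 149 * 3.40, tolerance = 1e-9)
  expect_equal(g$cos_gamma, 1, tolerance = 1e-12)
})

test_that("chain building is deterministic", {
  prof <- equilibrium_profile("XXXXXZZZZZXX", builtin_curved())
  c1 <- build_chain(prof)
  c2 <- build_chain(prof)
  expect_identical(c1$origins, c2$origins)
  expect_identical(c1$triads, c2$triads)
})

test_that("closure geometry is invariant under rigid motion of the chain", {
  set.seed(13)
  prof <- equilibrium_profile(random_sequence(40),
                              make_synthetic_parameter_set(2, seed = 3))
  ch <- build_chain(prof)
  g0 <- closure_geometry(ch)
  # random rigid motion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] + q[1] * q[4]),
                2 * (q[2] * q[4] - q[1] * q[3]),
                2 * (q[2] * q[3] - q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
                2 * (q[3] * q[4] + q[1] * q[2]),
                2 * (q[2] * q[4] + q[1] * q[3]),
                2 * (q[3] * q[4] - q[1] * q[2]),
                1 - 2 * (q[2]^2 + q[3]^2)), 3, 3)
  shift <- c(10, -20, 5)
  ch2 <- ch
  ch2$origins <- t(R %*% t(ch$origins) + shift)
  for (k in seq_len(ch$n)) ch2$triads[, , k] <- R %*% ch$triads[, , k]
  g1 <- closure_geometry(ch2)
  expect_equal(g1$r, g0$r, tolerance = 1e-9)
  expect_equal(g1$cos_gamma, g0$cos_gamma, tolerance = 1e-9)
  expect_equal(g1$phi, g0$phi, tolerance = 1e-9)
})

test_that("degenerate and half-turn closures give the textbook angles", {
  # coincident identical frames: one step with all-zero parameters
  ch <- build_chain(matrix(0, 6, 1))
  g <- closure_geometry(ch)
  expect_equal(g$r, 0)
  expect_equal(g$cos_gamma, 1)
  expect_equal(g$phi, 0)
  # frame 2 = frame 1 rotated half a turn about the shared normal
  ch <- build_chain(matrix(c(0, 0, 180, 0, 0, 1), 6, 1))
  g <- closure_geometry(ch)
  expect_equal(g$cos_gamma, 1, tolerance = 1e-12)
  expect_equal(abs(g$phi), pi, tolerance = 1e-9)
})

test_that("compiled closure stats agree with a plain-R computation", {
  set.seed(17)
  n <- 50
  q <- matrix(rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  R9 <- t(apply(q, 1, function(p) {
    w <- p[1]; x <- p[2]; y <- p[3]; z <- p[4]
    c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
      2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
      2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
  }))
  o3 <- matrix(rnorm(3 * n, sd = 20), n, 3)
  stats <- dnacyc:::cpp_closure_stats(R9, o3)
  for (i in seq_len(n)) {
    Q <- matrix(R9[i, ], 3, 3)
    expect_equal(stats[i, 1], sqrt(sum(o3[i, ]^2)), tolerance = 1e-12)
    expect_equal(stats[i, 2], Q[3, 3], tolerance = 1e-12)
    # independent phi computation: project short axes on the mean normal
    nav <- c(0, 0, 1) + Q[, 3]
    nav <- nav / sqrt(sum(nav^2))
    pr <- function(v) v - sum(v * nav) * nav
    a <- pr(c(1, 0, 0)); b <- pr(Q[, 1])
    cosphi <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    expect_equal(cos(stats[i, 3]), cosphi, tolerance = 1e-9)
  }
})

test_that("chain traces can be exported and tidied", {
  ch <- build_chain(equilibrium_profile("XXZZX", builtin_curved()))
  td <- tidy(ch)
  expect_equal(nrow(td), 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_chain_trace(ch, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$x, td$x)
  expect_equal(unname(as.matrix(back[3, paste0("t", rep(1:3, 3),
                                               rep(1:3, each = 3))])),
               matrix(as.numeric(ch$triads[, , 3]), 1, 9))
})
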