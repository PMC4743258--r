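test_that("loading fills absent columns and cells with defaults", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("context,roll", "AAA,5.0"), f)
  ps <- load_parameter_set(f, name = "one", context_width = 3)
  prof <- equilibrium_profile("AAAAA", ps)
  mid <- prof[prof$context %in% "AAA", ]
  expect_equal(mid$roll[1], 5.0)
  expect_equal(mid$twist[1], 34.30)
  expect_equal(mid$rise[1], 3.40)
  expect_equal(mid$tilt[1], 0)
})

test_that("load errors name the offending row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("context,roll", "AA,1.0", "CC,2.0"), f)
  expect_error(load_parameter_set(f, context_width = 3), "row 1.*width")

  writeLines(c("context,roll", "AB,1.0"), f)
  expect_error(load_parameter_set(f, context_width = 2), "alphabet")

  writeLines(c("context,roll", "AA,1.0", "AA,2.0"), f)
  expect_error(load_parameter_set(f, context_width = 2), "duplicate")

  writeLines(c("context,roll", "AA,x"), f)
  expect_error(load_parameter_set(f, context_width = 2), "non-numeric")
})

test_that("a roll-only trinucleotide table keeps default twist and rise", {
  set.seed(41)
  tab <- tibble::tibble(
    context = c("AAA", "ACA", "GGG", "TTT"),
    roll = runif(4, -8, 8))
  ps <- parameter_set(tab, context_width = 3, name = "roll-only")
  prof <- equilibrium_profile(random_sequence(60), ps)
  expect_true(all(prof$twist == 34.30))
  expect_true(all(prof$rise == 3.40))
  expect_true(all(prof$tilt == 0))
})

test_that("the straight model is sequence independent with zero bend", {
  ps <- builtin_straight()
  prof <- equilibrium_profile("ACGT", ps)
  expect_equal(nrow(prof), 3)
  expect_equal(nrow(dplyr::distinct(prof[, c("tilt", "roll", "twist",
                                             "shift", "slide", "rise")])), 1)
  expect_equal(prof$twist[1], 34.28)
  expect_equal(prof$rise[1], 3.40)
  expect_equal(sum(prof$tilt^2 + prof$roll^2), 0)
})

test_that("the curved model has the published X/Z dinucleotide values", {
  ps <- builtin_curved()
  prof <- equilibrium_profile("XZZX", ps)
  # steps XZ, ZZ, ZX
  expect_equal(prof$twist, c(36.00, 35.57, 35.57))
  expect_equal(prof$roll, c(0, 7.41, 7.41))
  expect_equal(prof$tilt, c(0, 0, 0))
  expect_error(equilibrium_profile("AA", ps), "alphabet")
})

test_that("profile windows are centred on the step and end windows default", {
  tab <- tibble::tibble(context = "AAA", roll = 9.0)
  ps <- parameter_set(tab, context_width = 3)
  prof <- equilibrium_profile("AAAA", ps)
  # step 1's window (bases 0..2) overruns the 5' end; steps 2 and 3 cover
  # bases 1..3 and 2..4, both reading AAA
  expect_true(is.na(prof$context[1]))
  expect_equal(prof$roll, c(0, 9, 9))
  # circular mode wraps instead
  profc <- equilibrium_profile("AAAA", ps, circular = TRUE)
  expect_equal(profc$roll, c(9, 9, 9))
})

test_that("profile length is sequence length minus one for all widths", {
  set.seed(7)
  for (w in c(2, 3, 5)) {
    ps <- make_synthetic_parameter_set(w, seed = w)
    for (n in c(max(2, w), 10, 37)) {
      s <- random_sequence(n)
      expect_equal(nrow(equilibrium_profile(s, ps)), n - 1)
    }
  }
})

test_that("full-coverage tables leave no interior step at defaults", {
  ps <- make_synthetic_parameter_set(3, seed = 5)
  prof <- equilibrium_profile(random_sequence(40), ps)
  interior <- prof[!is.na(prof$context), ]
  # synthetic twists are continuous on 30-40, so exact 34.30 marks a default
  expect_true(all(interior$twist != 34.30))
  # width-3 windows (bases k-1..k+1) only overrun at the 5' end (step 1);
  # a width-5 window also overruns at steps 2 and S
  expect_equal(which(is.na(prof$context)), 1L)
  prof5 <- equilibrium_profile(random_sequence(40),
                               make_synthetic_parameter_set(5, seed = 6))
  expect_equal(which(is.na(prof5$context)), c(1L, 2L, 39L))
})

test_that("invalid characters are reported with their position", {
  expect_error(equilibrium_profile("ACGNACG", builtin_straight()),
               "'N' at position 4")
})

test_that("missing dinucleotides resolve by reverse-complement symmetry", {
  tab <- tibble::tibble(context = "AA", tilt = 2.0, roll = 3.0,
                        twist = 35.0, shift = 0.5)
  ps <- parameter_set(tab, context_width = 2)
  prof <- equilibrium_profile("TT", ps)  # complement strand of AA
  expect_equal(prof$tilt, -2.0)
  expect_equal(prof$shift, -0.5)
  expect_equal(prof$roll, 3.0)
  expect_equal(prof$twist, 35.0)
})

test_that("write/load round trip reproduces the effective table", {
  ps <- make_synthetic_parameter_set(2, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_parameter_set(ps, f)
  ps2 <- load_parameter_set(f, name = ps$name, context_width = 2)
  s <- random_sequence(30)
  expect_equal(equilibrium_profile(s, ps2), equilibrium_profile(s, ps))
})
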