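# Seeded synthetic-data generators: parameter tables, pseudo-experimental
# benchmarks, and a known-density frame ensemble whose closure factors are
# analytically known.  Everything here is synthetic test scaffolding, not
# derived from measured DNA data.

#' Synthetic full-coverage parameter set
#'
#' Draws one row per context k-mer with twist uniform in 30-40 degrees and
#' roll/tilt uniform in -8 to 8 degrees; displacements stay at the
#' defaults.  Serializes and round-trips exactly through
#' [write_parameter_set()] / [load_parameter_set()].
#'
#' @param context_width 2, 3 or 5 (16, 64 or 1024 contexts).
#' @param seed Integer seed.
#' @param name Label for the set.
#' @return A [parameter_set()] covering every context.
#' @export
make_synthetic_parameter_set <- function(context_width, seed = 1,
                                         name = sprintf("synthetic%d",
                                                         context_width)) {
  stopifnot(context_width %in% c(2, 3, 5))
  bases <- c("A", "C", "G", "T")
  ctx <- do.call(paste0, rev(expand.grid(
    rep(list(bases), context_width), stringsAsFactors = FALSE)))
  withr::with_seed(as.integer(seed), {
    n <- length(ctx)
    tab <- tibble::tibble(
      context = sort(ctx),
      tilt = round(stats::runif(n, -8, 8), 3),
      roll = round(stats::runif(n, -8, 8), 3),
      twist = round(stats::runif(n, 30, 40), 3))
    parameter_set(tab, context_width = context_width, name = name)
  })
}

#' Synthetic benchmark with pseudo-experimental J factors
#'
#' Random uniform-base sequences whose "experimental" J factor is the
#' straight-model J at the sequence's length perturbed by lognormal noise:
#' `J_exp = J_straight(L) * 10^(noise * z)` with z standard normal.  The
#' generating z is kept in the `z_noise` column for recovery tests.
#'
#' @param n Number of records.
#' @param lengths Lengths (bp) to draw from (uniformly).
#' @param baseline Tibble with `length` and `j_M`: the straight-model J at
#'   every value of `lengths` (see [j_length_scan()]).
#' @param noise Lognormal sigma in log10 units (default 0.5).
#' @param seed Integer seed.
#' @return Benchmark tibble (`sequence_id`, `sequence`, `length`,
#'   `j_experimental_M`, `z_noise`) in the [read_benchmark()] schema.
#' @export
make_synthetic_benchmark <- function(n, lengths, baseline, noise = 0.5,
                                     seed = 1) {
  stopifnot(n >= 1)
  miss <- setdiff(lengths, baseline$length)
  if (length(miss) > 0) {
    rlang::abort(sprintf("baseline missing length(s): %s",
                         paste(miss, collapse = ", ")))
  }
  withr::with_seed(as.integer(seed), {
    L <- sample(rep(lengths, length.out = max(n, length(lengths))), n)
    z <- stats::rnorm(n)
    seqs <- vapply(L, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
            collapse = "")
    }, character(1))
    j0 <- baseline$j_M[match(L, baseline$length)]
    tibble::tibble(
      sequence_id = sprintf("syn_%03d_%dbp", seq_len(n), L),
      sequence = seqs,
      length = as.integer(L),
      j_experimental_M = j0 * 10^(noise * z),
      z_noise = z)
  })
}

#' Frame ensemble with uniform end density and isotropic orientations
#'
#' End frames whose origins are uniform in a cube of edge `box_side`
#' (centred on the start frame) and whose orientations are uniform random
#' rotations.  All three closure factors are then known in closed form:
#' the capture probability is V_cap/V_box, cos(gamma) is uniform on
#' [-1, 1] (density 1/2), and the residual twist is uniform on (-pi, pi]
#' (density 1/(2 pi)), so the implied J factor is exactly the molar
#' concentration of one end in the box, `1e27 / (N_A * V_box)`.  Used to
#' pin the J normalization.
#'
#' @param n Number of end frames.
#' @param box_side Cube edge in Angstrom (much larger than the capture
#'   radius).
#' @param seed Integer seed.
#' @return List of class `frame_ensemble` with `origins` (n x 3),
#'   `triads` (n x 9, column-major rows) and `box_side`.
#' @export
make_known_density_ensemble <- function(n, box_side = 150, seed = 1) {
  withr::with_seed(as.integer(seed), {
    o <- matrix(stats::runif(3 * n, -box_side / 2, box_side / 2), n, 3)
    # uniform rotations from normalized quaternions
    q <- matrix(stats::rnorm(4 * n), n, 4)
    q <- q / sqrt(rowSums(q^2))
    w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
    R <- cbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),
               2 * (x * z - w * y),
               2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),
               2 * (y * z + w * x),
               2 * (x * z + w * y), 2 * (y * z - w * x),
               1 - 2 * (x^2 + y^2))
    structure(list(origins = o, triads = R, box_side = box_side),
              class = "frame_ensemble")
  })
}

#' Closure tallies of a frame ensemble
#'
#' Applies the nested closure thresholds to each end frame of an ensemble
#' (relative to the canonical start frame) and tallies the counts.
#'
#' @param ensemble A [make_known_density_ensemble()] result (or any list
#'   with `origins` and `triads` in the same layout).
#' @param cfg A [sampler_config()].
#' @return A [closure_counts()].
#' @export
closure_counts_from_ensemble <- function(ensemble, cfg = sampler_config()) {
  stats <- cpp_closure_stats(ensemble$triads, ensemble$origins)
  r_hit <- stats[, 1] < cfg$capture_radius
  g_hit <- r_hit & !is.na(stats[, 2]) & stats[, 2] > cfg$cos_gamma_min
  p_hit <- g_hit & !is.na(stats[, 3]) &
    cos(stats[, 3]) > cfg$cos_phi_min
  closure_counts(nrow(stats), sum(r_hit), sum(g_hit), sum(p_hit))
}
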