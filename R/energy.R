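# Harmonic step energies, Boltzmann weights, and the principal-axis
# decomposition of the elastic force matrix used by the sampler.

#' Elastic fluctuation model for one base-pair step
#'
#' Either a diagonal shorthand of root-mean-square fluctuations per
#' coordinate, or a full symmetric 6x6 elastic force matrix normalized to
#' the thermal energy (beta F).  In the matrix, the quadratic form is over
#' deviations in radians (angles) and Angstrom (displacements); a diagonal
#' shorthand sigma_i corresponds to f_ii = 1/sigma_i^2 with sigma converted
#' to radians.  A sigma of zero freezes that coordinate at its equilibrium
#' value, represented in the matrix by a zero row/column (the zero acts as
#' a frozen-coordinate sentinel; physically the stiffness is infinite).
#'
#' The package default mirrors the isotropic-bending model used throughout
#' the simulations: RMS tilt and roll fluctuations of 4.84 degrees (a
#' persistence length of about 147 bp), RMS twist fluctuation of 4.09
#' degrees, and frozen displacements.
#'
#' @param sigma_tilt,sigma_roll,sigma_twist RMS angular fluctuations in
#'   degrees (0 = frozen).
#' @param sigma_shift,sigma_slide,sigma_rise RMS displacement fluctuations
#'   in Angstrom (0 = frozen).
#' @param beta_F Alternatively, a symmetric positive-semidefinite 6x6
#'   matrix of elastic moduli over (radian, Angstrom) deviations;
#'   overrides the sigma arguments when given.
#' @return An object of class `fluctuation_model` with elements `sigma`
#'   (degrees/Angstrom, or `NA` when constructed from a general matrix) and
#'   `beta_F`.
#' @examples
#' default_fluctuations()
#' fluctuation_model(sigma_tilt = 15, sigma_roll = 15, sigma_twist = 4.09)
#' @export
fluctuation_model <- function(sigma_tilt = 4.84, sigma_roll = 4.84,
                              sigma_twist = 4.09, sigma_shift = 0,
                              sigma_slide = 0, sigma_rise = 0,
                              beta_F = NULL) {
  if (is.null(beta_F)) {
    sigma <- c(tilt = sigma_tilt, roll = sigma_roll, twist = sigma_twist,
               shift = sigma_shift, slide = sigma_slide, rise = sigma_rise)
    if (any(!is.finite(sigma)) || any(sigma < 0)) {
      rlang::abort("sigma values must be finite and non-negative")
    }
    s_int <- sigma
    s_int[ANGLE_FIELDS] <- s_int[ANGLE_FIELDS] * pi / 180
    f <- ifelse(s_int > 0, 1 / s_int^2, 0)
    beta_F <- diag(f)
    dimnames(beta_F) <- list(STEP_FIELDS, STEP_FIELDS)
  } else {
    beta_F <- as.matrix(beta_F)
    if (!all(dim(beta_F) == c(6, 6))) {
      rlang::abort("beta_F must be a 6x6 matrix")
    }
    if (max(abs(beta_F - t(beta_F))) > 1e-8 * max(1, max(abs(beta_F)))) {
      rlang::abort("beta_F must be symmetric")
    }
    beta_F <- (beta_F + t(beta_F)) / 2
    dimnames(beta_F) <- list(STEP_FIELDS, STEP_FIELDS)
    dg <- diag(beta_F)
    sigma <- rep(NA_real_, 6)
    names(sigma) <- STEP_FIELDS
    if (max(abs(beta_F - diag(dg))) < 1e-12) {
      sigma <- ifelse(dg > 0, 1 / sqrt(dg), 0)
      sigma[ANGLE_FIELDS] <- sigma[ANGLE_FIELDS] * 180 / pi
      names(sigma) <- STEP_FIELDS
    }
  }
  structure(list(sigma = sigma, beta_F = beta_F),
            class = "fluctuation_model")
}

#' @rdname fluctuation_model
#' @export
default_fluctuations <- function() fluctuation_model()

#' @export
print.fluctuation_model <- function(x, ...) {
  if (!anyNA(x$sigma)) {
    cat("<fluctuation_model> diagonal, RMS:",
        paste(sprintf("%s=%.3g", STEP_FIELDS, x$sigma), collapse = " "),
        "\n  (angles in degrees, displacements in Angstrom; 0 = frozen)\n")
  } else {
    cat("<fluctuation_model> general symmetric beta*F (radians/Angstrom)\n")
    print(signif(x$beta_F, 4))
  }
  invisible(x)
}

as_dev_vector <- function(dev, units) {
  if (is.data.frame(dev)) dev <- unlist(dev[1, ])
  if (!is.null(names(dev)) && all(STEP_FIELDS %in% names(dev))) {
    dev <- dev[STEP_FIELDS]
  }
  if (length(dev) != 6) rlang::abort("deviation must have 6 entries")
  dev <- unname(as.numeric(dev))
  if (units == "degrees") dev[1:3] <- dev[1:3] * pi / 180
  dev
}

#' Harmonic energy of one base-pair step
#'
#' The quadratic form (1/2) sum_ij f_ij dtheta_i dtheta_j over the
#' deviations of the six step parameters from their equilibrium values, in
#' units of kT.  Zero deviation gives zero energy.  Deviations along frozen
#' coordinates (sigma = 0) contribute nothing: the sampler never displaces
#' them, and the zero row in `beta_F` encodes the frozen constraint rather
#' than a vanishing stiffness.
#'
#' @param dev Deviation vector (length 6, ordered tilt, roll, twist, shift,
#'   slide, rise, or named); angles in the units given by `units`.
#' @param fluct A [fluctuation_model()].
#' @param units Units of the angular entries of `dev` (default degrees, to
#'   match the rest of the interface).
#' @return Energy in kT (dimensionless, non-negative).
#' @examples
#' step_energy(c(0, 4.84, 0, 0, 0, 0), default_fluctuations())  # 0.5 kT
#' @export
step_energy <- function(dev, fluct, units = c("degrees", "radians")) {
  units <- match.arg(units)
  stopifnot(inherits(fluct, "fluctuation_model"))
  d <- as_dev_vector(dev, units)
  as.numeric(0.5 * crossprod(d, fluct$beta_F %*% d))
}

#' Total harmonic energy of a chain configuration
#'
#' Sum of [step_energy()] over all steps; additive and order-independent.
#'
#' @param devs A 6 x S matrix of per-step deviations (or a data frame with
#'   the six parameter columns, one row per step).
#' @param fluct A single [fluctuation_model()] applied to every step, or a
#'   list of per-step models (same length as the number of steps).
#' @inheritParams step_energy
#' @return Total energy in kT.
#' @export
total_energy <- function(devs, fluct, units = c("degrees", "radians")) {
  units <- match.arg(units)
  if (is.data.frame(devs)) devs <- t(as.matrix(devs[, STEP_FIELDS]))
  stopifnot(is.matrix(devs), nrow(devs) == 6)
  S <- ncol(devs)
  flucts <- if (inherits(fluct, "fluctuation_model")) {
    rep(list(fluct), S)
  } else {
    fluct
  }
  if (length(flucts) != S) {
    rlang::abort(sprintf("got %d fluctuation models for %d steps",
                         length(flucts), S))
  }
  sum(vapply(seq_len(S), function(k) {
    step_energy(devs[, k], flucts[[k]], units = units)
  }, numeric(1)))
}

#' Boltzmann weight of a configuration energy
#'
#' `exp(-E/kT)` for an energy already expressed in kT; the relative
#' probability of the configuration.  Factorizes over independent steps:
#' `boltzmann_weight(a + b) == boltzmann_weight(a) * boltzmann_weight(b)`.
#'
#' @param energy_kT Energy in units of kT (finite).
#' @return Dimensionless relative probability.
#' @export
boltzmann_weight <- function(energy_kT) {
  if (any(!is.finite(energy_kT))) rlang::abort("energy must be finite")
  exp(-energy_kT)
}

#' Principal axes of deformation of the elastic model
#'
#' Eigendecomposition of the symmetric force matrix beta F: the energy
#' rewritten as (1/2) sum_i D_ii omega_i^2 over normal coordinates omega
#' along orthonormal axes.  Sampling standard deviations along axis i are
#' 1/sqrt(D_ii); zero eigenvalues mark frozen directions (sampling sd 0),
#' matching the frozen-coordinate sentinel of [fluctuation_model()].
#'
#' @param fluct A [fluctuation_model()].
#' @param tol Eigenvalues below `-tol` are a (non-physical) error;
#'   magnitudes below `tol` are treated as frozen.
#' @return List of class `principal_axes` with `D` (eigenvalues, descending),
#'   `axes` (6x6 orthonormal, columns = axes), and `sampling_sd`
#'   (radians/Angstrom along each axis).
#' @export
principal_axes <- function(fluct, tol = 1e-10) {
  stopifnot(inherits(fluct, "fluctuation_model"))
  e <- eigen(fluct$beta_F, symmetric = TRUE)
  if (any(e$values < -tol)) {
    rlang::abort(sprintf(
      "beta_F has negative eigenvalue %.3g: non-physical stiffness",
      min(e$values)))
  }
  D <- pmax(e$values, 0)
  structure(list(D = D, axes = e$vectors,
                 sampling_sd = ifelse(D > tol, 1 / sqrt(D), 0)),
            class = "principal_axes")
}

# 6x6 matrix A such that dev = A %*% z (z iid standard normal) draws step
# deviations (radians/Angstrom) from the model's thermal distribution;
# frozen directions get exactly zero.
sampling_matrix <- function(fluct) {
  pa <- principal_axes(fluct)
  A <- pa$axes %*% diag(pa$sampling_sd)
  dimnames(A) <- list(STEP_FIELDS, NULL)
  A
}

#' Draw thermal step deviations from the fluctuation model
#'
#' Samples deviations of the six step parameters from the product of
#' independent normals along the principal axes of deformation (frozen
#' directions stay exactly zero).  Uses the current R random stream.
#'
#' @param fluct A [fluctuation_model()].
#' @param n Number of draws.
#' @param units Units for the returned angular rows.
#' @return A 6 x `n` matrix of deviations (rows named by parameter).
#' @export
sample_step_deviations <- function(fluct, n,
                                   units = c("degrees", "radians")) {
  units <- match.arg(units)
  A <- sampling_matrix(fluct)
  z <- matrix(stats::rnorm(6 * n), 6, n)
  dev <- A %*% z
  if (units == "degrees") dev[1:3, ] <- dev[1:3, ] * 180 / pi
  rownames(dev) <- STEP_FIELDS
  dev
}
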