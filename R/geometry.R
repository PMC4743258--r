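# Rigid-body frame algebra: step parameters -> frames -> chains -> closure
# geometry.  A chain is a list of base-pair frames, each an origin (Angstrom)
# plus an orthonormal triad whose columns are the short axis, long axis and
# normal of the base pair.

#' Rigid transform of one base-pair step
#'
#' Converts six step parameters into the rotation and translation relating
#' consecutive base-pair frames.  Tilt and roll combine into a single bend
#' about an in-plane axis whose phase is set by the twist; the twist is
#' applied symmetrically about the mid-step normal and the displacements are
#' expressed in the mid-step triad (the standard mid-step rebuild algebra
#' for these six coordinates).  A pure-twist step rotates about the frame
#' normal and translates by (0, 0, rise).
#'
#' @param step Named numeric vector (or one-row data frame) with `tilt`,
#'   `roll`, `twist` in degrees and `shift`, `slide`, `rise` in Angstrom;
#'   missing fields take [step_defaults()] of zero angles (but a `rise` must
#'   be supplied via the vector or defaults).
#' @return List with `rotation` (3x3 orthonormal, det +1) and `translation`
#'   (length-3, Angstrom).
#' @examples
#' step_transform(step_parameters(twist = 36))$rotation
#' @export
step_transform <- function(step) {
  if (is.data.frame(step)) step <- unlist(step[1, STEP_FIELDS])
  full <- step_defaults()
  full[] <- 0
  full["rise"] <- 3.40
  full[names(step)[names(step) %in% STEP_FIELDS]] <-
    step[names(step) %in% STEP_FIELDS]
  th <- full
  th[ANGLE_FIELDS] <- th[ANGLE_FIELDS] * pi / 180
  cpp_step_rt(unname(th))
}

new_dna_chain <- function(origins, triads) {
  structure(list(origins = origins, triads = triads, n = nrow(origins)),
            class = "dna_chain")
}

#' Build a chain of base-pair frames from a step-parameter profile
#'
#' Frame 1 is the canonical frame at the origin; each subsequent frame is
#' the previous frame composed with that step's rigid transform.  A profile
#' of S steps yields S + 1 frames.
#'
#' @param profile Output of [equilibrium_profile()] (or any data frame with
#'   the six parameter columns, angles in degrees), or a 6 x S numeric
#'   matrix in the same units.
#' @return An object of class `dna_chain` with `origins` (N x 3 matrix,
#'   Angstrom) and `triads` (3 x 3 x N array).
#' @examples
#' ch <- build_chain(equilibrium_profile("XXXXXZZZZZ", builtin_curved()))
#' closure_geometry(ch)
#' @export
build_chain <- function(profile) {
  theta <- profile_matrix(profile)
  res <- cpp_build_chain(theta)
  new_dna_chain(res$origins, res$triads)
}

#' @export
print.dna_chain <- function(x, ...) {
  geom <- closure_geometry(x)
  cat(sprintf(
    "<dna_chain>  %d base pairs; end-to-end %.1f A, cos(gamma) %.3f\n",
    x$n, geom$r, geom$cos_gamma))
  invisible(x)
}

#' Closure geometry of a chain
#'
#' Measures the three quantities thresholded by the ring-closure test:
#' end-to-end distance `r`, the cosine of the net bending angle between the
#' terminal base-pair normals, and the residual twist `phi` (the rotation
#' about the mean terminal normal carrying the first short axis onto the
#' last; well defined whenever the normals are not antiparallel, `NA`
#' otherwise).  All quantities are computed relative to the first frame, so
#' they are invariant under rigid motion of the whole chain.
#'
#' @param chain A `dna_chain`.
#' @return One-row tibble with `r` (Angstrom), `cos_gamma`, and `phi`
#'   (radians, in (-pi, pi]).
#' @export
closure_geometry <- function(chain) {
  stopifnot(inherits(chain, "dna_chain"), chain$n >= 2)
  T1 <- chain$triads[, , 1]
  TN <- chain$triads[, , chain$n]
  o <- drop(crossprod(T1, chain$origins[chain$n, ] - chain$origins[1, ]))
  Q <- crossprod(T1, TN)
  stats <- cpp_closure_stats(matrix(as.numeric(Q), 1, 9),
                             matrix(o, 1, 3))
  tibble::tibble(r = stats[1, 1], cos_gamma = stats[1, 2], phi = stats[1, 3])
}

#' @rdname closure_geometry
#' @param x A `dna_chain`.
#' @param ... Unused.
#' @export
tidy.dna_chain <- function(x, ...) {
  o <- x$origins
  tibble::tibble(frame = seq_len(x$n),
                 x = o[, 1], y = o[, 2], z = o[, 3])
}

#' Export a chain as a delimited text trace
#'
#' One row per base pair: frame index, origin coordinates, and the nine
#' triad entries (column-major), suitable for external visualization.
#'
#' @param chain A `dna_chain`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_chain_trace <- function(chain, path) {
  stopifnot(inherits(chain, "dna_chain"))
  tri <- apply(chain$triads, 3, as.numeric)
  tab <- tibble::as_tibble(t(tri), .name_repair = "minimal")
  names(tab) <- paste0("t", rep(1:3, 3), rep(1:3, each = 3))
  out <- dplyr::bind_cols(tidy(chain), tab)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
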