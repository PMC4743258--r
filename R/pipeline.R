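# Batch analyses: J factors across parameter sets, concordance with
# experimental measurements, random-sequence surveys and the
# straight-baseline comparison.

#' Read and write sequence collections as FASTA
#'
#' Sequences travel as tibbles with columns `sequence_id`, `sequence` and
#' `length`; on disk they are plain multi-record FASTA (read and written
#' with Biostrings, uppercase-normalized; arbitrary alphabets such as the
#' curved model's X/Z are allowed).
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a tibble; `write_fasta()`: `path`, invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- unname(toupper(as.character(ss)))
  tibble::tibble(sequence_id = names(ss), sequence = seqs,
                 length = nchar(seqs))
}

#' @rdname read_fasta
#' @param sequences Tibble with `sequence_id` and `sequence` columns.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::BStringSet(toupper(sequences$sequence))
  names(ss) <- sequences$sequence_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read and write an experimental J-factor benchmark table
#'
#' Tab-separated schema: `sequence_id`, `sequence`, `j_experimental_M`
#' (mol/L, positive) and an optional `source_ref`.  A `length` column is
#' derived from the sequence on read and checked for consistency if
#' present.
#'
#' @param path TSV file path.
#' @return `read_benchmark()`: a tibble with one row per sequence.
#' @export
read_benchmark <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sequence_id", "sequence", "j_experimental_M")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    rlang::abort(sprintf("benchmark table lacks column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  tab$sequence <- toupper(tab$sequence)
  if ("length" %in% names(tab) &&
      any(tab$length != nchar(tab$sequence))) {
    rlang::abort("benchmark 'length' column disagrees with sequences")
  }
  tab$length <- nchar(tab$sequence)
  if (any(!is.finite(tab$j_experimental_M) | tab$j_experimental_M <= 0)) {
    rlang::abort("experimental J factors must be positive")
  }
  tab
}

#' @rdname read_benchmark
#' @param records Benchmark tibble.
#' @export
write_benchmark <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Generate random DNA sequences with equal base probabilities
#'
#' Draws i.i.d. uniform A/C/G/T sequences, `n_per_length` for each
#' requested length, deterministically under the seed.
#'
#' @param n_per_length Sequences per length.
#' @param lengths Vector of sequence lengths (bp).
#' @param seed Integer seed.
#' @return Tibble with `sequence_id` (`L<length>_<index>`), `length`,
#'   `sequence`.
#' @examples
#' generate_random_sequences(3, c(100, 150), seed = 1)
#' @export
generate_random_sequences <- function(n_per_length, lengths, seed = 1) {
  stopifnot(all(lengths >= 1), n_per_length >= 1)
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(lengths, function(L) {
      m <- matrix(sample(c("A", "C", "G", "T"), n_per_length * L,
                         replace = TRUE), nrow = n_per_length)
      tibble::tibble(
        sequence_id = sprintf("L%04d_%04d", L, seq_len(n_per_length)),
        length = as.integer(L),
        sequence = apply(m, 1, paste, collapse = ""))
    })
  })
}

# Deterministic, order-independent sub-seed for one benchmark cell: hash of
# the effective step parameters, set label and master seed (not the cell's
# position, so permuting rows permutes the output only; two sequences with
# identical effective profiles share seed and hence cache entry).
cell_seed <- function(profile, set_name, seed) {
  h <- rlang::hash(list(profile[, STEP_FIELDS], set_name,
                        as.integer(seed)))
  strtoi(substr(h, 1, 7), base = 16L)
}

#' Evaluate a benchmark of sequences across parameter sets
#'
#' Runs the Monte Carlo J-factor estimator for every (record, parameter
#' set) pair.  Estimates whose chains never closed are retained at the
#' floor J and flagged; a sequence whose alphabet is incompatible with a
#' set is recorded as a failed cell and the run continues.  Results are
#' cached in `cache` keyed by the effective profile, elastic model and
#' sampler configuration, so re-running with the same cache recomputes
#' nothing, and two records with identical effective profiles (e.g. any
#' two sequences under the straight model) share one simulation.
#'
#' @param records Tibble with `sequence_id` and `sequence` columns (see
#'   [read_benchmark()]).
#' @param sets A [parameter_set()] or list of them.
#' @param fluct A [fluctuation_model()].
#' @param cfg A [sampler_config()].
#' @param method Estimator, `"halfchain"` (default) or `"naive"`.
#' @param seed Master seed; per-cell seeds derive from it and the cell's
#'   profile.
#' @param cache Environment used as cache (pass the same one to resume).
#' @return Tibble with one row per (record, set): `sequence_id`,
#'   `parameter_set`, `length_bp`, `j_M`, `rel_error`, `n_total`, `n_r`,
#'   `n_gamma`, `n_phi`, `floored`, `seed`, `status`.
#' @export
evaluate_benchmark <- function(records, sets, fluct = default_fluctuations(),
                               cfg = sampler_config(),
                               method = c("halfchain", "naive"), seed = 1,
                               cache = new.env(parent = emptyenv())) {
  method <- match.arg(method)
  if (inherits(sets, "parameter_set")) sets <- list(sets)
  stopifnot(nrow(records) > 0, length(sets) > 0)
  grid <- tidyr::expand_grid(rec = seq_len(nrow(records)),
                             set = seq_along(sets))
  purrr::pmap_dfr(grid, function(rec, set) {
    r <- records[rec, ]
    ps <- sets[[set]]
    base <- tibble::tibble(sequence_id = r$sequence_id,
                           parameter_set = ps$name,
                           length_bp = nchar(r$sequence))
    est <- tryCatch({
      prof <- equilibrium_profile(r$sequence, ps)
      cs <- cell_seed(prof, ps$name, seed)
      key <- rlang::hash(list(prof[, STEP_FIELDS], fluct$beta_F,
                              cfg[c("capture_radius", "cos_gamma_min",
                                    "cos_phi_min", "target_rel_error",
                                    "max_chains", "batch_size",
                                    "n_batches", "half_chains")],
                              method, cs))
      if (is.null(cache[[key]])) {
        cache[[key]] <- estimate_j(prof, fluct, cfg, method = method,
                                   seed = cs)
      }
      cache[[key]]
    }, error = function(e) e)
    if (inherits(est, "error")) {
      return(dplyr::mutate(base, j_M = NA_real_, rel_error = NA_real_,
                           n_total = NA_real_, n_r = NA_real_,
                           n_gamma = NA_real_, n_phi = NA_real_,
                           floored = NA, seed = NA_integer_,
                           status = paste("failed:", conditionMessage(est))))
    }
    dplyr::mutate(base, j_M = est$j, rel_error = est$rel_error,
                  n_total = est$counts$n_total, n_r = est$counts$n_r,
                  n_gamma = est$counts$n_gamma, n_phi = est$counts$n_phi,
                  floored = est$floored, seed = est$seed, status = "ok")
  })
}

#' Order-of-magnitude concordance curve
#'
#' For each threshold t (log10 units), the percentage of sequences whose
#' simulated and reference J factors differ by at most t orders of
#' magnitude.  Non-decreasing in t, bounded in [0, 100], and invariant
#' under a common rescaling of both J columns.
#'
#' @param data Data frame holding the paired J factors.
#' @param j_sim,j_exp Columns (tidy-eval) with the simulated and reference
#'   J factors (mol/L, positive; floored values participate as-is).
#' @param thresholds Threshold grid in log10 units.
#' @return Tibble of class `concordance_curve` with `threshold` and
#'   `percent_within`; the number of pairs is attached as attribute `n`.
#' @examples
#' d <- data.frame(js = c(1e-9, 1e-8), je = c(3e-10, 3e-7))
#' concordance_curve(d, js, je, thresholds = 0:2)
#' @export
concordance_curve <- function(data, j_sim, j_exp,
                              thresholds = seq(0, 8, by = 0.1)) {
  js <- dplyr::pull(data, {{ j_sim }})
  je <- dplyr::pull(data, {{ j_exp }})
  if (length(js) == 0) rlang::abort("no sequences to compare")
  if (any(!is.finite(js) | js <= 0) || any(!is.finite(je) | je <= 0)) {
    rlang::abort("J factors must be positive and finite")
  }
  d <- abs(log10(js) - log10(je))
  out <- tibble::tibble(
    threshold = thresholds,
    percent_within = vapply(thresholds,
                            function(t) 100 * mean(d <= t), numeric(1)))
  structure(out, class = c("concordance_curve", class(out)),
            n = length(d))
}

#' Length-stratified concordance curves
#'
#' The concordance curve for all sequences and for the two length strata
#' (at most / longer than `cutoff` bp), stacked with a `stratum` column.
#' The strata partition the data: at every threshold the count-weighted
#' combination of the two stratum percentages equals the overall one.
#'
#' @inheritParams concordance_curve
#' @param length Column with sequence lengths (bp).
#' @param cutoff Stratum boundary (default 100 bp).
#' @return Tibble of class `concordance_curve` with columns `stratum`,
#'   `threshold`, `percent_within`, `n`.
#' @export
concordance_by_length <- function(data, j_sim, j_exp, length,
                                  cutoff = 100,
                                  thresholds = seq(0, 8, by = 0.1)) {
  len <- dplyr::pull(data, {{ length }})
  strata <- list(all = rep(TRUE, nrow(data)),
                 shorter = len <= cutoff,
                 longer = len > cutoff)
  names(strata) <- c("all", sprintf("<=%g bp", cutoff),
                     sprintf(">%g bp", cutoff))
  out <- purrr::imap_dfr(strata, function(keep, lab) {
    if (!any(keep)) return(NULL)
    cc <- concordance_curve(data[keep, , drop = FALSE],
                            {{ j_sim }}, {{ j_exp }}, thresholds)
    dplyr::mutate(cc, stratum = lab, n = attr(cc, "n"),
                  .before = 1)
  })
  structure(out, class = c("concordance_curve", class(out)))
}

#' Deviation from the straight-DNA baseline
#'
#' Replaces the experimental reference of [concordance_curve()] with the
#' straight-model J factor at each sequence's length: the percentage of
#' sequences whose J factor lies within t orders of magnitude of the
#' intrinsically straight chain of the same length.
#'
#' @param j_values Tibble with `length` (or `length_bp`) and `j_M` columns,
#'   one row per sequence.
#' @param baseline Tibble with `length` and `j_M`: the straight-model J at
#'   every length occurring in `j_values` (computed once per length).
#' @inheritParams concordance_curve
#' @return A `concordance_curve` tibble.
#' @export
straight_baseline_deviation <- function(j_values, baseline,
                                        thresholds = seq(0, 8, by = 0.1)) {
  if ("length_bp" %in% names(j_values) && !"length" %in% names(j_values)) {
    j_values <- dplyr::rename(j_values, length = "length_bp")
  }
  miss <- setdiff(unique(j_values$length), baseline$length)
  if (length(miss) > 0) {
    rlang::abort(sprintf("baseline missing length(s): %s",
                         paste(miss, collapse = ", ")))
  }
  joined <- dplyr::left_join(j_values,
                             dplyr::select(baseline, "length",
                                           j_straight = "j_M"),
                             by = "length")
  concordance_curve(joined, .data$j_M, .data$j_straight, thresholds)
}

#' Per-length distribution summary of J factors
#'
#' Median and 25/75 % quantiles of the J factors within each length group
#' (exact order statistics, quantile type 7).
#'
#' @param j_values Tibble with `length` (or `length_bp`) and `j_M`.
#' @return Tibble of class `j_length_summary`: `length`, `n`, `median`,
#'   `q25`, `q75`.
#' @export
length_stratified_summary <- function(j_values) {
  if ("length_bp" %in% names(j_values) && !"length" %in% names(j_values)) {
    j_values <- dplyr::rename(j_values, length = "length_bp")
  }
  if (nrow(j_values) == 0) rlang::abort("no values to summarize")
  out <- j_values |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(n = dplyr::n(),
                     median = stats::median(.data$j_M),
                     q25 = stats::quantile(.data$j_M, 0.25, names = FALSE),
                     q75 = stats::quantile(.data$j_M, 0.75, names = FALSE),
                     .groups = "drop")
  structure(out, class = c("j_length_summary", class(out)))
}

#' J factor of the straight (or any sequence-independent) model across
#' lengths
#'
#' Runs the estimator once per length and returns the J(L) curve.  For
#' sequence-dependent sets supply `sequence_fun` to produce the fragment at
#' each length (e.g. [curved_repeat_sequence()] for the curved model).
#'
#' @param lengths Fragment lengths in bp.
#' @param params A [parameter_set()].
#' @inheritParams estimate_j
#' @param seed Master seed; each length gets a deterministic sub-seed.
#' @param sequence_fun Function length -> sequence (default: poly-A, which
#'   is sufficient for sequence-independent sets).
#' @return Tibble of class `j_scan`: `length`, `j_M`, `rel_error`,
#'   `n_total`, `n_phi`, `floored`.
#' @export
j_length_scan <- function(lengths, params = builtin_straight(),
                          fluct = default_fluctuations(),
                          cfg = sampler_config(),
                          method = c("halfchain", "naive"), seed = 1,
                          sequence_fun = function(L) strrep("A", L)) {
  method <- match.arg(method)
  out <- purrr::map_dfr(seq_along(lengths), function(i) {
    L <- lengths[i]
    est <- j_factor(sequence_fun(L), params, fluct, cfg, method = method,
                    seed = as.integer(seed) + 7919L * i,
                    sequence_id = sprintf("L%04d", L))
    tibble::tibble(length = as.integer(L), j_M = est$j,
                   rel_error = est$rel_error,
                   n_total = est$counts$n_total,
                   n_phi = est$counts$n_phi, floored = est$floored)
  })
  structure(out, class = c("j_scan", class(out)))
}

#' Oscillation period of a J(L) curve
#'
#' The torsional alignment of the fragment ends makes log10 J(L) oscillate
#' with the helical repeat (360/twist bp).  The period is estimated by
#' profile least squares: for each candidate period the model
#' `log10(J) ~ poly(L, 2) + cos(2 pi L / p) + sin(2 pi L / p)` is fitted
#' and the period minimizing the residual sum of squares is returned.
#'
#' @param scan A [j_length_scan()] result (floored lengths are dropped).
#' @param periods Candidate period grid (bp).
#' @return Best-fitting period in bp.
#' @export
oscillation_period <- function(scan, periods = seq(8, 14, by = 0.02)) {
  d <- dplyr::filter(scan, !.data$floored)
  if (nrow(d) < 12) rlang::abort("too few converged lengths to fit")
  y <- log10(d$j_M)
  L <- d$length
  sse <- vapply(periods, function(p) {
    X <- cbind(1, L, L^2, cos(2 * pi * L / p), sin(2 * pi * L / p))
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  periods[which.min(sse)]
}
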