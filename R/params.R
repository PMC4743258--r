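# Equilibrium base-pair-step parameter sets: representation, loading,
# builtin reference models, and application to sequences.

STEP_FIELDS <- c("tilt", "roll", "twist", "shift", "slide", "rise")
ANGLE_FIELDS <- c("tilt", "roll", "twist")

#' Default equilibrium step parameters
#'
#' The sequence-independent fallback values applied wherever a parameter
#' table does not specify a field: tilt 0, roll 0, helix twist 34.30 degrees,
#' shift 0, slide 0, rise 3.40 Angstrom.
#'
#' @return Named numeric vector with elements tilt, roll, twist (degrees)
#'   and shift, slide, rise (Angstrom).
#' @export
step_defaults <- function() {
  c(tilt = 0, roll = 0, twist = 34.30, shift = 0, slide = 0, rise = 3.40)
}

#' Construct a single set of base-pair-step parameters
#'
#' @param tilt,roll,twist Angles in degrees.
#' @param shift,slide,rise Displacements in Angstrom; `rise` must be
#'   positive for a physically meaningful step.
#' @return Named numeric vector of the six helicoidal parameters.
#' @examples
#' step_parameters(roll = 7.41, twist = 35.57)
#' @export
step_parameters <- function(tilt = 0, roll = 0, twist = 34.30,
                            shift = 0, slide = 0, rise = 3.40) {
  x <- c(tilt = tilt, roll = roll, twist = twist,
         shift = shift, slide = slide, rise = rise)
  if (!all(is.finite(x))) {
    rlang::abort("all six step parameters must be finite")
  }
  if (rise <= 0) {
    rlang::abort("rise must be positive")
  }
  x
}

validate_context <- function(context, width, alphabet, where = "table") {
  bad_len <- nchar(context) != width
  if (any(bad_len)) {
    rlang::abort(sprintf(
      "%s row %d: context '%s' has width %d, expected %d",
      where, which(bad_len)[1], context[bad_len][1],
      nchar(context[bad_len][1]), width))
  }
  chars <- unique(unlist(strsplit(context, "")))
  bad <- setdiff(chars, alphabet)
  if (length(bad) > 0) {
    i <- which(vapply(strsplit(context, ""),
                      function(ch) any(ch %in% bad), logical(1)))[1]
    rlang::abort(sprintf(
      "%s row %d: context '%s' contains characters outside alphabet {%s}",
      where, i, context[i], paste(alphabet, collapse = ",")))
  }
  dup <- duplicated(context)
  if (any(dup)) {
    rlang::abort(sprintf("%s row %d: duplicate context '%s'",
                         where, which(dup)[1], context[dup][1]))
  }
  invisible(context)
}

#' Construct a context-keyed parameter set
#'
#' A parameter set maps each context k-mer (di-, tri-, or pentanucleotide
#' window around a base-pair step) to equilibrium step parameters.  Fields
#' absent from the table fall back to `defaults` when the set is applied to
#' a sequence.
#'
#' @param table Data frame with a `context` character column plus any subset
#'   of the six parameter columns (`tilt`, `roll`, `twist`, `shift`,
#'   `slide`, `rise`); missing cells (`NA`) also fall back to defaults.
#' @param context_width Integer, one of 2, 3, 5.  Inferred from the table
#'   when omitted.
#' @param name Label for the set.
#' @param alphabet Character vector of allowed bases (default A/C/G/T).
#' @param defaults Fully populated fallback parameters, see
#'   [step_defaults()].
#' @return An object of class `parameter_set`.
#' @seealso [load_parameter_set()], [builtin_straight()], [builtin_curved()]
#' @export
parameter_set <- function(table = NULL, context_width = NULL, name = "custom",
                          alphabet = c("A", "C", "G", "T"),
                          defaults = step_defaults()) {
  if (is.null(table)) {
    table <- tibble::tibble(context = character(0))
  }
  table <- tibble::as_tibble(table)
  if (!"context" %in% names(table)) {
    rlang::abort("parameter table must have a 'context' column")
  }
  extra <- setdiff(names(table), c("context", STEP_FIELDS))
  if (length(extra) > 0) {
    rlang::abort(sprintf("unknown parameter column(s): %s",
                         paste(extra, collapse = ", ")))
  }
  table$context <- toupper(as.character(table$context))
  if (is.null(context_width)) {
    if (nrow(table) == 0) {
      rlang::abort("context_width must be given for an empty table")
    }
    context_width <- nchar(table$context[1])
  }
  context_width <- as.integer(context_width)
  if (!context_width %in% c(2L, 3L, 5L)) {
    rlang::abort("context_width must be 2, 3 or 5")
  }
  if (nrow(table) > 0) {
    validate_context(table$context, context_width, alphabet)
    for (f in intersect(names(table), STEP_FIELDS)) {
      if (!is.numeric(table[[f]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(table[[f]]))) &
                       !is.na(table[[f]]))
        rlang::abort(sprintf("table row %d: non-numeric value in column '%s'",
                             if (length(bad)) bad[1] else 1L, f))
      }
    }
  }
  defaults <- defaults[STEP_FIELDS]
  if (anyNA(defaults) || !all(is.finite(defaults))) {
    rlang::abort("defaults must populate all six step parameters")
  }
  structure(
    list(name = name, context_width = context_width,
         alphabet = toupper(alphabet), table = table,
         defaults = defaults),
    class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf(
    "<parameter_set '%s'>  context width %d, %d context(s), alphabet {%s}\n",
    x$name, x$context_width, nrow(x$table),
    paste(x$alphabet, collapse = ",")))
  cat("defaults:", paste(sprintf("%s=%.2f", STEP_FIELDS, x$defaults),
                         collapse = " "), "\n")
  invisible(x)
}

sniff_delim <- function(path) {
  line <- readLines(path, n = 1)
  if (grepl("\t", line)) "\t" else ","
}

#' Load a parameter set from a delimited text file
#'
#' Reads a comma- or tab-delimited table with a header row naming columns
#' from `context, tilt, roll, twist, shift, slide, rise` (angles in degrees,
#' displacements in Angstrom).  Columns absent from the file fall back to
#' the default parameters when the set is applied.
#'
#' @param path Path to the delimited text file.
#' @param name Label for the set (defaults to the file name).
#' @param context_width Expected k-mer width (2, 3 or 5); contexts of any
#'   other width are a load error naming the offending row.
#' @param alphabet Allowed bases.
#' @param defaults Fallback parameters.
#' @return A [parameter_set()].
#' @export
load_parameter_set <- function(path, name = NULL, context_width = NULL,
                               alphabet = c("A", "C", "G", "T"),
                               defaults = step_defaults()) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- readr::read_delim(path, delim = sniff_delim(path),
                           col_types = readr::cols(
                             context = readr::col_character(),
                             .default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE)
  for (f in intersect(names(tab), STEP_FIELDS)) {
    num <- suppressWarnings(as.numeric(tab[[f]]))
    bad <- which(!is.na(tab[[f]]) & is.na(num))
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "%s row %d: non-numeric value '%s' in column '%s'",
        basename(path), bad[1], tab[[f]][bad[1]], f))
    }
    tab[[f]] <- num
  }
  parameter_set(tab, context_width = context_width, name = name,
                alphabet = alphabet, defaults = defaults)
}

#' Write a parameter set to delimited text
#'
#' Writes the set's table in the same schema [load_parameter_set()] reads
#' (CSV unless the path ends in `.tsv`/`.txt`, then tab-separated), so a
#' load/write round trip reproduces the effective table exactly.
#'
#' @param set A [parameter_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(set, path) {
  stopifnot(inherits(set, "parameter_set"))
  if (grepl("\\.(tsv|txt)$", path)) {
    readr::write_tsv(set$table, path, progress = FALSE)
  } else {
    readr::write_csv(set$table, path, progress = FALSE)
  }
  invisible(path)
}

#' Built-in straight (ideal elastic rod) model
#'
#' The sequence-independent reference model of a homogeneous, intrinsically
#' straight double helix: equilibrium helix twist 34.28 degrees and rise
#' 3.40 Angstrom for every step, all other equilibrium values zero.  Its
#' intrinsic-curvature contribution is exactly zero at every step.
#'
#' @return A [parameter_set()] whose empty table makes every context resolve
#'   to the straight defaults.
#' @examples
#' equilibrium_profile("ACGT", builtin_straight())
#' @export
builtin_straight <- function() {
  parameter_set(tibble::tibble(context = character(0)),
                context_width = 2L, name = "straight",
                defaults = step_parameters(twist = 34.28))
}

#' Built-in curved reference model
#'
#' A dinucleotide model over an artificial two-letter alphabet {X, Z} whose
#' equilibrium values bend the molecule into a nearly circular arc at
#' 150 bp: XX and XZ steps have helix twist 36.00 degrees (one full turn
#' per 10 bp) and zero roll/tilt, while ZZ and ZX steps have twist 35.57
#' degrees and roll 7.41 degrees.  Displacements match the straight model
#' (shift = slide = 0, rise 3.40 Angstrom).
#'
#' @return A [parameter_set()] over alphabet {X, Z}.
#' @seealso [curved_repeat_sequence()]
#' @export
builtin_curved <- function() {
  tab <- tibble::tibble(
    context = c("XX", "XZ", "ZZ", "ZX"),
    tilt = c(0, 0, 0, 0),
    roll = c(0, 0, 7.41, 7.41),
    twist = c(36.00, 36.00, 35.57, 35.57),
    shift = 0, slide = 0, rise = 3.40)
  parameter_set(tab, context_width = 2L, name = "curved",
                alphabet = c("X", "Z"),
                defaults = step_parameters(twist = 34.28))
}

#' Periodic X/Z sequence for the curved reference model
#'
#' Repeats of `n_x` X bases followed by `n_z` Z bases (default the 5+5
#' pattern, one helical repeat per block), truncated to `length` bases.
#'
#' @param length Sequence length in bases.
#' @param n_x,n_z Block sizes of the repeat.
#' @return A character scalar over {X, Z}.
#' @export
curved_repeat_sequence <- function(length, n_x = 5, n_z = 5) {
  block <- paste0(strrep("X", n_x), strrep("Z", n_z))
  substr(strrep(block, ceiling(length / nchar(block))), 1, length)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

reverse_complement <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    paste(rev(unname(COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

# Effective parameters for a vector of contexts: table values where present,
# reverse-complement symmetry for A/C/G/T alphabets (tilt and shift change
# sign on the complementary strand), else defaults.  NA context = window
# overran a sequence end = defaults.
resolve_contexts <- function(set, contexts) {
  n <- length(contexts)
  out <- matrix(rep(set$defaults, each = n), nrow = n,
                dimnames = list(NULL, STEP_FIELDS))
  if (nrow(set$table) == 0 || n == 0) return(out)

  fill <- function(rows_idx, tab_idx, flip_sign) {
    for (f in intersect(names(set$table), STEP_FIELDS)) {
      v <- set$table[[f]][tab_idx]
      sgn <- if (flip_sign && f %in% c("tilt", "shift")) -1 else 1
      ok <- !is.na(v)
      out[rows_idx[ok], f] <<- sgn * v[ok]
    }
  }
  idx <- match(contexts, set$table$context)
  hit <- !is.na(idx)
  fill(which(hit), idx[hit], flip_sign = FALSE)

  miss <- which(!hit & !is.na(contexts))
  if (length(miss) > 0 && all(c("A", "C", "G", "T") %in% set$alphabet)) {
    rc <- reverse_complement(contexts[miss])
    idx2 <- match(rc, set$table$context)
    hit2 <- !is.na(idx2)
    fill(miss[hit2], idx2[hit2], flip_sign = TRUE)
  }
  out
}

step_contexts <- function(sequence, width, circular = FALSE) {
  n <- nchar(sequence)
  s <- seq_len(n - 1)
  start <- s - (width - 1L) %/% 2L
  end <- start + width - 1L
  if (circular) {
    chars <- strsplit(sequence, "")[[1]]
    vapply(s, function(k) {
      pos <- ((start[k]:end[k]) - 1L) %% n + 1L
      paste(chars[pos], collapse = "")
    }, character(1))
  } else {
    ctx <- substr(rep(sequence, length(s)), start, end)
    ctx[start < 1 | end > n] <- NA_character_
    ctx
  }
}

#' Sequence of equilibrium step parameters along a DNA fragment
#'
#' Maps each base-pair step of `sequence` to its equilibrium parameters
#' under a parameter set.  Step k (between bases k and k+1, 1-based)
#' receives the parameters of the context window around the step: bases
#' k..k+1 for dinucleotide sets, k-1..k+1 for trinucleotide, k-2..k+2 for
#' pentanucleotide sets.  Windows that overrun a sequence end resolve to
#' the set's defaults (or wrap when `circular = TRUE`); contexts missing
#' from the table resolve through reverse-complement symmetry for A/C/G/T
#' alphabets, else to defaults.
#'
#' @param sequence Character scalar over the set's alphabet
#'   (case-insensitive).
#' @param set A [parameter_set()].
#' @param circular Wrap context windows around the sequence ends.
#' @return A tibble with one row per step: `step`, `context` (NA when the
#'   window overran an end), and the six parameter columns, angles in
#'   degrees and displacements in Angstrom.
#' @examples
#' equilibrium_profile("XXZZ", builtin_curved())$twist
#' @export
equilibrium_profile <- function(sequence, set, circular = FALSE) {
  stopifnot(inherits(set, "parameter_set"))
  sequence <- toupper(gsub("\\s", "", sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% set$alphabet)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "invalid character '%s' at position %d (alphabet {%s})",
      chars[bad[1]], bad[1], paste(set$alphabet, collapse = ",")))
  }
  if (nchar(sequence) < max(2L, set$context_width)) {
    rlang::abort(sprintf("sequence must have at least %d bases",
                         max(2L, set$context_width)))
  }
  ctx <- step_contexts(sequence, set$context_width, circular = circular)
  vals <- resolve_contexts(set, ctx)
  dplyr::bind_cols(
    tibble::tibble(step = seq_along(ctx), context = ctx),
    tibble::as_tibble(vals))
}

# 6 x S matrix of step parameters with angles converted to radians; the one
# place where the degree -> radian conversion happens.
profile_matrix <- function(profile) {
  if (is.matrix(profile)) {
    stopifnot(nrow(profile) == 6)
    m <- profile
  } else {
    stopifnot(all(STEP_FIELDS %in% names(profile)))
    m <- t(as.matrix(profile[, STEP_FIELDS]))
  }
  m[1:3, ] <- m[1:3, ] * pi / 180
  dimnames(m) <- list(STEP_FIELDS, NULL)
  m
}
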