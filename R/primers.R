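# Primer registry: the common miniCOI primers and their pairings, shipped as a
# packaged text table and overridable from a user-supplied file of the same
# shape. Combination names accept either an ASCII hyphen or an en dash
# ("Leray-Geller" == "Leray–Geller").

.registry_env <- new.env(parent = emptyenv())

.normalize_name <- function(x) {
  x <- gsub("–|—", "-", x)
  trimws(x)
}

#' Construct a degenerate primer
#'
#' @param name short identifier.
#' @param sequence 5'->3' sequence over the IUPAC + inosine alphabet.
#' @param direction `"forward"` or `"reverse"`.
#' @return A `degenerate_primer` object (name, sequence, direction, length).
#' @export
#' @examples
#' degenerate_primer("toy", "GGWACW", "forward")
degenerate_primer <- function(name, sequence, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  chars <- .seq_chars(sequence, what = sprintf("primer '%s'", name))
  structure(
    list(
      name = as.character(name),
      sequence = paste(chars, collapse = ""),
      direction = direction,
      length = length(chars)
    ),
    class = "degenerate_primer"
  )
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("%s primer %s (%d nt, %d ambiguities)\n  5'-%s-3'\n",
              x$direction, x$name, x$length, count_ambiguities(x), x$sequence))
  invisible(x)
}

#' Number of ambiguous positions in a primer
#'
#' Counts positions whose symbol is not a concrete base; inosine counts as
#' ambiguous.
#'
#' @param primer a [degenerate_primer()] or sequence string.
#' @return Integer count.
#' @export
#' @examples
#' count_ambiguities(get_primer("jgHCO2198")) # 8
count_ambiguities <- function(primer) {
  seq <- if (inherits(primer, "degenerate_primer")) primer$sequence else primer
  sum(!.seq_chars(seq, "primer") %in% c("A", "C", "G", "T"))
}

#' Load a primer registry from text tables
#'
#' Reads the packaged primer and combination tables (or user overrides with
#' the same columns: `name`, `direction`, `sequence` for primers; `name`,
#' `forward`, `reverse` for combinations) and installs them as the active
#' registry used by [get_primer()] and [get_combination()].
#'
#' @param primers_path,combinations_path TSV paths; defaults are the packaged
#'   tables.
#' @return Invisibly, a list with `primers` and `combinations`.
#' @export
load_primer_registry <- function(
    primers_path = system.file("extdata", "primers.tsv", package = "minicoiscan"),
    combinations_path = system.file("extdata", "combinations.tsv", package = "minicoiscan")) {
  pt <- utils::read.delim(primers_path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "direction", "sequence") %in% names(pt)))
  primers <- lapply(seq_len(nrow(pt)), function(i) {
    degenerate_primer(pt$name[i], pt$sequence[i], pt$direction[i])
  })
  names(primers) <- pt$name

  ct <- utils::read.delim(combinations_path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "forward", "reverse") %in% names(ct)))
  combos <- lapply(seq_len(nrow(ct)), function(i) {
    fwd <- ct$forward[i]
    rev <- ct$reverse[i]
    if (!fwd %in% names(primers) || !rev %in% names(primers)) {
      stop(sprintf("combination '%s' refers to unregistered primers", ct$name[i]),
           call. = FALSE)
    }
    structure(
      list(name = ct$name[i], forward = primers[[fwd]], reverse = primers[[rev]]),
      class = "primer_combination"
    )
  })
  names(combos) <- .normalize_name(ct$name)

  .registry_env$primers <- primers
  .registry_env$combinations <- combos
  invisible(list(primers = primers, combinations = combos))
}

.registry <- function() {
  if (is.null(.registry_env$primers)) load_primer_registry()
  .registry_env
}

#' Look up a registered primer or combination
#'
#' The packaged registry holds the miniCOI primers mlCOIintF, mlCOIintF-XT,
#' HCO2198, dgHCO2198 and jgHCO2198, and the combinations Leray-Folmer,
#' Leray-Meyer, Leray-Geller and Leray XT.
#'
#' @param name registered name (combination names accept hyphen or en dash).
#' @return A `degenerate_primer` / `primer_combination`.
#' @export
#' @examples
#' get_primer("mlCOIintF")$sequence
#' get_combination("Leray-Geller")$reverse$name
get_primer <- function(name) {
  reg <- .registry()
  if (!name %in% names(reg$primers)) {
    stop(sprintf("unknown primer '%s'; registered: %s",
                 name, paste(names(reg$primers), collapse = ", ")), call. = FALSE)
  }
  reg$primers[[name]]
}

#' @rdname get_primer
#' @export
get_combination <- function(name) {
  reg <- .registry()
  key <- .normalize_name(name)
  if (!key %in% names(reg$combinations)) {
    stop(sprintf("unknown combination '%s'; registered: %s",
                 name, paste(names(reg$combinations), collapse = ", ")), call. = FALSE)
  }
  reg$combinations[[key]]
}

#' @rdname get_primer
#' @export
list_primers <- function() names(.registry()$primers)

#' @rdname get_primer
#' @export
list_combinations <- function() names(.registry()$combinations)

#' The two miniCOI forward primers as a named list
#'
#' Convenience accessor for the primer pair most analyses compare:
#' Leray's mlCOIintF and the more degenerate Leray XT forward (mlCOIintF-XT).
#'
#' @return Named list of two `degenerate_primer` objects.
#' @export
minicoi_forward_primers <- function() {
  list(mlCOIintF = get_primer("mlCOIintF"), `mlCOIintF-XT` = get_primer("mlCOIintF-XT"))
}

#' @export
print.primer_combination <- function(x, ...) {
  cat(sprintf("primer combination %s: %s / %s\n",
              x$name, x$forward$name, x$reverse$name))
  invisible(x)
}
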