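# Packaged primer-region fixtures and the synthetic-sequence generator.
#
# The fixture tables transcribe the variable-position states of three curated
# datasets of miniCOI forward-primer binding regions:
#   * oithona_similis  — 14 haplotype lineages with per-lineage multiplicity n
#                        (n sums to 247 sequences),
#   * appendicularia   — 21 sequences from 14 appendicularian species, with
#                        poly-T insert flags,
#   * thaliacea        — 15 sequences from 12 thaliacean species.
# Unlisted (conserved) positions are filled with a base chosen from the
# intersection of both forward primers' allowed sets, so the fill can never
# create a mismatch for either primer; the printed per-primer totals travel
# with the tables as reference columns used only for validation, never as an
# input to region construction.

.FIXTURE_FILES <- c(
  oithona_similis = "oithona_similis_lineages.tsv",
  appendicularia = "appendicularia_sequences.tsv",
  thaliacea = "thaliacea_sequences.tsv"
)

# Names reserved for datasets whose haplotype bases were never published as
# machine-readable tables (documented gap; no rows ship).
.FIXTURE_RESERVED <- c("oithona_nana_partial", "microsetella_norvegica_partial")

#' Conserved-fill bases for the miniCOI forward-primer region
#'
#' For each of the 26 positions, the lexicographically smallest base in the
#' intersection of the allowed sets of mlCOIintF and mlCOIintF-XT. Filling
#' conserved positions from this vector is provably mismatch-neutral for both
#' forward primers.
#'
#' @return Character vector of length 26.
#' @export
conserved_fill_bases <- function() {
  p1 <- .primer_chars(get_primer("mlCOIintF"))
  p2 <- .primer_chars(get_primer("mlCOIintF-XT"))
  vapply(seq_along(p1), function(i) {
    both <- intersect(.IUPAC_SETS[[p1[i]]], .IUPAC_SETS[[p2[i]]])
    if (length(both) == 0L) {
      stop(sprintf("no common allowed base at position %d", i), call. = FALSE)
    }
    sort(both)[1L]
  }, character(1))
}

#' Load a fixture transcription table
#'
#' @param dataset one of `"oithona_similis"`, `"appendicularia"`,
#'   `"thaliacea"`.
#' @return The transcription as a data frame (state columns `p<k>` hold the
#'   base at 1-based primer position `k`, empty where conserved; printed
#'   per-primer totals are carried in `printed_*` columns).
#' @export
fixture_table <- function(dataset) {
  if (dataset %in% .FIXTURE_RESERVED) {
    stop(sprintf(
      "dataset '%s' is reserved: its haplotype bases were never published in transcribable form",
      dataset), call. = FALSE)
  }
  dataset <- match.arg(dataset, names(.FIXTURE_FILES))
  path <- system.file("extdata", .FIXTURE_FILES[[dataset]], package = "minicoiscan")
  # colClasses: a state column holding only "T" would otherwise be read as
  # logical TRUE
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                           na.strings = character(0), check.names = FALSE)
  if ("n" %in% names(tab)) tab$n <- as.integer(tab$n)
  pos_cols <- grep("^p[0-9]+$", names(tab), value = TRUE)
  states <- unlist(tab[pos_cols], use.names = FALSE)
  states <- states[states != ""]
  if (!all(states %in% c("A", "C", "G", "T"))) {
    stop(sprintf("fixture '%s' contains non-concrete states", dataset), call. = FALSE)
  }
  pos <- as.integer(sub("^p", "", pos_cols))
  if (any(pos < 1L | pos > 26L)) {
    stop(sprintf("fixture '%s' lists positions outside 1..26", dataset), call. = FALSE)
  }
  if (dataset == "oithona_similis" && sum(tab$n) != 247L) {
    stop("oithona_similis multiplicities must sum to 247", call. = FALSE)
  }
  attr(tab, "dataset") <- dataset
  attr(tab, "positions") <- pos
  tab
}

#' Variable positions listed by a fixture
#'
#' @inheritParams fixture_table
#' @return Ascending integer vector of 1-based primer positions.
#' @export
fixture_positions <- function(dataset) {
  sort(attr(fixture_table(dataset), "positions"))
}

#' Build a concrete 26-nt binding region from variable-position states
#'
#' Listed positions take the given base; all other positions take the
#' conserved fill ([conserved_fill_bases()]), which matches both forward
#' primers by construction.
#'
#' @param states named character vector, names = 1-based positions, values =
#'   concrete bases (e.g. `c("12" = "G", "18" = "G")`).
#' @param id region identifier.
#' @param fill optional replacement fill vector of length 26 (must still be
#'   compatible with both forward primers at every position it fills).
#' @return A [template_region()].
#' @export
#' @examples
#' r <- build_region(c("12" = "G", "18" = "G"), id = "#II")
#' profile_mismatches(get_primer("mlCOIintF"), r)$mismatch_positions # 12 18
build_region <- function(states, id = "region", fill = conserved_fill_bases()) {
  stopifnot(length(fill) == 26L)
  bases <- fill
  if (length(states) > 0L) {
    pos <- as.integer(names(states))
    if (anyNA(pos) || any(pos < 1L | pos > 26L)) {
      stop("state names must be positions in 1..26", call. = FALSE)
    }
    bases[pos] <- toupper(unname(states))
  }
  template_region(paste(bases, collapse = ""), source_id = id, start = NA_integer_)
}

.row_states <- function(row, pos_cols) {
  s <- unlist(row[pos_cols], use.names = FALSE)
  keep <- s != ""
  stats::setNames(s[keep], sub("^p", "", pos_cols[keep]))
}

#' Expand a fixture into template regions
#'
#' @inheritParams fixture_table
#' @param with_multiplicity when the fixture carries per-row multiplicities
#'   (`n`), replicate each row `n` times with suffixed ids; otherwise one
#'   region per row.
#' @param fill see [build_region()].
#' @return List of [template_region()] objects, in the table's row order.
#' @export
#' @examples
#' length(fixture_regions("oithona_similis", with_multiplicity = TRUE)) # 247
fixture_regions <- function(dataset, with_multiplicity = FALSE,
                            fill = conserved_fill_bases()) {
  tab <- fixture_table(dataset)
  pos_cols <- grep("^p[0-9]+$", names(tab), value = TRUE)
  ids <- if ("label" %in% names(tab)) tab$label else tab$accession
  out <- vector("list", 0L)
  for (i in seq_len(nrow(tab))) {
    states <- .row_states(tab[i, ], pos_cols)
    n_i <- if (with_multiplicity && "n" %in% names(tab)) tab$n[i] else 1L
    if (n_i == 1L && !(with_multiplicity && "n" %in% names(tab))) {
      out[[length(out) + 1L]] <- build_region(states, id = ids[i], fill = fill)
    } else {
      for (k in seq_len(n_i)) {
        out[[length(out) + 1L]] <- build_region(
          states, id = sprintf("%s_%03d", ids[i], k), fill = fill)
      }
    }
  }
  out
}

#' Random concrete region with a prescribed mismatch count
#'
#' Property-test generator: draws a concrete 26-nt (or primer-length) region
#' with exactly `k_mismatches` positions incompatible with the primer,
#' optionally forcing one mismatch into the 3'-terminal window. Mismatching
#' bases are drawn outside the primer's allowed set, so positions whose symbol
#' allows all four bases (N, I) cannot be chosen.
#'
#' @param primer a [degenerate_primer()].
#' @param k_mismatches number of mismatching positions.
#' @param terminal force one mismatch into the last `terminal_window`
#'   positions.
#' @param seed optional integer seed (uses the current RNG stream when `NULL`).
#' @param terminal_window size of the 3'-terminal window (default 3).
#' @return A [template_region()].
#' @export
random_region <- function(primer, k_mismatches, terminal = FALSE, seed = NULL,
                          terminal_window = 3L) {
  if (!is.null(seed)) set.seed(seed)
  pchars <- .primer_chars(primer)
  L <- length(pchars)
  stopifnot(k_mismatches >= 0L, k_mismatches <= L)
  capable <- which(vapply(pchars, function(s) length(.IUPAC_SETS[[s]]) < 4L, logical(1)))
  if (k_mismatches > length(capable)) {
    stop(sprintf("cannot place %d mismatches: only %d positions have a non-universal symbol",
                 k_mismatches, length(capable)), call. = FALSE)
  }
  mm <- integer(0)
  if (k_mismatches > 0L) {
    if (terminal) {
      term_capable <- capable[capable > L - terminal_window]
      if (length(term_capable) == 0L) {
        stop("no mismatch-capable position in the 3'-terminal window", call. = FALSE)
      }
      first <- term_capable[sample.int(length(term_capable), 1L)]
      rest_pool <- setdiff(capable, first)
      rest <- if (k_mismatches > 1L) rest_pool[sample.int(length(rest_pool), k_mismatches - 1L)] else integer(0)
      mm <- sort(c(first, rest))
    } else {
      mm <- sort(capable[sample.int(length(capable), k_mismatches)])
    }
  }
  bases <- vapply(seq_len(L), function(i) {
    allowed <- .IUPAC_SETS[[pchars[i]]]
    pool <- if (i %in% mm) setdiff(c("A", "C", "G", "T"), allowed) else allowed
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  template_region(paste(bases, collapse = ""), source_id = sprintf("random_k%d", k_mismatches))
}

#' Synthetic-sequence configuration
#'
#' Controls the synthetic FASTA generator. Defaults emulate the miniCOI
#' amplicon context: a 313-bp fragment whose interior (261 nt between the two
#' 26-nt primer-binding regions) may carry a homopolymeric poly-T insert with
#' geometric length distribution of mean about 140 nt, truncated at 500 nt
#' (the sizes reported for *Oikopleura dioica*), never shorter than
#' `polyt_min` so that a planted insert is always a detectable run.
#'
#' @param flank_length random flanking sequence on each side (nt).
#' @param spacer_length interior length between the primer regions (nt).
#' @param polyt_mean,polyt_max,polyt_min insert length distribution (nt).
#' @param reverse_primer name of the reverse primer whose exact complement
#'   target is planted.
#' @param seed integer RNG seed; fully determines the output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(flank_length = 60L, spacer_length = 261L,
                             polyt_mean = 140, polyt_max = 500L, polyt_min = 10L,
                             reverse_primer = "jgHCO2198", seed = 1L) {
  stopifnot(flank_length >= 0L, spacer_length >= 0L,
            polyt_min <= polyt_mean, polyt_mean <= polyt_max)
  structure(
    list(flank_length = as.integer(flank_length),
         spacer_length = as.integer(spacer_length),
         polyt_mean = polyt_mean, polyt_max = as.integer(polyt_max),
         polyt_min = as.integer(polyt_min),
         reverse_primer = reverse_primer, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Random concrete sequence with no homopolymer run longer than max_run
# (avoids spurious poly-T/poly-A calls in random flanks and spacers).
.random_seq <- function(n, max_run = 7L) {
  if (n == 0L) return("")
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  r <- rle(x)
  while (any(r$lengths > max_run)) {
    idx <- cumsum(r$lengths)
    for (j in which(r$lengths > max_run)) {
      at <- idx[j] - r$lengths[j] + max_run + 1L
      x[at] <- sample(setdiff(c("A", "C", "G", "T"), x[at]), 1L)
    }
    r <- rle(x)
  }
  paste(x, collapse = "")
}

# A concrete expansion of a degenerate primer (each ambiguous position drawn
# uniformly from its allowed set).
.concrete_expansion <- function(primer) {
  pchars <- .primer_chars(primer)
  paste(vapply(pchars, function(s) {
    a <- .IUPAC_SETS[[s]]
    a[sample.int(length(a), 1L)]
  }, character(1)), collapse = "")
}

#' Synthesize FASTA-ready records around planted primer-binding regions
#'
#' Each record is assembled as: random flank, the supplied forward
#' primer-binding region, a random interior spacer optionally interrupted by a
#' poly-T insert, the exact complement target of the configured reverse
#' primer, and a closing random flank. Random segments are generated with
#' homopolymer runs capped below the poly-T detection floor, so only planted
#' inserts are detectable. Output is deterministic under the config seed.
#'
#' @param regions list of [template_region()] (e.g. from [fixture_regions()]).
#' @param config a [synthetic_config()].
#' @param polyt logical scalar or vector (recycled) saying which records get a
#'   poly-T insert.
#' @return Named character vector of sequences; attribute `meta` is a data
#'   frame with the planted coordinates (0-based) of the forward region, the
#'   amplicon span, and the poly-T insert (`NA` when absent), plus the seed.
#' @export
synthesize_fasta <- function(regions, config = synthetic_config(), polyt = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  polyt <- rep_len(as.logical(polyt), length(regions))
  rev_primer <- get_primer(config$reverse_primer)

  seqs <- character(length(regions))
  meta <- data.frame(
    id = character(length(regions)), fwd_start = NA_integer_,
    amplicon_start = NA_integer_, amplicon_end = NA_integer_,
    polyt_start = NA_integer_, polyt_length = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    flank1 <- .random_seq(config$flank_length)
    flank2 <- .random_seq(config$flank_length)
    rev_target <- reverse_complement(.concrete_expansion(rev_primer))

    insert <- ""
    ins_len <- NA_integer_
    if (polyt[i]) {
      extra <- stats::rgeom(1L, prob = 1 / max(1, config$polyt_mean - config$polyt_min))
      ins_len <- min(config$polyt_max, config$polyt_min + extra)
      insert <- strrep("T", ins_len)
    }
    # split the interior around the insert; an unsplit spacer when there is
    # none (two abutting capped runs could otherwise reach the detection floor)
    if (polyt[i] && config$spacer_length > 0L) {
      cut <- sample.int(config$spacer_length + 1L, 1L) - 1L
      sp_a <- .random_seq(cut)
      sp_b <- .random_seq(config$spacer_length - cut)
    } else {
      sp_a <- .random_seq(config$spacer_length)
      sp_b <- ""
    }

    seqs[i] <- paste0(flank1, reg$bases, sp_a, insert, sp_b, rev_target, flank2)
    fwd_start <- nchar(flank1)
    meta$id[i] <- reg$source_id
    meta$fwd_start[i] <- fwd_start
    meta$amplicon_start[i] <- fwd_start
    meta$amplicon_end[i] <- fwd_start + 26L + nchar(sp_a) + nchar(insert) +
      nchar(sp_b) + nchar(rev_target)
    if (polyt[i]) {
      meta$polyt_start[i] <- fwd_start + 26L + nchar(sp_a)
      meta$polyt_length[i] <- ins_len
    }
  }
  names(seqs) <- meta$id
  attr(seqs, "meta") <- meta
  attr(seqs, "seed") <- config$seed
  seqs
}

#' Write synthetic records to a FASTA file
#'
#' @param seqs named character vector (e.g. from [synthesize_fasta()]).
#' @param path output file; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
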