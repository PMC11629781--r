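# Pipeline layer: FASTA in, tab-separated reports out. These functions tie the
# stages together (locate -> profile -> classify; group -> summarize; poly-T
# scan; metasynthesis tallies) and are what the command-line wrapper in
# inst/cli/minicoi.R calls.

#' Read template sequences from FASTA
#'
#' @param path FASTA file, plain or gzip-compressed.
#' @return Named character vector of uppercase sequences.
#' @export
read_templates <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

.as_templates <- function(input) {
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    return(read_templates(input))
  }
  nm <- names(input)
  out <- toupper(unname(unlist(lapply(input, as.character))))
  if (length(out) == 0L) return(stats::setNames(character(0), character(0)))
  if (is.null(nm)) nm <- sprintf("seq%d", seq_along(out))
  names(out) <- nm
  out
}

#' Scan sequences for primer-binding sites and mismatch risk
#'
#' For every sequence x primer, locates the best binding window, profiles the
#' mismatches and classifies the amplification risk. Reverse primers are
#' scanned via the reverse complement automatically.
#'
#' @param input FASTA path or named character vector of sequences.
#' @param primers named list of [degenerate_primer()]s (default: both miniCOI
#'   forward primers).
#' @param max_scan_mismatches windows scoring above this are reported with
#'   `covered = "none"`.
#' @param policy an [inosine_policy()].
#' @param terminal_window 3'-terminal window size.
#' @return Data frame with one row per sequence x primer: `template_id`,
#'   `primer`, `covered`, `start`, `total`, `internal`, `terminal3_hit`,
#'   `mismatch_positions` (comma-joined, 1-based primer coordinates), `risk`,
#'   `rationale`.
#' @export
scan_fasta <- function(input, primers = minicoi_forward_primers(),
                       max_scan_mismatches = 10L, policy = inosine_policy(),
                       terminal_window = 3L) {
  seqs <- .as_templates(input)
  rows <- list()
  for (pn in names(primers)) {
    primer <- primers[[pn]]
    for (si in seq_along(seqs)) {
      id <- names(seqs)[si]
      reg <- locate_binding_site(seqs[[si]], primer,
                                 max_scan_mismatches = max_scan_mismatches,
                                 policy = policy, id = id)
      if (identical(reg$covered, "partial")) {
        rows[[length(rows) + 1L]] <- data.frame(
          template_id = id, primer = pn, covered = "partial",
          start = NA_integer_, total = NA_integer_, internal = NA_integer_,
          terminal3_hit = NA, mismatch_positions = "", risk = NA_character_,
          rationale = "template shorter than primer", stringsAsFactors = FALSE)
        next
      }
      prof <- profile_mismatches(primer, reg$bases, policy = policy,
                                 terminal_window = terminal_window)
      risk <- classify_risk(prof)
      rows[[length(rows) + 1L]] <- data.frame(
        template_id = id, primer = pn, covered = reg$covered,
        start = reg$start, total = prof$total, internal = prof$internal_total,
        terminal3_hit = prof$terminal3_hit,
        mismatch_positions = paste(prof$mismatch_positions, collapse = ","),
        risk = as.character(risk$level), rationale = risk$rationale,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    warning("no sequences to scan; returning empty table")
    return(data.frame(template_id = character(0), primer = character(0),
                      covered = character(0), start = integer(0),
                      total = integer(0), internal = integer(0),
                      terminal3_hit = logical(0), mismatch_positions = character(0),
                      risk = character(0), rationale = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Lineage analysis of full-length binding regions
#'
#' Finds the variable positions, groups the regions into haplotype lineages
#' and computes the per-position and per-lineage summaries.
#'
#' @param regions list of [template_region()]s (e.g. [fixture_regions()]) or
#'   equal-length character sequences.
#' @param primers named list of primers to profile against.
#' @param policy an [inosine_policy()].
#' @return List: `variable_positions`, `lineages` (Table-shaped data frame),
#'   `per_position`, `summary`.
#' @export
lineage_report <- function(regions, primers = minicoi_forward_primers(),
                           policy = inosine_policy()) {
  pos <- find_variable_positions(regions)
  groups <- group_by_haplotype(regions, pos, primers = primers, policy = policy)
  list(
    variable_positions = pos,
    lineages = groups,
    per_position = per_position_mismatch_counts(groups, primers, policy = policy),
    summary = summarize_lineages(groups)
  )
}

#' Poly-T report over a set of sequences
#'
#' @param input FASTA path or named character vector.
#' @param min_len minimum qualifying run length.
#' @param amplicon_spans optional named list of 0-based half-open spans per
#'   sequence id.
#' @param scan_complement also scan for poly-A runs.
#' @return Data frame: `template_id`, `n_runs`, `max_run`, `present`,
#'   `within_amplicon`.
#' @export
polyt_report <- function(input, min_len = 10L, amplicon_spans = NULL,
                         scan_complement = FALSE) {
  seqs <- .as_templates(input)
  rows <- lapply(seq_along(seqs), function(si) {
    id <- names(seqs)[si]
    span <- if (!is.null(amplicon_spans)) amplicon_spans[[id]] else NULL
    rep <- scan_polyT(seqs[[si]], amplicon_span = span, min_len = min_len,
                      id = id, scan_complement = scan_complement)
    data.frame(template_id = id, n_runs = nrow(rep$runs), max_run = rep$max_run,
               present = rep$present, within_amplicon = rep$within_amplicon,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    warning("no sequences to scan; returning empty table")
    return(data.frame(template_id = character(0), n_runs = integer(0),
                      max_run = integer(0), present = logical(0),
                      within_amplicon = logical(0)))
  }
  do.call(rbind, rows)
}

#' Metasynthesis report
#'
#' @param records study-outcome records (default: the packaged transcription).
#' @return As [summarize_misperformance()], plus a `headline` character line.
#' @export
meta_report <- function(records = load_outcomes()) {
  s <- summarize_misperformance(records)
  s$headline <- sprintf(
    "misperformance reported for %d taxa (%d copepods, %d tunicates, %d other)",
    s$n_taxa_misperforming, s$n_by_group[["copepod"]],
    s$n_by_group[["tunicate"]], s$n_by_group[["other"]])
  s
}

#' Write a report table as TSV
#'
#' UTF-8, tab-delimited, header row, no quoting — deterministic for a given
#' table.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
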