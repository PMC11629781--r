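# Metasynthesis of reviewed metabarcoding studies: one record per
# study x taxon x basin, with the primer combination used and the reported
# outcome (fail = no detection / false negative; bias = pronounced abundance
# bias; NA = not assessable; OK = fair-to-good correspondence). The packaged
# transcription covers the 30 reviewed studies, full outcome matrices for the
# two focal taxa (Appendicularians, Oithona similis) and all per-taxon
# misperformance records. A study sampling two basins carries one record per
# basin; distinct-study tallies deduplicate by study code.

.OUTCOMES <- c("fail", "bias", "NA", "OK")
.BASINS <- c("AO", "PO", "IO", "ArO", "SO", "Undet.")
.COMBINATIONS <- c("Leray-Folmer", "Leray-Meyer", "Leray-Geller", "Leray XT", "Other")
.GROUPS <- c("copepod", "tunicate", "other")
.FOCAL_TAXA <- c("Appendicularians", "Oithona similis")

#' Load (and validate) the study-outcome table
#'
#' @param path TSV with columns `study_code`, `taxon`, `taxon_group`,
#'   `ocean_basin`, `primer_combination`, `outcome`; default is the packaged
#'   transcription.
#' @return Validated data frame of study-outcome records.
#' @export
load_outcomes <- function(path = system.file("extdata", "study_outcomes.tsv",
                                             package = "minicoiscan")) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  rec <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                           na.strings = character(0), check.names = FALSE)
  need <- c("study_code", "taxon", "taxon_group", "ocean_basin",
            "primer_combination", "outcome")
  if (!all(need %in% names(rec))) {
    stop(sprintf("outcome table must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  rec$study_code <- as.integer(rec$study_code)
  rec$primer_combination <- .normalize_name(rec$primer_combination)

  .check_vocab <- function(col, vocab) {
    bad <- which(!rec[[col]] %in% vocab)
    if (length(bad) > 0L) {
      stop(sprintf("row %d: invalid %s '%s' (allowed: %s)",
                   bad[1L], col, rec[[col]][bad[1L]], paste(vocab, collapse = ", ")),
           call. = FALSE)
    }
  }
  .check_vocab("outcome", .OUTCOMES)
  .check_vocab("ocean_basin", .BASINS)
  .check_vocab("primer_combination", .COMBINATIONS)
  .check_vocab("taxon_group", .GROUPS)
  if (anyNA(rec$study_code)) stop("non-integer study_code", call. = FALSE)

  key <- paste(rec$study_code, rec$taxon, rec$ocean_basin, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("row %d: duplicate record for study %d / %s / %s",
                 d, rec$study_code[d], rec$taxon[d], rec$ocean_basin[d]),
         call. = FALSE)
  }
  rec
}

#' Write study-outcome records back to TSV
#'
#' @param records data frame as returned by [load_outcomes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Studies reporting misperformance for one taxon
#'
#' Counts distinct studies whose records for `taxon` report `fail` or `bias`,
#' by ocean basin and in total. A study listed under two basins counts once in
#' the total but in each basin column.
#'
#' @param records data frame from [load_outcomes()].
#' @param taxon taxon name as recorded.
#' @return List with `taxon`, `by_basin` (named integer vector over basins)
#'   and `total` (distinct study codes).
#' @export
#' @examples
#' tally_taxon(load_outcomes(), "Oithona similis")$total # 8
tally_taxon <- function(records, taxon) {
  if (!taxon %in% records$taxon) {
    stop(sprintf("unknown taxon '%s'", taxon), call. = FALSE)
  }
  mis <- records[records$taxon == taxon & records$outcome %in% c("fail", "bias"), ]
  by_basin <- vapply(.BASINS, function(b) {
    length(unique(mis$study_code[mis$ocean_basin == b]))
  }, integer(1))
  list(taxon = taxon, by_basin = by_basin,
       total = length(unique(mis$study_code)))
}

#' Metasynthesis summary of reported misperformance
#'
#' Computes the headline counts (taxa with at least one reported fail/bias,
#' overall and by group), the per-taxon study tallies, and the per-primer-
#' combination outcome matrices for the two focal taxa.
#'
#' @param records data frame from [load_outcomes()].
#' @return List with `n_taxa_misperforming`, `n_by_group`, `taxon_tally`
#'   (data frame), and `combination_matrix` (data frame: one row per
#'   combination x focal taxon with `reviewed`, `fail`, `bias`, `na`, `ok`).
#' @export
summarize_misperformance <- function(records) {
  stopifnot(nrow(records) > 0L)
  mis <- records[records$outcome %in% c("fail", "bias"), ]
  taxa <- unique(mis$taxon)
  grp <- vapply(taxa, function(t) mis$taxon_group[mis$taxon == t][1L], character(1))
  n_by_group <- vapply(.GROUPS, function(g) sum(grp == g), integer(1))

  taxon_tally <- do.call(rbind, lapply(taxa, function(t) {
    tl <- tally_taxon(records, t)
    cbind(data.frame(taxon = t, taxon_group = grp[[t]], stringsAsFactors = FALSE),
          as.data.frame(as.list(tl$by_basin)), total = tl$total)
  }))
  taxon_tally <- taxon_tally[order(-taxon_tally$total, taxon_tally$taxon), ]
  rownames(taxon_tally) <- NULL

  reviewed <- vapply(.COMBINATIONS, function(cb) {
    length(unique(records$study_code[records$primer_combination == cb]))
  }, integer(1))
  combination_matrix <- do.call(rbind, lapply(.FOCAL_TAXA, function(t) {
    do.call(rbind, lapply(.COMBINATIONS, function(cb) {
      sub <- records[records$taxon == t & records$primer_combination == cb, ]
      counts <- vapply(.OUTCOMES, function(o)
        length(unique(sub$study_code[sub$outcome == o])), integer(1))
      data.frame(taxon = t, combination = cb, reviewed = reviewed[[cb]],
                 fail = counts[["fail"]], bias = counts[["bias"]],
                 na = counts[["NA"]], ok = counts[["OK"]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(combination_matrix) <- NULL

  list(
    n_taxa_misperforming = length(taxa),
    n_by_group = n_by_group,
    taxon_tally = taxon_tally,
    combination_matrix = combination_matrix
  )
}
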