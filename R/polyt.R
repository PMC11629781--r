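# Homopolymer-run detection: poly-T inserts in the coding strand of
# appendicularian mitochondrial COI (poly-A on the non-coding strand) are
# tens to hundreds of nucleotides long and disrupt both amplification and
# sequencing; a run-length floor separates them from ordinary AT-rich COI.

#' Maximal homopolymer runs of a base
#'
#' @param seq concrete sequence string (empty gives an empty result).
#' @param base the nucleotide to scan for (default `"T"`).
#' @param min_len minimum run length to report (>= 2).
#' @return Data frame with 0-based `start` and `length` of every maximal run
#'   of `base` at least `min_len` long, ascending by `start`.
#' @export
#' @examples
#' find_runs(paste0("AC", strrep("T", 20), "GG"), min_len = 10)
find_runs <- function(seq, base = "T", min_len = 10L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (min_len < 2L) stop("min_len must be >= 2", call. = FALSE)
  base <- toupper(base)
  stopifnot(base %in% c("A", "C", "G", "T"))
  empty <- data.frame(start = integer(0), length = integer(0))
  if (nchar(seq) == 0L) return(empty)
  x <- toupper(strsplit(seq, "", fixed = TRUE)[[1L]])
  r <- rle(x == base)
  ends <- cumsum(r$lengths)
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(empty)
  data.frame(
    start = as.integer(ends[keep] - r$lengths[keep]),
    length = as.integer(r$lengths[keep])
  )
}

#' Scan a sequence for poly-T inserts
#'
#' Reports qualifying T-runs, the longest run, and whether any run intersects
#' a supplied amplicon span. Scanning is on the coding strand as supplied;
#' `scan_complement = TRUE` additionally scans for poly-A runs (the
#' non-coding-strand signature of the same insert).
#'
#' @param seq concrete sequence string.
#' @param amplicon_span optional 0-based half-open `c(start, end)` coordinates
#'   of the amplicon within `seq`.
#' @param min_len minimum run length (default 10: the insert floor of "tens of
#'   consecutive Ts"; reported inserts average about 140 nt).
#' @param id template identifier carried into the report.
#' @param scan_complement also report poly-A runs.
#' @return A `polyt_report` list: `template_id`, `runs` (data frame with
#'   `base`, `start`, `length`), `max_run`, `present`, `within_amplicon`
#'   (`NA` when no span given).
#' @export
scan_polyT <- function(seq, amplicon_span = NULL, min_len = 10L,
                       id = "sequence", scan_complement = FALSE) {
  runs <- find_runs(seq, "T", min_len)
  runs$base <- if (nrow(runs)) "T" else character(0)
  if (scan_complement) {
    runs_a <- find_runs(seq, "A", min_len)
    runs_a$base <- if (nrow(runs_a)) "A" else character(0)
    runs <- rbind(runs, runs_a)
    runs <- runs[order(runs$start), , drop = FALSE]
  }
  runs <- runs[, c("base", "start", "length"), drop = FALSE]
  rownames(runs) <- NULL

  within <- NA
  if (!is.null(amplicon_span)) {
    stopifnot(length(amplicon_span) == 2L)
    if (amplicon_span[1L] < 0L || amplicon_span[2L] > nchar(seq) ||
        amplicon_span[1L] > amplicon_span[2L]) {
      stop("amplicon span out of bounds", call. = FALSE)
    }
    within <- any(runs$start < amplicon_span[2L] &
                    runs$start + runs$length > amplicon_span[1L])
  }
  structure(
    list(
      template_id = id,
      runs = runs,
      max_run = if (nrow(runs)) max(runs$length) else 0L,
      present = nrow(runs) > 0L,
      within_amplicon = within
    ),
    class = "polyt_report"
  )
}

#' @export
print.polyt_report <- function(x, ...) {
  cat(sprintf("%s: %d run(s) >= threshold, max %d nt, present: %s\n",
              x$template_id, nrow(x$runs), x$max_run, x$present))
  invisible(x)
}
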