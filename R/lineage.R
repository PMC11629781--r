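# Haplotype-lineage analysis of primer-binding regions: variable-position
# detection, grouping by the tuple of bases at those positions, and the
# n-weighted summary statistics (mismatch ranges, 3'-terminal fractions,
# per-position mismatch counts).

# Regions -> character matrix (rows = regions, cols = positions).
.region_matrix <- function(regions) {
  if (inherits(regions, "template_region")) regions <- list(regions)
  bases <- vapply(regions, function(r) {
    if (inherits(r, "template_region")) r$bases else as.character(r)
  }, character(1))
  ids <- vapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    if (inherits(r, "template_region")) r$source_id else
      if (!is.null(names(regions))) names(regions)[i] else sprintf("seq%d", i)
  }, character(1))
  lens <- nchar(bases)
  if (length(unique(lens)) != 1L) {
    stop("regions have mixed lengths; align or trim them first", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(bases), "", fixed = TRUE))
  rownames(m) <- ids
  m
}

#' Variable (non-conserved) positions across equal-length regions
#'
#' A position is variable when its column holds more than one distinct
#' concrete base; `N` carries no information and never creates variability on
#' its own.
#'
#' @param regions list of [template_region()] objects or equal-length
#'   character sequences.
#' @return Ascending integer vector of 1-based positions.
#' @export
#' @examples
#' regs <- fixture_regions("oithona_similis")
#' find_variable_positions(regs) # 3 6 9 12 15 18 21 24
find_variable_positions <- function(regions) {
  m <- .region_matrix(regions)
  variable <- vapply(seq_len(ncol(m)), function(j) {
    obs <- unique(m[, j])
    length(setdiff(obs, "N")) > 1L
  }, logical(1))
  which(variable)
}

#' Group regions into haplotype lineages at given positions
#'
#' Partitions the regions by their tuple of bases at `positions`. Groups are
#' labelled `#I`, `#II`, ... in first-seen order of the input, so a documented
#' input ordering yields reproducible labels; reordering the input permutes
#' labels but never changes group contents or counts. Per-group mismatch
#' totals are computed with [profile_mismatches()] on each group's first
#' member (members of a group are expected to be identical across the full
#' region; a warning is raised otherwise).
#'
#' @inheritParams find_variable_positions
#' @param positions 1-based positions defining the haplotype (e.g. from
#'   [find_variable_positions()]).
#' @param primers named list of [degenerate_primer()]s to profile each lineage
#'   against (default: the two miniCOI forward primers).
#' @param policy an [inosine_policy()].
#' @return Data frame with columns `label`, `n`, one `p<k>` state column per
#'   position, and `total_<primer>` / `terminal3_<primer>` per primer;
#'   attribute `members` lists the region ids per group.
#' @export
group_by_haplotype <- function(regions, positions,
                               primers = minicoi_forward_primers(),
                               policy = inosine_policy()) {
  m <- .region_matrix(regions)
  if (length(positions) > 0L && max(positions) > ncol(m)) {
    stop("positions exceed region length", call. = FALSE)
  }
  keys <- if (length(positions) > 0L) {
    apply(m[, positions, drop = FALSE], 1L, paste, collapse = "")
  } else rep("", nrow(m))
  first_seen <- unique(keys)
  idx <- split(seq_len(nrow(m)), factor(keys, levels = first_seen))

  labels <- paste0("#", vapply(seq_along(idx), function(i)
    as.character(utils::as.roman(i)), character(1)))
  states <- do.call(rbind, lapply(idx, function(rows) m[rows[1L], positions, drop = TRUE]))
  out <- data.frame(label = labels, n = lengths(idx), stringsAsFactors = FALSE)
  if (length(positions) > 0L) {
    states <- matrix(states, nrow = length(idx))
    colnames(states) <- paste0("p", positions)
    out <- cbind(out, as.data.frame(states, stringsAsFactors = FALSE))
  }

  members <- lapply(idx, function(rows) rownames(m)[rows])
  uniform <- vapply(idx, function(rows) {
    length(unique(apply(m[rows, , drop = FALSE], 1L, paste, collapse = ""))) == 1L
  }, logical(1))
  if (!all(uniform)) {
    warning("some lineages vary outside the given positions; totals use each group's first member")
  }

  for (pn in names(primers)) {
    prof <- lapply(idx, function(rows) {
      profile_mismatches(primers[[pn]], paste(m[rows[1L], ], collapse = ""),
                         policy = policy)
    })
    out[[paste0("total_", pn)]] <- vapply(prof, function(p) p$total, integer(1))
    out[[paste0("terminal3_", pn)]] <- vapply(prof, function(p) p$terminal3_hit, logical(1))
  }
  rownames(out) <- NULL
  attr(out, "members") <- members
  attr(out, "positions") <- positions
  attr(out, "primers") <- names(primers)
  out
}

#' n-weighted per-position mismatch counts for a primer pair
#'
#' For each variable position, counts (weighting each lineage by its `n`) the
#' sequences whose base is incompatible with each primer, and reports whether
#' the two primers share an identical allowed set there (`shared_degeneracy`
#' implies equal counts).
#'
#' @param groups output of [group_by_haplotype()].
#' @param primer_pair list of two [degenerate_primer()]s (default: the miniCOI
#'   forward pair).
#' @param policy an [inosine_policy()].
#' @return Data frame: `position`, `observed_states`, `shared_degeneracy`, and
#'   one `mismatch_<primer>` column per primer.
#' @export
per_position_mismatch_counts <- function(groups,
                                         primer_pair = minicoi_forward_primers(),
                                         policy = inosine_policy()) {
  positions <- attr(groups, "positions")
  stopifnot(!is.null(positions))
  chars <- lapply(primer_pair, .primer_chars)
  out <- data.frame(position = positions)
  out$observed_states <- vapply(positions, function(p) {
    paste(sort(unique(groups[[paste0("p", p)]])), collapse = ",")
  }, character(1))
  out$shared_degeneracy <- vapply(positions, function(p) {
    sets <- lapply(chars, function(pc) .IUPAC_SETS[[pc[p]]])
    setequal(sets[[1L]], sets[[2L]])
  }, logical(1))
  for (pn in names(primer_pair)) {
    pc <- chars[[pn]]
    out[[paste0("mismatch_", pn)]] <- vapply(positions, function(p) {
      state <- groups[[paste0("p", p)]]
      mism <- !bases_compatible(rep(pc[p], length(state)), state, policy = policy)
      sum(groups$n[mism])
    }, integer(1))
  }
  out
}

# round half up to the nearest integer (printed-percentage convention)
.round_half_up <- function(x) floor(x + 0.5)

#' Summary statistics over haplotype lineages
#'
#' Per primer: the min/max lineage mismatch totals, the number of lineages
#' with a 3'-terminal-window mismatch, and the n-weighted percentage of
#' sequences affected by one (rounded half-up to an integer, the convention
#' used for printed percentages).
#'
#' @param groups output of [group_by_haplotype()].
#' @return List with `n_lineages`, `n_sequences` and a data frame `per_primer`.
#' @export
summarize_lineages <- function(groups) {
  stopifnot(nrow(groups) > 0L)
  primers <- attr(groups, "primers")
  per <- do.call(rbind, lapply(primers, function(pn) {
    tot <- groups[[paste0("total_", pn)]]
    term <- groups[[paste0("terminal3_", pn)]]
    data.frame(
      primer = pn,
      min_total = min(tot),
      max_total = max(tot),
      lineages_terminal3 = sum(term),
      sequences_terminal3 = sum(groups$n[term]),
      pct_sequences_terminal3 = .round_half_up(100 * sum(groups$n[term]) / sum(groups$n)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per) <- NULL
  list(n_lineages = nrow(groups), n_sequences = sum(groups$n), per_primer = per)
}

#' Uncorrected pairwise distance between two aligned sequences
#'
#' Proportion of differing sites among comparable sites; sites where either
#' sequence is not a concrete base (`N`, gaps, ambiguity codes) are excluded
#' from the denominator.
#'
#' @param a,b equal-length sequence strings (caller aligns/trims).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' p_distance("ACGT", "TGCA") # 1
p_distance <- function(a, b) {
  xa <- toupper(strsplit(a, "", fixed = TRUE)[[1L]])
  xb <- toupper(strsplit(b, "", fixed = TRUE)[[1L]])
  if (length(xa) != length(xb)) stop("sequences differ in length", call. = FALSE)
  conc <- c("A", "C", "G", "T")
  comparable <- xa %in% conc & xb %in% conc
  if (!any(comparable)) stop("no comparable sites", call. = FALSE)
  sum(xa[comparable] != xb[comparable]) / sum(comparable)
}
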