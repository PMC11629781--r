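# Independent oracles used by the property tests. These deliberately avoid
# the package's matching code paths: compatibility is re-derived by explicit
# enumeration of concrete primer expansions.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T")
)

# All concrete expansions of a degenerate sequence (rows of a matrix).
enumerate_expansions <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  sets <- lapply(chars, function(s) IUPAC_ORACLE[[s]])
  as.matrix(rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

# Minimum Hamming distance between a concrete region and any expansion.
min_hamming_to_expansions <- function(primer_seq, region_seq) {
  exp <- enumerate_expansions(primer_seq)
  reg <- strsplit(toupper(region_seq), "", fixed = TRUE)[[1L]]
  min(apply(exp, 1L, function(row) sum(row != reg)))
}

# Exhaustive sliding-window minimum-mismatch locator (position, score),
# 0-based start, compatibility by expansion enumeration per window column.
brute_force_locate <- function(template, primer_seq) {
  tchars <- strsplit(toupper(template), "", fixed = TRUE)[[1L]]
  pchars <- strsplit(toupper(primer_seq), "", fixed = TRUE)[[1L]]
  L <- length(pchars)
  scores <- vapply(seq_len(length(tchars) - L + 1L), function(s) {
    sum(vapply(seq_len(L), function(p) {
      !tchars[s + p - 1L] %in% IUPAC_ORACLE[[pchars[p]]]
    }, logical(1)))
  }, numeric(1))
  best <- which.min(scores)
  c(start = best - 1L, score = scores[best])
}

# Random degenerate primer with bounded expansion count (<= 2^12).
random_degenerate_primer <- function(len = 12L, name = "rnd") {
  codes <- names(IUPAC_ORACLE)
  repeat {
    s <- paste(sample(codes, len, replace = TRUE,
                      prob = c(rep(4, 4), rep(1.5, 6), rep(0.5, 4), 0.5, 0.5)),
               collapse = "")
    n_exp <- prod(lengths(lapply(strsplit(s, "")[[1L]], function(x) IUPAC_ORACLE[[x]])))
    if (n_exp <= 2^12) return(degenerate_primer(name, s, "forward"))
  }
}

random_concrete_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
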