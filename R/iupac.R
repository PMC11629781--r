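# IUPAC + inosine alphabet semantics.
#
# The matching convention throughout the package: a primer symbol is compatible
# with a template symbol iff their sets of concrete bases intersect. Inosine (I)
# is treated as a universal base pairing with A, C, G and T; the known stability
# ordering I-C > I-A > I-T ~ I-G is carried as metadata only and never changes a
# match/mismatch verdict.

# Allowed concrete bases per symbol. Inosine alongside the 15 IUPAC codes.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"),
  I = c("A", "C", "G", "T")
)

.ALPHABET <- names(.IUPAC_SETS)

# Complements follow IUPAC (W<->W, S<->S, R<->Y, K<->M, B<->V, D<->H, N<->N);
# the complement of inosine is taken as inosine.
.COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", I = "I"
)

# 16 x 16 logical compatibility lookup, built once at load.
.COMPAT <- local({
  n <- length(.ALPHABET)
  m <- matrix(FALSE, n, n, dimnames = list(.ALPHABET, .ALPHABET))
  for (a in .ALPHABET) {
    for (b in .ALPHABET) {
      m[a, b] <- length(intersect(.IUPAC_SETS[[a]], .IUPAC_SETS[[b]])) > 0L
    }
  }
  m
})

.check_symbols <- function(x, what = "sequence") {
  bad <- setdiff(unique(x), .ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf(
      "unknown symbol(s) in %s: %s (allowed: %s)",
      what, paste(bad, collapse = ", "), paste(.ALPHABET, collapse = "")
    ), call. = FALSE)
  }
  invisible(x)
}

# Split a sequence string into uppercase symbols, mapping U -> T.
.seq_chars <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- toupper(strsplit(seq, "", fixed = TRUE)[[1L]])
  x[x == "U"] <- "T"
  .check_symbols(x, what)
  x
}

#' Inosine policy
#'
#' Constructs the policy object controlling how inosine (I) is interpreted.
#' Under both modes inosine matches all four bases; `"ranked"` additionally
#' carries the duplex-stability ordering I-C > I-A > I-T ~ I-G as metadata for
#' reports, without ever changing a match/mismatch verdict.
#'
#' @param mode `"universal"` (default) or `"ranked"`.
#' @return An object of class `inosine_policy`.
#' @export
#' @examples
#' inosine_policy()
#' inosine_policy("ranked")$ranking
inosine_policy <- function(mode = c("universal", "ranked")) {
  mode <- match.arg(mode)
  structure(
    list(
      mode = mode,
      ranking = if (mode == "ranked") c("C", "A", "T", "G") else NULL
    ),
    class = "inosine_policy"
  )
}

.as_policy <- function(policy) {
  if (inherits(policy, "inosine_policy")) return(policy)
  inosine_policy(policy)
}

#' Concrete bases allowed by an IUPAC (or inosine) symbol
#'
#' @param code a single symbol from `ACGTRYSWKMBDHVNI` (case-insensitive;
#'   `U` is folded to `T`).
#' @param policy an [inosine_policy()] or its mode string. Both policies give
#'   inosine the full set `{A,C,G,T}`.
#' @return Character vector of concrete bases.
#' @export
#' @examples
#' allowed_bases("W") # A T
#' allowed_bases("I") # A C G T
allowed_bases <- function(code, policy = inosine_policy()) {
  .as_policy(policy)
  x <- .seq_chars(code, what = "code")
  if (length(x) != 1L) stop("'code' must be a single symbol", call. = FALSE)
  .IUPAC_SETS[[x]]
}

#' Are a primer symbol and a template symbol compatible?
#'
#' Compatibility is set intersection: the symbols are compatible iff they share
#' at least one concrete base. The template side may itself be ambiguous (e.g.
#' `N` in user-supplied sequence), in which case it matches any primer symbol.
#' Vectorised over equal-length inputs.
#'
#' @param primer_code,template_code symbols (or equal-length symbol vectors).
#' @param policy an [inosine_policy()]; see there.
#' @return Logical vector.
#' @export
#' @examples
#' bases_compatible("W", "A") # TRUE
#' bases_compatible("Y", "A") # FALSE
#' bases_compatible("R", "G") # TRUE
bases_compatible <- function(primer_code, template_code,
                             policy = inosine_policy()) {
  .as_policy(policy)
  p <- toupper(primer_code)
  t <- toupper(template_code)
  p[p == "U"] <- "T"
  t[t == "U"] <- "T"
  .check_symbols(p, "primer code")
  .check_symbols(t, "template code")
  if (length(p) != length(t)) {
    if (length(p) == 1L) p <- rep(p, length(t))
    else if (length(t) == 1L) t <- rep(t, length(p))
    else stop("primer and template code vectors differ in length", call. = FALSE)
  }
  unname(.COMPAT[cbind(p, t)])
}

#' Reverse complement of a (possibly degenerate) sequence
#'
#' Complements of ambiguity codes follow IUPAC; the complement of inosine is
#' inosine. The operation is an involution and preserves length.
#'
#' @param seq a single sequence string over the IUPAC + inosine alphabet.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("GATC")   # "GATC"
#' reverse_complement("TAAACT") # "AGTTTA"
reverse_complement <- function(seq) {
  x <- .seq_chars(seq)
  paste(rev(unname(.COMPLEMENT[x])), collapse = "")
}

#' @export
print.inosine_policy <- function(x, ...) {
  cat("inosine policy:", x$mode, "\n")
  if (!is.null(x$ranking)) {
    cat("  stability ranking I-", paste(x$ranking, collapse = " > I-"),
        " (metadata only)\n", sep = "")
  }
  invisible(x)
}
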