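DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate codes keyed by sorted base combination, e.g. "AG" -> "R"
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` strings.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

# reverse complement of an L x 4 count/probability matrix (columns A,C,G,T):
# reverse row order and swap A<->T, C<->G
revcomp_matrix <- function(m) {
  m[rev(seq_len(nrow(m))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

# consensus string from an L x 4 count matrix; ties become IUPAC codes
consensus_from_counts <- function(counts, tie_tol = 1e-9) {
  vapply(seq_len(nrow(counts)), function(i) {
    row <- counts[i, ]
    top <- max(row)
    hit <- DNA_BASES[row >= top - tie_tol]
    IUPAC_CODES[[paste(sort(hit), collapse = "")]]
  }, character(1))
}

# per-column information content (bits) of a count matrix after pseudocounts
column_information <- function(counts, pseudocount = 0.25) {
  p <- (counts + pseudocount) / rowSums(counts + pseudocount)
  2 + rowSums(ifelse(p > 0, p * log2(p), 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# van der Waerden normal scores: a rank-based z-normalization robust to the
# heavy tails of pooled enrichment/shape scores; monotone, so it preserves
# each score's own ranking. NAs map to 0 (scoreless words stay neutral).
normal_scores <- function(x) {
  out <- rep(0, length(x))
  ok <- !is.na(x)
  if (sum(ok) > 1 && stats::sd(x[ok]) > 0) {
    out[ok] <- stats::qnorm(rank(x[ok], ties.method = "average") /
                              (sum(ok) + 1))
  }
  out
}

stop_input <- function(msg) abort(msg, class = "motifshape_input_error")
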