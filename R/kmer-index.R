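#' Index every k-mer occurrence in a set of regions
#'
#' Counts and locates all length-`K` words across the input regions.
#' Windows containing `N` (or lowercase masked bases, when sequences were
#' loaded with `mask_lowercase = TRUE`) are excluded. With
#' `strand_mode = "both"` each position is also read on the reverse
#' complement strand and recorded, as a minus-strand occurrence, under the
#' word given by that reading; a word and its reverse complement are
#' therefore separate keys whose counts each pool both strands.
#'
#' @param regions Regions tibble (see [read_regions_fasta()]).
#' @param K Word length.
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @return An object of class `"kmer_index"` with elements `K`,
#'   `strand_mode`, `occurrences` (tibble `kmer`, `region`, `offset`,
#'   `strand`; offsets 0-based), `counts` (tibble `kmer`, `count`) and
#'   `n_positions` (number of indexable window positions per strand).
#' @export
#' @examples
#' idx <- kmer_index(regions_from_sequences("AAAA"), K = 2, strand_mode = "forward")
#' kmer_count(idx, "AA")
kmer_index <- function(regions, K, strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop_input("`K` must be >= 1")
  if (nrow(regions) == 0) stop_input("`regions` is empty")
  occ <- scan_words(regions$sequence, K)
  if (nrow(occ) == 0) {
    warn(paste0("K = ", K, " exceeds every region length; index is empty"))
  }
  if (strand_mode == "both" && nrow(occ) > 0) {
    minus <- occ
    minus$kmer <- revcomp(minus$kmer)
    minus$strand <- "-"
    occ <- bind_rows(occ, minus)
  }
  r <- rle(sort(occ$kmer, method = "radix"))
  counts <- tibble(kmer = r$values, count = r$lengths)
  structure(
    list(
      K = K, strand_mode = strand_mode, occurrences = occ, counts = counts,
      n_positions = sum(pmax(0L, nchar(regions$sequence) - K + 1L))
    ),
    class = "kmer_index"
  )
}

# vectorised forward-strand window scan; drops windows with non-ACGT chars
scan_words <- function(sequences, K) {
  kmers <- vector("list", length(sequences))
  offsets <- vector("list", length(sequences))
  for (ri in seq_along(sequences)) {
    n <- nchar(sequences[ri])
    if (n < K) next
    starts <- seq_len(n - K + 1L)
    words <- substring(sequences[ri], starts, starts + K - 1L)
    ok <- !grepl("[^ACGT]", words)
    if (!any(ok)) next
    kmers[[ri]] <- words[ok]
    offsets[[ri]] <- starts[ok] - 1L
  }
  lens <- lengths(kmers)
  tibble(
    kmer = unlist(kmers, use.names = FALSE) %||% character(0),
    region = rep(seq_along(sequences), lens),
    offset = unlist(offsets, use.names = FALSE) %||% integer(0),
    strand = rep("+", sum(lens))
  )
}

#' Count of one word in an index
#'
#' @param index A `"kmer_index"`.
#' @param word A word of length `index$K`.
#' @return Integer count (0 if absent).
#' @export
kmer_count <- function(index, word) {
  hit <- index$counts$count[index$counts$kmer == word]
  if (length(hit) == 0) 0L else hit[[1]]
}

#' Locate all occurrences of a word
#'
#' @param index A `"kmer_index"`.
#' @param word A word of length `index$K`; words containing `N` (never
#'   indexed) return an empty tibble.
#' @return Tibble with `region`, `offset`, `strand`.
#' @export
locate_kmer <- function(index, word) {
  if (nchar(word) != index$K) {
    stop_input(paste0("`word` must have length K = ", index$K))
  }
  index$occurrences %>%
    filter(.data$kmer == word) %>%
    select("region", "offset", "strand") %>%
    arrange(.data$region, .data$offset, .data$strand)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf(
    "<kmer_index> K=%d, %s strand(s): %d distinct words, %d occurrences\n",
    x$K, x$strand_mode, nrow(x$counts), nrow(x$occurrences)
  ))
  invisible(x)
}
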