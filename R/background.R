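#' Fit a Markov background model from target regions
#'
#' Maximum-likelihood base (order 0) or transition (order 1) frequencies
#' with add-one smoothing over unobserved states; `N` bases break the chain
#' and contribute nothing.
#'
#' @param regions Regions tibble.
#' @param order 0 or 1.
#' @return An object of class `"markov_background"` with `order`,
#'   `initial_probs` (named length-4), `transition_probs` (4x4 row-stochastic,
#'   `NULL` for order 0) and `source`.
#' @export
fit_background <- function(regions, order = 1L) {
  order <- as.integer(order)
  if (!order %in% c(0L, 1L)) stop_input("`order` must be 0 or 1")
  if (nrow(regions) == 0 || sum(nchar(regions$sequence)) == 0) {
    stop_input("cannot fit a background on empty input")
  }
  codes <- lapply(regions$sequence, encode_bases)
  base_counts <- rowSums(vapply(
    codes, function(cd) tabulate(cd, nbins = 4L), numeric(4)
  ))
  initial <- (base_counts + 1) / sum(base_counts + 1)
  names(initial) <- DNA_BASES
  transition <- NULL
  if (order == 1L) {
    tc <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    for (cd in codes) {
      if (length(cd) < 2) next
      a <- cd[-length(cd)]
      b <- cd[-1]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      tc <- tc + matrix(tabulate((a[ok] - 1L) * 4L + b[ok], nbins = 16L),
                        4, 4, byrow = TRUE)
    }
    transition <- (tc + 1) / rowSums(tc + 1)
  }
  structure(
    list(order = order, initial_probs = initial, transition_probs = transition,
         source = "target-regions"),
    class = "markov_background"
  )
}

encode_bases <- function(seq) {
  cd <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  cd
}

#' Simulate background sequence sets
#'
#' Draws `n_simulations` sets of sequences from a Markov background, each
#' set reproducing exactly the region-length multiset of the input. Each
#' region restarts the chain from the initial distribution.
#'
#' @param bg A `"markov_background"`.
#' @param lengths Integer vector of region lengths to reproduce.
#' @param n_simulations Number of independent sets.
#' @param seed Integer seed (local to this call).
#' @return List of length `n_simulations`; each element a character vector
#'   of sequences with lengths `lengths`.
#' @export
simulate_background <- function(bg, lengths, n_simulations = 5L, seed = 1L) {
  if (n_simulations < 1) stop_input("`n_simulations` must be >= 1")
  lengths <- as.integer(lengths)
  total <- sum(lengths)
  init_cum <- cumsum(bg$initial_probs)
  trans_cum <- if (is.null(bg$transition_probs)) {
    matrix(1, 4, 4)
  } else {
    t(apply(bg$transition_probs, 1, cumsum))
  }
  restarts <- cumsum(c(1L, lengths[-length(lengths)]))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n_simulations), function(s) {
    codes <- markov_sample_codes(
      stats::runif(total), init_cum, trans_cum, restarts, bg$order
    )
    long <- paste(DNA_BASES[codes], collapse = "")
    ends <- cumsum(lengths)
    substring(long, ends - lengths + 1L, ends)
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Over-representation p-value of a word count
#'
#' Word counts are modelled as Poisson with mean `lambda` (the simulated
#' average count). For large `lambda` the upper tail `P(WC >= wc)` uses the
#' Gaussian approximation `1 - pnorm((wc - lambda)/sqrt(lambda))`, which is
#' valid for means above ~10 but only agrees with the exact tail to within
#' 0.02 once `lambda` exceeds `gaussian_cutoff`; below the cutoff the exact
#' Poisson tail is used. Self-overlap of words is deliberately not
#' corrected for.
#'
#' @param wc Observed count(s), `>= 0`.
#' @param lambda Expected count(s), `> 0`.
#' @param gaussian_cutoff Mean above which the Gaussian approximation is
#'   used (default 50).
#' @return P-value vector.
#' @export
#' @examples
#' overrepresentation_pvalue(100, 100) # 0.5 under the Gaussian approximation
overrepresentation_pvalue <- function(wc, lambda, gaussian_cutoff = 50) {
  if (any(wc < 0) || any(lambda <= 0)) {
    stop_input("`wc` must be >= 0 and `lambda` > 0")
  }
  n <- max(length(wc), length(lambda))
  wc <- rep_len(wc, n)
  lambda <- rep_len(lambda, n)
  ifelse(
    lambda > gaussian_cutoff,
    stats::pnorm((wc - lambda) / sqrt(lambda), lower.tail = FALSE),
    stats::ppois(wc - 1, lambda, lower.tail = FALSE)
  )
}

#' Expected background counts and over-representation statistics
#'
#' Counts every indexed word in each simulated background set (with the
#' same strand handling as the index), averages to `lambda`, and derives
#' the p-value and odds ratio `S_W = wc / lambda`. Words never seen in any
#' simulation have `lambda` floored at 0.5 so `S_W` stays finite.
#'
#' @param index A `"kmer_index"` of the target regions.
#' @param simulations List of simulated sequence sets from
#'   [simulate_background()].
#' @return Tibble with `kmer`, `wc`, `lambda`, `pvalue`, `S_W`, sorted by
#'   `S_W` descending.
#' @export
kmer_enrichment <- function(index, simulations) {
  sim_counts <- lapply(simulations, function(seqs) {
    count_words_forward(seqs, index$K)
  })
  words <- index$counts$kmer
  rc_words <- if (index$strand_mode == "both") revcomp(words) else NULL
  lam <- rowMeans(vapply(
    sim_counts,
    function(tab) {
      v <- tab[words]
      v[is.na(v)] <- 0
      if (!is.null(rc_words)) { # both-strand counts pool both readings
        v2 <- tab[rc_words]
        v2[is.na(v2)] <- 0
        v <- v + v2
      }
      unname(v)
    },
    numeric(length(words))
  ))
  lam <- ifelse(lam == 0, 0.5, lam)
  tibble(
    kmer = words,
    wc = index$counts$count,
    lambda = lam,
    pvalue = overrepresentation_pvalue(index$counts$count, lam),
    S_W = index$counts$count / lam
  ) %>%
    arrange(desc(.data$S_W))
}

# forward-strand count-only scan used for simulated sets;
# returns a named integer vector
count_words_forward <- function(sequences, K) {
  words <- unlist(lapply(sequences, function(sq) {
    n <- nchar(sq)
    if (n < K) return(character(0))
    starts <- seq_len(n - K + 1L)
    w <- substring(sq, starts, starts + K - 1L)
    w[!grepl("[^ACGT]", w)]
  }), use.names = FALSE)
  if (length(words) == 0) return(integer(0))
  r <- rle(sort(words, method = "radix"))
  stats::setNames(r$lengths, r$values)
}

#' Select candidate seeds by over-representation
#'
#' Words with `pvalue < threshold`, ordered by decreasing odds ratio `S_W`
#' (the sequence-only ranking; signal-feature scoring may re-rank them).
#' No multiple-testing correction is applied; the threshold is meant to be
#' small.
#'
#' @param enrichment Tibble from [kmer_enrichment()].
#' @param pvalue_threshold Cutoff.
#' @param max_candidates Optional cap on the number of candidates kept
#'   (top of the `S_W` ranking).
#' @return Filtered, ordered tibble.
#' @export
select_candidates <- function(enrichment, pvalue_threshold = 1e-6,
                              max_candidates = Inf) {
  out <- enrichment %>%
    filter(.data$pvalue < pvalue_threshold) %>%
    arrange(desc(.data$S_W))
  if (is.finite(max_candidates) && nrow(out) > max_candidates) {
    out <- out[seq_len(max_candidates), ]
  }
  out
}
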