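#' Aggregate a signal track around all occurrences of a word
#'
#' For every occurrence, per-bp signal in the window
#' `[centre - halfwidth, centre + halfwidth)` around the occurrence midpoint
#' (`offset + floor(K/2)` in genomic coordinates) is collected; minus-strand
#' windows are reversed so profiles align in motif orientation; windows are
#' summed into `bin_width`-bp bins and then across occurrences. Positions
#' outside the track's covered range contribute 0.
#'
#' @param occurrences Tibble with `region`, `offset`, `strand` (e.g. from
#'   [locate_kmer()]).
#' @param regions Regions tibble carrying genomic coordinates.
#' @param track A `"signal_track"`.
#' @param K Word length (defines the occurrence midpoint).
#' @param halfwidth Window half-width in bp (multiple of `bin_width`).
#' @param bin_width Bin width in bp.
#' @param word Optional word label.
#' @return An object of class `"mark_distribution"`: `word`, `track_name`,
#'   `bins` (raw aggregate), `normalized`, `smoothed` (filled by
#'   [normalize_and_smooth()]), `bin_width`, `halfwidth`,
#'   `n_occurrences_used`.
#' @export
mark_distribution <- function(occurrences, regions, track, K,
                              halfwidth = 1000L, bin_width = 25L,
                              word = NA_character_) {
  if (nrow(occurrences) == 0) {
    stop_input("unscorable word: no occurrences to aggregate")
  }
  if (halfwidth %% bin_width != 0) {
    stop_input("`halfwidth` must be a multiple of `bin_width`")
  }
  if (any(is.na(regions$chrom[occurrences$region]))) {
    stop_input("regions lack genomic coordinates; cannot map onto the track")
  }
  W <- 2L * halfwidth
  B <- W %/% bin_width
  centres <- regions$start[occurrences$region] + occurrences$offset + K %/% 2L
  chroms <- regions$chrom[occurrences$region]
  minus <- occurrences$strand == "-"
  profile_bp <- numeric(W)
  for (ch in unique(chroms)) {
    vec <- track$values[[ch]] %||% numeric(0)
    len <- length(vec)
    sel <- which(chroms == ch)
    for (block in split(sel, ceiling(seq_along(sel) / 2000))) {
      starts <- centres[block] - halfwidth
      idx <- outer(starts, 0:(W - 1L), "+") + 1L # 0-based pos -> R index
      vals <- matrix(0, nrow = length(block), ncol = W)
      ok <- idx >= 1L & idx <= len
      vals[ok] <- vec[idx[ok]]
      mb <- minus[block]
      if (any(!mb)) profile_bp <- profile_bp + colSums(vals[!mb, , drop = FALSE])
      if (any(mb)) profile_bp <- profile_bp + rev(colSums(vals[mb, , drop = FALSE]))
    }
  }
  bins <- colSums(matrix(profile_bp, nrow = bin_width))
  structure(
    list(
      word = word, track_name = track$name, bins = bins,
      normalized = NULL, smoothed = NULL,
      bin_width = as.integer(bin_width), halfwidth = as.integer(halfwidth),
      n_occurrences_used = nrow(occurrences)
    ),
    class = "mark_distribution"
  )
}

#' Normalize and DFT-smooth a mark distribution
#'
#' The raw profile is normalized to unit mass, then smoothed by zeroing the
#' highest-frequency components of its discrete Fourier transform
#' (conjugate pairs kept together; the DC component is always retained),
#' flooring negative ringing at 0 and renormalizing.
#'
#' @param md A `"mark_distribution"`.
#' @param remove_frac Fraction of the `B/2` positive frequencies removed
#'   (default 5/8).
#' @return `md` with `normalized` and `smoothed` filled.
#' @export
normalize_and_smooth <- function(md, remove_frac = 5 / 8) {
  bins <- md$bins
  B <- length(bins)
  if (B %% 2L != 0L) stop_input("mark distribution needs an even bin count")
  if (all(bins == 0)) {
    warn(paste0("all-zero mark distribution for word ", md$word,
                "; falling back to uniform"))
    md$normalized <- rep(1 / B, B)
    md$smoothed <- rep(1 / B, B)
    return(md)
  }
  md$normalized <- bins / sum(bins)
  md$smoothed <- dft_smooth(md$normalized, remove_frac)
  md
}

dft_smooth <- function(x, remove_frac) {
  B <- length(x)
  n_remove <- ceiling(remove_frac * (B / 2))
  max_keep <- max(0L, B %/% 2L - n_remove) # highest retained frequency
  freq <- pmin(0:(B - 1L), B - (0:(B - 1L)))
  ft <- stats::fft(x)
  ft[freq > max_keep] <- 0
  sm <- Re(stats::fft(ft, inverse = TRUE)) / B
  sm <- pmax(sm, 0)
  if (sum(sm) == 0) rep(1 / B, B) else sm / sum(sm)
}

#' Intensity score of a mark distribution
#'
#' Mean total window signal per occurrence: the sum of the raw aggregated
#' profile divided by the number of occurrences.
#'
#' @param md A `"mark_distribution"`.
#' @return Numeric scalar.
#' @export
intensity_score <- function(md) {
  if (md$n_occurrences_used < 1) stop_input("no occurrences used")
  sum(md$bins) / md$n_occurrences_used
}

#' Kurtosis score of a mark distribution
#'
#' Excess kurtosis of the smoothed profile treated as a probability mass
#' function over bin-centre positions: `mu4 / mu2^2 - 3`. Sharply peaked
#' profiles score high; a flat profile scores about -1.2. A zero-variance
#' profile (all mass in one bin) is capped at `cap`.
#'
#' @param md A `"mark_distribution"` with `smoothed` filled.
#' @param cap Value returned for zero-variance profiles.
#' @return Numeric scalar.
#' @export
kurtosis_score <- function(md, cap = 50) {
  f <- md$smoothed
  if (is.null(f)) stop_input("call `normalize_and_smooth()` first")
  x <- seq_along(f)
  mu <- sum(f * x)
  m2 <- sum(f * (x - mu)^2)
  if (m2 <= .Machine$double.eps * length(f)) return(cap)
  m4 <- sum(f * (x - mu)^4)
  min(cap, m4 / m2^2 - 3)
}

#' Asymmetry score of a mark distribution
#'
#' Symmetrized Kullback-Leibler divergence (nats) between the left half of
#' the smoothed profile and the mirrored right half, each renormalized with
#' a small pseudo-mass. A profile symmetric about the window centre scores
#' 0; irregular, repeat-like profiles score high.
#'
#' @param md A `"mark_distribution"` with `smoothed` filled.
#' @param eps Pseudo-mass added per bin before renormalization.
#' @return Numeric scalar (`NA` when either half carries no mass at all).
#' @export
asymmetry_score <- function(md, eps = 1e-6) {
  f <- md$smoothed
  if (is.null(f)) stop_input("call `normalize_and_smooth()` first")
  B <- length(f)
  h <- B %/% 2L
  lhs <- f[seq_len(h)]
  rhs <- rev(f[(h + 1L):B]) # mirror: both halves read outward from centre
  if (sum(lhs) == 0 || sum(rhs) == 0) return(NA_real_)
  p <- lhs / sum(lhs)
  q <- rhs / sum(rhs)
  p <- (p + eps) / (1 + h * eps)
  q <- (q + eps) / (1 + h * eps)
  0.5 * sum(p * log(p / q)) + 0.5 * sum(q * log(q / p))
}

#' Score candidate seeds by combining over-representation and signal shape
#'
#' For every candidate word and every track, the word's mark distribution is
#' aggregated, smoothed, and reduced to intensity, kurtosis and asymmetry
#' sub-scores. Because the four scores live on incommensurable scales, each
#' sub-score - including the odds ratio `S_W`, whose spread across
#' candidates is data- and dataset-scale-dependent and heavy-tailed - is
#' mapped to normal scores (a rank-based z-normalization, van der Waerden)
#' across the candidate set, per track for the signal features, averaged
#' across tracks, and combined linearly:
#' `S = zS_W + beta_I * zS_I + beta_K * zS_K - beta_A * zS_A`
#' (asymmetry is penalised, so all weights are non-negative). Because the
#' normal-scores map is monotone, zero weights reproduce the pure `S_W`
#' ranking. With no tracks, `S = S_W` (sequence-only mode).
#'
#' @param candidates Tibble from [select_candidates()].
#' @param index The `"kmer_index"` the candidates came from.
#' @param regions Regions tibble with genomic coordinates.
#' @param tracks List of `"signal_track"` objects (possibly empty).
#' @param config A [motif_config()].
#' @return An object of class `"seed_scores"`: `$scores` (tibble `kmer`,
#'   `wc`, `lambda`, `pvalue`, `S_W`, z-averaged `S_I`, `S_K`, `S_A`, and
#'   combined `S`, sorted by `S` descending), `$features` (long tibble of
#'   raw per-track sub-scores with the smoothed profile as a list column)
#'   and `$weights`.
#' @export
score_seeds <- function(candidates, index, regions, tracks, config) {
  scores <- candidates
  if (length(tracks) == 0 || nrow(candidates) == 0) {
    scores <- scores %>%
      mutate(S_I = NA_real_, S_K = NA_real_, S_A = NA_real_, S = .data$S_W) %>%
      arrange(desc(.data$S))
    return(structure(
      list(scores = scores, features = NULL,
           weights = c(beta_I = 0, beta_K = 0, beta_A = 0)),
      class = "seed_scores"
    ))
  }
  feats <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    word <- candidates$kmer[i]
    occ <- locate_kmer(index, word)
    purrr::map_dfr(tracks, function(tr) {
      md <- mark_distribution(
        occ, regions, tr, K = index$K,
        halfwidth = config$profile_halfwidth, bin_width = config$bin_width,
        word = word
      )
      md <- normalize_and_smooth(md, config$smooth_remove_frac)
      tibble(
        kmer = word, track = tr$name,
        S_I = intensity_score(md),
        S_K = kurtosis_score(md),
        S_A = asymmetry_score(md),
        smoothed = list(md$smoothed)
      )
    })
  })
  zfeats <- feats %>%
    group_by(.data$track) %>%
    mutate(zI = normal_scores(.data$S_I), zK = normal_scores(.data$S_K),
           zA = normal_scores(.data$S_A)) %>%
    ungroup() %>%
    group_by(.data$kmer) %>%
    summarise(
      S_I = mean(.data$zI), S_K = mean(.data$zK), S_A = mean(.data$zA),
      .groups = "drop"
    )
  scores <- candidates %>%
    left_join(zfeats, by = "kmer") %>%
    mutate(
      S = normal_scores(.data$S_W) + config$beta_I * .data$S_I +
        config$beta_K * .data$S_K - config$beta_A * .data$S_A
    ) %>%
    arrange(desc(.data$S), desc(.data$S_W))
  structure(
    list(
      scores = scores, features = feats,
      weights = c(beta_I = config$beta_I, beta_K = config$beta_K,
                  beta_A = config$beta_A)
    ),
    class = "seed_scores"
  )
}

#' @export
print.seed_scores <- function(x, ...) {
  cat(sprintf("<seed_scores> %d candidate words\n", nrow(x$scores)))
  print(utils::head(x$scores, 10))
  invisible(x)
}
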