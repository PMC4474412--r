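#' Scan regions for motif occurrences
#'
#' Sliding-window log-odds scoring (`log2` of motif probability over
#' order-0 background probability, summed over columns) on both strands.
#' Windows scoring at least `threshold` are reported; overlapping sites of
#' the same motif are greedily resolved to the best-scoring one
#' (overlapping sites of different motifs are kept - co-factors co-occur).
#'
#' @param motifs List of `"pfm_motif"` objects.
#' @param regions Regions tibble.
#' @param background Length-4 background base frequencies (A,C,G,T) or a
#'   `"markov_background"` (its order-0 marginals are used). Default
#'   uniform.
#' @param threshold Numeric score threshold, or `NULL` to use
#'   `threshold_frac` of each motif's maximum attainable score.
#' @param threshold_frac Per-motif fractional threshold used when
#'   `threshold` is `NULL`.
#' @param resolve_overlaps Greedily resolve overlapping same-motif sites
#'   (default `TRUE`).
#' @param pseudocount Pseudocount for motif probabilities.
#' @return Tibble of predicted sites: `region_id`, `chrom`, `start`, `end`
#'   (genomic 0-based half-open when region coordinates exist, else
#'   region-local), `strand`, `motif_id`, `score` (log-odds bits),
#'   `score_frac` (fraction of the motif's maximum score).
#' @export
scan_sites <- function(motifs, regions, background = rep(0.25, 4),
                       threshold = NULL, threshold_frac = 0.7,
                       pseudocount = 0.25, resolve_overlaps = TRUE) {
  if (inherits(background, "markov_background")) {
    background <- background$initial_probs
  }
  background <- background / sum(background)
  encoded <- lapply(regions$sequence, encode_bases)
  out <- vector("list", length(motifs))
  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    lom <- log2(motif_probabilities(m, pseudocount)) -
      matrix(log2(background), nrow = nrow(m$counts), ncol = 4, byrow = TRUE)
    lom_rc <- revcomp_matrix(lom)
    L <- nrow(lom)
    max_score <- sum(apply(lom, 1, max))
    thr <- threshold %||% (threshold_frac * max_score)
    hits <- vector("list", nrow(regions))
    for (ri in seq_len(nrow(regions))) {
      cd <- encoded[[ri]]
      n <- length(cd)
      if (n < L) next
      np <- n - L + 1L
      fwd <- numeric(np)
      rev_ <- numeric(np)
      bad <- logical(np)
      for (i in seq_len(L)) {
        b <- cd[i:(i + np - 1L)]
        na <- is.na(b)
        bad <- bad | na
        b[na] <- 1L
        fwd <- fwd + lom[i, b]
        rev_ <- rev_ + lom_rc[i, b]
      }
      fwd[bad] <- -Inf
      rev_[bad] <- -Inf
      keep_f <- which(fwd >= thr)
      keep_r <- which(rev_ >= thr)
      if (length(keep_f) + length(keep_r) == 0) next
      cand <- tibble(
        offset = c(keep_f, keep_r) - 1L,
        strand = c(rep("+", length(keep_f)), rep("-", length(keep_r))),
        score = unname(c(fwd[keep_f], rev_[keep_r]))
      )
      if (resolve_overlaps) {
        cand <- cand[order(-cand$score, cand$offset), ]
        taken <- rep(FALSE, n)
        sel <- logical(nrow(cand))
        for (ci in seq_len(nrow(cand))) {
          span <- (cand$offset[ci] + 1L):(cand$offset[ci] + L)
          if (!any(taken[span])) {
            taken[span] <- TRUE
            sel[ci] <- TRUE
          }
        }
        cand <- cand[sel, ]
      }
      hits[[ri]] <- mutate(cand, region = ri)
    }
    hits <- bind_rows(hits)
    if (nrow(hits) == 0) next
    gstart <- ifelse(is.na(regions$start[hits$region]), 0L,
                     regions$start[hits$region]) + hits$offset
    out[[mi]] <- tibble(
      region_id = regions$id[hits$region],
      chrom = regions$chrom[hits$region],
      start = as.integer(gstart),
      end = as.integer(gstart + L),
      strand = hits$strand,
      motif_id = m$id %||% paste0("motif_", mi),
      score = hits$score,
      score_frac = hits$score / max_score
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(
      region_id = character(0), chrom = character(0), start = integer(0),
      end = integer(0), strand = character(0), motif_id = character(0),
      score = numeric(0), score_frac = numeric(0)
    ))
  }
  arrange(res, .data$chrom, .data$start)
}
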