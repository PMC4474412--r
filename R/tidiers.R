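#' Tidy a discovery result into a motif table
#'
#' @param x A `"motif_discovery"`.
#' @param ... Unused.
#' @return Tibble with one row per motif: `motif_id`, `consensus`,
#'   `length`, `support`, `score`, `seed_word`, `n_members`.
#' @export
tidy.motif_discovery <- function(x, ...) {
  purrr::map_dfr(x$motifs, function(m) {
    tibble(
      motif_id = m$id, consensus = m$consensus, length = nrow(m$counts),
      support = m$support, score = m$score %||% NA_real_,
      seed_word = m$seed_word,
      n_members = length(m$member_seeds %||% character(0))
    )
  })
}

#' One-row summary of a discovery run
#'
#' @param x A `"motif_discovery"`.
#' @param ... Unused.
#' @return One-row tibble mirroring the run report.
#' @export
glance.motif_discovery <- function(x, ...) {
  r <- x$report
  tibble(
    mode = r$mode, K = r$K, n_regions = r$n_regions,
    n_words_indexed = r$n_words_indexed, n_candidates = r$n_candidates,
    n_motifs = r$n_motifs, elapsed_s = r$elapsed_s
  )
}

#' Tidy a motif into per-position base probabilities
#'
#' @param x A `"pfm_motif"`.
#' @param pseudocount Pseudocount for normalization.
#' @param ... Unused.
#' @return Long tibble: `position`, `base`, `probability`, `count`.
#' @export
tidy.pfm_motif <- function(x, pseudocount = 0.25, ...) {
  p <- motif_probabilities(x, pseudocount)
  tibble(
    position = rep(seq_len(nrow(p)), times = 4),
    base = rep(DNA_BASES, each = nrow(p)),
    probability = as.vector(p),
    count = as.vector(x$counts)
  )
}

#' @export
glance.pfm_motif <- function(x, ...) {
  tibble(
    motif_id = x$id, consensus = x$consensus, length = nrow(x$counts),
    support = x$support, score = x$score %||% NA_real_
  )
}

#' Tidy ROC points of a site evaluation
#'
#' @param x A `"site_eval"`.
#' @param ... Unused.
#' @return The ROC tibble (threshold, confusion counts, fpr, sensitivity).
#' @export
tidy.site_eval <- function(x, ...) x$roc

#' @export
glance.site_eval <- function(x, ...) {
  tibble(auroc = x$auroc, n_summits = x$n_summits,
         n_thresholds = nrow(x$roc))
}

#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @export
glance.cv_result <- function(x, ...) {
  tibble(mean_auroc = x$mean_auroc, sd_auroc = x$sd_auroc,
         n_folds = nrow(x$folds))
}
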