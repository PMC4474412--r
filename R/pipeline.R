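#' Run the full motif discovery pipeline
#'
#' Wires the stages end to end: k-mer indexing, Markov background fit and
#' simulation, over-representation statistics, candidate selection, signal
#' feature scoring (signal-augmented mode), seed generalization, PFM
#' clustering with the gap statistic, merging and trimming. Sequence-only
#' mode uses the odds ratio alone; signal-augmented mode requires at least
#' one track and region coordinates. All randomness flows from
#' `config$seed`, so identical inputs and config reproduce identical
#' output.
#'
#' @param regions Regions tibble (see [read_regions_fasta()]).
#' @param tracks List of `"signal_track"` objects (possibly empty).
#' @param config A [motif_config()].
#' @param keep_intermediates Keep the k-mer index on the result (needed by
#'   [grid_search_betas()] re-scoring).
#' @return Object of class `"motif_discovery"`: `motifs` (ranked list of
#'   `"pfm_motif"`), `seed_scores`, `enrichment`, `background`, `config`,
#'   `mode`, `report` (per-stage counts), and `index` when
#'   `keep_intermediates = TRUE`.
#' @export
discover_motifs <- function(regions, tracks = list(), config = motif_config(),
                            keep_intermediates = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  mode <- config$mode %||% (if (length(tracks) > 0) "MOST+" else "MOST")
  if (mode == "MOST+" && length(tracks) == 0) {
    stop_input(paste0(
      "signal-augmented mode needs at least one signal track; ",
      'run with mode = "MOST" for sequence-only discovery'
    ))
  }
  if (mode == "MOST+" && all(is.na(regions$chrom))) {
    stop_input("signal-augmented mode needs region genomic coordinates")
  }
  if (mode == "MOST") tracks <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  index <- kmer_index(regions, config$K, config$strand_mode)
  background <- fit_background(regions, config$background_order)
  sims <- simulate_background(
    background, nchar(regions$sequence),
    n_simulations = config$n_simulations, seed = config$seed + 1L
  )
  enrichment <- kmer_enrichment(index, sims)
  candidates <- select_candidates(enrichment, config$pvalue_threshold,
                                  config$max_candidates)
  seed_scores <- score_seeds(candidates, index, regions, tracks, config)
  motifs <- build_motifs(seed_scores, index, config)
  report <- list(
    mode = mode, K = config$K, n_regions = nrow(regions),
    total_bp = sum(nchar(regions$sequence)),
    n_tracks = length(tracks),
    n_words_indexed = nrow(index$counts),
    n_candidates = nrow(candidates),
    n_seeds_generalized = min(nrow(seed_scores$scores), config$max_seeds),
    n_motifs = length(motifs),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
    warnings = character(0)
  )
  out <- list(
    motifs = motifs, seed_scores = seed_scores, enrichment = enrichment,
    background = background, config = config, mode = mode, report = report
  )
  if (keep_intermediates) out$index <- index
  structure(out, class = "motif_discovery")
}

#' @export
print.motif_discovery <- function(x, ...) {
  cat(sprintf(
    "<motif_discovery> %s, K=%d: %d candidates -> %d motifs\n",
    x$mode, x$config$K, x$report$n_candidates, x$report$n_motifs
  ))
  for (m in utils::head(x$motifs, 5)) {
    cat(sprintf("  %-10s %-20s support %6d\n", m$id, m$consensus,
                as.integer(round(m$support))))
  }
  invisible(x)
}

#' Write discovery outputs to a directory
#'
#' Writes the MEME minimal motif file, the per-motif score sidecar TSV and
#' a JSON run report.
#'
#' @param discovery A `"motif_discovery"`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_discovery <- function(discovery, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    motifs = file.path(dir, "motifs.meme"),
    scores = file.path(dir, "motif_scores.tsv"),
    report = file.path(dir, "report.json")
  )
  if (length(discovery$motifs) > 0) {
    write_meme_motifs(discovery$motifs, paths$motifs,
                      background = discovery$background$initial_probs)
    write_motif_scores_tsv(discovery$motifs, paths$scores)
  }
  jsonlite::write_json(discovery$report, paths$report, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Evaluate motifs against ChIP-seq summits
#'
#' Thin wrapper around [roc_auroc()] taking a `"motif_discovery"` (its top
#' motifs) or a plain motif list, with coordinate coherence checks.
#'
#' @param x A `"motif_discovery"` or list of `"pfm_motif"`.
#' @param regions Regions tibble with genomic coordinates.
#' @param summits Summits tibble.
#' @param config A [motif_config()].
#' @param n_motifs Number of top motifs used (default 3).
#' @param thresholds ROC sweep thresholds.
#' @return A `"site_eval"` object.
#' @export
evaluate_motifs <- function(x, regions, summits, config = motif_config(),
                            n_motifs = 3L,
                            thresholds = seq(0.45, 0.95, by = 0.05)) {
  motifs <- if (inherits(x, "motif_discovery")) x$motifs else x
  motifs <- utils::head(motifs, n_motifs)
  if (length(motifs) == 0) stop_input("no motifs to evaluate")
  if (all(is.na(regions$chrom))) {
    stop_input("regions lack genomic coordinates")
  }
  if (!any(summits$chrom %in% regions$chrom)) {
    stop_input("summits and regions share no chromosome; coordinate mismatch")
  }
  bg <- if (inherits(x, "motif_discovery")) {
    x$background$initial_probs
  } else {
    rep(0.25, 4)
  }
  roc_auroc(motifs, regions, summits, thresholds = thresholds,
            background = bg, pseudocount = config$pseudocount)
}
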