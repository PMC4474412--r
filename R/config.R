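#' Run configuration for motif discovery
#'
#' Bundles every tunable of the discovery pipeline into one validated list.
#' Defaults follow the tool's recommended operating point for typical
#' ChIP-seq peak sets (100-200 bp regions): word length `K = 9`, a
#' first-order Markov background estimated from the target regions,
#' over-representation assessed against `n_simulations = 5` simulated
#' background sequence sets, and no multiple-testing correction (a small
#' p-value threshold is used instead).
#'
#' @param K Word (k-mer) length in bp; `K >= 4`. Default 9.
#' @param mode `"MOST"` (sequence only) or `"MOST+"` (sequence + signal
#'   tracks). `discover_motifs()` auto-selects `"MOST+"` when tracks are
#'   supplied and `mode` is left `NULL`.
#' @param background_order Markov chain order of the background model, 0 or 1.
#' @param n_simulations Number of simulated background sequence sets used to
#'   estimate expected word counts.
#' @param pvalue_threshold Over-representation p-value cutoff for candidate
#'   seeds.
#' @param beta_I,beta_K,beta_A Non-negative weights of the intensity,
#'   kurtosis and asymmetry sub-scores in the combined seed score. The
#'   asymmetry sub-score is negated internally (high asymmetry penalises a
#'   seed), so all weights are `>= 0`.
#' @param beta_cluster Weight in `[0,1)` of the mark-distribution divergence
#'   term in the motif-motif distance used for clustering.
#' @param bin_width Bin width (bp) of aggregated mark distributions.
#' @param profile_halfwidth Half-width (bp) of the window centred on each
#'   k-mer occurrence over which signal is aggregated; must be a multiple of
#'   `bin_width`.
#' @param cluster_threshold Optional dendrogram height cutoff; when `NULL`
#'   (default) the cluster number is chosen by the gap statistic.
#' @param pseudocount Pseudocount added per PFM cell before normalization.
#' @param seed Integer seed; all pipeline randomness derives from it.
#' @param strand_mode `"both"` (default) or `"forward"`; whether k-mer
#'   occurrences are collected from both strands.
#' @param max_candidates Maximum number of candidate seeds carried into
#'   signal-feature scoring (top of the over-representation ranking).
#' @param max_seeds Maximum number of top-scored seeds generalized to PFMs
#'   and clustered.
#' @param smooth_remove_frac Fraction of the highest-frequency DFT
#'   components removed when smoothing mark distributions.
#' @param trim_min_info Minimum per-column information content (bits) kept
#'   by motif trimming.
#' @param trim_min_support_frac Minimum column support as a fraction of the
#'   maximum column support kept by trimming.
#' @param scan_threshold_frac Site-scanner score threshold as a fraction of
#'   each motif's maximum attainable log-odds score.
#' @param gap_B Number of reference datasets for the gap statistic.
#'
#' @return A list of class `"motif_config"`.
#' @export
#' @examples
#' cfg <- motif_config(K = 7, seed = 42)
#' cfg$K
motif_config <- function(K = 9L,
                         mode = NULL,
                         background_order = 1L,
                         n_simulations = 5L,
                         pvalue_threshold = 1e-6,
                         beta_I = 0.3,
                         beta_K = 0.5,
                         beta_A = 0.5,
                         beta_cluster = 0.2,
                         bin_width = 25L,
                         profile_halfwidth = 1000L,
                         cluster_threshold = NULL,
                         pseudocount = 0.25,
                         seed = 1L,
                         strand_mode = c("both", "forward"),
                         max_candidates = 60L,
                         max_seeds = 30L,
                         smooth_remove_frac = 5 / 8,
                         trim_min_info = 0.3,
                         trim_min_support_frac = 0.1,
                         scan_threshold_frac = 0.7,
                         gap_B = 20L) {
  strand_mode <- match.arg(strand_mode)
  K <- as.integer(K)
  if (is.na(K) || K < 4L) stop_input("`K` must be an integer >= 4")
  if (!is.null(mode) && !mode %in% c("MOST", "MOST+")) {
    stop_input('`mode` must be "MOST" or "MOST+"')
  }
  background_order <- as.integer(background_order)
  if (!background_order %in% c(0L, 1L)) {
    stop_input("`background_order` must be 0 or 1")
  }
  n_simulations <- as.integer(n_simulations)
  if (n_simulations < 1L) stop_input("`n_simulations` must be >= 1")
  for (b in c(beta_I, beta_K, beta_A, beta_cluster)) {
    if (!is.finite(b) || b < 0) stop_input("all beta weights must be >= 0")
  }
  bin_width <- as.integer(bin_width)
  profile_halfwidth <- as.integer(profile_halfwidth)
  if (profile_halfwidth %% bin_width != 0L) {
    stop_input("`profile_halfwidth` must be a multiple of `bin_width`")
  }
  if (pvalue_threshold <= 0 || pvalue_threshold > 1) {
    stop_input("`pvalue_threshold` must be in (0, 1]")
  }
  structure(
    list(
      K = K, mode = mode, background_order = background_order,
      n_simulations = n_simulations, pvalue_threshold = pvalue_threshold,
      beta_I = beta_I, beta_K = beta_K, beta_A = beta_A,
      beta_cluster = beta_cluster, bin_width = bin_width,
      profile_halfwidth = profile_halfwidth,
      cluster_threshold = cluster_threshold, pseudocount = pseudocount,
      seed = as.integer(seed), strand_mode = strand_mode,
      max_candidates = as.integer(max_candidates),
      max_seeds = as.integer(max_seeds),
      smooth_remove_frac = smooth_remove_frac,
      trim_min_info = trim_min_info,
      trim_min_support_frac = trim_min_support_frac,
      scan_threshold_frac = scan_threshold_frac,
      gap_B = as.integer(gap_B)
    ),
    class = "motif_config"
  )
}

#' @export
print.motif_config <- function(x, ...) {
  cat("<motif_config>\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flat)) cat(sprintf("  %-22s %s\n", nm, format(flat[[nm]])))
  invisible(x)
}

#' Read a run configuration from a flat-key YAML-like file
#'
#' Accepts files of `key: value` lines (comments with `#`). Keys must match
#' [motif_config()] argument names.
#'
#' @param path Path to the configuration file.
#' @return A `"motif_config"` list.
#' @export
read_motif_config <- function(path) {
  if (!file.exists(path)) stop_input(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) < 2L
  if (any(bad)) stop_input(paste0("malformed config line: ", lines[bad][1]))
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = ":"), character(1)))
  args <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(args) <- keys
  unknown <- setdiff(keys, names(formals(motif_config)))
  if (length(unknown)) {
    stop_input(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(motif_config, args)
}
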