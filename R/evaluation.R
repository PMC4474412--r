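#' Site-level confusion counts against ChIP-seq summits
#'
#' Each summit is flanked by `flank` bp on both sides (1300 bp total with
#' defaults) and discretized into `2 * flank / bin_width + 1` bins of
#' `bin_width` bp: one central TFBS bin spanning
#' `[summit - bin_width/2, summit + bin_width/2)` plus flanking bins tiling
#' the remainder (12 with defaults, 6 per side). A predicted site is
#' assigned to the bin containing its midpoint. Then
#' * TP = number of summits whose central bin contains a site midpoint
#'   (i.e. a site less than `bin_width / 2` = 50 bp from the summit),
#' * FP = number of flanking bins containing a site midpoint,
#' * FN = number of summits - TP,
#' * TN = total flanking bins - FP,
#' and sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).
#'
#' @param sites Predicted sites tibble from [scan_sites()] (needs `chrom`,
#'   `start`, `end`).
#' @param summits Summits tibble (`chrom`, `summit`).
#' @param flank Flank size in bp (default 650).
#' @param bin_width Bin width in bp (default 100).
#' @return One-row tibble: `TP`, `FP`, `FN`, `TN`, `sensitivity`,
#'   `specificity`, `n_summits`, `n_flanking_bins`, `window_bp`, `n_bins`.
#' @export
evaluate_sites <- function(sites, summits, flank = 650L, bin_width = 100L) {
  if (nrow(summits) == 0) stop_input("no summits to evaluate against")
  geom <- summit_geometry(flank, bin_width)
  n_summits <- nrow(summits)
  central <- geom$n_side # 0-based index of the central bin
  tp_hit <- rep(FALSE, n_summits)
  fp_bin_hit <- matrix(FALSE, nrow = n_summits, ncol = geom$n_bins)
  if (nrow(sites) > 0) {
    mids <- (sites$start + sites$end) / 2
    for (si in seq_len(n_summits)) {
      s <- summits$summit[si]
      on_chrom <- sites$chrom == summits$chrom[si]
      lo <- s - bin_width / 2 - geom$n_side * bin_width
      rel <- mids[on_chrom] - lo
      b <- floor(rel / bin_width)
      b <- b[b >= 0 & b < geom$n_bins]
      if (length(b) == 0) next
      if (any(b == central)) tp_hit[si] <- TRUE
      fp_bin_hit[si, setdiff(unique(b), central) + 1L] <- TRUE
    }
  }
  TP <- sum(tp_hit)
  FP <- sum(fp_bin_hit)
  FN <- n_summits - TP
  TN <- geom$n_flanking * n_summits - FP
  tibble(
    TP = TP, FP = FP, FN = FN, TN = TN,
    sensitivity = TP / (TP + FN),
    specificity = TN / (TN + FP),
    n_summits = n_summits,
    n_flanking_bins = geom$n_flanking,
    window_bp = geom$window_bp,
    n_bins = geom$n_bins
  )
}

#' Evaluation window geometry
#'
#' @param flank Flank size in bp each side of the summit.
#' @param bin_width Bin width in bp.
#' @return List with `window_bp` (total annotation span), `n_bins`,
#'   `n_side` (flanking bins per side) and `n_flanking`.
#' @export
summit_geometry <- function(flank = 650L, bin_width = 100L) {
  if ((2L * flank) %% bin_width != 0) {
    stop_input("`2 * flank` must be a multiple of `bin_width`")
  }
  n_bins <- as.integer(2L * flank / bin_width)
  if (n_bins %% 2L == 0L) {
    stop_input("bin geometry must yield an odd bin count (central TFBS bin)")
  }
  list(
    window_bp = as.integer(2L * flank),
    n_bins = n_bins,
    n_side = as.integer((n_bins - 1L) / 2L),
    n_flanking = n_bins - 1L
  )
}

#' ROC curve and AUROC of motif site predictions
#'
#' Scans the regions once at the loosest threshold, then sweeps the score
#' threshold, computing a (1 - specificity, sensitivity) point per
#' threshold from [evaluate_sites()]; anchors (0,0) and (1,1) are appended
#' and the area computed by the trapezoidal rule.
#'
#' @param motifs List of `"pfm_motif"` objects (e.g. top 3 from discovery).
#' @param regions Regions tibble with coordinates.
#' @param summits Summits tibble.
#' @param thresholds Numeric vector (>= 2 values) of fractional score
#'   thresholds swept, each a fraction of the per-motif maximum log-odds.
#' @param background Background base frequencies for the scanner.
#' @param flank,bin_width Evaluation geometry.
#' @param pseudocount Scanner pseudocount.
#' @return Object of class `"site_eval"`: `roc` (tibble with threshold,
#'   confusion counts, fpr, sensitivity), `auroc`, `n_summits`, `sites`.
#' @export
roc_auroc <- function(motifs, regions, summits,
                      thresholds = seq(0.45, 0.95, by = 0.05),
                      background = rep(0.25, 4), flank = 650L,
                      bin_width = 100L, pseudocount = 0.25) {
  if (length(thresholds) < 2) {
    warn("fewer than 2 thresholds; AUROC rests on the ROC anchors")
  }
  thresholds <- sort(unique(thresholds))
  sites <- scan_sites(motifs, regions, background = background,
                      threshold = NULL, threshold_frac = min(thresholds),
                      pseudocount = pseudocount)
  roc <- purrr::map_dfr(thresholds, function(t) {
    ev <- evaluate_sites(sites[sites$score_frac >= t, , drop = FALSE],
                         summits, flank, bin_width)
    mutate(ev, threshold = t, fpr = 1 - .data$specificity)
  })
  structure(
    list(
      roc = select(roc, "threshold", "TP", "FP", "FN", "TN",
                   "sensitivity", "specificity", "fpr"),
      auroc = trapezoid_auc(roc$fpr, roc$sensitivity),
      n_summits = nrow(summits),
      sites = sites
    ),
    class = "site_eval"
  )
}

# trapezoidal area under (x, y) points with (0,0) and (1,1) anchors
trapezoid_auc <- function(x, y) {
  x <- c(0, x, 1)
  y <- c(0, y, 1)
  ord <- order(x, y)
  x <- x[ord]
  y <- y[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.site_eval <- function(x, ...) {
  cat(sprintf("<site_eval> AUROC = %.3f over %d summits, %d ROC points\n",
              x$auroc, x$n_summits, nrow(x$roc)))
  invisible(x)
}

#' Cross-validated site-level accuracy of the discovery pipeline
#'
#' The regions (with their summits) are randomly divided into
#' `n_partitions` equal parts. Per fold, eight parts train the motif
#' finder, one validation part selects the scanner threshold floor, and one
#' held-out part yields the reported AUROC (partitions rotate between
#' folds). The top `n_motifs` discovered motifs are used for scanning.
#'
#' @param regions Regions tibble with coordinates.
#' @param summits Summits tibble.
#' @param config A [motif_config()].
#' @param tracks Optional list of `"signal_track"` objects.
#' @param n_partitions Number of partitions (default 10; >= 3).
#' @param n_folds Number of folds actually evaluated (default
#'   `n_partitions`).
#' @param n_motifs Number of top motifs scanned (default 3).
#' @param threshold_grid Fractional scanner thresholds tried on the
#'   validation partition.
#' @param thresholds ROC sweep thresholds.
#' @param seed Seed for the partition assignment.
#' @return Object of class `"cv_result"`: `folds` (tibble fold, threshold,
#'   auroc), `mean_auroc`, `sd_auroc`.
#' @export
cross_validate <- function(regions, summits, config, tracks = list(),
                           n_partitions = 10L, n_folds = n_partitions,
                           n_motifs = 3L,
                           threshold_grid = c(0.6, 0.7, 0.8),
                           thresholds = seq(0.45, 0.95, by = 0.05),
                           seed = config$seed) {
  if (n_partitions < 3) stop_input("need at least 3 partitions")
  n <- nrow(regions)
  if (n < n_partitions) stop_input("fewer regions than partitions")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  part <- sample(rep_len(seq_len(n_partitions), n))
  folds <- purrr::map_dfr(seq_len(min(n_folds, n_partitions)), function(f) {
    test_p <- f
    val_p <- f %% n_partitions + 1L
    train_idx <- which(!part %in% c(test_p, val_p))
    val_idx <- which(part == val_p)
    test_idx <- which(part == test_p)
    if (min(nchar(regions$sequence[train_idx])) < config$K) {
      stop_input("a training partition is too small for K")
    }
    disc <- discover_motifs(regions[train_idx, ], tracks = tracks,
                            config = config)
    motifs <- utils::head(disc$motifs, n_motifs)
    bg <- disc$background$initial_probs
    val_sum <- summits_in_regions(summits, regions[val_idx, ])
    best_thr <- threshold_grid[1]
    if (nrow(val_sum) > 0 && length(threshold_grid) > 1) {
      val_auc <- vapply(threshold_grid, function(tg) {
        ev <- roc_auroc(motifs, regions[val_idx, ], val_sum,
                        thresholds = pmax(thresholds, tg), background = bg,
                        pseudocount = config$pseudocount)
        ev$auroc
      }, numeric(1))
      best_thr <- threshold_grid[which.max(val_auc)]
    }
    test_sum <- summits_in_regions(summits, regions[test_idx, ])
    if (nrow(test_sum) == 0) {
      return(tibble(fold = f, threshold = best_thr, auroc = NA_real_))
    }
    ev <- roc_auroc(motifs, regions[test_idx, ], test_sum,
                    thresholds = pmax(thresholds, best_thr), background = bg,
                    pseudocount = config$pseudocount)
    tibble(fold = f, threshold = best_thr, auroc = ev$auroc)
  })
  structure(
    list(
      folds = folds,
      mean_auroc = mean(folds$auroc, na.rm = TRUE),
      sd_auroc = stats::sd(folds$auroc, na.rm = TRUE)
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mean AUROC %.3f (sd %.3f) over %d folds\n",
              x$mean_auroc, x$sd_auroc, nrow(x$folds)))
  invisible(x)
}

# summits whose position falls inside any of the given regions
summits_in_regions <- function(summits, regions) {
  keep <- vapply(seq_len(nrow(summits)), function(i) {
    any(regions$chrom == summits$chrom[i] &
          regions$start <= summits$summit[i] &
          regions$end > summits$summit[i], na.rm = TRUE)
  }, logical(1))
  summits[keep, , drop = FALSE]
}

#' Default weight grid for [grid_search_betas()]
#'
#' Cartesian product of modest discrete weight values; a finer systematic
#' search is obtained by passing denser vectors.
#'
#' @param beta_I,beta_K,beta_A,beta_cluster Candidate values per weight.
#' @return Tibble with one row per combination.
#' @export
default_beta_grid <- function(beta_I = c(0, 0.5),
                              beta_K = c(0, 0.5, 1, 2),
                              beta_A = c(0, 0.5, 1, 2),
                              beta_cluster = 0.2) {
  tidyr::expand_grid(beta_I = beta_I, beta_K = beta_K, beta_A = beta_A,
                     beta_cluster = beta_cluster)
}

#' Grid search over signal-feature weights
#'
#' Exhaustively evaluates validation AUROC over a Cartesian grid of
#' `beta_I`, `beta_K`, `beta_A`, `beta_cluster`: for each point, seeds
#' discovered on the training regions are re-scored and re-clustered with
#' those weights, the top motifs scanned on the validation regions, and the
#' AUROC recorded. Ties break toward the smallest L1-norm weight vector.
#'
#' @param train_regions,val_regions Region tibbles.
#' @param val_summits Summits within the validation regions.
#' @param tracks List of `"signal_track"` objects.
#' @param config A [motif_config()] (its betas are overridden per grid
#'   point).
#' @param grid Tibble/data frame with columns `beta_I`, `beta_K`, `beta_A`
#'   and optionally `beta_cluster`.
#' @param n_motifs Number of top motifs scanned.
#' @param thresholds ROC sweep thresholds.
#' @return List with `best` (one-row tibble) and `table` (full grid with
#'   AUROCs).
#' @export
grid_search_betas <- function(train_regions, val_regions, val_summits, tracks,
                              config, grid, n_motifs = 3L,
                              thresholds = seq(0.45, 0.95, by = 0.05)) {
  if (nrow(grid) == 0) stop_input("empty grid")
  if (is.null(grid$beta_cluster)) grid$beta_cluster <- config$beta_cluster
  base <- discover_motifs(train_regions, tracks = tracks, config = config,
                          keep_intermediates = TRUE)
  results <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$beta_I <- grid$beta_I[g]
    cfg$beta_K <- grid$beta_K[g]
    cfg$beta_A <- grid$beta_A[g]
    cfg$beta_cluster <- grid$beta_cluster[g]
    motifs <- rebuild_with_weights(base, cfg)
    ev <- roc_auroc(utils::head(motifs, n_motifs), val_regions, val_summits,
                    thresholds = thresholds,
                    background = base$background$initial_probs,
                    pseudocount = cfg$pseudocount)
    mutate(grid[g, ], auroc = ev$auroc)
  })
  l1 <- results$beta_I + results$beta_K + results$beta_A + results$beta_cluster
  best <- results[order(-results$auroc, l1), ][1, ]
  list(best = best, table = results)
}

# re-combine cached sub-scores with new weights and rebuild motifs
rebuild_with_weights <- function(discovery, config) {
  ss <- discovery$seed_scores
  if (is.null(ss$features)) {
    return(build_motifs(ss, discovery$index, config))
  }
  zf <- ss$features %>%
    group_by(.data$track) %>%
    mutate(zI = normal_scores(.data$S_I), zK = normal_scores(.data$S_K),
           zA = normal_scores(.data$S_A)) %>%
    ungroup() %>%
    group_by(.data$kmer) %>%
    summarise(S_I = mean(.data$zI), S_K = mean(.data$zK), S_A = mean(.data$zA),
              .groups = "drop")
  scores <- ss$scores %>%
    select(-dplyr::any_of(c("S_I", "S_K", "S_A", "S"))) %>%
    left_join(zf, by = "kmer") %>%
    mutate(
      S = normal_scores(.data$S_W) + config$beta_I * .data$S_I +
        config$beta_K * .data$S_K - config$beta_A * .data$S_A
    ) %>%
    arrange(desc(.data$S), desc(.data$S_W))
  rescored <- structure(
    list(scores = scores, features = ss$features,
         weights = c(beta_I = config$beta_I, beta_K = config$beta_K,
                     beta_A = config$beta_A)),
    class = "seed_scores"
  )
  build_motifs(rescored, discovery$index, config)
}
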