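mk_sites <- function(chrom, mids, L = 10L) {
  tibble::tibble(
    region_id = "r", chrom = chrom, start = as.integer(mids - L / 2),
    end = as.integer(mids + L / 2), strand = "+", motif_id = "m",
    score = 10, score_frac = 0.9
  )
}

test_that("summit geometry yields the 1300 bp / 13 bin / 12 flank layout", {
  g <- summit_geometry(650L, 100L)
  expect_equal(g$window_bp, 1300L)
  expect_equal(g$n_bins, 13L)
  expect_equal(g$n_flanking, 12L)
  expect_equal(g$n_side, 6L)
  expect_error(summit_geometry(655L, 100L), "multiple")
  # an even bin count leaves no centred TFBS bin
  expect_error(summit_geometry(500L, 100L), "odd")
})

test_that("confusion counts follow the printed bin definitions", {
  summits <- tibble::tibble(chrom = "c", summit = 10000L)
  ev <- evaluate_sites(mk_sites("c", 10000), summits)
  expect_equal(ev[, c("TP", "FP", "FN", "TN")],
               tibble::tibble(TP = 1L, FP = 0L, FN = 0L, TN = 12L))
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)

  # a site 300 bp away: central bin missed, one flanking bin hit
  ev <- evaluate_sites(mk_sites("c", 10300), summits)
  expect_equal(ev[, c("TP", "FP", "FN", "TN")],
               tibble::tibble(TP = 0L, FP = 1L, FN = 1L, TN = 11L))

  summits10 <- tibble::tibble(chrom = "c", summit = seq(5000L, 50000L,
                                                        length.out = 10))
  ev <- evaluate_sites(mk_sites("c", numeric(0))[0, ], summits10)
  expect_equal(ev[, c("TP", "FP", "FN", "TN")],
               tibble::tibble(TP = 0L, FP = 0L, FN = 10L, TN = 120L))
  expect_equal(ev$sensitivity, 0)
  expect_equal(ev$specificity, 1)
  expect_error(evaluate_sites(mk_sites("c", 1), summits10[0, ]), "no summits")
})

test_that("evaluation equals a brute-force per-bin membership check", {
  set.seed(33)
  for (trial in 1:100) {
    n_sum <- sample(1:5, 1)
    summits <- sort(sample(2000:40000, n_sum)) # may yield overlapping windows
    mids <- sample(0:42000, sample(0:30, 1))
    ev <- evaluate_sites(mk_sites("c", mids, L = 0L),
                         tibble::tibble(chrom = "c", summit = summits))
    oracle <- brute_evaluate(mids, summits)
    expect_equal(ev$TP, oracle$TP)
    expect_equal(ev$FP, oracle$FP)
    expect_equal(ev$FN, oracle$FN)
    expect_equal(ev$TN, oracle$TN)
    expect_equal(ev$TP + ev$FN, n_sum)
    expect_equal(ev$FP + ev$TN, 12L * n_sum)
  }
})

test_that("a perfectly separating fixture reaches AUROC 1", {
  fx <- make_fixture(fixture_spec(
    n_regions = 80, plant_rate = 1,
    planted_pfm = example_pfm("ATGCAAATC", dominance = 1),
    signal_shapes = list(), summit_jitter = 0, seed = 6
  ))
  m <- new_pfm_motif(example_pfm("ATGCAAATC", 1) * 100, support = 100, id = "m")
  ev <- roc_auroc(list(m), fx$regions, fx$summits)
  expect_equal(ev$auroc, 1.0, tolerance = 1e-9)
})

test_that("uniformly random sites give a chance-level AUROC", {
  set.seed(55)
  aucs <- vapply(1:10, function(i) {
    n <- 120
    summits <- tibble::tibble(chrom = "c",
                              summit = as.integer(sample(10000:200000, n)))
    mids <- sample(0:210000, 600)
    sites <- mk_sites("c", mids)
    sites$score_frac <- runif(600, 0.45, 1)
    roc <- purrr::map_dfr(seq(0.45, 0.95, 0.05), function(t) {
      ev <- evaluate_sites(sites[sites$score_frac >= t, ], summits)
      dplyr::mutate(ev, fpr = 1 - .data$specificity)
    })
    motifshape:::trapezoid_auc(roc$fpr, roc$sensitivity)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("AUROC is invariant to threshold order and monotone score maps", {
  fx <- make_fixture(fixture_spec(n_regions = 120, seed = 7))
  cfg <- motif_config(seed = 7)
  d <- discover_motifs(fx$regions, config = cfg)
  th <- seq(0.45, 0.9, 0.05)
  a1 <- roc_auroc(d$motifs[1], fx$regions, fx$summits, thresholds = th)
  a2 <- roc_auroc(d$motifs[1], fx$regions, fx$summits, thresholds = rev(th))
  expect_equal(a1$auroc, a2$auroc)
  # monotone transform of scores: sweep on transformed thresholds
  sites <- a1$sites
  roc_t <- purrr::map_dfr(th, function(t) {
    ev <- evaluate_sites(sites[exp(sites$score_frac) >= exp(t), ], fx$summits)
    dplyr::mutate(ev, fpr = 1 - .data$specificity)
  })
  expect_equal(motifshape:::trapezoid_auc(roc_t$fpr, roc_t$sensitivity),
               a1$auroc)
})

test_that("cross-validation is seed-deterministic and beats chance on planted data", {
  fx <- make_fixture(fixture_spec(n_regions = 300, seed = 18))
  cfg <- motif_config(seed = 18)
  cv1 <- cross_validate(fx$regions, fx$summits, cfg, n_partitions = 5,
                        n_folds = 2)
  cv2 <- cross_validate(fx$regions, fx$summits, cfg, n_partitions = 5,
                        n_folds = 2)
  expect_identical(cv1$folds, cv2$folds)
  expect_gt(cv1$mean_auroc, 0.6) # planted signal clearly beats the null
  expect_equal(nrow(tidy(cv1)), 2)
  expect_equal(glance(cv1)$mean_auroc, cv1$mean_auroc)
})

test_that("a zero-weight grid reproduces the sequence-only baseline", {
  fx <- make_fixture(fixture_spec(n_regions = 300, seed = 25))
  cfg <- motif_config(seed = 25, max_seeds = 10, gap_B = 5)
  n <- nrow(fx$regions)
  set.seed(2501) # distinct from the fixture seed so the split is independent
  val <- sample.int(n, 100)
  vs <- motifshape:::summits_in_regions(fx$summits, fx$regions[val, ])
  grid <- tibble::tibble(beta_I = 0, beta_K = 0, beta_A = 0,
                         beta_cluster = 0)
  gs <- grid_search_betas(fx$regions[-val, ], fx$regions[val, ], vs,
                          fx$tracks, cfg, grid)
  expect_equal(nrow(gs$table), 1)
  expect_equal(gs$best$beta_K, 0)
  # baseline: sequence-only discovery on the same split
  cfg0 <- motif_config(seed = 25, max_seeds = 10, gap_B = 5)
  d0 <- discover_motifs(fx$regions[-val, ], config = cfg0)
  ev0 <- roc_auroc(utils::head(d0$motifs, 3), fx$regions[val, ], vs,
                   background = d0$background$initial_probs)
  expect_equal(gs$best$auroc, ev0$auroc, tolerance = 0.02)
})
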