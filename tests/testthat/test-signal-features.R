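md_from_profile <- function(smoothed, bin_width = 10L) {
  structure(
    list(word = "TEST", track_name = "t", bins = smoothed,
         normalized = smoothed / sum(smoothed), smoothed = smoothed,
         bin_width = bin_width,
         halfwidth = as.integer(length(smoothed) * bin_width / 2),
         n_occurrences_used = 1L),
    class = "mark_distribution"
  )
}

test_that("aggregation bins a constant track exactly and is additive", {
  regions <- regions_from_sequences(c(strrep("A", 60), strrep("A", 60)),
                                    chrom = "c", start = c(100L, 400L))
  tr <- constant_track("t", "c", 600L, 2.5)
  occ1 <- tibble::tibble(region = 1L, offset = 20L, strand = "+")
  md1 <- mark_distribution(occ1, regions, tr, K = 4, halfwidth = 50L,
                           bin_width = 10L)
  expect_length(md1$bins, 10)
  expect_equal(md1$bins, rep(25, 10))

  occ2 <- tibble::tibble(region = c(1L, 2L), offset = c(20L, 20L),
                         strand = c("+", "+"))
  md2 <- mark_distribution(occ2, regions, tr, K = 4, halfwidth = 50L,
                           bin_width = 10L)
  expect_equal(md2$bins, 2 * md1$bins)
  expect_equal(md2$n_occurrences_used, 2L)
})

test_that("minus-strand windows are mirrored before binning", {
  ramp <- signal_track("t", list(c = as.numeric(0:199)))
  regions <- regions_from_sequences(strrep("A", 100), chrom = "c", start = 50L)
  occ_p <- tibble::tibble(region = 1L, offset = 48L, strand = "+")
  occ_m <- tibble::tibble(region = 1L, offset = 48L, strand = "-")
  mdp <- mark_distribution(occ_p, regions, ramp, K = 4, halfwidth = 40L,
                           bin_width = 10L)
  mdm <- mark_distribution(occ_m, regions, ramp, K = 4, halfwidth = 40L,
                           bin_width = 10L)
  expect_equal(mdm$bins, rev(mdp$bins))
})

test_that("windows beyond the covered chromosome zero-fill", {
  tr <- constant_track("t", "c", 100L, 1)
  regions <- regions_from_sequences(strrep("A", 100), chrom = "c", start = 0L)
  occ <- tibble::tibble(region = 1L, offset = 0L, strand = "+")
  md <- mark_distribution(occ, regions, tr, K = 4, halfwidth = 50L,
                          bin_width = 10L)
  # centre at bp 2: left half of the window hangs off the chromosome start
  expect_equal(sum(md$bins), sum(track_values(tr, "c", -48, 52)))
  expect_error(
    mark_distribution(occ[0, ], regions, tr, K = 4, halfwidth = 50L,
                      bin_width = 10L),
    "unscorable"
  )
})

test_that("normalize/smooth conserves mass and fixes low-frequency profiles", {
  B <- 32
  md <- md_from_profile(rep(3, B))
  sm <- normalize_and_smooth(md)
  expect_equal(sm$normalized, rep(1 / B, B))
  expect_equal(sm$smoothed, rep(1 / B, B), tolerance = 1e-12)

  spike <- md_from_profile(c(rep(0, 15), 10, rep(0, 16)))
  sm <- normalize_and_smooth(spike)
  expect_true(all(sm$smoothed >= 0))
  expect_equal(sum(sm$smoothed), 1, tolerance = 1e-9)
  expect_gt(sum(sm$smoothed > 1e-4), 1) # widened beyond one bin

  # cosine at a retained frequency is an eigenprofile of the truncation
  f <- 2
  x <- (1 + cos(2 * pi * f * (0:(B - 1)) / B)) / B
  sm <- normalize_and_smooth(md_from_profile(x))
  expect_equal(sm$smoothed, sm$normalized, tolerance = 1e-9)

  zero <- md_from_profile(rep(0, B))
  expect_warning(sm <- normalize_and_smooth(zero), "all-zero")
  expect_equal(sm$smoothed, rep(1 / B, B))
})

test_that("intensity is the mean per-occurrence window sum", {
  regions <- regions_from_sequences(strrep("A", 300), chrom = "c", start = 0L)
  tr <- constant_track("t", "c", 300L, 1)
  occ <- tibble::tibble(region = 1L, offset = 148L, strand = "+")
  md <- mark_distribution(occ, regions, tr, K = 4, halfwidth = 100L,
                          bin_width = 25L)
  expect_equal(intensity_score(md), 200)
  # doubling identical occurrences leaves the mean unchanged
  md2 <- mark_distribution(occ[c(1, 1), ], regions, tr, K = 4,
                           halfwidth = 100L, bin_width = 25L)
  expect_equal(intensity_score(md2), 200)
})

test_that("intensity equals a brute-force mean of window sums on random tracks", {
  set.seed(12)
  vec <- runif(2000)
  tr <- signal_track("t", list(c = vec))
  regions <- regions_from_sequences(rep(strrep("A", 100), 3), chrom = "c",
                                    start = c(100L, 600L, 1200L))
  occ <- tibble::tibble(region = 1:3, offset = c(10L, 40L, 80L),
                        strand = c("+", "+", "-"))
  md <- mark_distribution(occ, regions, tr, K = 5, halfwidth = 50L,
                          bin_width = 10L)
  centres <- regions$start[occ$region] + occ$offset + 2L
  sums <- vapply(centres, function(cc) sum(vec[(cc - 50 + 1):(cc + 50)]),
                 numeric(1))
  expect_equal(intensity_score(md), mean(sums))
})

test_that("kurtosis matches closed-form values for canonical shapes", {
  B <- 64
  # discrete uniform: excess kurtosis -(6/5)(B^2+1)/(B^2-1)
  exact <- -(6 / 5) * (B^2 + 1) / (B^2 - 1)
  expect_equal(kurtosis_score(md_from_profile(rep(1 / B, B))), exact,
               tolerance = 1e-9)
  expect_equal(kurtosis_score(md_from_profile(rep(1 / B, B))), -1.2,
               tolerance = 0.01)

  # binned standard Gaussian well inside the window: excess kurtosis ~ 0
  x <- seq(-8, 8, length.out = B)
  g <- dnorm(x); g <- g / sum(g)
  expect_equal(kurtosis_score(md_from_profile(g)), 0, tolerance = 0.05)

  # two far symmetric spikes: excess kurtosis of a symmetric two-point mass is -2
  two <- rep(0, B); two[1] <- 0.5; two[B] <- 0.5
  expect_equal(kurtosis_score(md_from_profile(two)), -2, tolerance = 1e-9)

  # all mass in one bin: capped sentinel
  one <- rep(0, B); one[10] <- 1
  expect_equal(kurtosis_score(md_from_profile(one)), 50)
})

test_that("kurtosis is invariant to bin-axis translation and rescaling", {
  set.seed(5)
  f <- runif(40); f <- f / sum(f)
  base <- kurtosis_score(md_from_profile(f))
  expect_equal(kurtosis_score(md_from_profile(f, bin_width = 50L)), base)
  # translation: shift mass along the axis by padding
  shifted <- c(rep(0, 8), f, rep(0, 8))
  shifted_md <- md_from_profile(shifted / sum(shifted))
  expect_equal(kurtosis_score(shifted_md), base, tolerance = 1e-9)
})

test_that("asymmetry is zero for mirror-symmetric profiles and symmetric in halves", {
  sym <- c(0.1, 0.2, 0.3, 0.4, 0.4, 0.3, 0.2, 0.1)
  expect_equal(asymmetry_score(md_from_profile(sym / sum(sym))), 0,
               tolerance = 1e-4)
  f <- c(0.05, 0.15, 0.4, 0.1, 0.12, 0.08, 0.06, 0.04)
  swapped <- c(rev(f[5:8]), rev(f[1:4])) # exchange mirrored halves
  expect_equal(asymmetry_score(md_from_profile(f)),
               asymmetry_score(md_from_profile(swapped)), tolerance = 1e-9)
  expect_gte(asymmetry_score(md_from_profile(f)), 0)
})

test_that("asymmetry reproduces the hand-computed KL for a two-bin half", {
  # halves (0.8, 0.2) vs mirrored (0.2, 0.8):
  # 0.8 ln(0.8/0.2) + 0.2 ln(0.2/0.8) = 0.8318 (antisymmetric pair)
  f <- c(0.8, 0.2, 0.8, 0.2) / 2
  expect_equal(asymmetry_score(md_from_profile(f)),
               0.8 * log(4) + 0.2 * log(1 / 4), tolerance = 1e-4)
  expect_equal(asymmetry_score(md_from_profile(f)), 0.8318, tolerance = 1e-3)
})

test_that("combined scoring reduces to the odds ratio without tracks or weights", {
  set.seed(41)
  fx <- make_fixture(fixture_spec(n_regions = 150, seed = 41))
  cfg <- motif_config(seed = 41, max_candidates = 20)
  idx <- kmer_index(fx$regions, cfg$K)
  bg <- fit_background(fx$regions, 0)
  sims <- simulate_background(bg, nchar(fx$regions$sequence), 5, seed = 42)
  cand <- select_candidates(kmer_enrichment(idx, sims), 1e-6, 20)
  ss_none <- score_seeds(cand, idx, fx$regions, list(), cfg)
  expect_equal(ss_none$scores$S, ss_none$scores$S_W)

  cfg0 <- motif_config(seed = 41, beta_I = 0, beta_K = 0, beta_A = 0)
  ss0 <- score_seeds(cand, idx, fx$regions, fx$tracks, cfg0)
  expect_equal(order(-ss0$scores$S), order(-ss0$scores$S_W))
})

test_that("a kurtotic profile outranks a flat one at equal odds ratio", {
  set.seed(51)
  fx <- make_spurious_word_fixture(fixture_spec(n_regions = 400, seed = 51),
                                   decoy_shape = list(shape = "flat"))
  cfg <- motif_config(seed = 51, beta_I = 0, beta_K = 1, beta_A = 0)
  d <- discover_motifs(fx$regions, tracks = fx$tracks, config = cfg)
  sc <- d$seed_scores$scores
  planted <- "ATGCAAATC"
  expect_true(all(c(planted, fx$repeat_word) %in% sc$kmer))
  # kurtosis: Gaussian peak vs flat decoy profile
  expect_gt(sc$S_K[sc$kmer == planted], sc$S_K[sc$kmer == fx$repeat_word])
})

test_that("shape features lift the planted word relative to pure odds ranking", {
  hits <- 0L
  for (s in 1:3) {
    fx <- make_spurious_word_fixture(fixture_spec(n_regions = 600, seed = 60 + s))
    cfg <- motif_config(seed = 60 + s, beta_I = 0, beta_K = 0.5, beta_A = 2)
    d <- discover_motifs(fx$regions, tracks = fx$tracks, config = cfg)
    sc <- d$seed_scores$scores
    r_sw <- match("ATGCAAATC", sc$kmer[order(-sc$S_W)])
    r_s <- match("ATGCAAATC", sc$kmer[order(-sc$S)])
    if (r_s <= r_sw) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})
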