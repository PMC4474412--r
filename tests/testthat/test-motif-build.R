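test_that("seed generalization enumerates 4K variants and fills the PFM", {
  regions <- regions_from_sequences(c("ACGTACGT", "ACGAACGT", "ACGTACGA"))
  idx <- kmer_index(regions, K = 8, strand_mode = "forward")
  m <- generalize_seed("ACGTACGT", idx)
  expect_equal(attr(m, "n_variants"), 32L) # 4 * 8 single-base enumerations
  expect_equal(m$support, kmer_count(idx, "ACGTACGT"))
  # the seed base at each position carries the seed's own count
  chars <- strsplit("ACGTACGT", "")[[1]]
  for (i in 1:8) {
    expect_equal(unname(m$counts[i, chars[i]]),
                 kmer_count(idx, "ACGTACGT"))
  }
  expect_equal(unname(m$counts[4, "A"]), kmer_count(idx, "ACGAACGT"))
  expect_error(generalize_seed("TTTTTTTT", idx), "not indexed")
})

test_that("a seed with no occurring variants yields a diagonal PFM", {
  regions <- regions_from_sequences(strrep("ACGT", 4))
  idx <- kmer_index(regions, K = 16, strand_mode = "forward")
  m <- generalize_seed(strrep("ACGT", 4), idx)
  chars <- strsplit(strrep("ACGT", 4), "")[[1]]
  for (i in seq_along(chars)) {
    expect_equal(unname(m$counts[i, chars[i]]), 1)
    expect_equal(sum(m$counts[i, ]), 1)
  }
})

test_that("generalization recovers planted PFM column frequencies", {
  # estimator validation: a strongly informative PFM planted in every
  # region, counted on the planting strand, so that the single-substitution
  # readout (which only sees consensus-elsewhere instances) has enough
  # effective sample at 500 instances for a 0.05 per-entry bound
  pfm <- example_pfm("ATGCAAATC", dominance = 0.95)
  fx <- make_fixture(fixture_spec(n_regions = 500, plant_rate = 1,
                                  planted_pfm = pfm, seed = 13,
                                  signal_shapes = list()))
  idx <- kmer_index(fx$regions, 9, strand_mode = "forward")
  m <- generalize_seed("ATGCAAATC", idx)
  freq <- m$counts / rowSums(m$counts)
  expect_lt(max(abs(freq - pfm)), 0.05)
})

test_that("motif distance is zero for identical and reverse-complement motifs", {
  set.seed(8)
  counts <- matrix(rpois(8 * 4, 30), ncol = 4)
  m <- new_pfm_motif(counts, support = 100, id = "m")
  d <- motif_distance(m, m)
  expect_equal(d$distance, 0, tolerance = 1e-12)
  expect_equal(d$offset, 0L)
  expect_equal(d$orientation, "+")

  rc <- new_pfm_motif(counts[rev(1:8), c(4, 3, 2, 1)], support = 100, id = "rc")
  d <- motif_distance(m, rc)
  expect_equal(d$distance, 0, tolerance = 1e-12)
  expect_equal(d$orientation, "-")
})

test_that("motif distance equals brute-force enumeration on random pairs", {
  set.seed(19)
  for (i in 1:20) {
    L1 <- sample(6:10, 1); L2 <- sample(6:10, 1)
    c1 <- matrix(rpois(L1 * 4, 10), ncol = 4)
    c2 <- matrix(rpois(L2 * 4, 10), ncol = 4)
    m1 <- new_pfm_motif(c1, 50); m2 <- new_pfm_motif(c2, 50)
    got <- motif_distance(m1, m2)$distance
    expect_equal(got, brute_motif_distance(c1, c2), tolerance = 1e-9)
  }
})

test_that("short motifs with no admissible overlap get the sentinel distance", {
  m1 <- new_pfm_motif(matrix(rpois(8, 10), ncol = 4), 10) # 2 columns
  m2 <- new_pfm_motif(matrix(rpois(8, 10), ncol = 4), 10)
  expect_equal(motif_distance(m1, m2)$distance, 2)
})

test_that("the distance matrix is symmetric with zero diagonal", {
  set.seed(23)
  motifs <- lapply(1:5, function(i) {
    new_pfm_motif(matrix(rpois(28, 15), ncol = 4), 40)
  })
  dm <- motif_distance_matrix(motifs)
  expect_equal(dm$distance, t(dm$distance))
  expect_equal(diag(dm$distance), rep(0, 5))
  expect_true(all(dm$distance >= 0 & dm$distance <= 2))
})

test_that("clustering separates copies from an orthogonal motif", {
  set.seed(3)
  a <- matrix(5, 8, 4); a[, 1] <- 100 # poly-A-ish
  b <- matrix(5, 8, 4); b[cbind(1:8, rep(c(2, 3), 4))] <- 100 # CG alternation
  motifs <- list(new_pfm_motif(a, 100, id = "a1"),
                 new_pfm_motif(a, 100, id = "a2"),
                 new_pfm_motif(b, 100, id = "b"))
  cl <- cluster_motifs(motifs, B = 10, seed = 4)
  expect_equal(cl$assignment[1], cl$assignment[2])
  expect_false(cl$assignment[1] == cl$assignment[3])
  expect_equal(cl$k, 2L)
})

test_that("a single motif forms a single cluster", {
  m <- new_pfm_motif(matrix(rpois(36, 10), ncol = 4), 10)
  cl <- cluster_motifs(list(m))
  expect_equal(cl$assignment, 1L)
  expect_equal(cl$k, 1L)
})

test_that("motifs with no admissible alignment remain singletons", {
  set.seed(44)
  motifs <- lapply(1:4, function(i) {
    new_pfm_motif(matrix(rpois(32, 15), ncol = 4), 30)
  })
  M <- 4
  D <- matrix(2, M, M); diag(D) <- 0 # sentinel everywhere: never merged
  dist <- list(distance = D, offset = matrix(0L, M, M),
               orientation = matrix("+", M, M))
  cl <- cluster_motifs(motifs, dist = dist, B = 10, seed = 5)
  expect_equal(cl$k, 4L)
  expect_equal(sort(unique(cl$assignment)), 1:4)
})

test_that("merging preserves identity, doubles duplicates, and aligns offsets", {
  set.seed(9)
  counts <- matrix(rpois(32, 20), ncol = 4)
  m <- new_pfm_motif(counts, 40, id = "m", score = 2)
  expect_identical(merge_cluster(list(m)), m)

  m2 <- new_pfm_motif(counts, 40, id = "m2", score = 1)
  merged <- merge_cluster(list(m, m2))
  expect_equal(merged$counts, 2 * counts, ignore_attr = TRUE)
  expect_equal(motif_probabilities(merged, 0), motif_probabilities(m, 0),
               tolerance = 1e-12)

  # toy shifted pair: m3 is m shifted right by one column
  strong <- matrix(1, 5, 4); strong[cbind(1:5, c(1, 2, 3, 4, 1))] <- 50
  lead <- matrix(1, 1, 4)
  a <- new_pfm_motif(rbind(strong, lead), 50, id = "a", score = 5)
  b <- new_pfm_motif(rbind(lead, strong), 50, id = "b", score = 1)
  merged <- merge_cluster(list(a, b))
  expect_equal(nrow(merged$counts), 7) # union span L + 1
  # the doubled overlap column: a's first strong column aligns with b's
  expect_equal(merged$counts[2, ], 2 * strong[1, ], ignore_attr = TRUE)
  expect_equal(merged$counts[1, ], lead[1, ], ignore_attr = TRUE)
})

test_that("merging a motif with its reverse complement doubles the counts", {
  set.seed(10)
  counts <- matrix(rpois(36, 25), ncol = 4)
  m <- new_pfm_motif(counts, 30, id = "f", score = 3)
  rc <- new_pfm_motif(counts[rev(1:9), c(4, 3, 2, 1)], 30, id = "r", score = 1)
  merged <- merge_cluster(list(m, rc))
  expect_equal(merged$counts, 2 * counts, ignore_attr = TRUE)
})

test_that("trimming strips uninformative ends but never below four columns", {
  core <- matrix(1, 6, 4); core[cbind(1:6, c(1, 2, 3, 4, 1, 2))] <- 200
  flank <- matrix(50, 1, 4) # uniform, 0-bit column
  m <- new_pfm_motif(rbind(flank, core, flank), 200, id = "m")
  trimmed <- trim_motif(m, min_info = 0.3)
  expect_equal(nrow(trimmed$counts), 6)
  expect_equal(trimmed$counts, core, ignore_attr = TRUE)

  strong <- new_pfm_motif(core, 200, id = "s")
  expect_equal(trim_motif(strong)$counts, strong$counts)

  # weak end columns with IC ~ 0.03 bits are trimmed from both sides
  weak <- matrix(c(0.3, 0.3, 0.2, 0.2) * 100, 1, 4)
  m2 <- new_pfm_motif(rbind(weak, core, weak), 200, id = "m2")
  expect_equal(nrow(trim_motif(m2, min_info = 0.3)$counts), 6)

  # a motif weak everywhere is returned untrimmed with a warning
  allweak <- new_pfm_motif(matrix(50, 6, 4), 300, id = "w")
  expect_warning(out <- trim_motif(allweak), "weak")
  expect_equal(nrow(out$counts), 6)
})

test_that("consensus ties fall back to IUPAC degenerate codes", {
  counts <- rbind(c(10, 10, 0, 0), c(0, 0, 0, 9), c(5, 5, 5, 5))
  m <- new_pfm_motif(counts, 10)
  expect_equal(m$consensus, "MTN")
})
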