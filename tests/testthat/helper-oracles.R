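# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by direct enumeration, not by calling package internals.

# character-by-character sliding-window k-mer count/locate
naive_kmer_scan <- function(sequences, K, strand_mode = "both") {
  complement <- c(A = "T", C = "G", G = "C", T = "A")
  counts <- new.env(parent = emptyenv())
  occs <- list()
  bump <- function(word, region, offset, strand) {
    prev <- if (is.null(counts[[word]])) 0L else counts[[word]]
    counts[[word]] <- prev + 1L
    occs[[length(occs) + 1L]] <<- list(word, region, offset, strand)
  }
  for (ri in seq_along(sequences)) {
    chars <- strsplit(sequences[ri], "")[[1]]
    n <- length(chars)
    if (n < K) next
    for (off in 0:(n - K)) {
      win <- chars[(off + 1):(off + K)]
      if (any(!win %in% names(complement))) next
      fwd <- paste(win, collapse = "")
      bump(fwd, ri, off, "+")
      if (strand_mode == "both") {
        rc <- paste(rev(unname(complement[win])), collapse = "")
        bump(rc, ri, off, "-")
      }
    }
  }
  cnt <- vapply(ls(counts), function(w) counts[[w]], integer(1))
  list(counts = cnt[order(names(cnt))],
       occurrences = occs)
}

naive_locate <- function(sequences, K, word, strand_mode = "both") {
  sc <- naive_kmer_scan(sequences, K, strand_mode)
  hits <- Filter(function(o) o[[1]] == word, sc$occurrences)
  df <- do.call(rbind, lapply(hits, function(o) {
    data.frame(region = o[[2]], offset = o[[3]], strand = o[[4]])
  }))
  if (is.null(df)) data.frame(region = integer(0), offset = integer(0),
                              strand = character(0))
  else df[order(df$region, df$offset, df$strand), , drop = FALSE]
}

# exhaustive offset/orientation enumeration of the best-alignment motif
# distance (sequence term only), using stats::cor directly
brute_motif_distance <- function(c1, c2, pseudocount = 0.25,
                                 min_overlap = NULL) {
  p1 <- (c1 + pseudocount) / rowSums(c1 + pseudocount)
  p2 <- (c2 + pseudocount) / rowSums(c2 + pseudocount)
  L1 <- nrow(p1); L2 <- nrow(p2)
  minov <- if (is.null(min_overlap)) max(4, ceiling(min(L1, L2) / 2)) else min_overlap
  rc <- function(m) m[rev(seq_len(nrow(m))), c(4, 3, 2, 1)]
  best <- 2
  for (ori in 1:2) {
    q <- if (ori == 1) p2 else rc(p2)
    for (o in -(L2 - minov):(L1 - minov)) {
      i1 <- max(1, o + 1):min(L1, o + L2)
      i2 <- i1 - o
      if (length(i1) < minov) next
      r <- suppressWarnings(stats::cor(as.vector(p1[i1, , drop = FALSE]),
                                       as.vector(q[i2, , drop = FALSE])))
      if (!is.na(r)) best <- min(best, 1 - r)
    }
  }
  best
}

# per-bin membership check of the summit evaluation, bin by bin
brute_evaluate <- function(site_mids, summits, flank = 650, bin_width = 100) {
  n_bins <- 2 * flank / bin_width
  half <- bin_width / 2
  TP <- 0L; FP <- 0L
  for (s in summits) {
    edges <- seq(s - half - (n_bins - 1) / 2 * bin_width,
                 by = bin_width, length.out = n_bins + 1)
    central <- (n_bins - 1) / 2 + 1
    for (b in seq_len(n_bins)) {
      hit <- any(site_mids >= edges[b] & site_mids < edges[b + 1])
      if (b == central) {
        if (hit) TP <- TP + 1L
      } else if (hit) {
        FP <- FP + 1L
      }
    }
  }
  list(TP = TP, FP = FP, FN = length(summits) - TP,
       TN = (n_bins - 1) * length(summits) - FP)
}

# exact Poisson upper tail by direct summation of the mass function
exact_poisson_tail <- function(wc, lambda) {
  hi <- max(wc, ceiling(lambda + 20 * sqrt(lambda) + 50))
  sum(dpois(wc:hi, lambda))
}

# minimum mismatch count between a found consensus and the planted one over
# all offsets and both orientations; planted positions left uncovered count
# as mismatches
consensus_mismatches <- function(found, planted) {
  complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(w) paste(rev(unname(complement[strsplit(w, "")[[1]]])),
                          collapse = "")
  pl <- strsplit(planted, "")[[1]]
  best <- length(pl)
  for (cand in c(found, rc(found))) {
    fc <- strsplit(cand, "")[[1]]
    for (o in -(length(fc) - 1):(length(pl) - 1)) {
      mism <- 0L
      for (i in seq_along(pl)) {
        j <- i - o
        if (j < 1 || j > length(fc)) {
          mism <- mism + 1L
        } else if (fc[j] != pl[i]) {
          mism <- mism + 1L
        }
      }
      best <- min(best, mism)
    }
  }
  best
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# tiny helper: constant-valued track over one chromosome
constant_track <- function(name, chrom, len, value) {
  signal_track(name, stats::setNames(list(rep(value, len)), chrom))
}
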