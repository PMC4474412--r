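#' Construct a PFM motif object
#'
#' @param counts L x 4 non-negative matrix (columns A,C,G,T) of per-position
#'   base occurrence counts.
#' @param support Total occurrences supporting the motif.
#' @param id Motif identifier.
#' @param seed_word Seed the motif was generalized from.
#' @param score Ranking score carried from seed scoring.
#' @param mark_profiles Optional named list (per track) of smoothed mark
#'   distribution vectors.
#' @param member_seeds Seeds merged into the motif (after clustering).
#' @return An object of class `"pfm_motif"`.
#' @export
new_pfm_motif <- function(counts, support, id = NULL, seed_word = NA_character_,
                          score = NA_real_, mark_profiles = NULL,
                          member_seeds = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) stop_input("`counts` must have 4 columns (A,C,G,T)")
  if (any(counts < 0)) stop_input("`counts` must be non-negative")
  colnames(counts) <- DNA_BASES
  consensus <- paste(consensus_from_counts(counts), collapse = "")
  structure(
    list(
      counts = counts, support = support, id = id %||% consensus,
      seed_word = seed_word, consensus = consensus, score = score,
      mark_profiles = mark_profiles,
      member_seeds = member_seeds %||% seed_word[!is.na(seed_word)]
    ),
    class = "pfm_motif"
  )
}

#' @export
print.pfm_motif <- function(x, ...) {
  cat(sprintf(
    "<pfm_motif '%s'> length %d, support %d, consensus %s\n",
    x$id, nrow(x$counts), as.integer(round(x$support)), x$consensus
  ))
  invisible(x)
}

#' Pseudocount-normalized probability matrix of a motif
#'
#' @param motif A `"pfm_motif"`.
#' @param pseudocount Pseudocount added per cell.
#' @return L x 4 row-stochastic matrix.
#' @export
motif_probabilities <- function(motif, pseudocount = 0.25) {
  m <- motif$counts + pseudocount
  m / rowSums(m)
}

#' Generalize a seed word into a primary motif
#'
#' Enumerates all `4 * K` single-position variants of the seed (the seed's
#' own base plus the 3 substitutions at each of the K positions; 32
#' enumerations for K = 8) and fills the PFM with each variant's occurrence
#' count from the index: `counts[i, b]` is the count of the word carrying
#' base `b` at position `i` and the seed bases elsewhere. Multi-mismatch
#' words are deliberately not enumerated.
#'
#' @param seed_word The seed k-mer (must be indexed).
#' @param index A `"kmer_index"` with `K == nchar(seed_word)`.
#' @return A `"pfm_motif"` with `support` equal to the seed's own count and
#'   attribute `n_variants = 4 * K`.
#' @export
generalize_seed <- function(seed_word, index) {
  K <- index$K
  if (nchar(seed_word) != K) stop_input("`seed_word` length must equal index K")
  wc <- kmer_count(index, seed_word)
  if (wc == 0) stop_input(paste0("seed '", seed_word, "' is not indexed"))
  chars <- strsplit(seed_word, "")[[1]]
  variants <- character(4L * K)
  v <- 0L
  for (i in seq_len(K)) {
    for (b in seq_len(4L)) {
      w <- chars
      w[i] <- DNA_BASES[b]
      v <- v + 1L
      variants[v] <- paste(w, collapse = "")
    }
  }
  cnt <- index$counts$count[match(variants, index$counts$kmer)]
  cnt[is.na(cnt)] <- 0
  counts <- matrix(cnt, nrow = K, ncol = 4, byrow = TRUE,
                   dimnames = list(NULL, DNA_BASES))
  out <- new_pfm_motif(counts, support = wc, id = seed_word,
                       seed_word = seed_word)
  attr(out, "n_variants") <- length(variants)
  out
}

#' Best-alignment distance between two motifs
#'
#' All relative offsets with overlap of at least `min_overlap` columns and
#' both orientations (the second motif as-is and reverse-complemented) are
#' checked; the Pearson correlation `r` between the flattened overlapping
#' probability sub-matrices defines the sequence dissimilarity `1 - r`, and
#' the alignment maximizing `r` is returned. When both motifs carry mark
#' profiles and `use_marks = TRUE`, the symmetrized KL divergence between
#' the profiles (rescaled into `[0, 1)` as `KL / (1 + KL)`, averaged over
#' shared tracks) is mixed in with weight `beta_cluster`.
#'
#' @param m1,m2 `"pfm_motif"` objects.
#' @param use_marks Whether to include the mark-distribution term.
#' @param beta_cluster Weight of the mark term in `[0, 1)`.
#' @param pseudocount Pseudocount for probability normalization.
#' @param min_overlap Minimum overlapping columns; default
#'   `max(4, ceiling(min(L1, L2) / 2))`.
#' @return List with `distance` (in `[0, 2]`; 2 when no admissible overlap
#'   exists), `offset` (m2's first column sits at m1 position `offset + 1`)
#'   and `orientation` (`"+"` or `"-"`).
#' @export
motif_distance <- function(m1, m2, use_marks = FALSE, beta_cluster = 0.2,
                           pseudocount = 0.25, min_overlap = NULL) {
  p1 <- motif_probabilities(m1, pseudocount)
  L1 <- nrow(p1); L2 <- nrow(m2$counts)
  minov <- min_overlap %||% max(4L, ceiling(min(L1, L2) / 2))
  if (minov > min(L1, L2)) {
    return(list(distance = 2, offset = 0L, orientation = "+"))
  }
  orientations <- list(
    "+" = motif_probabilities(m2, pseudocount),
    "-" = revcomp_matrix(motif_probabilities(m2, pseudocount))
  )
  marks1 <- m1$mark_profiles
  marks2 <- m2$mark_profiles
  with_marks <- use_marks && length(marks1) > 0 && length(marks2) > 0
  best <- list(distance = 2, offset = 0L, orientation = "+")
  for (ori in names(orientations)) {
    p2 <- orientations[[ori]]
    mark_term <- 0
    if (with_marks) {
      shared <- intersect(names(marks1), names(marks2))
      if (length(shared) > 0) {
        kl <- mean(vapply(shared, function(tr) {
          prof2 <- marks2[[tr]]
          if (ori == "-") prof2 <- rev(prof2)
          symmetrized_kl(marks1[[tr]], prof2)
        }, numeric(1)))
        mark_term <- kl / (1 + kl)
      }
    }
    for (o in seq(-(L2 - minov), L1 - minov)) {
      i1 <- max(1L, o + 1L):min(L1, o + L2)
      i2 <- i1 - o
      r <- fast_pearson(as.vector(p1[i1, , drop = FALSE]),
                        as.vector(p2[i2, , drop = FALSE]))
      if (is.na(r)) next
      d_seq <- 1 - r
      d <- if (with_marks) {
        (1 - beta_cluster) * d_seq + beta_cluster * mark_term
      } else {
        d_seq
      }
      if (d < best$distance) {
        best <- list(distance = d, offset = as.integer(o), orientation = ori)
      }
    }
  }
  best
}

fast_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den2 <- (n * sum(x * x) - sx * sx) * (n * sum(y * y) - sy * sy)
  if (den2 <= 0) return(NA_real_)
  num / sqrt(den2)
}

symmetrized_kl <- function(p, q, eps = 1e-6) {
  p <- p / sum(p); q <- q / sum(q)
  n <- length(p)
  p <- (p + eps) / (1 + n * eps)
  q <- (q + eps) / (1 + n * eps)
  0.5 * sum(p * log(p / q)) + 0.5 * sum(q * log(q / p))
}

#' Pairwise motif distance matrix
#'
#' @param motifs List of `"pfm_motif"` objects.
#' @inheritParams motif_distance
#' @return List with `distance` (M x M symmetric, zero diagonal), `offset`
#'   and `orientation` matrices recording each pair's best alignment.
#' @export
motif_distance_matrix <- function(motifs, use_marks = FALSE,
                                  beta_cluster = 0.2, pseudocount = 0.25) {
  M <- length(motifs)
  D <- matrix(0, M, M)
  off <- matrix(0L, M, M)
  ori <- matrix("+", M, M)
  if (M < 2) {
    return(list(distance = D, offset = off, orientation = ori))
  }
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      a <- motif_distance(motifs[[i]], motifs[[j]], use_marks, beta_cluster,
                          pseudocount)
      D[i, j] <- D[j, i] <- a$distance
      off[i, j] <- a$offset
      # alignment of (j, i) is the inverse transform of (i, j)
      off[j, i] <- if (a$orientation == "+") {
        -a$offset
      } else {
        as.integer(nrow(motifs[[j]]$counts) - nrow(motifs[[i]]$counts) + a$offset)
      }
      ori[i, j] <- ori[j, i] <- a$orientation
    }
  }
  list(distance = D, offset = off, orientation = ori)
}

#' Cluster primary motifs
#'
#' Average-linkage agglomerative clustering of the motif distance matrix.
#' The cluster number is chosen by the gap statistic with the one-standard-
#' error rule against `B` reference datasets of uniformly sampled
#' row-stochastic L x 4 matrices (paired with uniform-noise mark profiles
#' when the input motifs carry marks), unless a fixed dendrogram height
#' `cluster_threshold` is supplied.
#'
#' @param motifs List of `"pfm_motif"` objects.
#' @param dist Result of [motif_distance_matrix()] (computed when `NULL`).
#' @param use_marks,beta_cluster,pseudocount Passed to the distance.
#' @param B Number of gap-statistic reference datasets.
#' @param k_max Largest cluster number examined.
#' @param cluster_threshold Optional fixed height cutoff (disables the gap
#'   statistic).
#' @param seed Seed for the reference draws.
#' @return List with `assignment` (integer vector), `k`, `hclust`, `gap`
#'   (tibble of k, gap, se) and `dist`.
#' @export
cluster_motifs <- function(motifs, dist = NULL, use_marks = FALSE,
                           beta_cluster = 0.2, pseudocount = 0.25, B = 20L,
                           k_max = 30L, cluster_threshold = NULL, seed = 1L) {
  M <- length(motifs)
  if (M == 0) stop_input("no motifs to cluster")
  dist <- dist %||%
    motif_distance_matrix(motifs, use_marks, beta_cluster, pseudocount)
  if (M == 1) {
    return(list(assignment = 1L, k = 1L, hclust = NULL,
                gap = NULL, dist = dist))
  }
  hc <- stats::hclust(stats::as.dist(dist$distance), method = "average")
  if (!is.null(cluster_threshold)) {
    assignment <- enforce_sentinel(stats::cutree(hc, h = cluster_threshold),
                                   dist$distance)
    return(list(assignment = assignment, k = max(assignment), hclust = hc,
                gap = NULL, dist = dist))
  }
  ks <- seq_len(min(M, k_max))
  logW <- vapply(ks, function(k) {
    log_within_dispersion(dist$distance, stats::cutree(hc, k = k))
  }, numeric(1))
  track_names <- names(motifs[[1]]$mark_profiles %||% list())
  prof_len <- if (length(track_names)) length(motifs[[1]]$mark_profiles[[1]]) else 0L
  lens <- vapply(motifs, function(m) nrow(m$counts), integer(1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ref_logW <- matrix(NA_real_, nrow = B, ncol = length(ks))
  for (b in seq_len(B)) {
    ref <- lapply(lens, function(L) {
      p <- matrix(stats::rexp(L * 4), L, 4) # Dirichlet(1,1,1,1) rows
      p <- p / rowSums(p)
      marks <- NULL
      if (prof_len > 0) {
        marks <- lapply(stats::setNames(track_names, track_names), function(tr) {
          v <- stats::runif(prof_len)
          v / sum(v)
        })
      }
      new_pfm_motif(p * 100, support = 100, mark_profiles = marks)
    })
    refD <- motif_distance_matrix(ref, use_marks, beta_cluster, pseudocount)$distance
    ref_hc <- stats::hclust(stats::as.dist(refD), method = "average")
    ref_logW[b, ] <- vapply(ks, function(k) {
      log_within_dispersion(refD, stats::cutree(ref_hc, k = k))
    }, numeric(1))
  }
  gap <- colMeans(ref_logW) - logW
  se <- apply(ref_logW, 2, stats::sd) * sqrt(1 + 1 / B)
  k_star <- length(ks)
  for (k in seq_len(length(ks) - 1L)) {
    if (gap[k] >= gap[k + 1L] - se[k + 1L]) {
      k_star <- k
      break
    }
  }
  assignment <- enforce_sentinel(stats::cutree(hc, k = ks[k_star]),
                                 dist$distance)
  list(
    assignment = assignment, k = max(assignment), hclust = hc,
    gap = tibble(k = ks, gap = gap, se = se), dist = dist
  )
}

# pairs at the sentinel distance (no admissible alignment) must never share
# a cluster: split offending clusters into connected components of the
# "alignable" (d < 2) graph
enforce_sentinel <- function(assignment, D, sentinel = 2) {
  out <- integer(length(assignment))
  nxt <- 0L
  for (cl in unique(assignment)) {
    idx <- which(assignment == cl)
    comp <- rep(0L, length(idx))
    for (i in seq_along(idx)) {
      if (comp[i] > 0L) next
      nxt <- nxt + 1L
      queue <- i
      comp[i] <- nxt
      while (length(queue)) {
        cur <- queue[[1]]
        queue <- queue[-1]
        nb <- which(comp == 0L &
                      D[idx[cur], idx] < sentinel - 1e-9)
        comp[nb] <- nxt
        queue <- c(queue, nb)
      }
    }
    out[idx] <- comp
  }
  match(out, unique(out))
}

log_within_dispersion <- function(D, assignment) {
  W <- 0
  for (cl in unique(assignment)) {
    idx <- which(assignment == cl)
    if (length(idx) > 1) {
      W <- W + sum(D[idx, idx]) / (2 * length(idx))
    }
  }
  log(max(W, 1e-12))
}

#' Merge a cluster of motifs into one
#'
#' Members are star-aligned to the cluster's highest-scoring motif using
#' each member's best pairwise offset/orientation against that reference;
#' count matrices are summed column-wise over the union span and mark
#' profiles averaged weighted by support.
#'
#' @param members List of `"pfm_motif"` objects (one cluster).
#' @param use_marks,beta_cluster,pseudocount Passed to the pairwise
#'   alignment.
#' @return A merged `"pfm_motif"`.
#' @export
merge_cluster <- function(members, use_marks = FALSE, beta_cluster = 0.2,
                          pseudocount = 0.25) {
  if (length(members) == 0) stop_input("empty cluster")
  if (length(members) == 1) return(members[[1]])
  scores <- vapply(members, function(m) {
    s <- m$score
    if (is.na(s)) m$support else s
  }, numeric(1))
  ref_i <- which.max(scores)
  ref <- members[[ref_i]]
  Lref <- nrow(ref$counts)
  placements <- lapply(seq_along(members), function(i) {
    if (i == ref_i) {
      return(list(counts = members[[i]]$counts, offset = 0L, orientation = "+"))
    }
    a <- motif_distance(ref, members[[i]], use_marks, beta_cluster, pseudocount)
    cm <- members[[i]]$counts
    if (a$orientation == "-") cm <- revcomp_matrix(cm)
    list(counts = cm, offset = a$offset, orientation = a$orientation)
  })
  lo <- min(vapply(placements, function(p) p$offset + 1L, integer(1)), 1L)
  hi <- max(vapply(placements, function(p) p$offset + nrow(p$counts), integer(1)), Lref)
  counts <- matrix(0, nrow = hi - lo + 1L, ncol = 4,
                   dimnames = list(NULL, DNA_BASES))
  for (p in placements) {
    rows <- (p$offset + 1L):(p$offset + nrow(p$counts)) - lo + 1L
    counts[rows, ] <- counts[rows, ] + p$counts
  }
  supports <- vapply(members, function(m) m$support, numeric(1))
  marks <- NULL
  shared <- Reduce(intersect, lapply(members, function(m) names(m$mark_profiles %||% list())))
  if (length(shared) > 0) {
    marks <- lapply(stats::setNames(shared, shared), function(tr) {
      prof <- matrix(0, nrow = length(members),
                     ncol = length(members[[1]]$mark_profiles[[tr]]))
      for (i in seq_along(members)) {
        v <- members[[i]]$mark_profiles[[tr]]
        if (placements[[i]]$orientation == "-") v <- rev(v)
        prof[i, ] <- v
      }
      drop(supports %*% prof) / sum(supports)
    })
  }
  new_pfm_motif(
    counts, support = sum(supports), id = ref$id, seed_word = ref$seed_word,
    score = max(scores), mark_profiles = marks,
    member_seeds = unlist(lapply(members, function(m) m$member_seeds))
  )
}

#' Trim ambiguous or low-count motif ends
#'
#' Columns are stripped from each end while their information content is
#' below `min_info` bits (after pseudocounts) or their support is below
#' `min_support_frac` of the maximum column support; never trims below 4
#' columns. A motif that would vanish entirely is returned untrimmed with a
#' warning.
#'
#' @param motif A `"pfm_motif"`.
#' @param min_info Minimum column information content in bits.
#' @param min_support_frac Minimum column support fraction.
#' @param pseudocount Pseudocount for the information computation.
#' @return A trimmed `"pfm_motif"`.
#' @export
trim_motif <- function(motif, min_info = 0.3, min_support_frac = 0.1,
                       pseudocount = 0.25) {
  counts <- motif$counts
  L <- nrow(counts)
  if (L < 1) stop_input("motif has no columns")
  info <- column_information(counts, pseudocount)
  support <- rowSums(counts)
  weak <- info < min_info | support < min_support_frac * max(support)
  lo <- 1L
  hi <- L
  while (lo <= hi && weak[lo] && (hi - lo + 1L) > 4L) lo <- lo + 1L
  while (hi >= lo && weak[hi] && (hi - lo + 1L) > 4L) hi <- hi - 1L
  if (all(weak[lo:hi])) {
    warn(paste0("motif '", motif$id, "' is weak everywhere; returned untrimmed"))
    return(motif)
  }
  out <- motif
  out$counts <- counts[lo:hi, , drop = FALSE]
  out$consensus <- paste(consensus_from_counts(out$counts), collapse = "")
  out
}

#' Build final motifs from scored seeds
#'
#' Generalizes the top seeds to primary PFMs, clusters them, merges each
#' cluster, trims the merged motifs, and ranks by total support times the
#' best member score.
#'
#' @param seed_scores A `"seed_scores"` object (or its `$scores` tibble).
#' @param index A `"kmer_index"`.
#' @param config A [motif_config()].
#' @return List of trimmed, ranked `"pfm_motif"` objects with ids
#'   `motif_1`, `motif_2`, ...
#' @export
build_motifs <- function(seed_scores, index, config) {
  scores <- if (inherits(seed_scores, "seed_scores")) seed_scores$scores else seed_scores
  features <- if (inherits(seed_scores, "seed_scores")) seed_scores$features else NULL
  scores <- utils::head(scores, config$max_seeds)
  if (nrow(scores) == 0) return(list())
  use_marks <- !is.null(features) && config$beta_cluster > 0
  primaries <- lapply(seq_len(nrow(scores)), function(i) {
    m <- generalize_seed(scores$kmer[i], index)
    m$score <- scores$S[i]
    if (!is.null(features)) {
      f <- features %>% filter(.data$kmer == scores$kmer[i])
      if (nrow(f) > 0) {
        m$mark_profiles <- stats::setNames(f$smoothed, f$track)
      }
    }
    m
  })
  cl <- cluster_motifs(
    primaries, use_marks = use_marks, beta_cluster = config$beta_cluster,
    pseudocount = config$pseudocount, B = config$gap_B,
    cluster_threshold = config$cluster_threshold, seed = config$seed
  )
  merged <- lapply(split(seq_along(primaries), cl$assignment), function(idx) {
    merge_cluster(primaries[idx], use_marks = use_marks,
                  beta_cluster = config$beta_cluster,
                  pseudocount = config$pseudocount)
  })
  trimmed <- lapply(merged, trim_motif, min_info = config$trim_min_info,
                    min_support_frac = config$trim_min_support_frac,
                    pseudocount = config$pseudocount)
  # rank by the best member's combined seed score (the quantity Eq-2-style
  # ranking optimizes); support only breaks ties, so that sheer occurrence
  # volume (e.g. shifted-word repeat families) cannot outrank shape-backed
  # seeds
  rank_score <- vapply(trimmed, function(m) {
    if (is.na(m$score)) -Inf else m$score
  }, numeric(1))
  trimmed <- trimmed[order(-rank_score,
                           -vapply(trimmed, function(m) m$support, numeric(1)))]
  for (i in seq_along(trimmed)) trimmed[[i]]$id <- paste0("motif_", i)
  unname(trimmed)
}
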