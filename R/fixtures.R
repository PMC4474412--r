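#' Example planted position frequency matrix
#'
#' A length-`L` PFM with one dominant base per position (default consensus
#' `ATGCAAATC` for `L = 9`, an Oct4-like word) and the remaining mass
#' spread evenly - the canonical planted motif of the synthetic benchmarks.
#'
#' @param consensus Consensus string (defines the length).
#' @param dominance Probability of the consensus base at each position.
#' @return L x 4 row-stochastic matrix (columns A,C,G,T).
#' @export
example_pfm <- function(consensus = "ATGCAAATC", dominance = 0.85) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  if (any(!chars %in% DNA_BASES)) stop_input("consensus must be over ACGT")
  p <- matrix((1 - dominance) / 3, nrow = length(chars), ncol = 4,
              dimnames = list(NULL, DNA_BASES))
  for (i in seq_along(chars)) p[i, chars[i]] <- dominance
  p
}

#' Specification of a synthetic planted-motif fixture
#'
#' Describes a fully synthetic benchmark: background sequence from a Markov
#' chain, motif instances drawn from a known PFM planted at a controlled
#' rate at region centres, and per-track signal with a controlled shape
#' centred on each planted instance. The default is the benchmark operating
#' point used throughout the package's tests: 2000 regions of 200 bp,
#' uniform order-0 background, a 9-bp PFM planted in 40% of regions, a
#' DNase-like Gaussian peak track (sd 75 bp) and a flat-plus-noise decoy
#' track.
#'
#' @param n_regions Number of regions.
#' @param region_length Region length in bp.
#' @param background A `"markov_background"`, or `NULL` for uniform order 0.
#' @param planted_pfm L x 4 probability matrix of the planted motif.
#' @param plant_rate Fraction of regions receiving one instance.
#' @param signal_shapes Named list of per-track shape specs, each a list
#'   with `shape` in `c("gaussian", "flat", "asymmetric", "noisy")` and
#'   shape parameters (`sigma`, `height`, `level`, `noise_sd`, `skew`).
#' @param signal_halfwidth Signal support half-width (bp) around each
#'   planted instance midpoint.
#' @param summit_jitter Uniform jitter (bp, each direction) applied to the
#'   summit positions written for planted instances.
#' @param spacing Gap (bp) between consecutive regions on the synthetic
#'   chromosome; defaults to `2 * signal_halfwidth` so signal windows never
#'   overlap.
#' @param chrom Synthetic chromosome name.
#' @param seed Integer seed; fixtures are byte-reproducible under it.
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_regions = 2000L,
                         region_length = 200L,
                         background = NULL,
                         planted_pfm = example_pfm(),
                         plant_rate = 0.4,
                         signal_shapes = list(
                           DNaseI = list(shape = "gaussian", sigma = 75),
                           decoy = list(shape = "noisy", level = 1, noise_sd = 0.5)
                         ),
                         signal_halfwidth = 1000L,
                         summit_jitter = 10L,
                         spacing = NULL,
                         chrom = "chrSyn",
                         seed = 1L) {
  if (plant_rate < 0 || plant_rate > 1) stop_input("`plant_rate` must be in [0,1]")
  if (!is.null(planted_pfm)) {
    if (nrow(planted_pfm) > region_length) {
      stop_input("planted motif longer than the regions")
    }
    if (any(abs(rowSums(planted_pfm) - 1) > 1e-6)) {
      stop_input("`planted_pfm` rows must sum to 1")
    }
  }
  for (sh in signal_shapes) {
    if (!sh$shape %in% c("gaussian", "flat", "asymmetric", "noisy")) {
      stop_input(paste0("unknown signal shape: ", sh$shape))
    }
    if (!is.null(sh$sigma) && sh$sigma <= 0) stop_input("`sigma` must be > 0")
  }
  structure(
    list(
      n_regions = as.integer(n_regions),
      region_length = as.integer(region_length),
      background = background, planted_pfm = planted_pfm,
      plant_rate = plant_rate, signal_shapes = signal_shapes,
      signal_halfwidth = as.integer(signal_halfwidth),
      summit_jitter = as.integer(summit_jitter),
      spacing = as.integer(spacing %||% (2L * signal_halfwidth)),
      chrom = chrom, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

uniform_background <- function() {
  structure(
    list(order = 0L,
         initial_probs = stats::setNames(rep(0.25, 4), DNA_BASES),
         transition_probs = NULL, source = "target-regions"),
    class = "markov_background"
  )
}

#' Generate a synthetic planted-motif fixture
#'
#' Samples background regions, plants one PFM-drawn instance at the centre
#' of a random `plant_rate` fraction of regions, lays per-track signal with
#' the requested shape centred on each planted instance, and records
#' summits (jittered instance midpoints) and a truth table. When `dir` is
#' given, everything is also written in the standard formats
#' (FASTA/bedGraph/BED/TSV) so the normal readers can consume it.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory.
#' @return List with `regions` (tibble), `tracks` (list of
#'   `"signal_track"`), `summits` (tibble), `truth` (tibble with `region`,
#'   `offset`, `word`, `kind`, `centre`), `spec`, and `paths` when written.
#' @export
make_fixture <- function(spec, dir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  bg <- spec$background %||% uniform_background()
  n <- spec$n_regions
  len <- spec$region_length
  seqs <- simulate_background(bg, rep(len, n), n_simulations = 1L,
                              seed = spec$seed)[[1]]
  starts <- (seq_len(n) - 1L) * (len + spec$spacing)
  regions <- tibble(
    id = paste0("r", seq_len(n)),
    chrom = spec$chrom,
    start = as.integer(starts),
    end = as.integer(starts + len),
    sequence = seqs
  )
  truth <- tibble(region = integer(0), offset = integer(0),
                  word = character(0), kind = character(0),
                  centre = integer(0))
  if (!is.null(spec$planted_pfm) && spec$plant_rate > 0) {
    n_plant <- round(spec$plant_rate * n)
    planted_idx <- sort(sample.int(n, n_plant))
    planted <- plant_instances(regions, planted_idx, spec$planted_pfm, "motif")
    regions <- planted$regions
    truth <- bind_rows(truth, planted$truth)
  }
  tracks <- lapply(names(spec$signal_shapes), function(nm) {
    lay_signal(spec$signal_shapes[[nm]], nm, truth$centre,
               chrom = spec$chrom,
               chrom_len = max(regions$end) + spec$signal_halfwidth,
               halfwidth = spec$signal_halfwidth)
  })
  names(tracks) <- names(spec$signal_shapes)
  jitter <- if (nrow(truth) > 0 && spec$summit_jitter > 0) {
    sample(seq(-spec$summit_jitter, spec$summit_jitter), nrow(truth),
           replace = TRUE)
  } else {
    rep(0L, nrow(truth))
  }
  summits <- tibble(
    chrom = spec$chrom,
    summit = as.integer(truth$centre + jitter),
    name = paste0("summit", seq_len(nrow(truth)))
  )
  out <- list(regions = regions, tracks = tracks, summits = summits,
              truth = truth, spec = spec)
  if (!is.null(dir)) out$paths <- write_fixture(out, dir)
  out
}

plant_instances <- function(regions, idx, pfm, kind) {
  L <- nrow(pfm)
  len <- nchar(regions$sequence[1])
  offset <- (len - L) %/% 2L
  words <- vapply(seq_along(idx), function(i) {
    paste(DNA_BASES[vapply(
      seq_len(L), function(pos) sample.int(4L, 1L, prob = pfm[pos, ]),
      integer(1)
    )], collapse = "")
  }, character(1))
  seqs <- regions$sequence
  seqs[idx] <- paste0(
    substr(seqs[idx], 1L, offset), words,
    substr(seqs[idx], offset + L + 1L, len)
  )
  regions$sequence <- seqs
  truth <- tibble(
    region = idx, offset = offset, word = words, kind = kind,
    centre = as.integer(regions$start[idx] + offset + L %/% 2L)
  )
  list(regions = regions, truth = truth)
}

lay_signal <- function(shape, name, centres, chrom, chrom_len, halfwidth) {
  vec <- numeric(chrom_len)
  if (length(centres) > 0) {
    x <- seq(-halfwidth, halfwidth - 1L)
    profile <- switch(
      shape$shape,
      gaussian = (shape$height %||% 10) *
        exp(-x^2 / (2 * (shape$sigma %||% 75)^2)),
      flat = rep(shape$level %||% 1, length(x)),
      noisy = rep(shape$level %||% 1, length(x)),
      asymmetric = {
        s <- shape$sigma %||% 75
        k <- shape$skew %||% 4
        (shape$height %||% 10) *
          ifelse(x < 0, exp(-x^2 / (2 * s^2)), exp(-x^2 / (2 * (k * s)^2)))
      }
    )
    for (c0 in centres) {
      pos <- c0 + x
      ok <- pos >= 0 & pos < chrom_len
      vec[pos[ok] + 1L] <- vec[pos[ok] + 1L] + profile[ok]
    }
    if (shape$shape == "noisy") {
      covered <- which(vec > 0)
      vec[covered] <- pmax(
        0, vec[covered] + stats::rnorm(length(covered),
                                       sd = shape$noise_sd %||% 0.5)
      )
    }
  }
  signal_track(name, stats::setNames(list(vec), chrom))
}

#' Generate a fixture with a frequency-matched spurious repeat word
#'
#' Plants the motif (with its kurtotic signal shape) in a `plant_rate`
#' fraction of regions and a tandem-repeat decoy word in an equally sized,
#' disjoint set of regions whose signal takes the decoy shape
#' (flat/noisy/asymmetric). The repeat is over-represented to the same
#' degree as the motif word, so only the signal shape separates them.
#'
#' @param spec A [fixture_spec()]; its first signal shape is laid over the
#'   motif instances and `decoy_shape` over the repeat instances.
#' @param repeat_word The decoy word (default a CT tandem repeat of the
#'   planted motif's length).
#' @param decoy_shape Shape spec for the decoy signal (default flat).
#' @param dir Optional output directory.
#' @return As [make_fixture()]; the truth table's `kind` distinguishes
#'   `"motif"` from `"repeat"` instances.
#' @export
make_spurious_word_fixture <- function(spec, repeat_word = NULL,
                                       decoy_shape = list(shape = "asymmetric",
                                                          sigma = 75, skew = 4),
                                       dir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  L <- nrow(spec$planted_pfm)
  repeat_word <- repeat_word %||%
    paste(rep_len(c("C", "T"), L), collapse = "")
  bg <- spec$background %||% uniform_background()
  n <- spec$n_regions
  len <- spec$region_length
  seqs <- simulate_background(bg, rep(len, n), n_simulations = 1L,
                              seed = spec$seed)[[1]]
  starts <- (seq_len(n) - 1L) * (len + spec$spacing)
  regions <- tibble(
    id = paste0("r", seq_len(n)),
    chrom = spec$chrom,
    start = as.integer(starts),
    end = as.integer(starts + len),
    sequence = seqs
  )
  n_plant <- round(spec$plant_rate * n)
  # the decoy is planted deterministically while motif instances are
  # PFM-sampled, so matching the expected *consensus word* count needs
  # n_plant * P(consensus | PFM) decoy instances
  p_cons <- prod(apply(spec$planted_pfm, 1, max))
  n_repeat <- max(1L, round(n_plant * p_cons))
  if (n_plant + n_repeat > n) {
    stop_input("plant_rate too high to also plant the decoy")
  }
  pick <- sample.int(n, n_plant + n_repeat)
  motif_idx <- sort(pick[seq_len(n_plant)])
  repeat_idx <- sort(pick[n_plant + seq_len(n_repeat)])
  planted <- plant_instances(regions, motif_idx, spec$planted_pfm, "motif")
  regions <- planted$regions
  repeat_pfm <- diag_pfm(repeat_word)
  planted_r <- plant_instances(regions, repeat_idx, repeat_pfm, "repeat")
  regions <- planted_r$regions
  truth <- bind_rows(planted$truth, planted_r$truth)
  chrom_len <- max(regions$end) + spec$signal_halfwidth
  motif_shape <- spec$signal_shapes[[1]]
  # unless given explicitly, scale the decoy so its window integral matches
  # the motif shape's: the decoy differs in shape, not in total signal
  if (is.null(decoy_shape$height) && is.null(decoy_shape$level)) {
    a_m <- shape_area(motif_shape, spec$signal_halfwidth)
    a_d <- shape_area(decoy_shape, spec$signal_halfwidth)
    if (decoy_shape$shape %in% c("flat", "noisy")) {
      decoy_shape$level <- a_m / (2 * spec$signal_halfwidth)
    } else {
      decoy_shape$height <- (decoy_shape$height %||% 10) * a_m / a_d
    }
  }
  tracks <- list(
    lay_signal_two(motif_shape, decoy_shape,
                   names(spec$signal_shapes)[1] %||% "signal",
                   planted$truth$centre, planted_r$truth$centre,
                   spec$chrom, chrom_len, spec$signal_halfwidth)
  )
  names(tracks) <- names(spec$signal_shapes)[1] %||% "signal"
  jitter <- if (spec$summit_jitter > 0) {
    sample(seq(-spec$summit_jitter, spec$summit_jitter),
           nrow(planted$truth), replace = TRUE)
  } else {
    rep(0L, nrow(planted$truth))
  }
  summits <- tibble(
    chrom = spec$chrom,
    summit = as.integer(planted$truth$centre + jitter),
    name = paste0("summit", seq_len(nrow(planted$truth)))
  )
  out <- list(regions = regions, tracks = tracks, summits = summits,
              truth = truth, spec = spec, repeat_word = repeat_word)
  if (!is.null(dir)) out$paths <- write_fixture(out, dir)
  out
}

# integral of a shape's per-bp profile over the signal window
shape_area <- function(shape, halfwidth) {
  x <- seq(-halfwidth, halfwidth - 1L)
  sum(switch(
    shape$shape,
    gaussian = (shape$height %||% 10) *
      exp(-x^2 / (2 * (shape$sigma %||% 75)^2)),
    flat = rep(shape$level %||% 1, length(x)),
    noisy = rep(shape$level %||% 1, length(x)),
    asymmetric = {
      s <- shape$sigma %||% 75
      k <- shape$skew %||% 4
      (shape$height %||% 10) *
        ifelse(x < 0, exp(-x^2 / (2 * s^2)), exp(-x^2 / (2 * (k * s)^2)))
    }
  ))
}

# deterministic PFM whose consensus is the given word
diag_pfm <- function(word) {
  chars <- strsplit(word, "")[[1]]
  p <- matrix(0, nrow = length(chars), ncol = 4,
              dimnames = list(NULL, DNA_BASES))
  for (i in seq_along(chars)) p[i, chars[i]] <- 1
  p
}

# one track, motif centres with one shape and decoy centres with another
lay_signal_two <- function(shape_m, shape_d, name, centres_m, centres_d,
                           chrom, chrom_len, halfwidth) {
  t1 <- lay_signal(shape_m, name, centres_m, chrom, chrom_len, halfwidth)
  t2 <- lay_signal(shape_d, name, centres_d, chrom, chrom_len, halfwidth)
  signal_track(name, stats::setNames(
    list(t1$values[[chrom]] + t2$values[[chrom]]), chrom
  ))
}

write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    regions = file.path(dir, "regions.fa"),
    summits = file.path(dir, "summits.bed"),
    truth = file.path(dir, "truth.tsv")
  )
  write_regions_fasta(fx$regions, paths$regions)
  write_summits_bed(fx$summits, paths$summits)
  readr::write_tsv(fx$truth, paths$truth)
  paths$tracks <- vapply(names(fx$tracks), function(nm) {
    p <- file.path(dir, paste0(nm, ".bedGraph"))
    write_signal_bedgraph(fx$tracks[[nm]], p)
    p
  }, character(1))
  paths
}
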