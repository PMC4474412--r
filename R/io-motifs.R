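#' Write motifs in MEME minimal format (v4)
#'
#' Letter-probability rows are the pseudocount-normalized count matrix; each
#' row sums to 1 within 1e-6. A sidecar TSV with per-motif sub-scores and
#' mark-distribution vectors can be written with [write_motif_scores_tsv()].
#'
#' @param motifs List of `"pfm_motif"` objects.
#' @param path Output path.
#' @param background Optional length-4 background frequencies (A,C,G,T)
#'   written to the header; default uniform.
#' @param pseudocount Pseudocount per cell before normalization.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4),
                              pseudocount = 0) {
  if (length(motifs) == 0) stop_input("no motifs to write")
  lines <- c(
    "MEME version 4",
    "",
    "ALPHABET= ACGT",
    "",
    "strands: + -",
    "",
    "Background letter frequencies",
    paste(
      sprintf("%s %.6f", DNA_BASES, background / sum(background)),
      collapse = " "
    ),
    ""
  )
  for (m in motifs) {
    if (!inherits(m, "pfm_motif")) stop_input("motifs must be `pfm_motif` objects")
    if (m$support <= 0 || (all(m$counts == 0) && pseudocount <= 0)) {
      stop_input(paste0("motif '", m$id, "' has zero support"))
    }
    p <- motif_probabilities(m, pseudocount = pseudocount)
    lines <- c(
      lines,
      paste0("MOTIF ", m$id, " ", m$consensus),
      sprintf(
        "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
        nrow(p), max(1L, as.integer(round(m$support)))
      ),
      apply(p, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
      ""
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read motifs from a MEME minimal format file
#'
#' Round-trips the output of [write_meme_motifs()]. Probabilities are
#' rescaled by `nsites` back into pseudo-counts.
#'
#' @param path Path to a MEME minimal motif file.
#' @return List of `"pfm_motif"` objects.
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) stop_input(paste0("motif file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) stop_input(paste0("no MOTIF blocks in ", path))
  out <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    i <- starts[j]
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    id <- hdr[2]
    mat_line <- lines[i + 1L]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", mat_line))
    nsites <- as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", mat_line))
    rows <- lines[(i + 2L):(i + 1L + w)]
    p <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    if (ncol(p) != 4 || any(abs(rowSums(p) - 1) > 1e-4)) {
      stop_input(paste0("malformed letter-probability matrix for motif ", id))
    }
    colnames(p) <- DNA_BASES
    out[[j]] <- new_pfm_motif(
      counts = p * nsites, support = nsites, id = id,
      seed_word = if (length(hdr) >= 3) hdr[3] else NA_character_
    )
  }
  out
}

#' Write the per-motif score sidecar TSV
#'
#' One row per motif with support, ranking score, member seeds and (when
#' available) each track's smoothed mark-distribution vector serialized as a
#' comma-separated list.
#'
#' @param motifs List of `"pfm_motif"` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_scores_tsv <- function(motifs, path) {
  rows <- purrr::map_dfr(motifs, function(m) {
    base <- tibble(
      motif_id = m$id,
      consensus = m$consensus,
      length = nrow(m$counts),
      support = m$support,
      score = m$score %||% NA_real_,
      member_seeds = paste(m$member_seeds %||% m$seed_word, collapse = ",")
    )
    for (tr in names(m$mark_profiles %||% list())) {
      base[[paste0("profile_", tr)]] <-
        paste(signif(m$mark_profiles[[tr]], 6), collapse = ",")
    }
    base
  })
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Export a word's mark distribution as TSV
#'
#' Two columns, `bin_start` (bp relative to the occurrence centre) and
#' `value`, suitable for plotting aggregate profiles.
#'
#' @param md A `"mark_distribution"` object.
#' @param path Output path.
#' @param which One of `"bins"`, `"normalized"`, `"smoothed"`.
#' @return `path`, invisibly.
#' @export
write_mark_distribution_tsv <- function(md, path, which = "smoothed") {
  stopifnot(which %in% c("bins", "normalized", "smoothed"))
  B <- length(md$bins)
  readr::write_tsv(
    tibble(
      bin_start = (seq_len(B) - 1L) * md$bin_width - md$halfwidth,
      value = md[[which]]
    ),
    path
  )
  invisible(path)
}
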