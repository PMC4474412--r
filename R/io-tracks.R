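#' Construct a signal track
#'
#' A signal track is a named, per-bp numeric signal over one or more
#' chromosomes. Positions are 0-based: element `i` of a chromosome vector is
#' the value over `[i-1, i)`. Queries outside the covered range return 0
#' (tracks are sparse coverage; absence means no signal).
#'
#' @param name Track name (e.g. `"DNaseI"`, `"H3K4me1"`).
#' @param values Named list mapping chromosome to a numeric per-bp vector.
#' @param step Step size in bp (per-bp storage uses 1).
#' @return An object of class `"signal_track"`.
#' @export
signal_track <- function(name, values, step = 1L) {
  if (!is.list(values) || is.null(names(values)) || any(!nzchar(names(values)))) {
    stop_input("`values` must be a named list of numeric vectors")
  }
  for (v in values) {
    if (!is.numeric(v)) stop_input("track values must be numeric")
    if (any(!is.finite(v))) stop_input("track values must be finite")
  }
  if (step < 1) stop_input("`step` must be >= 1")
  structure(
    list(name = name, values = lapply(values, as.numeric), step = as.integer(step)),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf(
    "<signal_track '%s'> %d chromosome(s), %d bp covered\n",
    x$name, length(x$values), sum(lengths(x$values))
  ))
  invisible(x)
}

#' Read a signal track from a 4-column bedGraph file
#'
#' Intervals are 0-based half-open and must not overlap; gaps are treated as
#' zero signal when queried.
#'
#' @param path Path to a bedGraph file.
#' @param name Track name; defaults to the file name without extension.
#' @return A `"signal_track"` object (per-bp expansion).
#' @export
read_signal_bedgraph <- function(path, name = NULL) {
  if (!file.exists(path)) stop_input(paste0("bedGraph file not found: ", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) stop_input(paste0("malformed bedGraph '", path, "': ", conditionMessage(e)))
  )
  df <- as.data.frame(gr)
  if (nrow(df) == 0) stop_input(paste0("empty bedGraph: ", path))
  if (!is.numeric(df$score) || any(!is.finite(df$score))) {
    stop_input("non-numeric or non-finite bedGraph values")
  }
  track_from_intervals(
    chrom = as.character(df$seqnames),
    start = df$start - 1L, # GRanges is 1-based closed; back to 0-based half-open
    end = df$end,
    value = df$score,
    name = name %||% sub("\\.[^.]*$", "", basename(path))
  )
}

#' Read a signal track from a bigWig file
#'
#' Optional alternative reader with the same query contract as
#' [read_signal_bedgraph()].
#'
#' @inheritParams read_signal_bedgraph
#' @return A `"signal_track"` object.
#' @export
read_signal_bigwig <- function(path, name = NULL) {
  if (!file.exists(path)) stop_input(paste0("bigWig file not found: ", path))
  gr <- rtracklayer::import(path, format = "BigWig")
  df <- as.data.frame(gr)
  track_from_intervals(
    chrom = as.character(df$seqnames),
    start = df$start - 1L,
    end = df$end,
    value = df$score,
    name = name %||% sub("\\.[^.]*$", "", basename(path))
  )
}

track_from_intervals <- function(chrom, start, end, value, name) {
  values <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s <- start[sel]; e <- end[sel]; v <- value[sel]
    ord <- order(s)
    s <- s[ord]; e <- e[ord]; v <- v[ord]
    if (any(s[-1] < e[-length(e)])) {
      stop_input(paste0("overlapping bedGraph intervals on ", ch))
    }
    lens <- e - s
    vec <- numeric(max(e))
    vec[sequence(lens) + rep(s, lens)] <- rep(v, lens)
    values[[ch]] <- vec
  }
  signal_track(name, values)
}

#' Query per-bp values of a signal track
#'
#' Returns exactly `end - start` values for the 0-based half-open interval
#' `[start, end)`; positions outside the covered range are 0.
#'
#' @param track A `"signal_track"`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open query interval.
#' @return Numeric vector of length `end - start`.
#' @export
track_values <- function(track, chrom, start, end) {
  if (end <= start) stop_input("`end` must be > `start`")
  out <- numeric(end - start)
  vec <- track$values[[chrom]]
  if (is.null(vec)) return(out)
  lo <- max(start, 0L)
  hi <- min(end, length(vec))
  if (hi > lo) out[(lo - start + 1L):(hi - start)] <- vec[(lo + 1L):hi]
  out
}

#' Write a signal track to bedGraph
#'
#' Zero runs are omitted (they are implied by the sparse-coverage query
#' contract), keeping files small.
#'
#' @param track A `"signal_track"`.
#' @param path Output path.
#' @param digits Significant digits written.
#' @return `path`, invisibly.
#' @export
write_signal_bedgraph <- function(track, path, digits = 6) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- signif(track$values[[ch]], digits)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(
      paste(ch, starts[keep], ends[keep], format(r$values[keep], scientific = FALSE, trim = TRUE), sep = "\t"),
      con
    )
  }
  invisible(path)
}

#' Read ChIP-seq summits from a BED file
#'
#' Each record contributes one summit at its interval start (MACS-style
#' single-bp summit intervals `[pos, pos+1)`).
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `summit` (0-based position) and,
#'   when present in the file, `name`.
#' @export
read_summits_bed <- function(path) {
  if (!file.exists(path)) stop_input(paste0("BED file not found: ", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop_input(paste0("malformed BED '", path, "': ", conditionMessage(e)))
  )
  df <- as.data.frame(gr)
  out <- tibble(
    chrom = as.character(df$seqnames),
    summit = as.integer(df$start - 1L)
  )
  if (!is.null(df$name) && !all(is.na(df$name))) out$name <- df$name
  out
}

#' Write summits to BED
#'
#' @param summits Tibble with `chrom` and `summit` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summits_bed <- function(summits, path) {
  nm <- summits$name %||% paste0("summit", seq_len(nrow(summits)))
  writeLines(
    paste(summits$chrom, summits$summit, summits$summit + 1L, nm, sep = "\t"),
    path
  )
  invisible(path)
}

#' Write predicted sites to BED6
#'
#' Scores are rescaled to 0-1000 (BED convention) from the per-motif
#' fraction of the maximum attainable log-odds score.
#'
#' @param sites Tibble as returned by [scan_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  if (nrow(sites) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score1000 <- as.integer(round(1000 * pmax(0, pmin(1, sites$score_frac))))
  writeLines(
    paste(sites$chrom, sites$start, sites$end, sites$motif_id, score1000,
          sites$strand, sep = "\t"),
    path
  )
  invisible(path)
}
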