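#' Read target regions from a FASTA file
#'
#' One row per record. Genomic coordinates are parsed from headers of the
#' form `id::chrom:start-end` (0-based half-open, BED convention); headers
#' without coordinates yield `NA` coordinates, in which case signal tracks
#' cannot be mapped onto the regions.
#'
#' @param path Path to a FASTA file.
#' @param mask_lowercase If `FALSE` (default) soft-masked lowercase bases
#'   are uppercased; if `TRUE` they are kept lowercase and excluded from
#'   k-mer counting downstream.
#' @return A tibble with columns `id`, `chrom`, `start`, `end`, `sequence`.
#' @export
read_regions_fasta <- function(path, mask_lowercase = FALSE) {
  if (!file.exists(path)) stop_input(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_input(paste0("malformed FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(set) == 0) stop_input(paste0("empty FASTA: ", path))
  seqs <- as.character(set)
  if (!mask_lowercase) seqs <- toupper(seqs)
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad)) {
    stop_input(paste0(
      "non-DNA characters in FASTA record '", names(set)[bad][1], "'"
    ))
  }
  headers <- names(set)
  ids <- sub("::.*$", "", headers)
  coord <- stringr::str_match(headers, "::([^:]+):(\\d+)-(\\d+)\\s*$")
  regions <- tibble(
    id = ids,
    chrom = coord[, 2],
    start = suppressWarnings(as.integer(coord[, 3])),
    end = suppressWarnings(as.integer(coord[, 4])),
    sequence = unname(seqs)
  )
  has_coord <- !is.na(regions$chrom)
  if (any(has_coord & regions$end <= regions$start)) {
    stop_input("region with end <= start in FASTA headers")
  }
  mismatch <- has_coord &
    nchar(regions$sequence) != (regions$end - regions$start)
  if (any(mismatch)) {
    stop_input(paste0(
      "sequence length disagrees with header coordinates for region '",
      regions$id[mismatch][1], "'"
    ))
  }
  regions
}

#' Write regions to FASTA
#'
#' Inverse of [read_regions_fasta()]: regions with coordinates get
#' `id::chrom:start-end` headers.
#'
#' @param regions Tibble with `id`, `chrom`, `start`, `end`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_fasta <- function(regions, path) {
  headers <- ifelse(
    is.na(regions$chrom),
    regions$id,
    paste0(regions$id, "::", regions$chrom, ":", regions$start, "-", regions$end)
  )
  set <- Biostrings::BStringSet(regions$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Build a regions tibble from bare sequences
#'
#' Convenience constructor used throughout the examples and tests.
#'
#' @param sequences Character vector of DNA sequences.
#' @param ids Optional record ids (default `r1, r2, ...`).
#' @param chrom,start Optional coordinates; `start` gives each region's
#'   0-based start on `chrom`, `end` is derived from the sequence length.
#' @return A regions tibble.
#' @export
regions_from_sequences <- function(sequences, ids = NULL, chrom = NA_character_,
                                   start = NA_integer_) {
  n <- length(sequences)
  tibble(
    id = ids %||% paste0("r", seq_len(n)),
    chrom = rep_len(chrom, n),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(start, n) + nchar(sequences)),
    sequence = toupper(sequences)
  )
}
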