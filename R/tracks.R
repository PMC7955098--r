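## Read tracks: aligned single-end reads reduced to their 5' positions.
## A track is a tibble (chrom, pos5, strand) carrying the library size and
## the exogenous spike-in read count as attributes. Counting functions shift
## each 5' end `shift` bp toward 3' (default 75, half of an assumed 150-bp
## fragment) so that point counts land near fragment midpoints.

DEFAULT_SHIFT <- 75

#' Construct a read track
#'
#' @param chrom Character vector of chromosome names per read.
#' @param pos5 Numeric vector of 5' positions (0-based).
#' @param strand Character (`+`/`-`) or numeric (+1/-1) strand per read.
#' @param spikein_reads Number of reads mapped to the exogenous spike-in
#'   genome for this library (used by spike-in normalization); `NA` when not
#'   available.
#' @param library_size Total mapped reads; defaults to the number of reads
#'   supplied.
#' @return A tibble of class `read_track` with columns `chrom`, `pos5`,
#'   `strand` (+1/-1) and attributes `library_size`, `spikein_reads`.
#' @export
read_track <- function(chrom, pos5, strand, spikein_reads = NA_real_,
                       library_size = NULL) {
  if (is.character(strand)) {
    bad <- !strand %in% c("+", "-")
    if (any(bad)) {
      abort(sprintf("unknown strand symbol '%s'", strand[which(bad)[1]]))
    }
    strand <- ifelse(strand == "+", 1L, -1L)
  }
  x <- tibble(chrom = as.character(chrom), pos5 = as.numeric(pos5),
              strand = as.integer(strand))
  x <- dplyr::arrange(x, .data$chrom, .data$pos5)
  attr(x, "library_size") <- library_size %||% nrow(x)
  attr(x, "spikein_reads") <- spikein_reads
  class(x) <- c("read_track", class(x))
  x
}

#' @rdname read_track
#' @param track A `read_track`.
#' @export
library_size <- function(track) attr(track, "library_size", exact = TRUE)

#' @rdname read_track
#' @export
spikein_reads <- function(track) attr(track, "spikein_reads", exact = TRUE)

#' Read a tagAlign file into a read track
#'
#' tagAlign is BED6 (chrom, start, end, name, score, strand) where the
#' relevant coordinate is the read 5' end: the start for plus-strand reads
#' and `end - 1` for minus-strand reads. An empty file yields a usable track
#' with library size 0 (with a warning).
#'
#' @param path File path.
#' @param spikein_reads Spike-in read count to attach to the track.
#' @export
read_tagalign <- function(path, spikein_reads = NA_real_) {
  fields <- split_tsv_lines(path)
  if (length(fields) == 0) {
    warn(paste0("empty read file: ", path))
    return(read_track(character(), numeric(), integer(),
                      spikein_reads = spikein_reads))
  }
  if (any(lengths(fields) < 6)) {
    abort(sprintf("line %d: tagAlign needs 6 columns",
                  which(lengths(fields) < 6)[1]))
  }
  i <- seq_along(fields)
  start <- parse_num(vapply(fields, `[[`, "", 2), "start", i)
  end <- parse_num(vapply(fields, `[[`, "", 3), "end", i)
  strand <- vapply(fields, `[[`, "", 6)
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf("line %d: unknown strand symbol '%s'",
                  which(bad)[1], strand[which(bad)[1]]))
  }
  read_track(
    chrom = vapply(fields, `[[`, "", 1),
    pos5 = ifelse(strand == "+", start, end - 1),
    strand = strand,
    spikein_reads = spikein_reads
  )
}

#' @rdname read_tagalign
#' @param track A `read_track`.
#' @param read_length Read length used to materialize intervals on disk.
#' @export
write_tagalign <- function(track, path, read_length = 50) {
  plus <- track$strand > 0
  start <- ifelse(plus, track$pos5, track$pos5 - read_length + 1)
  start <- pmax(start, 0)
  end <- start + read_length
  writeLines(paste(track$chrom, format_coord(start), format_coord(end), ".",
                   "0", ifelse(plus, "+", "-"), sep = "\t"), path)
  invisible(path)
}

## Shifted point positions of every read (5' end moved `shift` bp toward 3').
shifted_positions <- function(track, shift = DEFAULT_SHIFT) {
  tibble(chrom = track$chrom, pos = track$pos5 + shift * track$strand)
}

## Count shifted read positions falling in each region ([start, end)).
## findInterval on per-chromosome sorted positions: O((n + m) log n).
count_in_regions <- function(x, track, shift = DEFAULT_SHIFT) {
  validate_regions(x)
  n <- nrow(x)
  counts <- numeric(n)
  if (n == 0 || nrow(track) == 0) return(counts)
  pts <- shifted_positions(track, shift)
  by_chrom <- split(pts$pos, pts$chrom)
  by_chrom <- lapply(by_chrom, sort)
  for (chrom in intersect(unique(x$chrom), names(by_chrom))) {
    rows <- which(x$chrom == chrom)
    p <- by_chrom[[chrom]]
    counts[rows] <- findInterval(x$end[rows] - 0.5, p) -
      findInterval(x$start[rows] - 0.5, p)
  }
  counts
}

#' Scaled read counts over regions
#'
#' Counts shifted read 5' positions inside each interval and multiplies by a
#' normalization scale (see [normalization_scale()]).
#'
#' @param x Region tibble.
#' @param track A `read_track`.
#' @param scale Multiplier applied to raw counts (default 1 = raw counts).
#' @param shift 3'-ward shift applied to read 5' ends before counting.
#' @return Numeric vector, one value per row of `x`.
#' @export
region_signal <- function(x, track, scale = 1, shift = DEFAULT_SHIFT) {
  count_in_regions(x, track, shift = shift) * scale
}
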