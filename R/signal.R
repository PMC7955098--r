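## Signal quantification: normalization scales (RPM or exogenous spike-in),
## binned heatmap matrices at 50-bp resolution, 400-bp center-window
## intensities and ranking, average profiles, and log2 fold changes.

#' Normalization scale for a library
#'
#' `RPM` scales counts to reads per million mapped reads
#' (`1e6 / library_reads`). `spikein` additionally equalizes the exogenous
#' spike-in recovery across libraries:
#' `reference_spikein / spikein_reads * 1e6 / library_reads`, so a library
#' that captured half the spike-in reads of the reference gets twice the
#' weight. When the sample's spike-in count equals the reference the formula
#' reduces to RPM.
#'
#' @param library_reads Total mapped reads in the library.
#' @param spikein_reads Reads mapped to the spike-in genome (required for
#'   `method = "spikein"`).
#' @param method `"RPM"` or `"spikein"`.
#' @param reference_spikein Spike-in read count of the reference library.
#' @return A positive multiplier applied to raw read counts.
#' @export
normalization_scale <- function(library_reads, spikein_reads = NULL,
                                method = c("RPM", "spikein"),
                                reference_spikein = NULL) {
  method <- match.arg(method)
  if (is.null(library_reads) || is.na(library_reads) || library_reads <= 0) {
    abort("library_reads must be positive")
  }
  rpm <- 1e6 / library_reads
  if (method == "RPM") return(rpm)
  if (is.null(spikein_reads) || is.na(spikein_reads) || spikein_reads <= 0) {
    abort("spikein_reads must be positive for spike-in normalization")
  }
  if (is.null(reference_spikein) || reference_spikein <= 0) {
    abort("reference_spikein must be positive")
  }
  reference_spikein / spikein_reads * rpm
}

#' Binned signal matrix around region centers
#'
#' Builds a regions x bins matrix of scaled read counts in `bin_bp` bins
#' covering `[center - flank_bp, center + flank_bp)` around each region's
#' midpoint. Rows whose window would extend past a chromosome edge are kept
#' (out-of-chromosome bins hold zeros) and flagged.
#'
#' @param x Region tibble (row order is preserved in the matrix).
#' @param track A `read_track`.
#' @param scale Normalization multiplier (default 1 = raw counts).
#' @param bin_bp Bin width in bp (default 50); must divide `2 * flank_bp`.
#' @param flank_bp Half-width of the window around each center
#'   (default 2000).
#' @param genome Optional named chromosome lengths used for edge flagging.
#' @param shift Read 5'-end shift.
#' @return A numeric matrix of class `signal_matrix` with attributes
#'   `regions`, `bin_bp`, `flank_bp`, `scale` and `edge_rows`; columns are
#'   named by bin start offset relative to the center.
#' @export
build_matrix <- function(x, track, scale = 1, bin_bp = 50, flank_bp = 2000,
                         genome = NULL, shift = DEFAULT_SHIFT) {
  validate_regions(x)
  if ((2 * flank_bp) %% bin_bp != 0) abort("bin_bp must divide 2 * flank_bp")
  nbin <- 2 * flank_bp / bin_bp
  centers <- floor((x$start + x$end) / 2)
  mat <- matrix(0, nrow = nrow(x), ncol = nbin)
  pts <- shifted_positions(track, shift)
  by_chrom <- lapply(split(pts$pos, pts$chrom), sort)
  for (r in seq_len(nrow(x))) {
    p <- by_chrom[[x$chrom[r]]]
    if (is.null(p)) next
    breaks <- seq(centers[r] - flank_bp, centers[r] + flank_bp, by = bin_bp)
    mat[r, ] <- diff(findInterval(breaks - 0.5, p))
  }
  genome <- genome %||% genome_of(x)
  edge <- rep(FALSE, nrow(x))
  if (!is.null(genome)) {
    edge <- centers - flank_bp < 0 |
      centers + flank_bp > unname(genome[x$chrom])
    if (any(edge)) {
      warn(sprintf("%d region(s) within %d bp of a chromosome edge: their windows are zero-padded", sum(edge), flank_bp))
    }
  }
  mat <- mat * scale
  colnames(mat) <- seq(-flank_bp, flank_bp - bin_bp, by = bin_bp)
  structure(mat, class = c("signal_matrix", "matrix", "array"),
            regions = x, bin_bp = bin_bp, flank_bp = flank_bp,
            scale = scale, edge_rows = which(edge))
}

#' Center-window intensity of regions
#'
#' Scaled read count in `[center - window/2, center + window/2)` around each
#' region midpoint — the quantity heatmap rows are ranked by (default
#' 400 bp).
#'
#' @inheritParams build_matrix
#' @param window Window width in bp.
#' @return Numeric vector over the rows of `x`.
#' @export
center_intensity <- function(x, track, scale = 1, window = 400,
                             shift = DEFAULT_SHIFT) {
  validate_regions(x)
  centers <- floor((x$start + x$end) / 2)
  win <- tibble(chrom = x$chrom,
                start = pmax(centers - window / 2, 0),
                end = centers + window / 2)
  region_signal(win, track, scale = scale, shift = shift)
}

#' Rank heatmap rows by center intensity
#'
#' Returns the row permutation sorting a [build_matrix()] result by
#' descending intensity in the central `window` bp, with stable tie-breaking
#' by the original (chrom, start) order.
#'
#' @param mat A `signal_matrix`.
#' @param window Center-window width in bp; must be a multiple of the
#'   matrix's bin size.
#' @return Integer permutation of row indices.
#' @export
rank_regions <- function(mat, window = 400) {
  bin_bp <- attr(mat, "bin_bp")
  flank <- attr(mat, "flank_bp")
  if (window %% bin_bp != 0) abort("window must be a multiple of bin_bp")
  offs <- as.numeric(colnames(mat))
  central <- offs >= -window / 2 & offs < window / 2
  key <- rowSums(mat[, central, drop = FALSE])
  x <- attr(mat, "regions")
  order(-key, x$chrom, x$start)
}

#' Average signal profile
#'
#' Column means of a signal matrix: the average normalized read count per
#' bin across regions.
#'
#' @param mat A `signal_matrix`.
#' @return Tibble with `offset` (bin start relative to center, bp) and
#'   `mean_signal`.
#' @export
average_profile <- function(mat) {
  if (nrow(mat) == 0) abort("empty matrix")
  tibble(offset = as.numeric(colnames(mat)), mean_signal = colMeans(mat))
}

#' Per-region log2 fold changes between two tracks
#'
#' `log2((count_a * scale_a + pc) / (count_b * scale_b + pc))` per region,
#' counted either over the whole interval or a center window.
#'
#' @param x Region tibble.
#' @param track_a,track_b `read_track`s.
#' @param scale_a,scale_b Normalization scales (default RPM).
#' @param pseudocount Added to both normalized counts (default 1).
#' @param window If non-`NULL`, count in a center window of this width
#'   instead of the full interval.
#' @param shift Read 5'-end shift.
#' @return Numeric vector of log2 ratios.
#' @export
log2_fold_changes <- function(x, track_a, track_b, scale_a = NULL,
                              scale_b = NULL, pseudocount = 1,
                              window = NULL, shift = DEFAULT_SHIFT) {
  scale_a <- scale_a %||% normalization_scale(library_size(track_a))
  scale_b <- scale_b %||% normalization_scale(library_size(track_b))
  if (is.null(window)) {
    a <- region_signal(x, track_a, scale_a, shift = shift)
    b <- region_signal(x, track_b, scale_b, shift = shift)
  } else {
    a <- center_intensity(x, track_a, scale_a, window = window, shift = shift)
    b <- center_intensity(x, track_b, scale_b, window = window, shift = shift)
  }
  log2((a + pseudocount) / (b + pseudocount))
}

#' Percentage as printed in a results narrative
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places —
#' the arithmetic behind worked percentages such as 1,504/16,003 = 9.4%.
#'
#' @param numerator,denominator Counts with
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @param decimals Decimal places to keep (default 1).
#' @export
percent_report <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) abort("denominator must be positive")
  if (any(numerator < 0) || any(numerator > denominator)) {
    abort("numerator must be between 0 and denominator")
  }
  x <- 100 * numerator / denominator
  floor(x * 10^decimals + 0.5) / 10^decimals
}
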