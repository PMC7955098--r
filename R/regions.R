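## Interval data model: regions are plain tibbles with chrom/start/end
## (0-based, half-open) plus optional name/score columns. The genome (named
## vector of chromosome lengths) travels as an attribute so set operations can
## refuse to mix assemblies. All strand information is ignored for interval
## algebra; strand only matters for TSSs and read 5' ends.

#' Construct a region tibble
#'
#' Builds a tibble of genomic intervals in 0-based half-open coordinates,
#' validating the basic invariants (`0 <= start < end`, non-empty chromosome
#' names, intervals within their chromosome when a genome is supplied).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-ish vectors; `start` is 0-based inclusive, `end`
#'   exclusive.
#' @param name Optional character labels.
#' @param score Optional numeric scores (BED column 5).
#' @param genome Optional named numeric vector of chromosome lengths; attached
#'   as the `genome` attribute and checked against the intervals.
#' @return A tibble with columns `chrom`, `start`, `end` and any of
#'   `name`/`score` supplied.
#' @examples
#' regions("chr1", c(0, 500), c(100, 600))
#' @export
regions <- function(chrom, start, end, name = NULL, score = NULL,
                    genome = NULL) {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end)
  )
  if (!is.null(name)) x$name <- as.character(name)
  if (!is.null(score)) x$score <- as.numeric(score)
  validate_regions(x, genome = genome)
  set_genome(x, genome)
}

validate_regions <- function(x, genome = NULL) {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort("regions need `chrom`, `start` and `end` columns")
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort("chromosome names must be non-empty")
  }
  if (any(x$start < 0)) abort("start must be >= 0")
  if (any(x$end <= x$start)) abort("end must be greater than start")
  genome <- genome %||% genome_of(x)
  if (!is.null(genome)) {
    unknown <- setdiff(unique(x$chrom), names(genome))
    if (length(unknown) > 0) {
      abort(paste0("chromosome(s) not in genome: ",
                   paste(unknown, collapse = ", ")))
    }
    if (any(x$end > genome[x$chrom])) {
      abort("interval(s) extend beyond chromosome length")
    }
  }
  invisible(x)
}

#' @rdname regions
#' @param x A region tibble.
#' @export
set_genome <- function(x, genome) {
  if (!is.null(genome)) attr(x, "genome") <- genome
  x
}

#' @rdname regions
#' @export
genome_of <- function(x) attr(x, "genome", exact = TRUE)

## keep the genome attribute through dplyr verbs we use internally
reattach_genome <- function(out, src) set_genome(out, genome_of(src))

check_same_genome <- function(a, b) {
  ga <- genome_of(a)
  gb <- genome_of(b)
  if (!is.null(ga) && !is.null(gb) && !identical(ga[order(names(ga))],
                                                 gb[order(names(gb))])) {
    abort("region sets come from different genome assemblies")
  }
  invisible(TRUE)
}

## Internal: convert 0-based half-open tibble rows to a GRanges (1-based
## closed) so IRanges/GenomicRanges can do the heavy lifting.
as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

gr_to_regions <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' Pairwise interval overlap test
#'
#' Two half-open intervals overlap when they share at least one base:
#' same chromosome and `a.start < b.end` and `b.start < a.end`. Inputs are
#' recycled row-wise like base arithmetic.
#'
#' @param a,b Region tibbles (or single-row tibbles) compared row by row.
#' @return Logical vector.
#' @examples
#' region_overlaps(regions("chr1", 0, 100), regions("chr1", 100, 200))
#' @export
region_overlaps <- function(a, b) {
  validate_regions(a)
  validate_regions(b)
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Members of one region set overlapping another
#'
#' Returns the rows of `a` that overlap (share >= 1 base with) at least one
#' interval of `b`, keeping `a`'s coordinates. This is the primitive behind
#' all co-occupancy ("factor+") calls: a site counts as bound by a factor when
#' any of that factor's islands touches it.
#'
#' @param a,b Region tibbles; if both carry a `genome` attribute the
#'   assemblies must match.
#' @param invert If `TRUE`, return the rows of `a` overlapping nothing in `b`.
#' @param min_overlap_frac Minimum fraction of an `a` interval that must be
#'   covered by `b` to count as overlapping; the default 0 keeps the
#'   >= 1 base criterion.
#' @return A tibble, subset of `a`.
#' @export
subset_overlapping <- function(a, b, invert = FALSE, min_overlap_frac = 0) {
  validate_regions(a)
  validate_regions(b)
  check_same_genome(a, b)
  hit <- overlaps_any(a, b, min_overlap_frac = min_overlap_frac)
  reattach_genome(a[if (invert) !hit else hit, , drop = FALSE], a)
}

#' @rdname subset_overlapping
#' @return For `overlaps_any()`, a logical vector over the rows of `a`.
#' @export
overlaps_any <- function(a, b, min_overlap_frac = 0) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  # disjoint chromosome sets are a legitimate "no overlap", not a warning
  if (min_overlap_frac <= 0) {
    return(suppressWarnings(
      GenomicRanges::countOverlaps(as_gr(a), as_gr(b)) > 0
    ))
  }
  gr_a <- as_gr(a)
  gr_b <- GenomicRanges::reduce(as_gr(b))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_a, gr_b))
  ov <- IRanges::width(IRanges::pintersect(
    gr_a[S4Vectors::queryHits(hits)], gr_b[S4Vectors::subjectHits(hits)]
  ))
  covered <- tapply(ov, S4Vectors::queryHits(hits), sum)
  frac <- numeric(nrow(a))
  frac[as.integer(names(covered))] <- covered
  frac / (a$end - a$start) >= min_overlap_frac
}

#' Merge nearby intervals
#'
#' Merges intervals that overlap or are separated by at most `max_gap` bases,
#' returning a sorted, non-overlapping set. `max_gap = 0` merges exactly the
#' overlapping/bookended-with-shared-base cases (half-open adjacency does not
#' merge at gap 0 only when a gap of >= 1 base separates the intervals).
#'
#' @param x Region tibble.
#' @param max_gap Maximum separation (bp) still merged; must be >= 0.
#' @return Region tibble with columns `chrom`, `start`, `end`.
#' @export
merge_regions <- function(x, max_gap = 0) {
  if (length(max_gap) != 1 || is.na(max_gap) || max_gap < 0) {
    abort("max_gap must be a single non-negative number")
  }
  validate_regions(x)
  if (nrow(x) == 0) return(reattach_genome(x[c("chrom", "start", "end")], x))
  red <- GenomicRanges::reduce(as_gr(x), min.gapwidth = max_gap + 1)
  red <- GenomicRanges::sort(red)
  reattach_genome(gr_to_regions(red), x)
}

#' Sort and collapse a region set
#'
#' Normalization sorts by (chrom, start) and merges overlapping intervals so
#' the set satisfies the non-overlapping invariant assumed by the set algebra.
#'
#' @inheritParams merge_regions
#' @export
normalize_regions <- function(x) merge_regions(x, max_gap = 0)

#' Sort a region tibble by (chrom, start, end) without merging
#' @param x Region tibble.
#' @export
sort_regions <- function(x) {
  reattach_genome(dplyr::arrange(x, .data$chrom, .data$start, .data$end), x)
}
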