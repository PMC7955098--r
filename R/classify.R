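## Chromatin-state classification and SWI/SNF complex assignment.
## States follow the standard enhancer vocabulary: promoters are TSS +/- 1 kb;
## promoter-distal regions carrying both H3K4me1 and H3K27ac islands are
## active enhancers, H3K4me1-only ones are primed enhancers, everything else
## is "other". Promoter overlap takes precedence over the enhancer states.

#' Promoter regions from a gene table
#'
#' Promoters are transcription start sites +/- `halfwidth` bp (default 1 kb),
#' clipped to chromosome bounds and merged where they overlap.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `tss` and optionally
#'   `strand`.
#' @param genome Optional named vector of chromosome lengths for clipping.
#' @param halfwidth Half-width in bp (default 1000).
#' @return Region tibble of merged promoter intervals.
#' @export
define_promoters <- function(genes, genome = NULL, halfwidth = 1000) {
  x <- tibble(
    chrom = genes$chrom,
    start = pmax(genes$tss - halfwidth, 0),
    end = genes$tss + halfwidth
  )
  if (!is.null(genome)) x$end <- pmin(x$end, genome[x$chrom])
  merge_regions(set_genome(x, genome), max_gap = 0)
}

#' Classify regions into chromatin states
#'
#' Assigns each query region one of `promoter`, `active_enhancer`,
#' `primed_enhancer`, `other`: promoter overlap wins; otherwise
#' H3K4me1+ H3K27ac+ regions are active enhancers, H3K4me1+ H3K27ac-
#' regions are primed enhancers, and H3K4me1- regions are other. A region
#' spanning several classes takes the highest-precedence one it touches.
#'
#' @param x Region tibble to classify.
#' @param promoters Promoter region tibble ([define_promoters()]).
#' @param k4me1,k27ac H3K4me1 and H3K27ac island region tibbles.
#' @return `x` with logical columns `h3k4me1`, `h3k27ac` and a factor column
#'   `state` (levels promoter, active_enhancer, primed_enhancer, other).
#' @export
classify_state <- function(x, promoters, k4me1, k27ac) {
  validate_regions(x)
  prom <- overlaps_any(x, promoters)
  me1 <- overlaps_any(x, k4me1)
  ac <- overlaps_any(x, k27ac)
  state <- dplyr::case_when(
    prom ~ "promoter",
    me1 & ac ~ "active_enhancer",
    me1 & !ac ~ "primed_enhancer",
    TRUE ~ "other"
  )
  out <- dplyr::mutate(x, h3k4me1 = me1, h3k27ac = ac,
                       state = factor(state, levels = STATE_LEVELS))
  reattach_genome(out, x)
}

#' Assign SWI/SNF complex identities to SMARCA4 sites
#'
#' Complex membership is decided by subunit co-occupancy, anchored on the
#' SMARCA4 site coordinates: BAF sites are SMARCA4+ SS18+ ARID1A+, PBAF sites
#' SMARCA4+ ARID2+, GBAF sites SMARCA4+ BRD9+. A site may belong to several
#' complexes.
#'
#' @param smarca4 SMARCA4 binding-site region tibble (the anchor set).
#' @param ss18,arid1a,arid2,brd9 Subunit binding-site region tibbles.
#' @return `smarca4` with logical columns `baf`, `pbaf`, `gbaf`.
#' @export
assign_complexes <- function(smarca4, ss18, arid1a, arid2, brd9) {
  validate_regions(smarca4)
  for (s in list(ss18, arid1a, arid2, brd9)) check_same_genome(smarca4, s)
  out <- dplyr::mutate(
    smarca4,
    baf = overlaps_any(smarca4, ss18) & overlaps_any(smarca4, arid1a),
    pbaf = overlaps_any(smarca4, arid2),
    gbaf = overlaps_any(smarca4, brd9)
  )
  reattach_genome(out, smarca4)
}

#' Venn partition of an anchor set
#'
#' Assigns every anchor interval its pattern of membership (>= 1 bp overlap)
#' across the named region sets and counts the patterns; counts sum to the
#' anchor size.
#'
#' @param anchor Region tibble whose intervals are partitioned.
#' @param sets Named list of region tibbles.
#' @return Tibble with one logical column per set plus `n`.
#' @export
venn_partition <- function(anchor, sets) {
  validate_regions(anchor)
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  flags <- purrr::map(sets, function(s) {
    check_same_genome(anchor, s)
    overlaps_any(anchor, s)
  })
  memb <- tibble::as_tibble(flags)
  dplyr::count(memb, dplyr::across(dplyr::everything()), name = "n")
}

#' Genomic distribution of a peak set across chromatin states
#'
#' Classifies each call once (precedence promoter > active enhancer > primed
#' enhancer > other) and reports counts and fractions per state; fractions
#' sum to 1.
#'
#' @inheritParams classify_state
#' @param calls Region tibble of peak calls.
#' @return Tibble with `state`, `n`, `fraction`, covering all four states.
#' @export
genomic_distribution <- function(calls, promoters, k4me1, k27ac) {
  if (nrow(calls) == 0) abort("empty input")
  classify_state(calls, promoters, k4me1, k27ac) |>
    dplyr::count(.data$state, name = "n", .drop = FALSE) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}
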