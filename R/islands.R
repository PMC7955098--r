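## Window/gap Poisson island caller. The genome is tiled with non-overlapping
## w-bp windows; windows whose read count is improbably high under a Poisson
## background are "eligible", runs of eligible windows with internal gaps of
## at most g bp are stitched into islands, and each island is then tested as
## a unit against a (control-scaled or genome-density) Poisson expectation,
## with Benjamini-Hochberg control across islands. Two published regimes are
## provided: broad histone marks (w = 200, g = 200, FDR 1e-3) and narrow
## non-histone factors (w = 50, g = 50, FDR 1e-10).

#' Island-calling parameter sets
#'
#' @param mode `"histone"` (window 200 bp, gap 200 bp, FDR 1e-3, for broad
#'   marks such as H3K4me1/H3K27ac) or `"factor"` (window 50 bp, gap 50 bp,
#'   FDR 1e-10, for transcription factors and remodeler subunits).
#' @param window_w,gap_g Window and gap sizes in bp; `gap_g` must be a
#'   multiple of `window_w`.
#' @param fdr_alpha FDR threshold applied to island q-values.
#' @param eligibility_p Poisson upper-tail probability below which a single
#'   window is eligible (default 0.20).
#' @param effective_genome_fraction Proportion of the genome considered
#'   mappable when deriving background densities (default 0.8).
#' @return A list of class `island_params`.
#' @export
island_params <- function(mode = c("histone", "factor"),
                          window_w = NULL, gap_g = NULL, fdr_alpha = NULL,
                          eligibility_p = 0.2,
                          effective_genome_fraction = 0.8) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    histone = list(window_w = 200, gap_g = 200, fdr_alpha = 1e-3),
    factor = list(window_w = 50, gap_g = 50, fdr_alpha = 1e-10)
  )
  p <- list(
    mode = mode,
    window_w = window_w %||% defaults$window_w,
    gap_g = gap_g %||% defaults$gap_g,
    fdr_alpha = fdr_alpha %||% defaults$fdr_alpha,
    eligibility_p = eligibility_p,
    effective_genome_fraction = effective_genome_fraction
  )
  if (p$window_w < 1) abort("window_w must be >= 1")
  if (p$gap_g < 0 || p$gap_g %% p$window_w != 0) {
    abort("gap_g must be a non-negative multiple of window_w")
  }
  if (p$fdr_alpha <= 0 || p$fdr_alpha >= 1) abort("fdr_alpha must be in (0,1)")
  structure(p, class = "island_params")
}

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`; the per-window and per-island
#' enrichment p-value.
#'
#' @param k Observed count(s), >= 0.
#' @param lam Expected count(s), > 0.
#' @export
poisson_upper_tail <- function(k, lam) {
  if (any(lam <= 0)) abort("lam must be positive")
  if (any(k < 0)) abort("k must be non-negative")
  ppois(k - 1, lam, lower.tail = FALSE)
}

#' Per-window read counts
#'
#' Tiles each chromosome with `w`-bp windows (`window i` covers
#' `[i * w, (i + 1) * w)`) and counts shifted read 5' positions per window.
#'
#' @param track A `read_track`.
#' @param w Window size (bp).
#' @param genome Named vector of chromosome lengths.
#' @param shift 3'-ward shift applied to read 5' ends.
#' @return Tibble with columns `chrom`, `window` (0-based index), `count`;
#'   one row per window, zero-count windows included.
#' @export
window_counts <- function(track, w, genome, shift = DEFAULT_SHIFT) {
  if (w < 1) abort("w must be >= 1")
  pts <- shifted_positions(track, shift)
  purrr::map_dfr(names(genome), function(chrom) {
    len <- genome[[chrom]]
    nwin <- ceiling(len / w)
    pos <- pts$pos[pts$chrom == chrom]
    pos <- pmin(pmax(pos, 0), len - 1)
    tibble(
      chrom = chrom,
      window = seq_len(nwin) - 1,
      count = tabulate(floor(pos / w) + 1, nbins = nwin)
    )
  })
}

#' Flag windows exceeding the Poisson background
#'
#' A window is eligible when its count's Poisson upper-tail probability under
#' the background rate is below `eligibility_p`.
#'
#' @param counts Tibble from [window_counts()] (or any tibble with a `count`
#'   column).
#' @param lam_background Expected background reads per window.
#' @param eligibility_p Upper-tail threshold (default 0.20).
#' @return `counts` with a logical `eligible` column added.
#' @export
eligible_windows <- function(counts, lam_background, eligibility_p = 0.2) {
  if (lam_background <= 0) abort("lam_background must be positive")
  counts$eligible <- poisson_upper_tail(counts$count, lam_background) <
    eligibility_p
  counts
}

#' Stitch eligible windows into islands
#'
#' Maximal runs of eligible windows are merged, allowing internal runs of
#' ineligible windows spanning at most `g` bp; islands separated by more than
#' `g` bp of ineligible windows stay distinct.
#'
#' @param eligible Tibble with `chrom`, `window`, `eligible` columns
#'   (from [eligible_windows()]).
#' @param w,g Window and gap sizes (bp); `g` must be a multiple of `w`.
#' @param genome Optional named vector of chromosome lengths used to clip
#'   island ends.
#' @return Region tibble of islands.
#' @export
form_islands <- function(eligible, w, g, genome = NULL) {
  if (g %% w != 0) abort("g must be a multiple of w")
  hits <- dplyr::filter(eligible, .data$eligible)
  if (nrow(hits) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  out <- hits |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$window, .by_group = TRUE) |>
    dplyr::mutate(
      gap_bp = (.data$window - dplyr::lag(.data$window) - 1) * w,
      island = cumsum(dplyr::coalesce(.data$gap_bp > g, TRUE))
    ) |>
    dplyr::group_by(.data$chrom, .data$island) |>
    dplyr::summarise(
      start = min(.data$window) * w,
      end = (max(.data$window) + 1) * w,
      .groups = "drop"
    ) |>
    dplyr::select("chrom", "start", "end") |>
    dplyr::arrange(.data$chrom, .data$start)
  if (!is.null(genome) && nrow(out) > 0) {
    out$end <- pmin(out$end, genome[out$chrom])
    out <- set_genome(out, genome)
  }
  out
}

#' Benjamini-Hochberg step-up procedure
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return List with `reject` (logical) and `q_values`; the rejection set is
#'   the standard step-up prefix of the sorted p-values (`q <= alpha`).
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(list(reject = logical(0), q_values = numeric(0)))
  }
  if (any(p_values < 0 | p_values > 1)) abort("p-values must be in [0, 1]")
  q <- p.adjust(p_values, method = "BH")
  list(reject = q <= alpha, q_values = q)
}

#' Score and filter islands against a control
#'
#' Each island's p-value is the Poisson upper tail of its ChIP read count at
#' expectation `lambda`. With a control track, `lambda` is the island's
#' control count (floored at 1 read to avoid zero-rate degeneracy) scaled by
#' the library-size ratio, and never below the genome-wide ChIP background
#' expectation for the island's width — the floor keeps sampling noise in a
#' sparse control from fabricating enrichment. Without a control, `lambda`
#' is the background expectation alone (island width times genome-wide read
#' density over the effective genome fraction). q-values are
#' Benjamini-Hochberg across all candidate islands and the result keeps
#' islands with `q < fdr_alpha`.
#'
#' @param islands Region tibble of candidate islands.
#' @param chip,control `read_track`s; `control = NULL` activates control-free
#'   mode.
#' @param params An [island_params()] list.
#' @param genome Named vector of chromosome lengths.
#' @param shift Read 5'-end shift.
#' @return Tibble of retained islands with `chip_reads`, `control_lambda`,
#'   `score` (-ln p), `p_value`, `q_value` columns, sorted by coordinate.
#' @export
score_islands <- function(islands, chip, control = NULL, params, genome,
                          shift = DEFAULT_SHIFT) {
  chip_n <- library_size(chip)
  if (chip_n == 0) {
    warn("zero-read chip track: no islands scored")
    return(islands[0, , drop = FALSE])
  }
  if (nrow(islands) == 0) {
    return(dplyr::mutate(islands, chip_reads = numeric(0),
                         control_lambda = numeric(0), score = numeric(0),
                         p_value = numeric(0), q_value = numeric(0)))
  }
  chip_reads <- count_in_regions(islands, chip, shift = shift)
  density <- chip_n / (sum(genome) * params$effective_genome_fraction)
  lam_bg <- (islands$end - islands$start) * density
  if (is.null(control)) {
    lam <- lam_bg
  } else {
    control_n <- library_size(control)
    if (control_n == 0) abort("control track has no reads")
    control_reads <- count_in_regions(islands, control, shift = shift)
    lam <- pmax(pmax(control_reads, 1) * chip_n / control_n, lam_bg)
  }
  p <- poisson_upper_tail(chip_reads, lam)
  bh <- benjamini_hochberg(p, alpha = params$fdr_alpha)
  out <- islands |>
    dplyr::mutate(
      chip_reads = chip_reads,
      control_lambda = lam,
      score = -log(pmax(p, .Machine$double.xmin)),
      p_value = p,
      q_value = bh$q_values
    ) |>
    dplyr::filter(.data$q_value < params$fdr_alpha) |>
    dplyr::arrange(.data$chrom, .data$start)
  reattach_genome(out, islands)
}

#' Call enriched islands from a read track
#'
#' End-to-end caller: window counts, background eligibility (from the ChIP
#' track's genome-wide density over the effective genome fraction), island
#' stitching, and island-level significance with FDR filtering.
#'
#' @inheritParams score_islands
#' @param mode Passed to [island_params()] when `params` is not given.
#' @param params Optional [island_params()] overriding `mode`.
#' @return Scored island tibble (see [score_islands()]).
#' @examples
#' \donttest{
#' genome <- c(chr1 = 1e6)
#' chip <- read_track("chr1", sort(runif(2000, 0, 1e6)), "+")
#' call_islands(chip, genome = genome, mode = "histone")
#' }
#' @export
call_islands <- function(chip, control = NULL, genome,
                         mode = c("histone", "factor"), params = NULL,
                         shift = DEFAULT_SHIFT) {
  params <- params %||% island_params(match.arg(mode))
  if (library_size(chip) == 0) {
    warn("zero-read chip track: no islands called")
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  w <- params$window_w
  counts <- window_counts(chip, w, genome, shift = shift)
  lam_bg <- library_size(chip) /
    (sum(genome) * params$effective_genome_fraction) * w
  elig <- eligible_windows(counts, lam_bg, params$eligibility_p)
  islands <- form_islands(elig, w, params$gap_g, genome = genome)
  score_islands(islands, chip, control, params, genome, shift = shift)
}

#' Most significant islands
#'
#' Selects the `n` islands with the smallest q-values, breaking ties by
#' higher score, then (chrom, start) — the deterministic selection feeding
#' downstream motif analysis.
#'
#' @param calls Scored island tibble from [call_islands()].
#' @param n Number of islands to keep (default 3000).
#' @export
top_n_by_significance <- function(calls, n = 3000) {
  out <- calls |>
    dplyr::arrange(.data$q_value, dplyr::desc(.data$score), .data$chrom,
                   .data$start) |>
    dplyr::slice_head(n = n)
  reattach_genome(out, calls)
}
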