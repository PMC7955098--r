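## Enhancer dynamics and dependency labelling: temporal (prebound vs de novo
## binding across timepoints), lineage-factor (adipogenic) binding, MLL4
## stratification, pioneer-factor activation by an over-2-fold H3K27ac gain,
## and ATPase-depletion dependency of pioneer-factor binding.

#' Activation/dependency fold-change parameters
#'
#' @param h3k27ac_fold Strict fold threshold on the H3K27ac gain calling an
#'   enhancer activated (default 2: "over 2-fold").
#' @param dependency_fold Strict fold threshold on the binding loss calling a
#'   site depletion-dependent (default 2).
#' @param pseudocount Normalized reads added to both sides of each ratio
#'   (default 1).
#' @export
activation_params <- function(h3k27ac_fold = 2, dependency_fold = 2,
                              pseudocount = 1) {
  if (h3k27ac_fold <= 1 || dependency_fold <= 1) {
    abort("fold thresholds must exceed 1")
  }
  list(h3k27ac_fold = h3k27ac_fold, dependency_fold = dependency_fold,
       pseudocount = pseudocount)
}

#' Prebound versus de novo binding across timepoints
#'
#' Sites bound at the later timepoint that overlap a site bound at the
#' earlier timepoint are `prebound`; the rest are `de_novo`. The two labels
#' partition the late set.
#'
#' @param bound_late Region tibble of sites bound at the later timepoint.
#' @param bound_early Region tibble of sites bound at the earlier timepoint.
#' @return `bound_late` with a factor column `temporal`
#'   (levels prebound, de_novo).
#' @export
classify_temporal <- function(bound_late, bound_early) {
  validate_regions(bound_late)
  check_same_genome(bound_late, bound_early)
  pre <- overlaps_any(bound_late, bound_early)
  out <- dplyr::mutate(
    bound_late,
    temporal = factor(ifelse(pre, "prebound", "de_novo"),
                      levels = c("prebound", "de_novo"))
  )
  reattach_genome(out, bound_late)
}

#' Adipogenic enhancers
#'
#' Active enhancers bound by at least one lineage-determining factor
#' (C/EBPb, C/EBPa or PPARg).
#'
#' @param aes Region tibble of active enhancers.
#' @param cebpb,cebpa,pparg Binding-site region tibbles for the three
#'   lineage factors.
#' @return Subset of `aes` overlapping the union of the three sets.
#' @export
define_adipogenic <- function(aes, cebpb, cebpa, pparg) {
  ldtf <- merge_regions(dplyr::bind_rows(
    cebpb[c("chrom", "start", "end")],
    cebpa[c("chrom", "start", "end")],
    pparg[c("chrom", "start", "end")]
  ), max_gap = 0)
  subset_overlapping(aes, ldtf)
}

#' Stratify sites by MLL4 occupancy
#'
#' @param sites Region tibble.
#' @param mll4 MLL4 binding-site region tibble.
#' @return `sites` with a factor column `mll4_status`
#'   (levels MLL4_pos, MLL4_neg); the two strata partition `sites`.
#' @export
stratify_mll4 <- function(sites, mll4) {
  validate_regions(sites)
  check_same_genome(sites, mll4)
  pos <- overlaps_any(sites, mll4)
  out <- dplyr::mutate(
    sites,
    mll4_status = factor(ifelse(pos, "MLL4_pos", "MLL4_neg"),
                         levels = c("MLL4_pos", "MLL4_neg"))
  )
  reattach_genome(out, sites)
}

#' Call pioneer-factor-activated enhancers
#'
#' Compares normalized H3K27ac read counts over each candidate enhancer in
#' treated (ectopic pioneer factor) versus control cells and flags enhancers
#' whose pseudocounted ratio strictly exceeds `h3k27ac_fold` ("over 2-fold
#' increased"). Candidates are expected to already satisfy the upstream
#' selection (pioneer-factor-positive active enhancers carrying the required
#' co-factors).
#'
#' @param candidates Candidate enhancer region tibble.
#' @param k27ac_treated,k27ac_control H3K27ac `read_track`s for the two
#'   conditions.
#' @param params [activation_params()].
#' @param scale_treated,scale_control Normalization scales; default RPM from
#'   each track's library size.
#' @param shift Read 5'-end shift.
#' @return `candidates` with columns `signal_treated`, `signal_control`,
#'   `k27ac_ratio` and logical `activated`.
#' @export
call_activated_enhancers <- function(candidates, k27ac_treated,
                                     k27ac_control,
                                     params = activation_params(),
                                     scale_treated = NULL,
                                     scale_control = NULL,
                                     shift = DEFAULT_SHIFT) {
  validate_regions(candidates)
  if (library_size(k27ac_treated) == 0 || library_size(k27ac_control) == 0) {
    abort("zero-depth H3K27ac track")
  }
  scale_treated <- scale_treated %||%
    normalization_scale(library_size(k27ac_treated))
  scale_control <- scale_control %||%
    normalization_scale(library_size(k27ac_control))
  pc <- params$pseudocount
  st <- region_signal(candidates, k27ac_treated, scale_treated, shift = shift)
  sc <- region_signal(candidates, k27ac_control, scale_control, shift = shift)
  out <- dplyr::mutate(
    candidates,
    signal_treated = st,
    signal_control = sc,
    k27ac_ratio = (st + pc) / (sc + pc),
    activated = .data$k27ac_ratio > params$h3k27ac_fold
  )
  reattach_genome(out, candidates)
}

#' Dependency of pioneer-factor binding on the remodeler ATPase
#'
#' For enhancers whose activation was called, compares the pioneer factor's
#' normalized signal in a 400-bp window around each enhancer center between
#' control and ATPase-depleted cells. Sites whose control/depleted ratio
#' strictly exceeds `dependency_fold` (occupancy reduced on depletion) are
#' `SMARCA4_dependent`; the rest (binding unchanged) are
#' `SMARCA4_independent`.
#'
#' @param sites Region tibble of activated enhancers.
#' @param cebpb_control,cebpb_depleted Pioneer-factor `read_track`s in
#'   control and depleted cells.
#' @param params [activation_params()].
#' @param window Center-window width in bp (default 400).
#' @param scale_control,scale_depleted Normalization scales (default RPM).
#' @param shift Read 5'-end shift.
#' @return `sites` with `dependency_ratio` and a factor column `dependency`
#'   (levels SMARCA4_dependent, SMARCA4_independent).
#' @export
classify_smarca4_dependency <- function(sites, cebpb_control, cebpb_depleted,
                                        params = activation_params(),
                                        window = 400,
                                        scale_control = NULL,
                                        scale_depleted = NULL,
                                        shift = DEFAULT_SHIFT) {
  validate_regions(sites)
  scale_control <- scale_control %||%
    normalization_scale(library_size(cebpb_control))
  scale_depleted <- if (library_size(cebpb_depleted) == 0) {
    1 # empty depleted track: pseudocount carries the ratio
  } else {
    scale_depleted %||% normalization_scale(library_size(cebpb_depleted))
  }
  pc <- params$pseudocount
  ctrl <- center_intensity(sites, cebpb_control, scale = scale_control,
                           window = window, shift = shift)
  depl <- center_intensity(sites, cebpb_depleted, scale = scale_depleted,
                           window = window, shift = shift)
  ratio <- (ctrl + pc) / (depl + pc)
  out <- dplyr::mutate(
    sites,
    dependency_ratio = ratio,
    dependency = factor(
      ifelse(ratio > params$dependency_fold,
             "SMARCA4_dependent", "SMARCA4_independent"),
      levels = c("SMARCA4_dependent", "SMARCA4_independent")
    )
  )
  reattach_genome(out, sites)
}

#' Partition activated enhancers by prior BAF binding
#'
#' Activated enhancers overlapping a BAF site already present in control
#' (pre-perturbation) cells are `prebound`; enhancers acquiring BAF only
#' after the perturbation are `de_novo`.
#'
#' @param activated Region tibble of activated enhancers.
#' @param baf_prebinding Region tibble of BAF (SMARCA4+ ARID1A+) sites in
#'   control cells.
#' @return `activated` with a factor column `baf_binding`
#'   (levels prebound, de_novo).
#' @export
partition_by_baf_prebinding <- function(activated, baf_prebinding) {
  out <- classify_temporal(activated, baf_prebinding)
  out <- dplyr::rename(out, baf_binding = "temporal")
  reattach_genome(out, activated)
}
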