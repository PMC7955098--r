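## End-to-end analysis: island calling for every track, chromatin-state and
## complex assignment, temporal / activation / dependency labelling, and an
## evaluation helper comparing the pipeline's labels with a synthetic
## landscape's programmed truth.

#' Default factor-by-condition track manifest
#'
#' One row per simulated library: all profiled factors and both marks at the
#' differentiation timepoint (D2), the BAF subunits at the earlier timepoint
#' (Dm3), and the ectopic-pioneer-factor preadipocyte experiment (H3K27ac
#' with/without ectopic expression; pioneer factor with/without ATPase
#' depletion). `regime` selects the island-calling parameter set; `call`
#' marks tracks used only for signal quantification.
#'
#' @return Tibble with columns `factor`, `condition`, `regime`, `call`.
#' @export
default_track_manifest <- function() {
  dplyr::bind_rows(
    tibble(factor = c("SMARCA4", "SS18", "ARID1A", "ARID2", "BRD9", "MLL4",
                      "CBP", "CEBPB", "CEBPA", "PPARG", "ATAC"),
           condition = "D2", regime = "factor", call = TRUE),
    tibble(factor = c("H3K4me1", "H3K27ac"), condition = "D2",
           regime = "histone", call = TRUE),
    tibble(factor = c("SMARCA4", "SS18", "ARID1A"), condition = "Dm3",
           regime = "factor", call = TRUE),
    tibble(factor = "H3K27ac", condition = "pread_vec", regime = "histone",
           call = FALSE),
    tibble(factor = c("CEBPB", "SMARCA4", "ARID1A", "MLL4"),
           condition = "pread_cebpb", regime = "factor", call = TRUE),
    tibble(factor = "H3K27ac", condition = "pread_cebpb", regime = "histone",
           call = TRUE),
    tibble(factor = "CEBPB", condition = "pread_cebpb_smarca4dep",
           regime = "factor", call = FALSE)
  )
}

track_name <- function(factor, condition) paste(factor, condition, sep = ".")

#' Simulate every track in a manifest
#'
#' @param landscape A [generate_landscape()] result.
#' @param manifest Track manifest (default [default_track_manifest()]).
#' @return Named list of `read_track`s, names `<factor>.<condition>`.
#' @export
simulate_tracks <- function(landscape, manifest = default_track_manifest()) {
  tracks <- purrr::pmap(manifest, function(factor, condition, ...) {
    simulate_reads(landscape, factor, condition)
  })
  setNames(tracks, track_name(manifest$factor, manifest$condition))
}

#' Run the full enhancer-classification pipeline
#'
#' From read tracks to labels: calls islands per track (broad regime for
#' marks, narrow for factors), defines promoters from the gene table,
#' classifies chromatin states, assigns SWI/SNF complexes on SMARCA4 sites,
#' labels BAF-bound active enhancers as prebound or de novo across
#' timepoints, stratifies them by MLL4, defines adipogenic enhancers,
#' selects pioneer-factor candidate enhancers (factor-positive active
#' enhancers carrying SMARCA4/ARID1A/MLL4), calls activation by the
#' over-2-fold H3K27ac rule, classifies ATPase-depletion dependency of the
#' activated set, and partitions it by prior BAF binding.
#'
#' @param tracks Named list of `read_track`s (`<factor>.<condition>`), e.g.
#'   from [simulate_tracks()].
#' @param genes Gene tibble with `chrom`, `tss`.
#' @param genome Named chromosome lengths.
#' @param manifest Track manifest describing the island-calling regime per
#'   track.
#' @param activation [activation_params()].
#' @param shift Read 5'-end shift.
#' @return List with `islands` (named list of scored island tibbles),
#'   `promoters`, `complexes`, `baf_sites`/`pbaf_sites`/`gbaf_sites`,
#'   `distribution` (genomic distribution of SMARCA4 sites), `baf_aes`
#'   (temporal + MLL4 labels), `adipogenic`, `candidates`, `activated`,
#'   `dependency`, `baf_partition`.
#' @export
run_pipeline <- function(tracks, genes, genome,
                         manifest = default_track_manifest(),
                         activation = activation_params(),
                         shift = DEFAULT_SHIFT) {
  called <- manifest[manifest$call, ]
  islands <- purrr::pmap(called, function(factor, condition, regime, ...) {
    call_islands(tracks[[track_name(factor, condition)]], genome = genome,
                 mode = regime, shift = shift)
  })
  names(islands) <- track_name(called$factor, called$condition)

  promoters <- define_promoters(genes, genome = genome)
  isl <- function(nm) islands[[nm]][c("chrom", "start", "end")]

  ## SWI/SNF complexes anchored on SMARCA4 sites
  complexes <- assign_complexes(
    islands[["SMARCA4.D2"]], isl("SS18.D2"), isl("ARID1A.D2"),
    isl("ARID2.D2"), isl("BRD9.D2")
  )
  distribution <- genomic_distribution(
    islands[["SMARCA4.D2"]], promoters, isl("H3K4me1.D2"), isl("H3K27ac.D2")
  )

  ## BAF-bound active enhancers: SMARCA4 sites SS18+, state active
  smarca4_states <- classify_state(
    complexes, promoters, isl("H3K4me1.D2"), isl("H3K27ac.D2")
  )
  baf_bound <- dplyr::filter(
    smarca4_states,
    .data$state == "active_enhancer",
    overlaps_any(smarca4_states, isl("SS18.D2"))
  )
  early_baf <- subset_overlapping(isl("SMARCA4.Dm3"), isl("SS18.Dm3"))
  baf_aes <- baf_bound |>
    classify_temporal(early_baf) |>
    stratify_mll4(isl("MLL4.D2"))

  aes_d2 <- dplyr::filter(smarca4_states, .data$state == "active_enhancer")
  adipogenic <- define_adipogenic(aes_d2, isl("CEBPB.D2"), isl("CEBPA.D2"),
                                  isl("PPARG.D2"))

  ## pioneer-factor-activated enhancers in preadipocytes
  cebpb_sites <- islands[["CEBPB.pread_cebpb"]]
  candidates <- cebpb_sites[
    !overlaps_any(cebpb_sites, promoters) &
      overlaps_any(cebpb_sites, isl("H3K27ac.pread_cebpb")) &
      overlaps_any(cebpb_sites, isl("SMARCA4.pread_cebpb")) &
      overlaps_any(cebpb_sites, isl("ARID1A.pread_cebpb")) &
      overlaps_any(cebpb_sites, isl("MLL4.pread_cebpb")), ,
    drop = FALSE
  ]
  activated <- call_activated_enhancers(
    candidates[c("chrom", "start", "end")],
    k27ac_treated = tracks[["H3K27ac.pread_cebpb"]],
    k27ac_control = tracks[["H3K27ac.pread_vec"]],
    params = activation, shift = shift
  )
  activated_set <- dplyr::filter(activated, .data$activated)
  dependency <- classify_smarca4_dependency(
    activated_set[c("chrom", "start", "end")],
    cebpb_control = tracks[["CEBPB.pread_cebpb"]],
    cebpb_depleted = tracks[["CEBPB.pread_cebpb_smarca4dep"]],
    params = activation, shift = shift
  )
  baf_prebinding <- subset_overlapping(isl("SMARCA4.Dm3"), isl("ARID1A.Dm3"))
  baf_partition <- partition_by_baf_prebinding(
    activated_set[c("chrom", "start", "end")], baf_prebinding
  )

  list(
    islands = islands,
    promoters = promoters,
    complexes = complexes,
    baf_sites = dplyr::filter(complexes, .data$baf),
    pbaf_sites = dplyr::filter(complexes, .data$pbaf),
    gbaf_sites = dplyr::filter(complexes, .data$gbaf),
    distribution = distribution,
    baf_aes = baf_aes,
    adipogenic = adipogenic,
    candidates = candidates,
    activated = activated,
    dependency = dependency,
    baf_partition = baf_partition
  )
}

#' Compare pipeline labels with programmed truth
#'
#' Anchors every comparison on the truth regions: chromatin state (all
#' regions), SWI/SNF complex set (SMARCA4-occupied regions, all three
#' complex flags must match), temporal label (BAF-bound active enhancers),
#' activation (candidate enhancers), dependency (activated enhancers), and
#' the differential / co-factor-dependent gene calls from simulated
#' expression libraries.
#'
#' @param landscape A [generate_landscape()] result.
#' @param pipeline A [run_pipeline()] result.
#' @return Tibble with `label_class`, `n`, `n_correct`, `accuracy`.
#' @export
score_recovery <- function(landscape, pipeline) {
  truth <- landscape$truth
  reg <- truth[c("chrom", "start", "end")]
  res <- list()

  st <- classify_state(
    reg, pipeline$promoters,
    pipeline$islands[["H3K4me1.D2"]][c("chrom", "start", "end")],
    pipeline$islands[["H3K27ac.D2"]][c("chrom", "start", "end")]
  )
  res$state <- as.character(st$state) == truth$class

  anchor <- truth$smarca4
  pred_baf <- overlaps_any(reg, pipeline$baf_sites)
  pred_pbaf <- overlaps_any(reg, pipeline$pbaf_sites)
  pred_gbaf <- overlaps_any(reg, pipeline$gbaf_sites)
  true_baf <- truth$smarca4 & truth$ss18 & truth$arid1a
  true_pbaf <- truth$smarca4 & truth$arid2
  true_gbaf <- truth$smarca4 & truth$brd9
  res$complex <- (pred_baf == true_baf & pred_pbaf == true_pbaf &
                    pred_gbaf == true_gbaf)[anchor]

  tsel <- !is.na(truth$temporal)
  pred_pre <- overlaps_any(
    reg[tsel, ], dplyr::filter(pipeline$baf_aes, .data$temporal == "prebound")
  )
  res$temporal <- pred_pre == (truth$temporal[tsel] == "prebound")

  csel <- truth$candidate
  pred_act <- overlaps_any(
    reg[csel, ], dplyr::filter(pipeline$activated, .data$activated)
  )
  res$activation <- pred_act == truth$activated[csel]

  asel <- truth$activated
  pred_dep <- overlaps_any(
    reg[asel, ],
    dplyr::filter(pipeline$dependency,
                  .data$dependency == "SMARCA4_dependent")
  )
  res$dependency <- pred_dep == truth$dependent[asel]

  ## expression labels
  t_dm3 <- simulate_expression(landscape, "control_Dm3")
  t_d2 <- simulate_expression(landscape, "control_D2")
  t_ko <- simulate_expression(landscape, "ko_D2")
  diff <- differential_genes(t_dm3, t_d2)
  up <- diff$gene_id[diff$direction == "up"]
  res$induced_genes <- (landscape$genes$gene_id %in% up) ==
    landscape$genes$induced
  dep <- dependent_genes(up, t_d2, t_ko)
  dep_ids <- dep$gene_id[dep$dependent]
  isel <- landscape$genes$induced
  res$dependent_genes <- (landscape$genes$gene_id[isel] %in% dep_ids) ==
    landscape$genes$dependent[isel]

  purrr::imap_dfr(res, function(v, nm) {
    tibble(label_class = nm, n = length(v), n_correct = sum(v),
           accuracy = mean(v))
  })
}
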