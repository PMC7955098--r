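## Synthetic landscape generator. Produces a ground-truth table of regulatory
## regions (promoters plus enhancers with programmed chromatin states,
## per-factor occupancy, temporal/activation/dependency labels), read tracks
## with Poisson background and fold-enriched peaks, spike-in counts, and
## gene-level expression counts — the statistical structure the analysis
## assumes, so every pipeline stage is testable without external data.

#' Landscape configuration
#'
#' Defaults describe the study-scale conditions in miniature: one 10-Mb
#' chromosome, 1,000 enhancers, 200 genes, 2e5 reads per track, 8-fold
#' peak enrichment over background; the condition grid covers two
#' differentiation timepoints plus the ectopic-pioneer-factor preadipocyte
#' experiment with and without ATPase depletion.
#'
#' @param seed Integer seed; every stochastic output is reproducible from
#'   (config, seed).
#' @param genome Named vector of chromosome lengths.
#' @param n_enhancers,n_genes Region and gene counts.
#' @param enhancer_width Enhancer width in bp.
#' @param class_fractions Fractions of enhancers that are active, primed,
#'   other (must sum to 1).
#' @param cooccupancy Named list of per-factor binding probabilities for
#'   enhancer classes and promoters; see defaults.
#' @param dynamics_fractions `prebound`/`de_novo` split of BAF-bound active
#'   enhancers (sum 1).
#' @param activated_fraction Fraction of candidate enhancers programmed as
#'   pioneer-factor activated.
#' @param dependent_fraction Fraction of activated enhancers whose
#'   pioneer-factor binding is depletion-dependent.
#' @param enrichment_fold Peak-to-background read density ratio.
#' @param activation_fold Programmed H3K27ac gain on activated enhancers.
#' @param knockdown_fold Programmed binding loss on dependent sites upon
#'   depletion.
#' @param depth Expected reads per track.
#' @param spikein_mean Mean exogenous spike-in reads per track.
#' @param promoter_marked_prob Probability a promoter carries both marks.
#' @param rna List: `induced_fraction`, `dependent_fraction`, `fold`
#'   (programmed induction), `depth` (exonic reads per library),
#'   `rpkm_range` (log-uniform baseline expression).
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(
    seed = 1,
    genome = c(chr1 = 10e6),
    n_enhancers = 1000,
    n_genes = 200,
    enhancer_width = 1000,
    class_fractions = c(active_enhancer = 0.5, primed_enhancer = 0.3,
                        other = 0.2),
    cooccupancy = NULL,
    dynamics_fractions = c(prebound = 0.4, de_novo = 0.6),
    activated_fraction = 0.5,
    dependent_fraction = 0.5,
    enrichment_fold = 8,
    activation_fold = 4,
    knockdown_fold = 4,
    depth = 2e5,
    spikein_mean = 1e4,
    promoter_marked_prob = 0.9,
    rna = list(induced_fraction = 0.3, dependent_fraction = 0.4, fold = 8,
               depth = 5e6, rpkm_range = c(2, 50))) {
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    abort("class_fractions must sum to 1")
  }
  if (abs(sum(dynamics_fractions) - 1) > 1e-8) {
    abort("dynamics_fractions must sum to 1")
  }
  if (enrichment_fold < 1) abort("enrichment_fold must be >= 1")
  fr <- c(class_fractions, activated_fraction, dependent_fraction,
          dynamics_fractions, promoter_marked_prob)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  cooccupancy <- cooccupancy %||% list(
    ## P(factor bound | region kind); enhancer kinds by chromatin class
    active_enhancer = c(SMARCA4 = 0.85, SS18 = 0.75, ARID1A = 0.75,
                        ARID2 = 0.15, BRD9 = 0.2, MLL4 = 0.5, CBP = 0.5,
                        CEBPB = 0.6, CEBPA = 0.4, PPARG = 0.4),
    primed_enhancer = c(SMARCA4 = 0.5, SS18 = 0.3, ARID1A = 0.3,
                        ARID2 = 0.05, BRD9 = 0.1, MLL4 = 0.2, CBP = 0.1,
                        CEBPB = 0.2, CEBPA = 0.1, PPARG = 0.1),
    other = c(SMARCA4 = 0.3, SS18 = 0.1, ARID1A = 0.1, ARID2 = 0.05,
              BRD9 = 0.3, MLL4 = 0.05, CBP = 0.05, CEBPB = 0.1,
              CEBPA = 0.05, PPARG = 0.05),
    promoter = c(SMARCA4 = 0.5, SS18 = 0.1, ARID1A = 0.1, ARID2 = 0.6,
                 BRD9 = 0.1, MLL4 = 0.2, CBP = 0.3, CEBPB = 0, CEBPA = 0,
                 PPARG = 0)
  )
  structure(
    list(seed = seed, genome = genome, n_enhancers = n_enhancers,
         n_genes = n_genes, enhancer_width = enhancer_width,
         class_fractions = class_fractions, cooccupancy = cooccupancy,
         dynamics_fractions = dynamics_fractions,
         activated_fraction = activated_fraction,
         dependent_fraction = dependent_fraction,
         enrichment_fold = enrichment_fold,
         activation_fold = activation_fold,
         knockdown_fold = knockdown_fold, depth = depth,
         spikein_mean = spikein_mean,
         promoter_marked_prob = promoter_marked_prob, rna = rna),
    class = "landscape_config"
  )
}

## run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## deterministic per-track seed below 2^31
track_seed <- function(seed, factor, condition) {
  key <- sum(utf8ToInt(paste(factor, condition, sep = "."))) %% 10000
  (seed * 100003 + key * 7 + 11) %% .Machine$integer.max
}

SIM_CONDITIONS <- c("D2", "Dm3", "pread_vec", "pread_cebpb",
                    "pread_cebpb_smarca4dep")

#' Generate a ground-truth regulatory landscape
#'
#' Places non-overlapping promoters and enhancers on the genome, samples
#' chromatin classes and per-factor occupancy from the configured
#' probabilities, and programs the downstream labels: BAF-prebound versus
#' de novo binding across timepoints, pioneer-factor activation of eligible
#' candidates, depletion dependency of activated sites, and induced /
#' co-factor-dependent genes. Deterministic given the config seed.
#'
#' @param config A [landscape_config()].
#' @return A list of class `landscape`: `truth` (region tibble with class,
#'   occupancy flags and labels), `genes` (gene tibble with expression
#'   programming), `genome`, `config`.
#' @export
generate_landscape <- function(config = landscape_config()) {
  with_seed(config$seed, {
    genome <- config$genome
    n_enh <- config$n_enhancers
    n_gene <- config$n_genes
    n_slot <- n_enh + n_gene
    ## deterministic slot grid, shuffled assignment; slots are far enough
    ## apart that promoters (+/- 1 kb) never touch enhancers
    chrom_slots <- round(n_slot * genome / sum(genome))
    chrom_slots[length(chrom_slots)] <- n_slot - sum(head(chrom_slots, -1))
    slot_tbl <- purrr::map_dfr(names(genome), function(ch) {
      k <- chrom_slots[[ch]]
      spacing <- floor(genome[[ch]] / (k + 1))
      tibble(chrom = ch,
             pos = spacing * seq_len(k) +
               sample.int(1000, k, replace = TRUE) - 500)
    })
    slot_tbl <- slot_tbl[sample.int(n_slot), ]
    w <- config$enhancer_width

    enh <- slot_tbl[seq_len(n_enh), ]
    classes <- sample(names(config$class_fractions), n_enh, replace = TRUE,
                      prob = config$class_fractions)
    gene_slots <- slot_tbl[n_enh + seq_len(n_gene), ]

    truth <- tibble(
      region_id = sprintf("enh_%04d", seq_len(n_enh)),
      kind = "enhancer",
      chrom = enh$chrom,
      start = enh$pos,
      end = enh$pos + w,
      class = classes
    )
    prom <- tibble(
      region_id = sprintf("prom_%04d", seq_len(n_gene)),
      kind = "promoter",
      chrom = gene_slots$chrom,
      start = gene_slots$pos,
      end = gene_slots$pos + w,
      class = "promoter"
    )
    truth <- dplyr::bind_rows(truth, prom)
    truth$promoter_marked <- truth$kind == "promoter" &
      runif(nrow(truth)) < config$promoter_marked_prob

    ## factor occupancy, class-conditional
    occ_kind <- ifelse(truth$kind == "promoter", "promoter", truth$class)
    factors <- names(config$cooccupancy[[1]])
    for (f in factors) {
      p <- vapply(occ_kind, function(k) config$cooccupancy[[k]][[f]], 0,
                  USE.NAMES = FALSE)
      truth[[tolower(f)]] <- runif(nrow(truth)) < p
    }
    ## marks follow the programmed chromatin class
    truth$h3k4me1 <- truth$class %in%
      c("active_enhancer", "primed_enhancer") | truth$promoter_marked
    truth$h3k27ac <- truth$class == "active_enhancer" | truth$promoter_marked
    truth$atac <- truth$class %in% c("active_enhancer", "promoter")

    ## temporal: BAF-bound AEs split prebound/de novo; promoters are
    ## constitutively bound at both timepoints
    baf_ae <- truth$class == "active_enhancer" & truth$smarca4 & truth$ss18
    truth$temporal <- NA_character_
    truth$temporal[baf_ae] <- sample(
      names(config$dynamics_fractions), sum(baf_ae), replace = TRUE,
      prob = config$dynamics_fractions
    )
    truth$bound_early <- truth$kind == "promoter" |
      (!is.na(truth$temporal) & truth$temporal == "prebound")

    ## pioneer-factor activation candidates and programmed labels
    truth$candidate <- truth$class == "active_enhancer" & truth$cebpb &
      truth$smarca4 & truth$arid1a & truth$mll4
    truth$activated <- truth$candidate &
      runif(nrow(truth)) < config$activated_fraction
    truth$dependent <- truth$activated &
      runif(nrow(truth)) < config$dependent_fraction

    ## genes: TSS at promoter-slot centers, programmed expression
    rr <- config$rna$rpkm_range
    genes <- tibble(
      gene_id = sprintf("gene_%04d", seq_len(n_gene)),
      chrom = gene_slots$chrom,
      tss = gene_slots$pos + w / 2,
      strand = sample(c("+", "-"), n_gene, replace = TRUE),
      exonic_length = sample(1000:5000, n_gene, replace = TRUE),
      base_rpkm = exp(runif(n_gene, log(rr[1]), log(rr[2]))),
      induced = runif(n_gene) < config$rna$induced_fraction
    )
    genes$dependent <- genes$induced &
      runif(n_gene) < config$rna$dependent_fraction

    structure(list(truth = truth, genes = genes, genome = genome,
                   config = config),
              class = "landscape")
  })
}

## Per-region enrichment fold for a (factor, condition) pair. Folds are
## relative to the uniform background; unbound regions sit at 1.
occupancy_fold <- function(landscape, factor, condition) {
  truth <- landscape$truth
  cfg <- landscape$config
  E <- cfg$enrichment_fold
  f <- tolower(factor)
  fold <- rep(1, nrow(truth))
  flag <- switch(f,
    h3k4me1 = truth$h3k4me1,
    h3k27ac = truth$h3k27ac,
    atac = truth$atac,
    truth[[f]] %||% abort(paste0("unknown factor: ", factor))
  )
  if (condition == "D2") {
    fold[flag] <- E
  } else if (condition == "Dm3") {
    ## early timepoint: enhancer binding only where prebound; promoters and
    ## chromatin marks of primed/constitutive regions persist
    if (f %in% c("h3k4me1", "atac")) {
      fold[flag] <- E
    } else if (f == "h3k27ac") {
      fold[flag & truth$bound_early] <- E
    } else {
      fold[flag & truth$bound_early] <- E
    }
  } else if (condition == "pread_vec") {
    ## preadipocytes, no ectopic pioneer factor
    if (f == "h3k27ac") {
      fold[flag] <- E
      fold[truth$activated] <- E / cfg$activation_fold
    } else if (f == "cebpb") {
      ## no ectopic expression: background only
    } else {
      fold[flag] <- E
    }
  } else if (condition == "pread_cebpb") {
    fold[flag] <- E
  } else if (condition == "pread_cebpb_smarca4dep") {
    fold[flag] <- E
    if (f == "cebpb") fold[truth$dependent] <- E / cfg$knockdown_fold
  } else {
    abort(paste0("unknown condition: ", condition))
  }
  fold
}

#' Simulate a ChIP/ATAC read track
#'
#' Background reads are uniform over the genome; occupied regions receive
#' reads at `fold` times the background density, where the per-region fold
#' comes from the programmed occupancy for the requested factor and
#' condition. The background rate is solved so the expected total equals the
#' configured depth. A Poisson spike-in read count is attached.
#'
#' @param landscape A [generate_landscape()] result.
#' @param factor Factor/mark name (e.g. `"SMARCA4"`, `"H3K4me1"`).
#' @param condition One of `"D2"`, `"Dm3"`, `"pread_vec"`, `"pread_cebpb"`,
#'   `"pread_cebpb_smarca4dep"`.
#' @param seed Optional seed; defaults to a deterministic function of the
#'   config seed, factor and condition.
#' @param shift Fragment-shift convention matched by the counting functions.
#' @return A `read_track`.
#' @export
simulate_reads <- function(landscape, factor, condition = "D2", seed = NULL,
                           shift = DEFAULT_SHIFT) {
  cfg <- landscape$config
  seed <- seed %||% track_seed(cfg$seed, factor, condition)
  with_seed(seed, {
    genome <- landscape$genome
    truth <- landscape$truth
    G <- sum(genome)
    fold <- occupancy_fold(landscape, factor, condition)
    widths <- truth$end - truth$start
    rate <- cfg$depth / (G + sum((fold - 1) * widths))

    n_bg <- rpois(1, rate * G)
    bg_chrom <- sample(names(genome), n_bg, replace = TRUE,
                       prob = genome / G)
    bg_pos <- floor(runif(n_bg) * genome[bg_chrom])

    n_peak <- rpois(nrow(truth), (fold - 1) * rate * widths)
    idx <- rep.int(seq_len(nrow(truth)), n_peak)
    peak_chrom <- truth$chrom[idx]
    peak_pos <- floor(truth$start[idx] + runif(length(idx)) * widths[idx])

    chrom <- c(bg_chrom, peak_chrom)
    x <- c(bg_pos, peak_pos)
    ## clamp shifted centers so 5' ends stay on-chromosome
    x <- pmin(pmax(x, shift), genome[chrom] - shift - 1)
    strand <- sample(c(1L, -1L), length(x), replace = TRUE)
    read_track(chrom, x - shift * strand, strand,
               spikein_reads = rpois(1, cfg$spikein_mean))
  })
}

#' Simulate gene-level exonic counts for one library
#'
#' Counts are Poisson with mean proportional to each gene's programmed RPKM
#' times its exonic length; induced genes gain the configured fold at the
#' later timepoint, and dependent genes lose that induction in knockout
#' cells.
#'
#' @param landscape A [generate_landscape()] result.
#' @param condition One of `"control_Dm3"`, `"control_D2"`, `"ko_Dm3"`,
#'   `"ko_D2"`.
#' @param seed Optional seed (deterministic default as in
#'   [simulate_reads()]).
#' @return An [expression_table()].
#' @export
simulate_expression <- function(landscape, condition = "control_D2",
                                seed = NULL) {
  cfg <- landscape$config
  genes <- landscape$genes
  stopifnot(condition %in% c("control_Dm3", "control_D2", "ko_Dm3", "ko_D2"))
  seed <- seed %||% track_seed(cfg$seed, "RNA", condition)
  with_seed(seed, {
    rpkm_now <- genes$base_rpkm
    late <- grepl("_D2$", condition)
    ko <- grepl("^ko_", condition)
    if (late) {
      gain <- genes$induced & !(ko & genes$dependent)
      rpkm_now[gain] <- rpkm_now[gain] * cfg$rna$fold
    }
    ## expected count at RPKM r in a transcriptome-wide library of `depth`
    ## exonic reads: r * (len/1e3) * (depth/1e6); the genes here are a
    ## subset of that library, so the depth is passed as the RPKM
    ## denominator explicitly
    lam <- rpkm_now * (genes$exonic_length / 1e3) * (cfg$rna$depth / 1e6)
    expression_table(genes, rpois(nrow(genes), lam),
                     total_exonic_reads = cfg$rna$depth)
  })
}

#' Write and reload a fixture bundle
#'
#' Materializes a landscape as plain-text files: genome file, gene table,
#' ground-truth region table (TSV), truth regions as BED, the configuration
#' as YAML, and optionally one tagAlign per simulated track. The bundle is
#' the on-disk input contract of the pipeline.
#'
#' @param landscape A [generate_landscape()] result.
#' @param outdir Output directory (created if needed).
#' @param tracks Optional named list of `read_track`s to write as
#'   `<name>.tagAlign`.
#' @return `outdir`, invisibly. `read_fixture_bundle()` returns a
#'   `landscape` (with `tracks` when present in the bundle).
#' @export
write_fixture_bundle <- function(landscape, outdir, tracks = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_genome(landscape$genome, file.path(outdir, "genome.txt"))
  utils::write.table(landscape$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(landscape$genes, file.path(outdir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(landscape$truth[c("chrom", "start", "end", "region_id")],
            file.path(outdir, "truth_regions.bed"))
  cfg <- landscape$config
  cfg$genome <- as.list(cfg$genome)
  cfg$cooccupancy <- lapply(cfg$cooccupancy, as.list)
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))
  for (nm in names(tracks)) {
    write_tagalign(tracks[[nm]], file.path(outdir, paste0(nm, ".tagAlign")))
  }
  if (!is.null(tracks)) {
    spike <- vapply(tracks, function(t) as.numeric(spikein_reads(t)), 0)
    utils::write.table(
      tibble(track = names(tracks), spikein_reads = spike),
      file.path(outdir, "spikein_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(outdir)
}

#' @rdname write_fixture_bundle
#' @export
read_fixture_bundle <- function(outdir) {
  genome <- read_genome(file.path(outdir, "genome.txt"))
  truth <- as_tibble(utils::read.table(
    file.path(outdir, "truth.tsv"), header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  ))
  genes <- as_tibble(utils::read.table(
    file.path(outdir, "genes.tsv"), header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  ))
  cfg <- yaml::read_yaml(file.path(outdir, "config.yaml"))
  cfg$genome <- unlist(cfg$genome)
  cfg$cooccupancy <- lapply(cfg$cooccupancy, unlist)
  class(cfg) <- "landscape_config"
  out <- structure(list(truth = truth, genes = genes, genome = genome,
                        config = cfg), class = "landscape")
  spike_path <- file.path(outdir, "spikein_counts.tsv")
  ta <- list.files(outdir, pattern = "\\.tagAlign$", full.names = TRUE)
  if (length(ta) > 0) {
    spike <- if (file.exists(spike_path)) {
      s <- utils::read.table(spike_path, header = TRUE, sep = "\t")
      setNames(s$spikein_reads, s$track)
    }
    out$tracks <- setNames(
      lapply(ta, function(p) {
        nm <- sub("\\.tagAlign$", "", basename(p))
        read_tagalign(p, spikein_reads = spike[[nm]] %||% NA_real_)
      }),
      sub("\\.tagAlign$", "", basename(ta))
    )
  }
  out
}
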