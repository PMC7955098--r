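test_that("landscapes are deterministic given the seed", {
  a <- generate_landscape(tiny_config(seed = 3))
  b <- generate_landscape(tiny_config(seed = 3))
  expect_identical(a$truth, b$truth)
  expect_identical(a$genes, b$genes)
  c2 <- generate_landscape(tiny_config(seed = 4))
  expect_false(identical(a$truth, c2$truth))
  # and tracks too
  t1 <- simulate_reads(a, "SMARCA4", "D2")
  t2 <- simulate_reads(b, "SMARCA4", "D2")
  expect_identical(t1$pos5, t2$pos5)
})

test_that("programmed marginals hit the configured fractions", {
  cfg <- landscape_config(seed = 9, class_fractions = c(
    active_enhancer = 1, primed_enhancer = 0, other = 0
  ))
  ls0 <- generate_landscape(cfg)
  enh <- ls0$truth[ls0$truth$kind == "enhancer", ]
  expect_true(all(enh$class == "active_enhancer"))
  expect_true(all(enh$h3k4me1 & enh$h3k27ac))

  # de novo fraction lands in the binomial 99% interval
  cfg2 <- landscape_config(seed = 10)
  ls2 <- generate_landscape(cfg2)
  tl <- ls2$truth$temporal
  n <- sum(!is.na(tl))
  de_novo <- sum(tl == "de_novo", na.rm = TRUE)
  expect_gt(de_novo, 0.6 * n - 2.58 * sqrt(n * 0.6 * 0.4))
  expect_lt(de_novo, 0.6 * n + 2.58 * sqrt(n * 0.6 * 0.4))

  # label consistency by construction
  expect_true(all(ls2$truth$candidate[ls2$truth$activated]))
  expect_true(all(ls2$truth$activated[ls2$truth$dependent]))
  expect_true(all(ls2$genes$induced[ls2$genes$dependent]))

  expect_error(landscape_config(class_fractions = c(
    active_enhancer = 0.5, primed_enhancer = 0.2, other = 0.2
  )), "sum to 1")
})

test_that("unoccupied factors and unit enrichment give background tracks", {
  cfg <- tiny_config(seed = 5)
  ls0 <- generate_landscape(cfg)
  # CEBPB in non-ectopic preadipocytes is programmed unbound
  tr <- simulate_reads(ls0, "CEBPB", "pread_vec")
  occ <- ls0$truth[ls0$truth$cebpb, c("chrom", "start", "end")]
  dens_in <- sum(region_signal(occ, tr)) / sum(occ$end - occ$start)
  dens_all <- library_size(tr) / sum(ls0$genome)
  expect_lt(dens_in / dens_all, 1.5)

  # enrichment_fold 1 -> statistically uniform -> ~no islands
  flat <- generate_landscape(tiny_config(seed = 6, enrichment_fold = 1))
  n_isl <- nrow(call_islands(simulate_reads(flat, "H3K4me1", "D2"),
                             genome = flat$genome, mode = "histone"))
  expect_lte(n_isl, 1)
})

test_that("in-peak read density approaches fold x background", {
  cfg <- landscape_config(seed = 12, depth = 1e6)
  ls0 <- generate_landscape(cfg)
  tr <- simulate_reads(ls0, "H3K4me1", "D2")
  occ <- ls0$truth$h3k4me1
  inr <- ls0$truth[occ, c("chrom", "start", "end")]
  out_bp <- sum(ls0$genome) - sum(ls0$truth$end - ls0$truth$start)
  in_reads <- sum(region_signal(inr, tr))
  unocc <- ls0$truth[!occ, c("chrom", "start", "end")]
  bg_reads <- library_size(tr) - in_reads - sum(region_signal(unocc, tr))
  dens_ratio <- (in_reads / sum(inr$end - inr$start)) / (bg_reads / out_bp)
  expect_equal(dens_ratio, cfg$enrichment_fold, tolerance = 0.1)
})

test_that("spike-in counts are attached and reproducible", {
  ls0 <- generate_landscape(tiny_config(seed = 2))
  tr <- simulate_reads(ls0, "MLL4", "D2")
  expect_true(spikein_reads(tr) > 0)
  expect_identical(spikein_reads(simulate_reads(ls0, "MLL4", "D2")),
                   spikein_reads(tr))
})

test_that("fixture bundles round trip through plain text", {
  ls0 <- generate_landscape(tiny_config(seed = 8))
  tracks <- list(SMARCA4.D2 = simulate_reads(ls0, "SMARCA4", "D2"))
  dir <- withr::local_tempdir()
  write_fixture_bundle(ls0, dir, tracks = tracks)
  expect_true(all(file.exists(file.path(
    dir, c("genome.txt", "truth.tsv", "genes.tsv", "truth_regions.bed",
           "config.yaml", "SMARCA4.D2.tagAlign", "spikein_counts.tsv")
  ))))
  back <- read_fixture_bundle(dir)
  expect_equal(back$genome, ls0$genome)
  expect_equal(back$truth$start, ls0$truth$start)
  expect_equal(back$truth$activated, ls0$truth$activated)
  expect_equal(back$genes$gene_id, ls0$genes$gene_id)
  expect_equal(back$config$seed, ls0$config$seed)
  expect_equal(sort(back$tracks$SMARCA4.D2$pos5),
               sort(tracks$SMARCA4.D2$pos5))
  expect_equal(spikein_reads(back$tracks$SMARCA4.D2),
               spikein_reads(tracks$SMARCA4.D2))
})

test_that("expression simulation programs induction and dependency", {
  ls0 <- generate_landscape(tiny_config(seed = 14))
  t_dm3 <- simulate_expression(ls0, "control_Dm3")
  t_d2 <- simulate_expression(ls0, "control_D2")
  t_ko <- simulate_expression(ls0, "ko_D2")
  diff <- differential_genes(t_dm3, t_d2)
  up <- diff$gene_id[diff$direction == "up"]
  ind <- ls0$genes$gene_id[ls0$genes$induced]
  expect_gte(mean(ind %in% up), 0.95)
  # no-induction config yields ~no up calls
  quiet <- generate_landscape(tiny_config(
    seed = 15,
    rna = list(induced_fraction = 0, dependent_fraction = 0, fold = 8,
               depth = 2e6, rpkm_range = c(2, 50))
  ))
  dq <- differential_genes(simulate_expression(quiet, "control_Dm3"),
                           simulate_expression(quiet, "control_D2"))
  expect_lte(sum(dq$direction == "up"), 1)
  # dependent genes lose induction in the knockout
  dep <- dependent_genes(up, t_d2, t_ko)
  dep_truth <- ls0$genes$gene_id[ls0$genes$dependent]
  expect_gte(mean(dep_truth %in% dep$gene_id[dep$dependent]), 0.95)
})
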