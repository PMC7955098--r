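test_that("temporal labels partition the late set", {
  late <- rg("chr1", seq(0, 6000, by = 1000), seq(0, 6000, by = 1000) + 500)
  # 3 of the 7 late sites covered by early sites
  early <- rg("chr1", c(100, 2100, 4100), c(300, 2300, 4300))
  got <- classify_temporal(late, early)
  expect_equal(sum(got$temporal == "prebound"), 3)
  expect_equal(sum(got$temporal == "de_novo"), 4)
  expect_equal(got$temporal == "prebound", brute_overlaps_any(late, early))

  expect_true(all(classify_temporal(late, late)$temporal == "prebound"))
  expect_true(all(classify_temporal(late, rg("chr2", 0, 10))$temporal ==
                    "de_novo"))
})

test_that("adipogenic enhancers match the union of lineage-factor passes", {
  withr::with_seed(21, {
    aes <- random_regions(60, 8000)
    cebpb <- random_regions(10, 8000)
    cebpa <- random_regions(10, 8000)
    pparg <- random_regions(10, 8000)
    got <- define_adipogenic(aes, cebpb, cebpa, pparg)
    hit <- brute_overlaps_any(aes, cebpb) | brute_overlaps_any(aes, cebpa) |
      brute_overlaps_any(aes, pparg)
    expect_equal(nrow(got), sum(hit))
    expect_equal(got$start, aes$start[hit])
  })
  # bound by a single factor is enough; bound by none is excluded
  one_ae <- rg("chr1", 100, 200)
  expect_equal(nrow(define_adipogenic(one_ae, rg("chr2", 0, 10),
                                      rg("chr2", 0, 10),
                                      rg("chr1", 150, 160))), 1)
  expect_equal(nrow(define_adipogenic(one_ae, rg("chr2", 0, 10),
                                      rg("chr2", 0, 10),
                                      rg("chr2", 0, 10))), 0)
})

test_that("MLL4 stratification is an exact two-way partition", {
  sites <- rg("chr1", c(0, 100, 200), c(50, 150, 250))
  none <- stratify_mll4(sites, rg("chr2", 0, 10))
  expect_true(all(none$mll4_status == "MLL4_neg"))
  all_pos <- stratify_mll4(sites, rg("chr1", 0, 1000))
  expect_true(all(all_pos$mll4_status == "MLL4_pos"))
  some <- stratify_mll4(sites, rg("chr1", 120, 130))
  expect_equal(sum(some$mll4_status == "MLL4_pos") +
                 sum(some$mll4_status == "MLL4_neg"), nrow(sites))
})

test_that("activation is a strict over-threshold call with pseudocount", {
  cand <- rg("chr1", 1000, 2000)
  # scales forced to 1 so counts are read directly
  treated <- point_track(seq(1000, 1999, length.out = 9)) # 9 reads
  control <- point_track(seq(1000, 1999, length.out = 4)) # 4 reads
  got <- call_activated_enhancers(cand, treated, control,
                                  scale_treated = 1, scale_control = 1,
                                  shift = 0)
  expect_equal(got$k27ac_ratio, 2) # (9+1)/(4+1): exactly 2 -> excluded
  expect_false(got$activated)

  up <- call_activated_enhancers(
    cand, point_track(seq(1000, 1999, length.out = 8)),
    point_track(5000), scale_treated = 1, scale_control = 1, shift = 0
  )
  expect_equal(up$k27ac_ratio, 9) # control 0 reads in region, pc = 1
  expect_true(up$activated)

  expect_error(
    call_activated_enhancers(cand, point_track(numeric()), control),
    "zero-depth"
  )
})

test_that("raising the activation fold never grows the activated set", {
  withr::with_seed(8, {
    cand <- rg("chr1", seq(0, 19000, by = 1000), seq(0, 19000, by = 1000) + 500)
    treated <- point_track(floor(runif(2000, 0, 20000)))
    control <- point_track(floor(runif(1200, 0, 20000)))
    prev <- NULL
    for (f in c(1.5, 2, 3, 5)) {
      got <- call_activated_enhancers(
        cand, treated, control, params = activation_params(h3k27ac_fold = f),
        scale_treated = 1, scale_control = 1, shift = 0
      )
      if (!is.null(prev)) expect_true(all(got$activated <= prev))
      prev <- got$activated
    }
  })
})

test_that("programmed activation landscape is recovered at 4x enrichment", {
  accs <- vapply(c(101, 202, 303), function(seed) {
    cfg <- landscape_config(seed = seed, activation_fold = 4)
    ls0 <- generate_landscape(cfg)
    cand_rows <- ls0$truth$candidate
    cand <- ls0$truth[cand_rows, c("chrom", "start", "end")]
    treated <- simulate_reads(ls0, "H3K27ac", "pread_cebpb")
    control <- simulate_reads(ls0, "H3K27ac", "pread_vec")
    got <- call_activated_enhancers(cand, treated, control)
    truth <- ls0$truth$activated[cand_rows]
    c(missed = sum(truth & !got$activated),
      false = sum(!truth & got$activated),
      n_true = sum(truth))
  }, numeric(3))
  # at least 95% of programmed activations recovered, at most 2 false calls
  expect_true(all(accs["missed", ] <= 0.05 * accs["n_true", ]))
  expect_true(all(accs["false", ] <= 2))
})

test_that("dependency labels split on binding loss", {
  sites <- rg("chr1", c(1000, 5000), c(2000, 6000))
  tr <- point_track(c(seq(1400, 1600, length.out = 20),
                      seq(5400, 5600, length.out = 20)))
  same <- classify_smarca4_dependency(sites, tr, tr, shift = 0)
  expect_true(all(same$dependency == "SMARCA4_independent"))

  empty <- read_track(character(), numeric(), integer())
  gone <- classify_smarca4_dependency(sites, tr, empty, scale_control = 1,
                                      shift = 0)
  expect_true(all(gone$dependency == "SMARCA4_dependent"))
})

test_that("programmed 50/50 dependency split is recovered", {
  cfg <- landscape_config(seed = 404, knockdown_fold = 4)
  ls0 <- generate_landscape(cfg)
  act <- ls0$truth$activated
  sites <- ls0$truth[act, c("chrom", "start", "end")]
  ctrl <- simulate_reads(ls0, "CEBPB", "pread_cebpb")
  depl <- simulate_reads(ls0, "CEBPB", "pread_cebpb_smarca4dep")
  got <- classify_smarca4_dependency(sites, ctrl, depl)
  truth <- ifelse(ls0$truth$dependent[act], "SMARCA4_dependent",
                  "SMARCA4_independent")
  expect_gte(mean(as.character(got$dependency) == truth), 0.95)
})

test_that("BAF prebinding partition agrees with the temporal classifier", {
  withr::with_seed(31, {
    activated <- random_regions(40, 5000)
    prebound <- random_regions(12, 5000)
    a <- partition_by_baf_prebinding(activated, prebound)
    b <- classify_temporal(activated, prebound)
    expect_equal(as.character(a$baf_binding), as.character(b$temporal))
    expect_equal(sum(a$baf_binding == "prebound") +
                   sum(a$baf_binding == "de_novo"), nrow(activated))
  })
  none <- partition_by_baf_prebinding(rg("chr1", 0, 100), rg("chr2", 0, 10))
  expect_equal(as.character(none$baf_binding), "de_novo")
})
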