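# Fixture builders shared across tests. All tracks built here use plain
# point reads; tests that care about the fragment shift pass `shift = 0`
# so brute-force expectations stay readable.

rg <- function(chrom, start, end, ...) regions(chrom, start, end, ...)

# a track whose shifted positions (shift = 0) are exactly `pos`
point_track <- function(pos, chrom = "chr1", strand = "+", ...) {
  read_track(rep(chrom, length.out = length(pos)), pos,
             rep(strand, length.out = length(pos)), ...)
}

random_regions <- function(n, max_pos = 10000, width = 50,
                           chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  regions(sample(chroms, n, replace = TRUE), start,
          start + sample.int(width, n, replace = TRUE))
}

# all-pairs brute-force overlap oracle
brute_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & a$start[i] < b$end & b$start < a$end[i])
  }, logical(1))
}

# exact one-sided signed-rank p-value by enumerating all 2^n sign vectors
enumerate_wsr_p <- function(x, alternative = "greater") {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  if (alternative == "greater") mean(w_all >= w_obs) else mean(w_all <= w_obs)
}

tiny_config <- function(seed = 1,
                        rna = list(induced_fraction = 0.3,
                                   dependent_fraction = 0.4, fold = 8,
                                   depth = 2e6, rpkm_range = c(2, 50)),
                        ...) {
  landscape_config(
    seed = seed,
    genome = c(chr1 = 2e6),
    n_enhancers = 150,
    n_genes = 40,
    depth = 6e4,
    rna = rna,
    ...
  )
}
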