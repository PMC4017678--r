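test_that("landscape scaling, amplitude maps and background floor", {
  g <- tiny_genome(3)
  raw <- binned_track(g, c(2, 4, 0))
  expect_equal(build_ipls(raw)$values$chrT, c(0.5, 1, 1e-4))
  expect_equal(build_ipls(raw, "constant", background = 0)$values$chrT,
               c(1, 1, 0))
  g2 <- tiny_genome(2)
  expect_equal(build_ipls(binned_track(g2, c(1, 4)), "square")$values$chrT,
               c(0.0625, 1))
  expect_equal(build_ipls(binned_track(g2, c(1, 4)), "sqrt")$values$chrT,
               c(0.5, 1))
  expect_error(build_ipls(binned_track(g, c(0, 0, 0))), "empty landscape")
  expect_error(build_ipls(raw, background = 1.5), "background")
})

test_that("landscape construction is scale-invariant and respects invariants", {
  g <- tiny_genome(50)
  set.seed(9)
  for (amp in c("linear", "square", "sqrt", "constant")) {
    x <- rexp(50) * (runif(50) > 0.5)
    a <- build_ipls(binned_track(g, x), amp)
    b <- build_ipls(binned_track(g, 17.3 * x), amp)
    expect_equal(a$values$chrT, b$values$chrT)
    v <- a$values$chrT
    expect_true(all(v >= 1e-4 & v <= 1))
    expect_true(any(v > 1e-4))
  }
})

test_that("TSS landscape assigns probability one per TSS bin, idempotently", {
  g <- tiny_genome(10)
  ip <- ipls_from_tss(interval_set("chrT", 750, 751), g)
  expect_equal(ip$values$chrT, c(1e-4, 1, rep(1e-4, 8)))
  # two TSS in the same bin still give 1.0
  ip2 <- ipls_from_tss(interval_set(c("chrT", "chrT"), c(700, 900),
                                    c(701, 901)), g)
  expect_equal(ip2$values$chrT, ip$values$chrT)
  expect_error(ipls_from_tss(interval_set(), g), "empty landscape")
})

test_that("G-quadruplex scan finds planted motifs on both strands", {
  sf <- make_sequence_fixture(n_bins = 12, g4_bins = 3, g4_revcomp_bins = 8,
                              seed = 2)
  ip <- ipls_from_g4(sf$seqs, sf$genome)
  v <- ip$values$chrS
  # motif length 15 is the unique maximum raw value -> both loci scale to 1
  expect_equal(which(v == 1), c(3, 8))
  expect_true(all(v[-c(3, 8)] == 1e-4))
  # raw motif-length oracle from a literal regex on the planted string
  m <- gregexpr("G{3,}[ACGTN]{1,7}G{3,}[ACGTN]{1,7}G{3,}[ACGTN]{1,7}G{3,}",
                sf$motif, perl = TRUE)[[1]]
  expect_equal(attr(m, "match.length"), nchar(sf$motif))

  all_a <- Biostrings::DNAStringSet(strrep("A", 3000))
  names(all_a) <- "chrS"
  ga <- genome_index("chrS", 3000)
  expect_error(ipls_from_g4(all_a, ga), "empty landscape")
})

test_that("GC landscape reflects per-bin base composition", {
  sf <- make_sequence_fixture(n_bins = 6, gc_rich_bins = 5, seed = 3)
  ip <- ipls_from_gc(sf$seqs, sf$genome)
  v <- ip$values$chrS
  expect_equal(v[5], 1)          # pure GC bin
  expect_true(all(v[-5] <= 1e-4 + 1e-12))  # A/T background floors out
  expect_error(ipls_from_gc(sf$seqs, genome_index("chrX", 1000)),
               "absent from FASTA")
})

test_that("CpG observed/expected separates CG-dense from CG-sparse bins", {
  # same base composition, different dinucleotide arrangement
  s <- paste0(strrep("CG", 250), strrep("CCGG", 125))
  seqs <- Biostrings::DNAStringSet(s)
  names(seqs) <- "chrS"
  g <- genome_index("chrS", 1000)
  ip <- ipls_from_cpg(seqs, g)
  v <- ip$values$chrS
  # direct dinucleotide count oracle
  oe <- function(x) {
    cg <- lengths(regmatches(x, gregexpr("(?=CG)", x, perl = TRUE)))
    nc <- nchar(gsub("[^C]", "", x))
    ng <- nchar(gsub("[^G]", "", x))
    cg * nchar(x) / (nc * ng)
  }
  expected <- oe(c(strrep("CG", 250), strrep("CCGG", 125)))
  expect_equal(v, expected / max(expected))
  expect_gt(v[1], v[2])
})

test_that("overlap subtraction removes co-localized records only", {
  a <- interval_set(c("chrT", "chrT"), c(0, 1000), c(500, 1500), 1)
  b <- interval_set("chrT", 400, 600, 1)
  red <- subtract_overlap(a, b)
  expect_equal(nrow(red), 1)
  expect_equal(red$start, 1000)
  # disjoint sets leave a unchanged; empty b is identity; a vs a empties
  far <- interval_set("chrT", 5000, 5100, 1)
  expect_equal(nrow(subtract_overlap(a, far)), 2)
  expect_equal(subtract_overlap(a, interval_set()), a)
  expect_equal(nrow(subtract_overlap(a, a)), 0)
  # slop widens the overlap test
  nearby <- interval_set("chrT", 550, 650, 1)
  expect_equal(nrow(subtract_overlap(a, nearby)), 2)
  expect_equal(nrow(subtract_overlap(a, nearby, slop = 100)), 1)
})

test_that("random subtraction is size-matched to overlap subtraction", {
  set.seed(20)
  start <- sort(sample(0:980, 60)) * 100
  a <- interval_set("chrT", start, start + 80, 1)
  b <- interval_set("chrT", c(0, 50000), c(20000, 60000), 1)
  red_ov <- subtract_overlap(a, b)
  k <- nrow(a) - nrow(red_ov)
  red_rand <- subtract_random(a, k, seed = 3)
  expect_equal(nrow(red_rand), nrow(red_ov))
  expect_equal(subtract_random(a, k, seed = 3), red_rand)  # deterministic
  expect_error(subtract_random(a, nrow(a) + 1), "between 0 and")
})

test_that("interval subsampling keeps the requested fraction, reproducibly", {
  start <- (0:999) * 100
  a <- interval_set("chrT", start, start + 50, 1)
  expect_equal(subsample_intervals(a, 1, seed = 1), a)
  s25 <- subsample_intervals(a, 0.25, seed = 7)
  expect_equal(nrow(s25), 250)
  expect_equal(subsample_intervals(a, 0.25, seed = 7), s25)
  expect_false(identical(subsample_intervals(a, 0.25, seed = 8), s25))
})

test_that("translocation fuses landscapes with conserved lengths", {
  gA <- genome_index("chr12", 10 * 500)
  gB <- genome_index("chr21", 8 * 500)
  set.seed(2)
  ipa <- build_ipls(binned_track(gA, runif(10)))
  ipb <- build_ipls(binned_track(gB, runif(8)))
  # fusion at bin boundaries is exact concatenation
  fu <- fuse_translocation(ipa, ipb, "chr12", "chr21", 4 * 500, 3 * 500)
  expect_equal(fu$ipls$values$der,
               c(ipa$values$chr12[1:4], ipb$values$chr21[4:8]))
  expect_equal(fu$ipls$genome$lengths[["der"]], 4 * 500 + (8 - 3) * 500)
  # reciprocal product lengths sum to the source total
  rec <- fuse_translocation(ipa, ipb, "chr12", "chr21", 4 * 500, 3 * 500,
                            orientation = "BA")
  expect_equal(fu$ipls$genome$lengths[["der"]] +
                 rec$ipls$genome$lengths[["der"]], (10 + 8) * 500)
  expect_error(fuse_translocation(ipa, ipb, "chr12", "chr21", 99 * 500, 0),
               "beyond chromosome end")
  # mapping table covers every fused bin and switches donor at the junction
  expect_equal(nrow(fu$map), 9)
  expect_equal(fu$map$source, c(rep("chr12", 4), rep("chr21", 5)))
})

test_that("off-boundary breakpoints give the junction bin to the majority donor", {
  gA <- genome_index("a", 4 * 500)
  gB <- genome_index("b", 4 * 500)
  ipa <- build_ipls(binned_track(gA, c(1, 1, 1, 1)), background = 0)
  ipb <- build_ipls(binned_track(gB, c(0.5, 0.5, 0.5, 1)), background = 0)
  # breakpoint 400 bases into a: the junction bin is 80% donor a
  fu <- fuse_translocation(ipa, ipb, "a", "b", 400, 0)
  expect_equal(fu$ipls$values$der[1], ipa$values$a[1])
  # breakpoint 100 bases into a: the junction bin is 80% donor b
  fu2 <- fuse_translocation(ipa, ipb, "a", "b", 100, 0)
  expect_equal(fu2$ipls$values$der[1], ipb$values$b[1])
})
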