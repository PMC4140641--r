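test_that("footprint assignment rules place one count per read", {
  sl <- c(chrT = 300L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  # one 27-nt footprint at 101..127 on each strand
  writeLines(c("seqid\tstart\tend\tstrand",
               "chrT\t101\t127\t+",
               "chrT\t101\t127\t-"), tsv)
  tr <- assign_footprints(tsv, sl, rule = "center")
  expect_equal(tr$counts$chrT$`+`[114], 1)  # 101 + floor(26/2)
  expect_equal(tr$counts$chrT$`-`[114], 1)  # center is strand-agnostic
  expect_equal(sum(tr$counts$chrT$`+`) + sum(tr$counts$chrT$`-`), 2)

  tr3 <- assign_footprints(tsv, sl, rule = "offset3p", offset = 12L)
  expect_equal(tr3$counts$chrT$`+`[115], 1)  # 127 - 12
  expect_equal(tr3$counts$chrT$`-`[113], 1)  # 3' end is 101 on the minus strand
})

test_that("SAM alignments are counted and unusable reads tallied", {
  sam <- withr::local_tempfile(fileext = ".sam")
  reads <- paste0(strrep("A", 27))
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrT\tLN:300",
    paste("r1", 0, "chrT", 101, 60, "27M", "*", 0, 0, reads,
          strrep("I", 27), sep = "\t"),
    paste("r2", 16, "chrT", 151, 60, "27M", "*", 0, 0, reads,
          strrep("I", 27), sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, reads,
          strrep("I", 27), sep = "\t")
  ), sam)
  tr <- assign_footprints(sam, c(chrT = 300L))
  expect_equal(tr$counts$chrT$`+`[114], 1)
  expect_equal(tr$counts$chrT$`-`[164], 1)
  expect_equal(tr$skipped, 1L)
})

test_that("codon binning sums counts and respects strand orientation", {
  ref <- tiny_reference("ATGAAACCGTGGGCTGATCATTGGTAA")  # 27 nt, 9 codons
  g <- ref$genes[1, ]
  # counts at the 4th and 5th nt of the CDS -> codon 2
  tr <- track_fixture(ref$seqlengths, pos = g$start + c(3L, 4L),
                      count = c(2, 1))
  occ <- codon_occupancy(tr, g)
  expect_equal(occ$reads_per_codon, c(0, 3, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(occ$gene_mean, 3 / 9)

  # uniform 1 read/nt -> 3 per codon, conservation of counts
  tru <- track_fixture(ref$seqlengths, pos = g$start:g$end, count = 1)
  occu <- codon_occupancy(tru, g)
  expect_true(all(occu$reads_per_codon == 3))
  expect_equal(sum(occu$reads_per_codon), g$end - g$start + 1L)

  # minus-strand gene: a count at the genomic position of its start codon
  # (the genomic 3' end) must land in codon 1
  refm <- tiny_reference("ATGAAACCGTGGGCTGATCATTGGTAA", strand = "-")
  gm <- refm$genes[1, ]
  trm <- track_fixture(refm$seqlengths, pos = gm$end, strand = "-", count = 5)
  occm <- codon_occupancy(trm, gm)
  expect_equal(occm$reads_per_codon[1], 5)
  expect_true(all(occm$reads_per_codon[-1] == 0))
})

test_that("offset rules agree on uniform coverage", {
  ref <- tiny_reference("ATGAAACCGTGGGCTGATCATTGGTAA", pad5 = 40L, pad3 = 40L)
  g <- ref$genes[1, ]
  tsv <- withr::local_tempfile(fileext = ".tsv")
  # saturating 27-nt reads starting at every position spanning the CDS
  starts <- (g$start - 30L):(g$end + 3L)
  writeLines(c("seqid\tstart\tend\tstrand",
               paste("chrT", starts, starts + 26L, "+", sep = "\t")), tsv)
  t_center <- assign_footprints(tsv, ref$seqlengths, rule = "center")
  t_off <- assign_footprints(tsv, ref$seqlengths, rule = "offset3p", offset = 12L)
  expect_equal(codon_occupancy(t_center, g)$reads_per_codon,
               codon_occupancy(t_off, g)$reads_per_codon)
})

test_that("coverage filter is inclusive at the threshold", {
  expect_false(filter_covered(occ_fixture(rep(2.9, 10))))
  expect_true(filter_covered(occ_fixture(rep(3, 10))))
  expect_false(filter_covered(occ_fixture(rep(0, 10))))
  expect_true(filter_covered(occ_fixture(rep(2.9, 10)), threshold = 2))
})

test_that("normalized occupancy has mean 1 for covered genes", {
  set.seed(1)
  for (k in 1:20) {
    v <- rpois(50, 5) + 1
    expect_equal(mean(normalized_occupancy(occ_fixture(v))), 1,
                 tolerance = 1e-12)
  }
  expect_true(all(is.na(normalized_occupancy(occ_fixture(rep(0, 5))))))
})

test_that("replicate correlation behaves at the identity and null extremes", {
  a <- c(g1 = 100, g2 = 2000, g3 = 50, g4 = 700)
  expect_equal(replicate_correlation(a, a), 1)
  set.seed(42)
  x <- stats::setNames(exp(rnorm(500, 5, 2)), paste0("g", 1:500))
  y <- stats::setNames(exp(rnorm(500, 5, 2)), paste0("g", 1:500))
  expect_lt(abs(replicate_correlation(x, y)), 0.2)
  expect_error(replicate_correlation(a[1:2], a[1:2]), "fewer than 3")
})

test_that("replicate averaging flags large disagreement", {
  expect_equal(as.numeric(average_replicates(c(10, 12))), 11)
  expect_false(attr(average_replicates(c(10, 12)), "discordant"))
  expect_equal(as.numeric(average_replicates(7)), 7)
  m <- average_replicates(c(0, 8))
  expect_equal(as.numeric(m), 4)
  expect_true(attr(m, "discordant"))
  expect_error(average_replicates(numeric()), "no replicate")
})

test_that("track TSV and bedGraph round-trips preserve counts", {
  fx <- small_fixture()
  tr <- fx$tracks[[1]]
  sl <- vapply(fx$genome, nchar, 0L)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_track(tr, tsv)
  tr2 <- read_track(tsv, sl)
  expect_equal(tr2$counts$chrSim$`+`, tr$counts$chrSim$`+`)
  expect_equal(tr2$counts$chrSim$`-`, tr$counts$chrSim$`-`)

  prefix <- withr::local_tempfile()
  paths <- write_track_bedgraph(tr, prefix)
  tr3 <- read_track(paths[1], sl, minus = paths[2])
  expect_equal(tr3$counts$chrSim$`+`, unname(tr$counts$chrSim$`+`))
  expect_equal(tr3$counts$chrSim$`-`, unname(tr$counts$chrSim$`-`))
})
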