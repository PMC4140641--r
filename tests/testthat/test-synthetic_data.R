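test_that("reference generation is deterministic and internally consistent", {
  spec <- sim_spec(n_genes = 10L, len_range = c(60L, 100L), n_strong = 2L,
                   n_decoy = 3L, seed = 19L)
  r1 <- generate_reference(spec)
  r2 <- generate_reference(spec)
  expect_identical(r1, r2)
  # byte-identical FASTA under the same seed
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  g1 <- withr::local_tempfile(fileext = ".gff3")
  write_reference(r1$genome, r1$genes, f1, g1)
  write_reference(r2$genome, r2$genes, f2, g1)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the output
  r3 <- generate_reference(sim_spec(n_genes = 10L, len_range = c(60L, 100L),
                                    n_strong = 2L, n_decoy = 3L, seed = 20L))
  expect_false(identical(r1$genome, r3$genome))
  # every stored protein is the translation of its CDS
  for (i in seq_len(nrow(r1$genes))) {
    expect_identical(translate_cds(r1$genes$cds_nt[i]), r1$genes$protein[i])
  }
})

test_that("planted motifs are recovered by the scanner at exact coordinates", {
  spec <- sim_spec(n_genes = 12L, len_range = c(80L, 120L), n_strong = 4L,
                   n_decoy = 4L, seed = 23L)
  ref <- generate_reference(spec)
  sites <- find_ppx_sites_all(ref$genes)
  key <- function(d) paste(d$gene_id, d$x_codon_index)
  expect_true(all(key(ref$truth) %in% key(sites)))
  m <- match(key(ref$truth), key(sites))
  expect_identical(sites$motif[m], substr(ref$truth$motif,
                                          nchar(ref$truth$motif) - 2L,
                                          nchar(ref$truth$motif)))
  # Z-2 context of a planted ZPPX site is the planted Z residue
  z <- substr(ref$truth$motif, 1, 1)
  expect_identical(sites$z2[m], z)
})

test_that("explicit planting validates boundaries and the emission rule", {
  pm <- data.frame(gene = 2L, motif = "IPPPE", codon_pos = 20L,
                   multiplier = 15)
  spec <- sim_spec(n_genes = 4L, len_range = c(60L, 80L),
                   planted_motifs = pm, seed = 3L)
  ref <- generate_reference(spec)
  sites <- find_ppx_sites(ref$genes$protein[2], ref$genes$gene_id[2])
  planted <- sites[sites$x_codon_index %in% c(23L, 24L), ]
  expect_identical(planted$motif, c("PPP", "PPE"))

  bad <- sim_spec(n_genes = 4L, len_range = c(60L, 80L),
                  planted_motifs = data.frame(gene = 1L, motif = "EPPK",
                                              codon_pos = 1L,
                                              multiplier = 15),
                  seed = 3L)
  expect_error(generate_reference(bad), "start or stop")
  expect_error(sim_spec(multiplier = 0.5), ">= 1")
})

test_that("simulated counts have negative-binomial moments", {
  # one long flat gene: per-codon counts should match NB(mean, size)
  spec <- sim_spec(n_genes = 1L, len_range = c(3400L, 3400L), n_strong = 0L,
                   n_decoy = 0L, expr_sdlog = 0, depth = 20, dispersion = 10,
                   replicates = 1L, seed = 29L)
  ref <- generate_reference(spec)
  tracks <- simulate_tracks(spec, ref)
  occ <- codon_occupancy(tracks[[1]], ref$genes[1, ])
  x <- occ$reads_per_codon
  mu <- 20
  expect_equal(mean(x), mu, tolerance = 0.05)
  expect_equal(stats::var(x), mu + mu^2 / 10, tolerance = 0.2)
  # far from Poisson
  expect_gt(stats::var(x), 2 * mu)
})

test_that("tracks are deterministic and counts land inside genes", {
  fx <- small_fixture()
  t1 <- simulate_tracks(fx$spec, list(genome = fx$genome, genes = fx$genes,
                                      truth = fx$truth))
  expect_identical(t1, fx$tracks)
  # all simulated counts fall within annotated CDS on the right strand
  tr <- fx$tracks[[1]]
  total <- sum(tr$counts$chrSim$`+`) + sum(tr$counts$chrSim$`-`)
  in_genes <- sum(footprints_per_gene(tr, fx$genes))
  expect_equal(total, in_genes)
})

test_that("planted pause indices match the closed-form expectation", {
  # deep coverage, fixed length: estimator converges to m/(1+(w/L)(m-1))
  pm <- data.frame(gene = 1:2, motif = "EPPK", codon_pos = c(100L, 150L),
                   multiplier = 15)
  # near-Poisson counts isolate the estimator's convergence from
  # overdispersion noise (the standard-dispersion case is covered by the
  # full-fixture recovery test, which averages over many sites)
  spec <- sim_spec(n_genes = 2L, len_range = c(300L, 300L),
                   planted_motifs = pm, expr_sdlog = 0, depth = 200,
                   dispersion = 1000, replicates = 2L, seed = 37L)
  ref <- generate_reference(spec)
  tracks <- simulate_tracks(spec, ref)
  expected <- expected_pausing_index(15, 301)
  wt_all <- c()
  for (g in 1:2) {
    win <- ref$truth$win_start[g]:ref$truth$x_codon_index[g]
    idx <- vapply(tracks, function(tr) {
      if (tr$strain != "delta_efp") return(NA_real_)
      pausing_index(codon_occupancy(tr, ref$genes[g, ]), win)
    }, 0)
    est <- mean(idx, na.rm = TRUE)
    expect_equal(est, expected, tolerance = 0.1)
    wt_all <- c(wt_all, vapply(tracks, function(tr) {
      if (tr$strain != "WT") return(NA_real_)
      pausing_index(codon_occupancy(tr, ref$genes[g, ]), win)
    }, 0))
  }
  # WT condition stays flat at the planted windows (null case)
  expect_equal(mean(wt_all, na.rm = TRUE), 1, tolerance = 0.3)
})

test_that("the complemented condition restores planted sites towards WT", {
  pm <- data.frame(gene = 1L, motif = "EPPK", codon_pos = 100L,
                   multiplier = 15)
  spec <- sim_spec(n_genes = 1L, len_range = c(300L, 300L),
                   planted_motifs = pm, expr_sdlog = 0, depth = 100,
                   include_complemented = TRUE, replicates = 2L, seed = 41L)
  ref <- generate_reference(spec)
  tracks <- simulate_tracks(spec, ref)
  win <- ref$truth$win_start[1]:ref$truth$x_codon_index[1]
  idx <- vapply(tracks, function(tr) {
    pausing_index(codon_occupancy(tr, ref$genes[1, ]), win)
  }, 0)
  strain <- vapply(tracks, function(tr) tr$strain, "")
  m <- tapply(idx, strain, mean)
  expect_lt(m[["complemented"]], m[["delta_efp"]])
  expect_gt(m[["complemented"]], m[["WT"]])
})

test_that("fixture files round-trip through the package readers", {
  dir <- withr::local_tempdir()
  spec <- sim_spec(n_genes = 6L, len_range = c(60L, 90L), n_strong = 2L,
                   n_decoy = 2L, seed = 43L)
  fx <- end_to_end_fixture(spec, dir)
  genome <- load_genome(fx$paths$fasta)
  genes <- load_annotation(fx$paths$gff, genome)
  expect_identical(sort(genes$gene_id), sort(fx$genes$gene_id))
  truth <- utils::read.delim(fx$paths$truth)
  expect_identical(nrow(truth), nrow(fx$truth))
  sl <- vapply(genome, nchar, 0L)
  tr <- read_track(file.path(dir, paste0(names(fx$tracks)[1], ".track.tsv")), sl)
  expect_equal(tr$counts$chrSim$`+`, fx$tracks[[1]]$counts$chrSim$`+`)
})
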