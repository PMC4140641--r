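test_that("pausing index is the window/gene density ratio", {
  expect_equal(pausing_index(occ_fixture(rep(4, 25)), 7:9), 1)
  v <- c(1, 1, 1, 1, 50, 1, 1, 1, 1, 1)
  expect_equal(pausing_index(occ_fixture(v), 5), 50 / 5.9)
  expect_equal(pausing_index(occ_fixture(v), 4:6), (52 / 3) / 5.9)
  expect_error(pausing_index(occ_fixture(v), 11), "outside gene")
  expect_warning(idx <- pausing_index(occ_fixture(rep(0, 5)), 2), "undefined")
  expect_true(is.na(idx))
})

test_that("exhaustive single-codon indices average to 1", {
  set.seed(3)
  for (k in 1:20) {
    occ <- occ_fixture(rpois(40, 8) + 1)
    all_idx <- vapply(1:40, function(i) pausing_index(occ, i), 0)
    expect_equal(mean(all_idx), 1, tolerance = 1e-12)
  }
})

test_that("pause classification matches the threshold convention", {
  expect_identical(classify_pause(15.77), "strong")
  expect_identical(classify_pause(10), "strong")     # inclusive boundary
  expect_identical(classify_pause(9.99), "elevated")
  expect_identical(classify_pause(2.5), "elevated")
  expect_identical(classify_pause(2), "neutral")
  expect_identical(classify_pause(1.5), "neutral")
  expect_identical(classify_pause(1), "non_pausing")
  expect_identical(classify_pause(0.9), "non_pausing")
  expect_error(classify_pause(-0.1), ">= 0")
  # monotone in the index
  set.seed(4)
  x <- sort(runif(200, 0, 30))
  lev <- c(non_pausing = 1, neutral = 2, elevated = 3, strong = 4)
  expect_false(is.unsorted(lev[classify_pause(x)]))
})

test_that("strain comparison computes folds, flags and dependence", {
  mk <- function(wt, de, comp = NULL) {
    d <- data.frame(
      strain = c("WT", "WT", "delta_efp", "delta_efp"),
      replicate = c(1, 2, 1, 2), index = c(wt, de),
      stringsAsFactors = FALSE
    )
    if (!is.null(comp)) {
      d <- rbind(d, data.frame(strain = "complemented", replicate = 1:2,
                               index = comp))
    }
    d
  }
  # clear EF-P dependent pause: low WT, strong delta-efp
  call <- compare_strains(mk(c(1.0, 1.1), c(13.5, 14.26), c(7.4, 7.84)))
  expect_equal(call$index_by_strain$WT, 1.05)
  expect_equal(call$index_by_strain$delta_efp, 13.88)
  expect_equal(call$fold_change, 13.88 / 1.05)
  expect_true(call$efp_dependent)
  expect_true(call$complement_restored)
  expect_false(call$wt_near_zero)

  # zero WT index: pseudocount fold, flagged
  call0 <- compare_strains(mk(c(0, 0), c(16.4, 16.9)))
  expect_true(call0$wt_near_zero)
  expect_equal(call0$fold_change, (16.65 + 0.1) / 0.1)
  expect_true(call0$efp_dependent)

  # strong in both strains: not EF-P dependent by the fold criterion
  calls <- compare_strains(mk(c(10.5, 11.0), c(15.5, 16.04)))
  expect_identical(calls$classification$delta_efp, "strong")
  expect_false(calls$efp_dependent)

  # missing delta_efp -> partial call
  expect_warning(
    pc <- compare_strains(data.frame(strain = "WT", replicate = 1, index = 2)),
    "partial"
  )
  expect_true(is.na(pc$fold_change))
})

test_that("de novo scan merges runs above threshold", {
  v <- rep(1, 20)
  v[7] <- 12
  occ <- occ_fixture(v * 5)
  dn <- scan_denovo_pauses(occ)
  norm <- v * 5 / mean(v * 5)
  expect_identical(nrow(dn), if (max(norm) >= 10) 1L else 0L)

  # explicit fixture: two adjacent codons far above 10x the gene mean
  w <- c(rep(1, 6), 30, 33, rep(1, 42))
  occw <- occ_fixture(w)
  dnw <- scan_denovo_pauses(occw)
  expect_identical(nrow(dnw), 1L)
  expect_identical(dnw$start, 7L)
  expect_identical(dnw$end, 8L)
  expect_identical(dnw$width, 2L)
  expect_equal(dnw$peak_value, 33 / mean(w))

  # just below threshold -> nothing
  w2 <- c(rep(1, 9), 9.85)
  expect_identical(nrow(scan_denovo_pauses(occ_fixture(w2))), 0L)
})

test_that("de novo windows equal the exhaustive per-codon oracle", {
  set.seed(7)
  for (k in 1:200) {
    v <- rexp(sample(10:80, 1), rate = 0.6)
    v[sample(length(v), sample(0:3, 1))] <- runif(1, 20, 60)
    occ <- occ_fixture(v)
    dn <- scan_denovo_pauses(occ)
    orc <- oracle_denovo(normalized_occupancy(occ))
    expect_identical(dn$start, orc$start)
    expect_identical(dn$end, orc$end)
  }
})

test_that("the pause table sorts, classifies and pairs PPPX rows", {
  # empty input -> header-only table
  empty <- build_pause_table(find_ppx_sites(""), list())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("gene_id", "motif", "index_delta_efp") %in% names(empty)))

  # a PPPX gene yields two rows with upstream sequences offset by one
  sites <- find_ppx_sites("MGATKWQPPPEL", "lepA_like")
  expect_identical(nrow(sites), 2L)
  calls <- lapply(1:2, function(i) {
    compare_strains(data.frame(
      strain = c("WT", "delta_efp"), replicate = 1,
      index = c(2.1, 13.3 + 0.05 * i), stringsAsFactors = FALSE
    ))
  })
  tab <- build_pause_table(sites, calls)
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$classification_delta_efp == "strong"))
  expect_identical(substr(tab$upstream20[order(tab$x_codon_index)][1], 2, 20),
                   substr(tab$upstream20[order(tab$x_codon_index)][2], 1, 19))
  # sorted by delta-efp index, descending
  expect_false(is.unsorted(rev(tab$index_delta_efp)))
})
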