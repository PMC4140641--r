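#' Load the RNA/RNA nearest-neighbor stack table
#'
#' Turner-style stack free energies at 37 C (kcal/mol) for Watson-Crick and
#' GU wobble pairs, packaged as a TSV. The entry for the helix step
#' `5'-WX-3' / 3'-ZY-5'` is `M["WZ", "YX"]`.
#'
#' @param path Parameter TSV; default the packaged Turner 2004 table.
#' @return 6x6 numeric matrix with pair names `CG, GC, GU, UG, AU, UA`.
#' @export
load_stack_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rna_stack_params.tsv",
                        package = "ribopause", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$pair
  storage.mode(m) <- "double"
  m
}

.asd_pairs <- c(AU = TRUE, UA = TRUE, CG = TRUE, GC = TRUE, GU = TRUE, UG = TRUE)

can_pair <- function(a, b) {
  !is.na(.asd_pairs[paste0(a, b)])
}

as_rna <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x)
}

#' Minimum duplex free energy against the anti-Shine-Dalgarno sequence
#'
#' Hybridization model for short SD-like elements: the query window (mRNA,
#' 5'->3') is paired antiparallel against the aSD 8-mer in every possible
#' register, allowing contiguous runs of at least 2 Watson-Crick or GU pairs,
#' and the minimum over all runs of the summed nearest-neighbor stack
#' energies is returned. No intramolecular structure, bulges or internal
#' loops, and (by default) no duplex-initiation or terminal-AU terms: the
#' score is a comparative screen, not a full folding energy. A window with no
#' favorable duplex scores 0 with an empty pairing.
#'
#' @param window RNA (or DNA) string, 6-12 nt.
#' @param asd The anti-SD sequence, 5'->3' (default the E. coli 16S 3' end
#'   `CACCUCCU`).
#' @param params Stack matrix from [load_stack_params()].
#' @return List of class `duplex_result`: `window`, `delta_g` (kcal/mol,
#'   <= 0), `pairing` (2-column matrix of window/asd 1-based positions, zero
#'   rows when `delta_g == 0`).
#' @export
duplex_energy <- function(window, asd = "CACCUCCU",
                          params = load_stack_params()) {
  w <- as_rna(window)
  a <- as_rna(asd)
  if (grepl("[^ACGU]", w) || grepl("[^ACGU]", a)) {
    stop("sequences must be over A/C/G/U (or T)")
  }
  n <- nchar(w)
  m <- nchar(a)
  if (n < 6L || n > 12L) stop("window length must be 6-12 nt, got ", n)
  wv <- strsplit(w, "")[[1]]
  av <- strsplit(a, "")[[1]]
  best <- 0
  best_pairs <- matrix(integer(), ncol = 2)
  # antiparallel register: window position i pairs asd position K - i
  for (K in 3L:(n + m - 1L)) {
    i_lo <- max(1L, K - m)
    i_hi <- min(n, K - 1L)
    if (i_hi - i_lo < 1L) next
    ii <- i_lo:i_hi
    jj <- K - ii
    paired <- can_pair(wv[ii], av[jj])
    # stack energy of each step between consecutive paired positions
    k <- length(ii)
    step <- rep(NA_real_, k - 1L)
    both <- paired[-k] & paired[-1L]
    if (!any(both)) next
    p1 <- paste0(wv[ii[-k]], av[jj[-k]])
    p2 <- paste0(av[jj[-1L]], wv[ii[-1L]])
    step[both] <- params[cbind(p1[both], p2[both])]
    # minimum-sum contiguous segment within runs of valid steps
    for (seg in split(seq_len(k - 1L), cumsum(!both))) {
      seg <- seg[both[seg]]
      if (length(seg) == 0L) next
      e <- step[seg]
      # Kadane (min-sum) with segment tracking
      cur <- 0; cur_start <- 1L
      for (t in seq_along(e)) {
        if (cur > 0) { cur <- 0; cur_start <- t }
        cur <- cur + e[t]
        if (cur < best) {
          best <- cur
          idx <- seg[cur_start]:(seg[t] + 1L)  # step range -> pair range
          best_pairs <- cbind(ii[idx], jj[idx])
        }
      }
    }
  }
  structure(
    list(window = w, delta_g = best, pairing = best_pairs),
    class = "duplex_result"
  )
}

#' @export
print.duplex_result <- function(x, ...) {
  cat("<duplex_result> ", x$window, "  dG = ", format(x$delta_g),
      " kcal/mol (|dG| = ", format(abs(x$delta_g)), "), ",
      nrow(x$pairing), " paired bases\n", sep = "")
  invisible(x)
}

#' Scan the region upstream of a PPX site for aSD-like elements
#'
#' For each offset, an 8-nt mRNA window whose 3' end sits `offset` nucleotides
#' from the third nucleotide of the X codon (offset 0 = that nucleotide
#' itself; negative = upstream) is scored with [duplex_energy()]. Offsets
#' whose window would run past the CDS start are dropped and the result is
#' flagged truncated. The summary reports the best (most negative) energy in
#' the -9..-7 offset band, where SD-like elements position a paused ribosome
#' with X in the A site.
#'
#' @param cds_nt CDS nucleotide string (coding strand).
#' @param x_codon_index 1-based codon index of the A-site residue X.
#' @param offsets Integer offsets of the window 3' end (default -20..-5).
#' @param window_width Window width in nt (default 8, the aSD length).
#' @param asd,params Passed to [duplex_energy()].
#' @param weak_cutoff,sd_cutoff Energy cutoffs (kcal/mol) for the
#'   `weak_binder` (default -2) and `SD_like` (default -4) flags.
#' @return `data.frame` with columns `offset, window, delta_g`; attributes
#'   `best_band` (best energy at offsets -9..-7), `weak_binder`, `sd_like`,
#'   `truncated`.
#' @export
scan_upstream_affinity <- function(cds_nt, x_codon_index, offsets = -20:-5,
                                   window_width = 8L, asd = "CACCUCCU",
                                   params = load_stack_params(),
                                   weak_cutoff = -2, sd_cutoff = -4) {
  if (any(offsets > 0L)) stop("offsets must be <= 0")
  p3 <- 3L * x_codon_index
  if (p3 > nchar(cds_nt)) stop("x_codon_index outside the CDS")
  ends <- p3 + offsets
  starts <- ends - window_width + 1L
  ok <- starts >= 1L & ends >= window_width
  truncated <- any(!ok)
  rows <- lapply(which(ok), function(k) {
    win <- substr(cds_nt, starts[k], ends[k])
    d <- duplex_energy(win, asd = asd, params = params)
    data.frame(offset = offsets[k], window = d$window, delta_g = d$delta_g,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(offset = integer(), window = character(), delta_g = numeric(),
               stringsAsFactors = FALSE)
  band <- out$delta_g[out$offset >= -9L & out$offset <= -7L]
  best_band <- if (length(band)) min(band) else NA_real_
  attr(out, "best_band") <- best_band
  attr(out, "weak_binder") <- isTRUE(best_band <= weak_cutoff)
  attr(out, "sd_like") <- isTRUE(best_band <= sd_cutoff)
  attr(out, "truncated") <- truncated
  out
}
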