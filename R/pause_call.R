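#' Pausing index of a codon window
#'
#' Ratio of the mean per-codon footprint density over a window to the mean
#' density of the whole gene. A uniform gene scores 1 everywhere; a strong
#' pause accumulates density at the stall window and scores high.
#'
#' @param occ A `codon_occupancy`.
#' @param window Integer vector of 1-based codon indices (typically the
#'   3-codon stall window P-1, P, X).
#' @return Numeric index, or `NA` (with a warning) when the gene mean is 0.
#' @export
pausing_index <- function(occ, window) {
  if (any(window < 1L | window > length(occ$reads_per_codon))) {
    stop("window outside gene for '", occ$gene_id, "'")
  }
  if (occ$gene_mean == 0) {
    warning("gene mean is 0 for '", occ$gene_id, "'; index undefined")
    return(NA_real_)
  }
  mean(occ$reads_per_codon[window]) / occ$gene_mean
}

#' Classify a pausing index
#'
#' `strong` at index >= 10 (inclusive), `elevated` above 2, `non_pausing` at
#' or below 1, `neutral` in between.
#'
#' @param index Numeric vector of pausing indices (NA allowed).
#' @param strong,elevated,nonpausing Thresholds.
#' @return Character vector of labels.
#' @export
classify_pause <- function(index, strong = 10, elevated = 2, nonpausing = 1) {
  if (any(index < 0, na.rm = TRUE)) stop("pausing index must be >= 0")
  out <- rep(NA_character_, length(index))
  ok <- !is.na(index)
  out[ok & index >= strong] <- "strong"
  out[ok & is.na(out) & index > elevated] <- "elevated"
  out[ok & is.na(out) & index <= nonpausing] <- "non_pausing"
  out[ok & is.na(out)] <- "neutral"
  out
}

#' Compare pausing between strains at one site
#'
#' Indices are averaged over replicates within each strain, then the
#' delta-efp / WT fold change is computed. When the WT index is below the
#' pseudocount, the pseudocount is added to both numerator and denominator and
#' the call is flagged `wt_near_zero` (the raw indices are preserved). A site
#' is EF-P dependent when its delta-efp classification is `strong` *and* the
#' fold change reaches `fold_threshold`; this separates sites that pause only
#' without EF-P from sites (such as constitutively paused ones) that are
#' strong in every strain.
#'
#' @param indices `data.frame` with columns `strain, replicate, index`;
#'   strains named `WT`, `delta_efp` and optionally `complemented`.
#' @param pseudocount Added to both ratio terms when WT is near zero.
#' @param fold_threshold Minimum delta-efp/WT fold for EF-P dependence.
#' @param strong,elevated,nonpausing Passed to [classify_pause()].
#' @return List of class `pause_call`: per-strain averaged indices and
#'   classifications, `fold_change`, `wt_near_zero`, `efp_dependent`,
#'   `complement_restored` (NA when no complemented strain), `discordant`
#'   per-strain replicate flags.
#' @export
compare_strains <- function(indices, pseudocount = 0.1, fold_threshold = 3,
                            strong = 10, elevated = 2, nonpausing = 1) {
  if (!all(c("strain", "replicate", "index") %in% names(indices))) {
    stop("indices needs columns strain, replicate, index")
  }
  if (!"WT" %in% indices$strain || !"delta_efp" %in% indices$strain) {
    warning("missing WT or delta_efp strain; partial call")
  }
  avg <- list(); disc <- list()
  for (s in unique(indices$strain)) {
    v <- indices$index[indices$strain == s]
    v <- v[!is.na(v)]
    if (length(v) == 0L) next
    m <- average_replicates(v)
    avg[[s]] <- as.numeric(m)
    disc[[s]] <- attr(m, "discordant")
  }
  wt <- avg[["WT"]]
  de <- avg[["delta_efp"]]
  comp <- avg[["complemented"]]
  fold <- NA_real_
  wt_near_zero <- FALSE
  if (!is.null(wt) && !is.null(de)) {
    if (wt < pseudocount) {
      fold <- (de + pseudocount) / (wt + pseudocount)
      wt_near_zero <- TRUE
    } else {
      fold <- de / wt
    }
  }
  classification <- lapply(avg, classify_pause,
                           strong = strong, elevated = elevated,
                           nonpausing = nonpausing)
  efp_dependent <- !is.null(de) && classification[["delta_efp"]] == "strong" &&
    !is.na(fold) && fold >= fold_threshold
  complement_restored <- if (is.null(comp) || is.null(de)) NA else comp < de
  structure(
    list(index_by_strain = avg, classification = classification,
         fold_change = fold, wt_near_zero = wt_near_zero,
         efp_dependent = efp_dependent,
         complement_restored = complement_restored, discordant = disc),
    class = "pause_call"
  )
}

#' De novo pause scan of one gene
#'
#' Finds maximal runs of consecutive codons whose normalized occupancy
#' (reads per codon / gene mean) reaches `threshold`; each run is reported as
#' one window with its peak codon and peak value. Windows overlapping a PPX
#' site window can be cross-annotated by [run_pipeline()]; the remainder are
#' non-PPX pauses.
#'
#' @param occ A `codon_occupancy` (should pass the coverage filter).
#' @param threshold Normalized-occupancy threshold (default 10, the strong
#'   pause criterion).
#' @return `data.frame` with columns `gene_id, start, end, width, peak_codon,
#'   peak_value` (zero rows when nothing exceeds the threshold).
#' @export
scan_denovo_pauses <- function(occ, threshold = 10) {
  empty <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), width = integer(),
                      peak_codon = integer(), peak_value = numeric(),
                      stringsAsFactors = FALSE)
  norm <- normalized_occupancy(occ)
  if (all(is.na(norm))) return(empty)
  hit <- norm >= threshold
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    pk <- idx[which.max(norm[idx])]
    data.frame(gene_id = occ$gene_id, start = starts[k], end = ends[k],
               width = length(idx), peak_codon = pk, peak_value = norm[pk],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble the pause report table
#'
#' One row per site: identity and context of the motif, replicate-averaged
#' pausing index per strain, fold change and flags, sorted by the delta-efp
#' index in decreasing order. Mirrors the layout of a strain-comparison pause
#' listing; an external protein-ratio column can be joined on `gene_id`.
#'
#' @param sites PPX site table ([find_ppx_sites_all()]).
#' @param calls List of `pause_call` objects parallel to `sites` rows (NULL
#'   entries are dropped, e.g. uncovered genes).
#' @param protein_ratio Optional named vector of delta-efp/WT protein-level
#'   ratios joined by gene.
#' @return `data.frame` report.
#' @export
build_pause_table <- function(sites, calls, protein_ratio = NULL) {
  stopifnot(nrow(sites) == length(calls))
  keep <- !vapply(calls, is.null, TRUE)
  sites <- sites[keep, , drop = FALSE]
  calls <- calls[keep]
  get_idx <- function(call, s) {
    v <- call$index_by_strain[[s]]
    if (is.null(v)) NA_real_ else v
  }
  tab <- data.frame(
    gene_id = sites$gene_id,
    motif = sites$motif,
    x_codon_index = sites$x_codon_index,
    z3 = sites$z3, z2 = sites$z2,
    upstream20 = sites$upstream20,
    index_wt = vapply(calls, get_idx, 0, s = "WT"),
    index_delta_efp = vapply(calls, get_idx, 0, s = "delta_efp"),
    index_complemented = vapply(calls, get_idx, 0, s = "complemented"),
    fold_change = vapply(calls, function(x) x$fold_change, 0),
    wt_near_zero = vapply(calls, function(x) x$wt_near_zero, TRUE),
    classification_delta_efp = vapply(calls, function(x) {
      cl <- x$classification[["delta_efp"]]
      if (is.null(cl)) NA_character_ else cl
    }, ""),
    efp_dependent = vapply(calls, function(x) isTRUE(x$efp_dependent), TRUE),
    complement_restored = vapply(calls, function(x) {
      cr <- x$complement_restored
      if (is.null(cr)) NA else cr
    }, TRUE),
    stringsAsFactors = FALSE
  )
  if (!is.null(protein_ratio)) {
    tab$protein_ratio <- unname(protein_ratio[tab$gene_id])
  }
  tab <- tab[order(-tab$index_delta_efp, tab$gene_id, tab$x_codon_index), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}
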