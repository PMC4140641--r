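#' ZPPX context matrix
#'
#' Aggregates pause calls over the (Z-2 residue, A-site residue X) grid: site
#' counts, mean replicate-averaged delta-efp index, and counts of strong and
#' non-pausing classifications. Combinations with no sites are absent from
#' the output (missing, not zero).
#'
#' @param pause_tab Report from [build_pause_table()].
#' @return `data.frame` with columns `z2, x, n_sites, mean_index_delta_efp,
#'   n_strong, n_nonpausing`.
#' @export
zppx_matrix <- function(pause_tab) {
  if (nrow(pause_tab) == 0L) {
    return(data.frame(z2 = character(), x = character(), n_sites = integer(),
                      mean_index_delta_efp = numeric(), n_strong = integer(),
                      n_nonpausing = integer(), stringsAsFactors = FALSE))
  }
  x <- substr(pause_tab$motif, 3L, 3L)
  key <- paste(pause_tab$z2, x, sep = "|")
  split_idx <- split(seq_len(nrow(pause_tab)), key)
  out <- lapply(names(split_idx), function(k) {
    idx <- split_idx[[k]]
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    cl <- pause_tab$classification_delta_efp[idx]
    data.frame(
      z2 = parts[1], x = parts[2], n_sites = length(idx),
      mean_index_delta_efp = mean(pause_tab$index_delta_efp[idx], na.rm = TRUE),
      n_strong = sum(cl == "strong", na.rm = TRUE),
      n_nonpausing = sum(cl == "non_pausing", na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$z2, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Class-level contingency summary of pausing context
#'
#' Cross-tabulates sites by (Z-2 class, X class) into pausing (strong) and
#' non-pausing counts, and flags class pairs observed only among pausing
#' sites or only among non-pausing sites (e.g. an acidic A-site residue that
#' stalls regardless of Z-2).
#'
#' @param pause_tab Report from [build_pause_table()].
#' @return `data.frame` with columns `z2_class, x_class, n_pausing,
#'   n_nonpausing, n_other, only_pausing, only_nonpausing`.
#' @export
class_summary <- function(pause_tab) {
  if (nrow(pause_tab) == 0L) {
    return(data.frame(z2_class = character(), x_class = character(),
                      n_pausing = integer(), n_nonpausing = integer(),
                      n_other = integer(), only_pausing = logical(),
                      only_nonpausing = logical(), stringsAsFactors = FALSE))
  }
  z2c <- classify_residue(pause_tab$z2)
  xc <- classify_residue(substr(pause_tab$motif, 3L, 3L))
  cl <- pause_tab$classification_delta_efp
  key <- paste(z2c, xc, sep = "|")
  split_idx <- split(seq_len(nrow(pause_tab)), key)
  out <- lapply(names(split_idx), function(k) {
    idx <- split_idx[[k]]
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    np <- sum(cl[idx] == "strong", na.rm = TRUE)
    nn <- sum(cl[idx] == "non_pausing", na.rm = TRUE)
    data.frame(
      z2_class = parts[1], x_class = parts[2],
      n_pausing = np, n_nonpausing = nn,
      n_other = length(idx) - np - nn,
      only_pausing = np > 0L && nn == 0L,
      only_nonpausing = nn > 0L && np == 0L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$z2_class, out$x_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of pausing indices
#'
#' Left-inclusive, right-exclusive bins; the default edges separate the
#' non-pausing (<1), neutral, elevated and strong regimes.
#'
#' @param indices Numeric vector (NA dropped).
#' @param breaks Monotone increasing bin edges; last edge may be `Inf`.
#' @return `data.frame` with columns `bin, lower, upper, count, fraction`.
#' @export
pausing_histogram <- function(indices,
                              breaks = c(0, 1, 2, 5, 10, 20, 50, Inf)) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing")
  }
  indices <- indices[!is.na(indices)]
  if (any(indices < breaks[1] | indices >= breaks[length(breaks)])) {
    stop("index value(s) outside the bin range")
  }
  nb <- length(breaks) - 1L
  bin <- findInterval(indices, breaks, rightmost.closed = FALSE)
  count <- tabulate(bin, nbins = nb)
  data.frame(
    bin = paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")"),
    lower = breaks[-length(breaks)], upper = breaks[-1],
    count = count,
    fraction = if (sum(count) > 0) count / sum(count) else rep(0, nb),
    stringsAsFactors = FALSE
  )
}

#' Load a codon-usage table
#'
#' The packaged default is an E. coli K-12 genome-wide usage table
#' (frequency per thousand codons); any TSV with columns
#' `codon, aa, per_thousand` can be substituted.
#'
#' @param path TSV path; default the packaged table.
#' @return `data.frame` with columns `codon, aa, per_thousand`.
#' @export
load_codon_usage <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ecoli_codon_usage.tsv",
                        package = "ribopause", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("codon", "aa", "per_thousand") %in% names(tab)))
  tab$codon <- toupper(gsub("U", "T", tab$codon))
  tab
}

#' Codon usage and rarity of an A-site codon
#'
#' Looks a sense codon up in the usage table and flags it rare when its
#' frequency falls below a cutoff, by default the lower quartile of all sense
#' codons (a proxy for rare-tRNA decoding). Stop codons and unknown triplets
#' are errors.
#'
#' @param codon 3-letter DNA (or RNA) codon(s).
#' @param usage Usage table from [load_codon_usage()].
#' @param cutoff Per-thousand threshold; default the sense-codon lower
#'   quartile.
#' @return `data.frame` with columns `codon, aa, per_thousand, rare`.
#' @export
codon_rarity <- function(codon, usage = load_codon_usage(), cutoff = NULL) {
  codon <- toupper(gsub("U", "T", codon))
  sense <- usage[usage$aa != "*", ]
  if (is.null(cutoff)) {
    cutoff <- stats::quantile(sense$per_thousand, 0.25, names = FALSE)
  }
  idx <- match(codon, usage$codon)
  if (anyNA(idx)) {
    stop("unknown codon(s): ", paste(codon[is.na(idx)], collapse = ", "))
  }
  if (any(usage$aa[idx] == "*")) {
    stop("stop codon has no A-site decoding: ",
         paste(codon[usage$aa[idx] == "*"], collapse = ", "))
  }
  data.frame(
    codon = codon, aa = usage$aa[idx],
    per_thousand = usage$per_thousand[idx],
    rare = usage$per_thousand[idx] < cutoff,
    stringsAsFactors = FALSE
  )
}

#' Concordance of footprint and protein-abundance ratios
#'
#' Bins genes shared by a ribo-seq ratio table and a protein-abundance ratio
#' table (both oriented as delta-efp / WT; use `invert_protein = TRUE` for
#' tables reported as WT / delta-efp) by the 0.5-2 / above-2 / below-0.5
#' partition on both axes. Every shared gene lands in exactly one bin.
#'
#' @param ribo_ratio Named numeric vector, delta-efp/WT footprints per gene.
#' @param protein_ratio Named numeric vector of protein abundance ratios.
#' @param invert_protein Set TRUE when the protein table is WT/delta-efp.
#' @param lower,upper Band considered "unchanged" (default 0.5-2).
#' @return `data.frame` with columns `label, count, fraction`; attribute
#'   `n_shared` gives the number of genes compared.
#' @export
concordance <- function(ribo_ratio, protein_ratio, invert_protein = FALSE,
                        lower = 0.5, upper = 2) {
  shared <- intersect(names(ribo_ratio), names(protein_ratio))
  if (length(shared) < 1L) stop("no shared genes between the two tables")
  r <- ribo_ratio[shared]
  p <- protein_ratio[shared]
  if (invert_protein) p <- 1 / p
  band <- function(x) ifelse(x > upper, "up", ifelse(x < lower, "down", "mid"))
  rb <- band(r); pb <- band(p)
  lab <- rep("discordant", length(shared))
  lab[rb == "mid" & pb == "mid"] <- "both_0.5_2"
  lab[rb == "up" & pb == "up"] <- "both_up"
  lab[rb == "up" & pb == "mid"] <- "ribo_up_only"
  lab[rb == "down" & pb == "down"] <- "both_down"
  lab[rb == "down" & pb == "mid"] <- "ribo_down_only"
  levels <- c("both_0.5_2", "ribo_up_only", "both_up", "ribo_down_only",
              "both_down", "discordant")
  count <- vapply(levels, function(l) sum(lab == l), 0L)
  out <- data.frame(label = levels, count = unname(count),
                    fraction = unname(count) / length(shared),
                    stringsAsFactors = FALSE)
  attr(out, "n_shared") <- length(shared)
  out
}
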