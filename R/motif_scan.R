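#' Enumerate PPX motif sites in a protein
#'
#' A site is every position `i` with `protein[i] == "P"` and
#' `protein[i+1] == "P"` and an A-site residue `X = protein[i+2]` present.
#' Consequently a run of L consecutive prolines followed by X emits `L - 1`
#' sites (a PPPX gene is listed twice, once for the PPP window and once for
#' the PPX window). A proline run that ends the protein emits nothing for its
#' trailing pair: the A site must hold an amino acid, not the chain end, and
#' the stop codon is never X.
#'
#' The returned window is the codon triple (P at -1, P at the P site, X at the
#' A site). Context columns: `z2`/`z3` are the residues two and three
#' positions upstream of the P-site proline (`-` when the protein starts
#' first), and `upstream20` is the 20 residues immediately preceding the first
#' proline of the window, left-padded with `-`.
#'
#' @param protein Amino-acid string.
#' @param gene_id Identifier copied into the output.
#' @return `data.frame` with columns `gene_id, motif, x_codon_index,
#'   win_start, z3, z2, upstream20`, sorted by position. Zero rows when the
#'   protein has no PPX.
#' @export
find_ppx_sites <- function(protein, gene_id = NA_character_) {
  n <- nchar(protein)
  empty <- data.frame(
    gene_id = character(), motif = character(), x_codon_index = integer(),
    win_start = integer(), z3 = character(), z2 = character(),
    upstream20 = character(), stringsAsFactors = FALSE
  )
  if (n < 3L) return(empty)
  aa <- strsplit(protein, "")[[1]]
  i <- which(aa[seq_len(n - 2L)] == "P" & aa[seq_len(n - 2L) + 1L] == "P")
  if (length(i) == 0L) return(empty)
  sites <- data.frame(
    gene_id = gene_id,
    motif = paste0("PP", aa[i + 2L]),
    x_codon_index = i + 2L,
    win_start = i,
    z3 = ifelse(i >= 3L, aa[pmax(i - 2L, 1L)], "-"),
    z2 = ifelse(i >= 2L, aa[pmax(i - 1L, 1L)], "-"),
    upstream20 = vapply(i, function(p) upstream_padded(aa, p, 20L), ""),
    stringsAsFactors = FALSE
  )
  sites[order(sites$x_codon_index), , drop = FALSE]
}

upstream_padded <- function(aa, pos, width) {
  from <- pos - width
  res <- aa[seq.int(max(from, 1L), pos - 1L)]
  if (pos - 1L < 1L) res <- character()
  paste0(strrep("-", max(0L, width - length(res))),
         paste(res, collapse = ""))
}

#' Scan a gene table for PPX sites
#'
#' @param genes Gene record `data.frame` (see [load_annotation()]).
#' @return Row-bound [find_ppx_sites()] output for every gene, sorted by
#'   `(gene_id, x_codon_index)`.
#' @export
find_ppx_sites_all <- function(genes) {
  if (nrow(genes) == 0L) return(find_ppx_sites(""))
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    find_ppx_sites(genes$protein[i], genes$gene_id[i])
  }))
  out <- out[order(out$gene_id, out$x_codon_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Physico-chemical class of an amino acid
#'
#' Classes used for context analysis of the A-site and Z-2 residues:
#' acidic (D, E), basic (K, R, H), amide (N, Q), hydroxy (S, T, Y),
#' proline (P), glycine (G), hydrophobic_aromatic (A, V, L, I, M, F, W, C;
#' cysteine is grouped here by default), `none` for the `-` padding character,
#' `other` (with a warning) for anything else.
#'
#' @param aa Character vector of single-letter residues.
#' @return Character vector of class labels.
#' @export
classify_residue <- function(aa) {
  map <- c(
    D = "acidic", E = "acidic",
    K = "basic", R = "basic", H = "basic",
    N = "amide", Q = "amide",
    S = "hydroxy", T = "hydroxy", Y = "hydroxy",
    P = "proline", G = "glycine",
    A = "hydrophobic_aromatic", V = "hydrophobic_aromatic",
    L = "hydrophobic_aromatic", I = "hydrophobic_aromatic",
    M = "hydrophobic_aromatic", F = "hydrophobic_aromatic",
    W = "hydrophobic_aromatic", C = "hydrophobic_aromatic",
    `-` = "none"
  )
  out <- unname(map[aa])
  if (anyNA(out)) {
    warning("unknown residue(s): ", paste(unique(aa[is.na(out)]), collapse = ", "))
    out[is.na(out)] <- "other"
  }
  out
}

#' Write a PPX site table as TSV
#'
#' Fixed column order `gene_id, motif, x_codon_index, z3, z2, upstream20`.
#'
#' @param sites Output of [find_ppx_sites_all()].
#' @param path Output path.
#' @export
write_ppx_table <- function(sites, path) {
  cols <- c("gene_id", "motif", "x_codon_index", "z3", "z2", "upstream20")
  utils::write.table(sites[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
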