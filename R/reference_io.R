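#' Load a genome from FASTA
#'
#' Reads a (multi-)FASTA file into a named character vector of uppercase DNA
#' sequences, one element per record. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase DNA sequences
#'   (alphabet A/C/G/T/N).
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("invalid FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("no sequences in FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  seqs
}

#' Translate a coding sequence
#'
#' Standard (bacterial) genetic code via [Biostrings::GENETIC_CODE]. A terminal
#' stop codon is dropped; an internal stop is an error reporting the 1-based
#' codon index. Codons containing N (or any non-ACGT base) translate to `X`.
#'
#' @param cds_nt DNA string, length divisible by 3.
#' @return Amino-acid string (no trailing `*`).
#' @export
translate_cds <- function(cds_nt) {
  cds_nt <- toupper(cds_nt)
  n <- nchar(cds_nt)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length (", n, ") not a positive multiple of 3")
  }
  codons <- substring(cds_nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  ncod <- length(aa)
  if (aa[ncod] == "*") aa <- aa[-ncod]
  internal <- which(aa == "*")
  if (length(internal) > 0L) {
    stop("internal stop codon at codon index ", internal[1L])
  }
  paste(aa, collapse = "")
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

extract_cds <- function(genome, seqid, start, end, strand) {
  s <- substr(genome[[seqid]], start, end)
  if (strand == "-") s <- reverse_complement(s) else s
}

#' Load CDS annotation (GFF3 or TSV) into gene records
#'
#' Accepts GFF3 (features of type `CDS`; gene identifier taken from the `ID`,
#' `gene` or `locus_tag` attribute, in that order) or a tab-separated table
#' with header columns `gene_id, seqid, start, end, strand` (1-based
#' inclusive). Coordinates are kept 1-based inclusive internally. Minus-strand
#' CDS are reverse-complemented before translation.
#'
#' Records whose length is not a multiple of 3 or that contain an internal
#' stop codon are skipped with a warning; an unknown sequence id or
#' out-of-bounds interval is fatal. When a `gene_id` occurs more than once,
#' only the longest CDS is kept.
#'
#' @param path Annotation file (`.gff`/`.gff3` or TSV).
#' @param genome Named character vector from [load_genome()].
#' @return `data.frame` with columns `gene_id, seqid, start, end, strand,
#'   cds_nt, protein`.
#' @export
load_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("annotation not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) == "cds"]
    if (length(gr) == 0L) stop("no CDS features in ", path)
    ids <- rep(NA_character_, length(gr))
    for (key in c("ID", "gene", "locus_tag")) {
      if (key %in% names(S4Vectors::mcols(gr))) {
        v <- as.character(S4Vectors::mcols(gr)[[key]])
        ids[is.na(ids) & !is.na(v)] <- v[is.na(ids) & !is.na(v)]
      }
    }
    if (anyNA(ids)) stop("CDS feature(s) without ID/gene/locus_tag attribute")
    tab <- data.frame(
      gene_id = ids,
      seqid = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("gene_id", "seqid", "start", "end", "strand")
    if (!all(need %in% names(tab))) {
      stop("TSV annotation must have columns: ", paste(need, collapse = ", "))
    }
    tab <- tab[, need]
  }
  if (any(!tab$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' for every CDS")
  }
  unknown <- setdiff(unique(tab$seqid), names(genome))
  if (length(unknown) > 0L) {
    stop("annotation references unknown sequence id(s): ",
         paste(unknown, collapse = ", "))
  }
  lens <- nchar(genome)[tab$seqid]
  if (any(tab$start < 1L | tab$end > lens | tab$start > tab$end)) {
    stop("CDS interval out of sequence bounds")
  }

  keep <- rep(TRUE, nrow(tab))
  cds <- character(nrow(tab))
  prot <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    len <- tab$end[i] - tab$start[i] + 1L
    if (len %% 3L != 0L) {
      warning("skipping '", tab$gene_id[i], "': CDS length ", len,
              " not divisible by 3")
      keep[i] <- FALSE
      next
    }
    cds[i] <- extract_cds(genome, tab$seqid[i], tab$start[i], tab$end[i],
                          tab$strand[i])
    p <- tryCatch(translate_cds(cds[i]), error = function(e) e)
    if (inherits(p, "error")) {
      warning("skipping '", tab$gene_id[i], "': ", conditionMessage(p))
      keep[i] <- FALSE
      next
    }
    prot[i] <- p
  }
  tab$cds_nt <- cds
  tab$protein <- prot
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no usable CDS records in ", path)

  # one ORF per gene_id: keep the longest
  len <- nchar(tab$cds_nt)
  ord <- order(tab$gene_id, -len)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$gene_id), , drop = FALSE]
  tab <- tab[order(tab$seqid, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write genome and gene records back to FASTA + GFF3
#'
#' Inverse of [load_genome()] / [load_annotation()]; used by the simulator and
#' for round-trip checks.
#'
#' @param genome Named character vector of DNA sequences.
#' @param genes Gene record `data.frame` (see [load_annotation()]).
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_reference <- function(genome, genes, fasta_path, gff_path) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seqid,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "CDS"
  gr$ID <- genes$gene_id
  gr$phase <- 0L
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(list(fasta = fasta_path, gff = gff_path))
}
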