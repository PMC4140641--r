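#' @title Footprint tracks and per-codon occupancy
#' @name occupancy
#' @description
#' A *sample track* holds per-nucleotide footprint counts for one sequencing
#' sample (one strain, one replicate), as dense per-strand vectors over each
#' reference sequence. Tracks come from aligned footprints
#' ([assign_footprints()]), from coverage files ([read_track()]), or from the
#' simulator ([simulate_tracks()]). [codon_occupancy()] bins a track into
#' per-codon counts for one gene.
NULL

new_sample_track <- function(seqlengths, sample_id = "sample",
                             strain = "custom", replicate = 1L) {
  counts <- lapply(seqlengths, function(L) {
    list(`+` = numeric(L), `-` = numeric(L))
  })
  structure(
    list(sample_id = sample_id, strain = strain,
         replicate = as.integer(replicate),
         seqlengths = seqlengths, counts = counts, skipped = 0L),
    class = "sample_track"
  )
}

#' @export
print.sample_track <- function(x, ...) {
  tot <- sum(vapply(x$counts, function(s) sum(s$`+`) + sum(s$`-`), 0))
  cat("<sample_track> ", x$sample_id, " (strain=", x$strain,
      ", replicate=", x$replicate, ")\n",
      "  sequences: ", length(x$counts),
      "; total counts: ", format(tot),
      "; skipped alignments: ", x$skipped, "\n", sep = "")
  invisible(x)
}

track_total <- function(track) {
  sum(vapply(track$counts, function(s) sum(s$`+`) + sum(s$`-`), 0))
}

#' Assign aligned footprints to single nucleotide positions
#'
#' Each usable alignment contributes one count at one nucleotide. Under the
#' default `"center"` rule that nucleotide is the center of the footprint,
#' `floor((start + end - 1) / 2)` in 0-based terms — equivalently
#' `start + floor((width - 1) / 2)` 1-based. Under the `"offset3p"` rule it is
#' a fixed distance `offset` upstream of the footprint 3' end (strand-aware).
#' Unmapped, secondary and supplementary alignments are skipped and tallied in
#' the track's `skipped` field.
#'
#' @param path SAM/BAM file, or a read-interval TSV with header columns
#'   `seqid, start, end, strand` (1-based inclusive).
#' @param seqlengths Named integer vector of reference sequence lengths.
#' @param rule `"center"` (default) or `"offset3p"`.
#' @param offset Distance from the 3' end for `rule = "offset3p"` (default 12,
#'   i.e. the assigned base is 12 nt 5' of the 3'-terminal base).
#' @param sample_id,strain,replicate Sample metadata stored on the track.
#' @return A `sample_track`.
#' @export
assign_footprints <- function(path, seqlengths, rule = c("center", "offset3p"),
                              offset = 12L, sample_id = "sample",
                              strain = "custom", replicate = 1L) {
  rule <- match.arg(rule)
  if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
    ali <- read_alignments_sam(path)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("seqid", "start", "end", "strand")
    if (!all(need %in% names(tab))) {
      stop("read-interval TSV must have columns: ", paste(need, collapse = ", "))
    }
    ali <- list(seqid = tab$seqid, start = as.integer(tab$start),
                end = as.integer(tab$end), strand = tab$strand, skipped = 0L)
  }
  track <- new_sample_track(seqlengths, sample_id, strain, replicate)
  track$skipped <- ali$skipped
  if (length(ali$start) == 0L) return(track)
  width <- ali$end - ali$start + 1L
  pos <- if (rule == "center") {
    ali$start + (width - 1L) %/% 2L
  } else {
    ifelse(ali$strand == "-", ali$start + offset, ali$end - offset)
  }
  ok <- ali$seqid %in% names(seqlengths) &
    pos >= 1L & pos <= unname(seqlengths[ali$seqid])
  track$skipped <- track$skipped + sum(!ok)
  for (sq in unique(ali$seqid[ok])) {
    for (st in c("+", "-")) {
      sel <- ok & ali$seqid == sq & ali$strand == st
      if (any(sel)) {
        t <- tabulate(pos[sel], nbins = seqlengths[[sq]])
        track$counts[[sq]][[st]] <- track$counts[[sq]][[st]] + t
      }
    }
  }
  track
}

read_alignments_sam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  } else {
    bam <- path
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  par <- Rsamtools::ScanBamParam(flag = flags,
                                 what = c("rname", "pos", "qwidth", "strand"))
  res <- Rsamtools::scanBam(bam, param = par)[[1]]
  n_all <- Rsamtools::countBam(bam)$records
  keep <- !is.na(res$pos)
  list(
    seqid = as.character(res$rname)[keep],
    start = res$pos[keep],
    end = res$pos[keep] + res$qwidth[keep] - 1L,
    strand = as.character(res$strand)[keep],
    skipped = n_all - sum(keep)
  )
}

#' Read / write per-nucleotide coverage tracks
#'
#' `read_track()` accepts a stranded TSV (`seqid, pos, strand, count`, 1-based)
#' or a pair of bedGraph files (plus/minus strand). `write_track()` writes the
#' stranded TSV; `write_track_bedgraph()` writes the bedGraph pair via
#' \pkg{rtracklayer}.
#'
#' @param path TSV path, or the plus-strand bedGraph when `minus` is given.
#' @param seqlengths Named integer vector of reference sequence lengths.
#' @param minus Optional minus-strand bedGraph path.
#' @param sample_id,strain,replicate Sample metadata.
#' @return A `sample_track`.
#' @export
read_track <- function(path, seqlengths, minus = NULL, sample_id = "sample",
                       strain = "custom", replicate = 1L) {
  track <- new_sample_track(seqlengths, sample_id, strain, replicate)
  if (is.null(minus) && !grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("seqid", "pos", "strand", "count")
    if (!all(need %in% names(tab))) {
      stop("track TSV must have columns: ", paste(need, collapse = ", "))
    }
    for (sq in unique(tab$seqid)) {
      if (!sq %in% names(seqlengths)) stop("unknown sequence id: ", sq)
      for (st in c("+", "-")) {
        sel <- tab$seqid == sq & tab$strand == st
        if (any(sel)) {
          v <- numeric(seqlengths[[sq]])
          v[tab$pos[sel]] <- tab$count[sel]
          track$counts[[sq]][[st]] <- v
        }
      }
    }
    return(track)
  }
  paths <- c(`+` = path, `-` = minus)
  for (st in names(paths)) {
    gr <- rtracklayer::import(paths[[st]], format = "bedGraph")
    for (sq in unique(as.character(GenomicRanges::seqnames(gr)))) {
      if (!sq %in% names(seqlengths)) stop("unknown sequence id: ", sq)
      sel <- gr[as.character(GenomicRanges::seqnames(gr)) == sq]
      v <- track$counts[[sq]][[st]]
      for (k in seq_along(sel)) {
        idx <- GenomicRanges::start(sel)[k]:GenomicRanges::end(sel)[k]
        v[idx] <- v[idx] + sel$score[k]
      }
      track$counts[[sq]][[st]] <- v
    }
  }
  track
}

#' @rdname read_track
#' @param track A `sample_track`.
#' @export
write_track <- function(track, path) {
  rows <- list()
  for (sq in names(track$counts)) {
    for (st in c("+", "-")) {
      v <- track$counts[[sq]][[st]]
      nz <- which(v > 0)
      if (length(nz) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = sq, pos = nz, strand = st, count = v[nz],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqid = character(), pos = integer(), strand = character(),
               count = numeric())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_track
#' @param prefix Output prefix; writes `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph`.
#' @export
write_track_bedgraph <- function(track, prefix) {
  out <- c(`+` = paste0(prefix, ".plus.bedGraph"),
           `-` = paste0(prefix, ".minus.bedGraph"))
  for (st in c("+", "-")) {
    grl <- list()
    for (sq in names(track$counts)) {
      v <- track$counts[[sq]][[st]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values > 0
      if (any(keep)) {
        grl[[length(grl) + 1L]] <- GenomicRanges::GRanges(
          seqnames = sq,
          ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
          score = r$values[keep]
        )
      }
    }
    gr <- if (length(grl)) {
      do.call(c, grl)
    } else {
      g0 <- GenomicRanges::GRanges()
      g0$score <- numeric()
      g0
    }
    rtracklayer::export(gr, out[[st]], format = "bedGraph")
  }
  invisible(unname(out))
}

#' Per-codon ribosome occupancy for one gene
#'
#' Sums nucleotide counts in consecutive 3-nt bins along the coding strand of
#' the gene. For minus-strand genes codon 1 is the bin at the genomic 3' end.
#' The vector covers every codon of the CDS including the stop codon, so its
#' length is protein length + 1. `gene_mean` is the arithmetic mean over all
#' codons.
#'
#' @param track A `sample_track`.
#' @param gene One row of a gene record `data.frame`.
#' @return List of class `codon_occupancy` with `gene_id, sample_id,
#'   reads_per_codon, gene_mean`.
#' @export
codon_occupancy <- function(track, gene) {
  if (!gene$seqid %in% names(track$counts)) {
    stop("gene '", gene$gene_id, "' on unknown sequence: ", gene$seqid)
  }
  v <- track$counts[[gene$seqid]][[gene$strand]][gene$start:gene$end]
  if (gene$strand == "-") v <- rev(v)
  ncod <- length(v) %/% 3L
  per_codon <- colSums(matrix(v, nrow = 3L, ncol = ncod))
  structure(
    list(gene_id = gene$gene_id, sample_id = track$sample_id,
         reads_per_codon = per_codon, gene_mean = mean(per_codon)),
    class = "codon_occupancy"
  )
}

#' Gene-level coverage filter
#'
#' A gene is analysed only when its mean footprint density reaches
#' `threshold` reads per codon (boundary inclusive; default 3).
#'
#' @param occ A `codon_occupancy`.
#' @param threshold Minimum mean reads/codon.
#' @return Logical scalar.
#' @export
filter_covered <- function(occ, threshold = 3) {
  occ$gene_mean >= threshold
}

#' Normalized occupancy
#'
#' Per-codon counts divided by the gene mean, so the normalized vector has
#' mean 1 for any covered gene.
#'
#' @param occ A `codon_occupancy`.
#' @return Numeric vector, or all-NA when the gene mean is 0.
#' @export
normalized_occupancy <- function(occ) {
  if (occ$gene_mean == 0) return(rep(NA_real_, length(occ$reads_per_codon)))
  occ$reads_per_codon / occ$gene_mean
}

#' Replicate correlation of footprints per gene
#'
#' Pearson correlation of log10(total footprints per gene + 1) over the genes
#' shared by two replicates.
#'
#' @param a,b Named numeric vectors of total footprints per gene.
#' @return Correlation coefficient.
#' @export
replicate_correlation <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  stats::cor(log10(a[shared] + 1), log10(b[shared] + 1))
}

#' Total footprints per gene for one track
#'
#' @param track A `sample_track`.
#' @param genes Gene record `data.frame`.
#' @return Named numeric vector (one total per gene).
#' @export
footprints_per_gene <- function(track, genes) {
  tot <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    sum(track$counts[[g$seqid]][[g$strand]][g$start:g$end])
  }, 0)
  names(tot) <- genes$gene_id
  tot
}

#' Average per-replicate values
#'
#' Arithmetic mean of per-replicate statistics (applied to pausing indices
#' after per-replicate computation). When replicates disagree by more than
#' `flag_fold`-fold the result carries attribute `discordant = TRUE`.
#'
#' @param values Numeric vector, one value per replicate.
#' @param flag_fold Disagreement ratio beyond which replicates are flagged.
#' @return Mean, with a `discordant` attribute.
#' @export
average_replicates <- function(values, flag_fold = 5) {
  if (length(values) == 0L) stop("no replicate values")
  m <- mean(values)
  disc <- FALSE
  if (length(values) > 1L) {
    lo <- min(values)
    hi <- max(values)
    disc <- hi > 0 && (lo == 0 || hi / lo > flag_fold)
  }
  attr(m, "discordant") <- disc
  m
}
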