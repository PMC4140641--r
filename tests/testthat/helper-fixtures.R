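# Shared fixtures and independent brute-force oracles.
# Oracles are deliberately naive re-derivations used to cross-check the
# package implementations; they must stay independent of the code they test.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# build a codon_occupancy object directly from a per-codon vector
occ_fixture <- function(reads, gene_id = "g", sample_id = "s") {
  structure(
    list(gene_id = gene_id, sample_id = sample_id,
         reads_per_codon = as.numeric(reads), gene_mean = mean(reads)),
    class = "codon_occupancy"
  )
}

# single-gene genome: spacer + CDS (strand-aware) + spacer
tiny_reference <- function(cds, strand = "+", pad5 = 12L, pad3 = 9L,
                           gene_id = "g1") {
  up <- strrep("A", pad5)
  down <- strrep("C", pad3)
  body <- if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  } else cds
  genome <- c(chrT = paste0(up, body, down))
  genes <- data.frame(
    gene_id = gene_id, seqid = "chrT",
    start = pad5 + 1L, end = pad5 + nchar(cds), strand = strand,
    cds_nt = cds, protein = translate_cds(cds),
    stringsAsFactors = FALSE
  )
  list(genome = genome, genes = genes,
       seqlengths = c(chrT = nchar(genome[[1]])))
}

# track with counts placed at explicit (pos, strand) 1-based coordinates
track_fixture <- function(seqlengths, pos, strand = "+", count = 1,
                          sample_id = "s", strain = "custom", replicate = 1L) {
  tr <- ribopause:::new_sample_track(seqlengths, sample_id, strain, replicate)
  sq <- names(seqlengths)[1]
  df <- data.frame(pos = pos, strand = strand, count = count)
  for (i in seq_len(nrow(df))) {
    tr$counts[[sq]][[df$strand[i]]][df$pos[i]] <-
      tr$counts[[sq]][[df$strand[i]]][df$pos[i]] + df$count[i]
  }
  tr
}

# ---- brute-force oracles -------------------------------------------------

# PPX emission: scan every position with a plain loop
oracle_ppx_positions <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  hits <- integer()
  if (n < 3) return(hits)
  for (i in 1:(n - 2)) {
    if (aa[i] == "P" && aa[i + 1] == "P") hits <- c(hits, i)
  }
  hits
}

# de novo pause windows: exhaustive per-codon check, then manual merging
oracle_denovo <- function(norm, threshold = 10) {
  hit <- which(norm >= threshold)
  if (length(hit) == 0) return(data.frame(start = integer(), end = integer()))
  breaks <- which(diff(hit) > 1)
  starts <- hit[c(1, breaks + 1)]
  ends <- hit[c(breaks, length(hit))]
  data.frame(start = starts, end = ends)
}

# duplex minimum: enumerate every register, start and length explicitly
ASD_PAIR_OK <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

oracle_duplex <- function(window, asd = "CACCUCCU",
                          params = load_stack_params()) {
  w <- strsplit(chartr("Tt", "UU", toupper(window)), "")[[1]]
  a <- strsplit(chartr("Tt", "UU", toupper(asd)), "")[[1]]
  n <- length(w); m <- length(a)
  best <- 0
  for (i0 in 1:(n - 1)) {
    for (j0 in 2:m) {
      maxlen <- min(n - i0 + 1, j0)
      if (maxlen < 2) next
      for (len in 2:maxlen) {
        ii <- i0:(i0 + len - 1)
        jj <- j0 - (0:(len - 1))
        if (!all(ASD_PAIR_OK(w[ii], a[jj]))) next
        e <- 0
        for (t in 1:(len - 1)) {
          e <- e + params[paste0(w[ii[t]], a[jj[t]]),
                          paste0(a[jj[t + 1]], w[ii[t + 1]])]
        }
        if (e < best) best <- e
      }
    }
  }
  best
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# small simulated dataset reused by several test files
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- end_to_end_fixture(
        sim_spec(n_genes = 25L, len_range = c(150L, 250L), n_strong = 4L,
                 n_decoy = 6L, depth = 20, replicates = 2L, seed = 11L)
      )
    }
    cache
  }
})
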