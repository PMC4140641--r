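AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of a synthetic ribo-seq dataset
#'
#' Defines every parameter of the simulator: gene complement, per-gene
#' expression, planted stall sites and their dwell multipliers, sequencing
#' depth, count overdispersion, strains and replicates, and the seed that
#' fully determines the output.
#'
#' The defaults are the package's standard validation fixture: 200 genes of
#' 150-450 codons, log-normal expression (meanlog 0, sdlog 1), 30 planted
#' strong stall sites with dwell multiplier 15 in the `delta_efp` condition,
#' 100 decoy PPX sites with multiplier 1, mean depth 20 reads/codon at unit
#' expression, negative-binomial counts with size 10, and two replicates per
#' condition.
#'
#' @param n_genes Number of genes.
#' @param len_range Protein length range (codons), sampled uniformly.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of per-gene relative
#'   expression.
#' @param n_strong,n_decoy Numbers of planted stall and decoy PPX sites.
#' @param multiplier Dwell multiplier at planted stall windows in the
#'   `delta_efp` condition (decoys and all WT windows stay at 1).
#' @param depth Mean footprint reads per codon at expression 1.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param replicates Replicates per condition.
#' @param include_complemented Also simulate a `complemented` condition in
#'   which planted multipliers are restored towards 1 (residual dwell
#'   `1 + 0.25 * (multiplier - 1)`).
#' @param rare_a_site Back-translate the A-site codon of planted motifs with
#'   the rarest synonymous codon instead of the most frequent one.
#' @param planted_motifs Optional explicit placement: `data.frame` with
#'   columns `gene` (gene index), `motif` (ZPPX string, e.g. "EPPK"),
#'   `codon_pos` (codon index of the first motif residue) and `multiplier`
#'   (dwell multiplier in `delta_efp`). When NULL, `n_strong` + `n_decoy`
#'   sites are placed automatically. A motif overlapping the start or stop
#'   codon is an error.
#' @param seed Integer seed; the same spec always yields byte-identical
#'   output.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 200L, len_range = c(150L, 450L),
                     expr_meanlog = 0, expr_sdlog = 1,
                     n_strong = 30L, n_decoy = 100L, multiplier = 15,
                     depth = 20, dispersion = 10, replicates = 2L,
                     include_complemented = FALSE, rare_a_site = FALSE,
                     planted_motifs = NULL, seed = 42L) {
  if (multiplier < 1) stop("stall multiplier must be >= 1")
  if (is.null(planted_motifs) && n_strong + n_decoy > n_genes) {
    stop("more planted sites than genes (one planted site per gene)")
  }
  if (!is.null(planted_motifs)) {
    stopifnot(all(c("gene", "motif", "codon_pos", "multiplier") %in%
                    names(planted_motifs)))
    if (any(planted_motifs$multiplier < 1)) {
      stop("stall multiplier must be >= 1")
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), len_range = as.integer(len_range),
         expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
         n_strong = as.integer(n_strong), n_decoy = as.integer(n_decoy),
         multiplier = multiplier, depth = depth, dispersion = dispersion,
         replicates = as.integer(replicates),
         include_complemented = isTRUE(include_complemented),
         rare_a_site = isTRUE(rare_a_site),
         planted_motifs = planted_motifs, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# ZPPX strings planted at stall sites / decoy sites; contexts echo the kinds
# of combinations seen at strong vs. silent diprolyl motifs (acidic/amide Z
# or X at stalls, hydrophobic at decoys), though in the simulator only the
# dwell multiplier - not the sequence - determines the planted truth.
.strong_motifs <- c("EPPK", "DPPD", "EPPN", "RPPE", "IPPP", "EPPQ", "DPPG", "EPPS")
.decoy_motifs <- c("VPPA", "LPPL", "APPV", "GPPF", "NPPK", "QPPV", "TPPI", "KPPM")

#' Generate a synthetic genome, annotation and truth table
#'
#' Builds random bacterial-style CDSs (ATG start, no internal stops, TAA
#' stop), plants ZPPX motifs at known codon positions by back-translation,
#' lays the genes on both strands of one chromosome with random intergenic
#' spacers, and draws per-gene expression levels. Deterministic under the
#' spec seed.
#'
#' @param spec A [sim_spec()].
#' @return List with `genome` (named character vector), `genes` (gene record
#'   `data.frame` with an extra `expression` column) and `truth`
#'   (`data.frame`: `gene_id, motif, win_start, x_codon_index, multiplier,
#'   planted`).
#' @export
generate_reference <- function(spec) {
  set.seed(spec$seed)
  usage <- load_codon_usage()
  sense <- usage[usage$aa != "*", ]
  top_codon <- vapply(split(sense, sense$aa), function(d) {
    d$codon[which.max(d$per_thousand)]
  }, "")
  rare_codon <- vapply(split(sense, sense$aa), function(d) {
    d$codon[which.min(d$per_thousand)]
  }, "")

  # sample() semantics change for length-1 x; index explicitly
  resample <- function(x, size) x[sample.int(length(x), size, replace = TRUE)]
  n <- spec$n_genes
  lens <- resample(spec$len_range[1]:spec$len_range[2], n)
  proteins <- vapply(lens, function(L) {
    paste0("M", paste(sample(AA20, L - 1L, replace = TRUE), collapse = ""))
  }, "")

  if (is.null(spec$planted_motifs)) {
    n_sites <- spec$n_strong + spec$n_decoy
    site_gene <- sample.int(n, n_sites)
    planted <- rep(c("strong", "decoy"), c(spec$n_strong, spec$n_decoy))
    motif <- c(sample(.strong_motifs, spec$n_strong, replace = TRUE),
               sample(.decoy_motifs, spec$n_decoy, replace = TRUE))
    z_pos <- vapply(site_gene, function(g) {
      resample(10:(lens[g] - 10L), 1L)
    }, 0L)
    site_mult <- ifelse(planted == "strong", spec$multiplier, 1)
  } else {
    pm <- spec$planted_motifs
    n_sites <- nrow(pm)
    site_gene <- as.integer(pm$gene)
    if (any(site_gene < 1L | site_gene > n)) stop("planted gene index out of range")
    motif <- toupper(pm$motif)
    z_pos <- as.integer(pm$codon_pos)
    site_mult <- pm$multiplier
    planted <- ifelse(site_mult > 1, "strong", "decoy")
  }
  mlen <- nchar(motif)
  if (any(mlen < 4L)) stop("planted motifs must be ZPPX-style (>= 4 residues)")
  if (any(z_pos < 2L | z_pos + mlen - 1L >= lens[site_gene])) {
    stop("planted motif collides with the start or stop codon")
  }
  for (k in seq_len(n_sites)) {
    g <- site_gene[k]
    p <- proteins[g]
    substr(p, z_pos[k], z_pos[k] + mlen[k] - 1L) <- motif[k]
    proteins[g] <- p
  }

  back_translate <- function(prot, rare_at = NA_integer_) {
    aa <- strsplit(prot, "")[[1]]
    codons <- top_codon[aa]
    if (!is.na(rare_at)) codons[rare_at] <- rare_codon[aa[rare_at]]
    paste0(paste(codons, collapse = ""), "TAA")
  }
  x_at <- rep(NA_integer_, n)
  if (spec$rare_a_site) x_at[site_gene] <- z_pos + mlen - 1L
  cds <- vapply(seq_len(n), function(g) back_translate(proteins[g], x_at[g]), "")

  strand <- sample(c("+", "-"), n, replace = TRUE)
  spacers <- vapply(sample(50:150, n + 1L, replace = TRUE), function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  pieces <- character(2L * n + 1L)
  pieces[1L] <- spacers[1L]
  start <- integer(n); end <- integer(n)
  at <- nchar(spacers[1L])
  for (g in seq_len(n)) {
    s <- if (strand[g] == "-") reverse_complement(cds[g]) else cds[g]
    pieces[2L * g] <- s
    pieces[2L * g + 1L] <- spacers[g + 1L]
    start[g] <- at + 1L
    end[g] <- at + nchar(s)
    at <- end[g] + nchar(spacers[g + 1L])
  }
  genome <- c(chrSim = paste(pieces, collapse = ""))

  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n)),
    seqid = "chrSim", start = start, end = end, strand = strand,
    cds_nt = cds, protein = proteins,
    expression = stats::rlnorm(n, spec$expr_meanlog, spec$expr_sdlog),
    stringsAsFactors = FALSE
  )
  # the planted stall window is the last 3 codons of the motif (P-1, P, X)
  truth <- data.frame(
    gene_id = genes$gene_id[site_gene],
    motif = motif,
    win_start = z_pos + mlen - 3L,
    x_codon_index = z_pos + mlen - 1L,
    multiplier = site_mult,
    planted = planted,
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$gene_id, truth$x_codon_index), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome, genes = genes, truth = truth)
}

sim_conditions <- function(spec) {
  conds <- c("WT", "delta_efp")
  if (spec$include_complemented) conds <- c(conds, "complemented")
  conds
}

site_dwell_factor <- function(spec, condition, multiplier) {
  switch(condition,
         WT = rep(1, length(multiplier)),
         delta_efp = multiplier,
         complemented = 1 + 0.25 * (multiplier - 1),
         stop("unknown condition: ", condition))
}

#' Simulate footprint tracks for every condition and replicate
#'
#' Per-codon footprint counts are drawn as
#' `NegBin(mean = depth * expression_g * dwell(g, codon), size = dispersion)`,
#' with dwell equal to the planted multiplier over the 3-codon stall window
#' (P-1, P, X) in the stall condition and 1 elsewhere; each codon's count is
#' then spread at random over its 3 nucleotides on the coding strand.
#' Deterministic under (spec seed, condition, replicate).
#'
#' @param spec A [sim_spec()].
#' @param reference Output of [generate_reference()] for the same spec.
#' @return Named list of `sample_track` objects, one per
#'   `<condition>_rep<k>`.
#' @export
simulate_tracks <- function(spec, reference) {
  genes <- reference$genes
  truth <- reference$truth
  seqlengths <- vapply(reference$genome, nchar, 0L)
  conds <- sim_conditions(spec)
  tracks <- list()
  for (ci in seq_along(conds)) {
    for (r in seq_len(spec$replicates)) {
      set.seed(spec$seed + 1009L * ci + r)
      id <- sprintf("%s_rep%d", conds[ci], r)
      track <- new_sample_track(seqlengths, sample_id = id,
                                strain = conds[ci], replicate = r)
      for (g in seq_len(nrow(genes))) {
        gene <- genes[g, ]
        ncod <- (gene$end - gene$start + 1L) %/% 3L
        dwell <- rep(1, ncod)
        tg <- truth[truth$gene_id == gene$gene_id, , drop = FALSE]
        if (nrow(tg) > 0L) {
          fac <- site_dwell_factor(spec, conds[ci], tg$multiplier)
          for (s in seq_len(nrow(tg))) {
            win <- tg$win_start[s]:tg$x_codon_index[s]
            dwell[win] <- pmax(dwell[win], fac[s])
          }
        }
        mu <- spec$depth * gene$expression * dwell
        counts <- stats::rnbinom(ncod, size = spec$dispersion, mu = mu)
        n1 <- stats::rbinom(ncod, counts, 1 / 3)
        n2 <- stats::rbinom(ncod, counts - n1, 1 / 2)
        nt <- as.vector(rbind(n1, n2, counts - n1 - n2))
        if (gene$strand == "-") nt <- rev(nt)
        v <- track$counts[[gene$seqid]][[gene$strand]]
        v[gene$start:gene$end] <- v[gene$start:gene$end] + nt
        track$counts[[gene$seqid]][[gene$strand]] <- v
      }
      tracks[[id]] <- track
    }
  }
  tracks
}

#' Write a complete synthetic fixture to disk
#'
#' Emits genome FASTA, GFF3 annotation, per-sample bedGraph pairs and
#' stranded track TSVs, and the planted-site truth table, then returns all
#' in-memory objects for direct use.
#'
#' @param spec A [sim_spec()].
#' @param dir Output directory (created if needed); NULL to skip writing.
#' @return List with `spec, genome, genes, truth, tracks, paths`.
#' @export
end_to_end_fixture <- function(spec = sim_spec(), dir = NULL) {
  reference <- generate_reference(spec)
  tracks <- simulate_tracks(spec, reference)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      fasta = file.path(dir, "genome.fa"),
      gff = file.path(dir, "annotation.gff3"),
      truth = file.path(dir, "truth.tsv")
    )
    write_reference(reference$genome, reference$genes, paths$fasta, paths$gff)
    utils::write.table(reference$truth, paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (id in names(tracks)) {
      paths[[paste0("track_", id)]] <-
        write_track_bedgraph(tracks[[id]], file.path(dir, id))
      write_track(tracks[[id]], file.path(dir, paste0(id, ".track.tsv")))
    }
  }
  list(spec = spec, genome = reference$genome, genes = reference$genes,
       truth = reference$truth, tracks = tracks, paths = paths)
}

#' Closed-form expected pausing index of a planted stall
#'
#' With dwell multiplier `m` over a window of `w` codons in a gene of `L`
#' codons, the expected gene mean is inflated by the stall itself, so the
#' expected index is `m / (1 + (w / L) * (m - 1))`, not `m`.
#'
#' @param m Dwell multiplier.
#' @param L Gene length in codons (including the stop codon bin).
#' @param w Stall window width in codons.
#' @return Expected pausing index.
#' @export
expected_pausing_index <- function(m, L, w = 3) {
  m / (1 + (w / L) * (m - 1))
}
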