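#' Validate a pipeline configuration
#'
#' A configuration is a plain list; unknown keys are rejected and thresholds
#' must be positive. Defaults: coverage 3 reads/codon, strong 10, elevated 2,
#' non-pausing 1, fold 3, pseudocount 0.1, de novo threshold 10.
#'
#' @param config Named list of overrides.
#' @return Completed configuration list.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    coverage_threshold = 3, strong_threshold = 10, elevated_threshold = 2,
    nonpausing_threshold = 1, fold_threshold = 3, pseudocount = 0.1,
    denovo_threshold = 10, scan_asd = TRUE, asd = "CACCUCCU",
    asd_offsets = -20:-5
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  for (k in grep("threshold|pseudocount", names(cfg), value = TRUE)) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      stop("config key '", k, "' must be a positive number")
    }
  }
  cfg
}

#' Run the pausing analysis pipeline
#'
#' Orchestrates the full chain on in-memory objects: per-codon occupancy for
#' every sample, gene coverage gate, PPX motif scan, per-replicate pausing
#' indices, strain comparison and classification, de novo (motif-agnostic)
#' pause scan, context aggregation, A-site codon rarity, upstream aSD
#' affinity, replicate correlation, and (optionally) concordance with an
#' external protein-ratio table. A gene enters the analysis when its mean
#' density reaches the coverage threshold in every sample.
#'
#' @param genome Named character vector from [load_genome()] or the
#'   simulator.
#' @param genes Gene record `data.frame` ([load_annotation()]).
#' @param tracks Named list of `sample_track` objects covering at least the
#'   `WT` and `delta_efp` strains.
#' @param config List of overrides, see [pipeline_config()].
#' @param protein_ratio Optional named vector of delta-efp/WT protein
#'   abundance ratios for the concordance analysis.
#' @param out_dir Optional directory; when given, report tables (TSV), the
#'   histogram CSV and a JSON summary are written there.
#' @return List of class `pause_report` with elements `pause_table, denovo,
#'   zppx, class_summary, histograms, asd, rarity, concordance,
#'   replicate_correlation, covered_genes, summary, config`.
#' @export
run_pipeline <- function(genome, genes, tracks, config = list(),
                         protein_ratio = NULL, out_dir = NULL) {
  cfg <- pipeline_config(config)
  strains <- vapply(tracks, function(t) t$strain, "")
  if (!all(c("WT", "delta_efp") %in% strains)) {
    stop("tracks must include both WT and delta_efp strains")
  }

  # per-sample, per-gene occupancy and the coverage gate
  occs <- lapply(tracks, function(tr) {
    o <- lapply(seq_len(nrow(genes)), function(i) codon_occupancy(tr, genes[i, ]))
    names(o) <- genes$gene_id
    o
  })
  covered <- genes$gene_id[vapply(genes$gene_id, function(g) {
    all(vapply(occs, function(o) filter_covered(o[[g]], cfg$coverage_threshold),
               TRUE))
  }, TRUE)]
  if (length(covered) == 0L) {
    warning("no gene passes the coverage filter; empty report")
  }
  gsub_covered <- genes[genes$gene_id %in% covered, , drop = FALSE]

  sites <- find_ppx_sites_all(gsub_covered)

  # per-site, per-sample pausing indices -> strain comparison
  calls <- vector("list", nrow(sites))
  for (k in seq_len(nrow(sites))) {
    win <- sites$win_start[k]:sites$x_codon_index[k]
    idx <- do.call(rbind, lapply(tracks, function(tr) {
      data.frame(strain = tr$strain, replicate = tr$replicate,
                 index = pausing_index(occs[[tr$sample_id]][[sites$gene_id[k]]],
                                       win),
                 stringsAsFactors = FALSE)
    }))
    calls[[k]] <- compare_strains(
      idx, pseudocount = cfg$pseudocount, fold_threshold = cfg$fold_threshold,
      strong = cfg$strong_threshold, elevated = cfg$elevated_threshold,
      nonpausing = cfg$nonpausing_threshold
    )
  }
  pause_table <- build_pause_table(sites, calls, protein_ratio)

  # de novo scan on replicate-averaged normalized occupancy, per strain
  denovo <- list()
  for (s in unique(strains)) {
    ids <- names(tracks)[strains == s]
    rows <- lapply(covered, function(g) {
      mats <- vapply(ids, function(id) normalized_occupancy(occs[[id]][[g]]),
                     numeric(length(occs[[ids[1]]][[g]]$reads_per_codon)))
      avg <- rowMeans(mats)
      occ <- structure(list(gene_id = g, sample_id = s,
                            reads_per_codon = avg, gene_mean = mean(avg)),
                       class = "codon_occupancy")
      scan_denovo_pauses(occ, threshold = cfg$denovo_threshold)
    })
    dn <- do.call(rbind, rows)
    if (!is.null(dn)) {
      dn$strain <- rep(s, nrow(dn))
      dn$overlaps_ppx <- vapply(seq_len(nrow(dn)), function(i) {
        ss <- sites[sites$gene_id == dn$gene_id[i], , drop = FALSE]
        any(ss$win_start <= dn$end[i] & ss$x_codon_index >= dn$start[i])
      }, TRUE)
    }
    denovo[[s]] <- dn
  }
  denovo <- do.call(rbind, denovo[!vapply(denovo, is.null, TRUE)])
  if (!is.null(denovo)) rownames(denovo) <- NULL

  zppx <- zppx_matrix(pause_table)
  cls <- class_summary(pause_table)
  histograms <- list(
    WT = pausing_histogram(pause_table$index_wt),
    delta_efp = pausing_histogram(pause_table$index_delta_efp)
  )

  # A-site codon rarity and upstream aSD affinity for every site
  rarity <- NULL
  asd <- NULL
  if (nrow(pause_table) > 0L) {
    cds <- genes$cds_nt[match(pause_table$gene_id, genes$gene_id)]
    a_codon <- substr(cds, 3L * pause_table$x_codon_index - 2L,
                      3L * pause_table$x_codon_index)
    rarity <- cbind(pause_table[, c("gene_id", "motif", "x_codon_index")],
                    codon_rarity(a_codon))
    if (isTRUE(cfg$scan_asd)) {
      params <- load_stack_params()
      asd <- do.call(rbind, lapply(seq_len(nrow(pause_table)), function(k) {
        sc <- scan_upstream_affinity(cds[k], pause_table$x_codon_index[k],
                                     offsets = cfg$asd_offsets,
                                     asd = cfg$asd, params = params)
        data.frame(gene_id = pause_table$gene_id[k],
                   motif = pause_table$motif[k],
                   x_codon_index = pause_table$x_codon_index[k],
                   best_band_delta_g = attr(sc, "best_band"),
                   weak_binder = attr(sc, "weak_binder"),
                   sd_like = attr(sc, "sd_like"),
                   truncated = attr(sc, "truncated"),
                   stringsAsFactors = FALSE)
      }))
    }
  }

  # replicate correlation of log10 footprints/gene within each strain
  repcor <- list()
  for (s in unique(strains)) {
    ids <- names(tracks)[strains == s]
    if (length(ids) >= 2L) {
      tot <- lapply(ids, function(id) footprints_per_gene(tracks[[id]], genes))
      repcor[[s]] <- replicate_correlation(tot[[1]], tot[[2]])
    }
  }

  conc <- if (!is.null(protein_ratio)) {
    ids_wt <- names(tracks)[strains == "WT"]
    ids_de <- names(tracks)[strains == "delta_efp"]
    wt_tot <- Reduce(`+`, lapply(ids_wt, function(id)
      footprints_per_gene(tracks[[id]], genes)))
    de_tot <- Reduce(`+`, lapply(ids_de, function(id)
      footprints_per_gene(tracks[[id]], genes)))
    ribo <- (de_tot + 1) / (wt_tot + 1)
    concordance(ribo, protein_ratio)
  } else NULL

  summary <- list(
    n_genes = nrow(genes), n_covered = length(covered),
    n_ppx_sites = nrow(pause_table),
    classification_counts = lapply(
      stats::setNames(nm = c("index_wt", "index_delta_efp")),
      function(col) table(classify_pause(
        pause_table[[col]], strong = cfg$strong_threshold,
        elevated = cfg$elevated_threshold,
        nonpausing = cfg$nonpausing_threshold))
    ),
    n_efp_dependent = sum(pause_table$efp_dependent),
    n_denovo = if (is.null(denovo)) 0L else nrow(denovo),
    replicate_correlation = repcor
  )

  report <- structure(
    list(pause_table = pause_table, denovo = denovo, zppx = zppx,
         class_summary = cls, histograms = histograms, asd = asd,
         rarity = rarity, concordance = conc,
         replicate_correlation = repcor, covered_genes = covered,
         summary = summary, config = cfg),
    class = "pause_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pause_report <- function(x, ...) {
  cat("<pause_report>\n",
      "  genes: ", x$summary$n_genes, " (", x$summary$n_covered,
      " covered)\n",
      "  PPX sites scored: ", x$summary$n_ppx_sites, "\n",
      "  EF-P dependent strong pauses: ", x$summary$n_efp_dependent, "\n",
      "  de novo pause windows: ", x$summary$n_denovo, "\n", sep = "")
  for (s in names(x$replicate_correlation)) {
    cat("  replicate correlation (", s, "): ",
        round(x$replicate_correlation[[s]], 4), "\n", sep = "")
  }
  invisible(x)
}

#' Write a pause report bundle to disk
#'
#' TSV tables (pause table, de novo windows, ZPPX matrix, class summary,
#' rarity, aSD scan), a histogram CSV and a JSON summary.
#'
#' @param report A `pause_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(obj, file) {
    if (!is.null(obj) && nrow(obj) > 0L) {
      utils::write.table(obj, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(report$pause_table, "pause_table.tsv")
  wt(report$denovo, "denovo_pauses.tsv")
  wt(report$zppx, "zppx_matrix.tsv")
  wt(report$class_summary, "class_summary.tsv")
  wt(report$rarity, "codon_rarity.tsv")
  wt(report$asd, "asd_scan.tsv")
  if (!is.null(report$concordance)) wt(report$concordance, "concordance.tsv")
  hist_tab <- do.call(rbind, lapply(names(report$histograms), function(s) {
    h <- report$histograms[[s]]
    h$strain <- s
    h
  }))
  utils::write.csv(hist_tab, file.path(out_dir, "pausing_histogram.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Simulate a dataset from a spec (convenience wrapper)
#'
#' Delegates to [end_to_end_fixture()]; exists so that simulation and
#' analysis share one entry-point style.
#'
#' @param spec A [sim_spec()].
#' @param dir Optional output directory.
#' @return See [end_to_end_fixture()].
#' @export
simulate_dataset <- function(spec = sim_spec(), dir = NULL) {
  end_to_end_fixture(spec, dir)
}
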