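---
title: "Quantifying EF-P dependent translational pausing with ribopause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EF-P dependent translational pausing with ribopause}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopause)
```

## The biological problem and the model

Elongation factor P (EF-P) relieves ribosome stalling at polyproline
stretches. When *efp* is deleted, ribosomes dwell longer at susceptible
diprolyl (PPX) motifs, and ribosome profiling shows a local excess of
footprint density at the stall window. `ribopause` models this with a
single, deliberately simple statistic: the **pausing index**, the ratio of
mean footprint density over a codon window to the mean density of the whole
ORF. The index is self-normalizing — gene expression cancels between
numerator and denominator — so it can be compared across genes and strains
without library-size normalization, at the cost of two known biases
discussed under *Limitations*.

The analysis chain is: footprint assignment → per-codon occupancy →
coverage gate → PPX enumeration → per-replicate indices → strain
comparison and classification → context statistics. Each stage is an
exported function; `run_pipeline()` only orchestrates them.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| coverage threshold | 3 | mean reads/codon | genes below this give unstable indices; the gate is inclusive (3.0 passes) and applies to the full-ORF mean, since per-codon zeros are ubiquitous in bacterial ribo-seq |
| strong threshold | 10 | index | the conventional strong-pause criterion; inclusive (≥ 10) |
| elevated threshold | 2 | index | separates mild slow-down from background |
| non-pausing threshold | 1 | index | at or below the gene average |
| fold threshold | 3 | Δefp/WT ratio | EF-P dependence requires both a strong Δefp index and this fold change, so constitutively paused sites (strong in every strain) are not called EF-P dependent |
| pseudocount | 0.1 | index | added to both ratio terms only when the WT index is below it; the raw zero is preserved in output and the call flagged |
| window statistic | mean over 3 codons | — | the stall signal spreads over the P₋₁/P/X codons; the mean is less noisy than the max (a `window_mode`-style max is easy to compute from the occupancy vector if wanted) |
| footprint rule | center nucleotide | — | robust to footprint-length variation; a fixed 3′ offset rule is available (`assign_footprints(rule = "offset3p")`); both rules coincide on uniform coverage, which is tested |

Replicates are handled by computing the index per replicate and averaging;
pairs disagreeing by more than 5-fold are flagged discordant rather than
dropped. A gene enters the analysis only when it passes the coverage gate
in **every** sample, so indices are defined in all strains being compared.

## Coordinate conventions

All internal coordinates are 1-based inclusive, the R/Bioconductor
convention: GFF3 needs no conversion, `substr()` and vector indexing map
directly, and GRanges round-trips are identity. Minus-strand CDS are
reverse-complemented on extraction, and codon 1 of a minus-strand gene is
the 3-nt bin at the genomic 3′ end. The occupancy vector covers every
codon including the stop (length = protein length + 1); the A-site residue
of a motif is indexed by its codon position in the protein.

## Motif enumeration and context

A PPX site exists at every protein position *i* with `P` at *i* and
*i*+1 and any residue X at *i*+2. A run of L prolines followed by X
therefore emits L − 1 overlapping sites — a PPPX gene is scored at both
the PPP and the PPX window, matching how paused density is distributed
over a triproline. Two boundary rules are deliberate: a proline run that
ends the protein emits nothing for its trailing pair (there is no A-site
amino acid), and the stop codon is never X (the A site would hold release
factor, outside this model). Context is read at fixed offsets from the
P-site proline: Z₋₂ and Z₋₃ two and three positions upstream, plus a
20-residue upstream string left-padded with `-`. Amino-acid classes group
the A-site and Z₋₂ residues (acidic, basic, amide, hydroxy, proline,
glycine, hydrophobic/aromatic); cysteine is grouped with the
hydrophobic/aromatic class, an assumption rather than an established
convention.

## The anti-Shine-Dalgarno duplex model

SD-like elements upstream of a stall can slow elongation by pairing with
the 16S rRNA anti-SD tail (`5'-CACCUCCU-3'`). `duplex_energy()` scores a
6–12-nt mRNA window by the minimum, over all antiparallel registers and
contiguous runs of ≥ 2 Watson-Crick or GU pairs, of summed
nearest-neighbor stack free energies (Turner 2004 RNA/RNA parameters at
37 °C, packaged as `inst/extdata/rna_stack_params.tsv`). This is a
hybridization screen, not a folding calculation: no intramolecular
structure, no bulges or internal loops, and by default no duplex
initiation or terminal-AU terms. Consequently the absolute energies are
more negative than a full duplex calculation would give (the perfect
8-mer complement scores −17.5 kcal/mol), and the weak/SD-like cutoffs
(−2 and −4 kcal/mol) are calibrated to this model, not transferable to
other tools. `scan_upstream_affinity()` slides the window so its 3′ end
sits 5–20 nt upstream of the third nucleotide of the X codon and
summarizes the −9…−7 band, where an SD-like element positions a paused
ribosome with X in the A site; the full profile is returned so any band
can be read. Windows running past the CDS start are dropped and flagged
rather than padded.

One non-obvious property of the parameter set: because some GU stacks are
stronger than the corresponding AU stacks, the perfect complement is the
global minimum among equal-length windows but not uniquely so — a
GU-substituted variant can tie it. The acceptance suite verifies the
global-minimum property by closed enumeration over anti-SD segments and
allowed partners rather than by brute force over all 4⁸ windows.

## Codon rarity

The A-site codon of each site is annotated with its genome-wide usage
frequency (per thousand) from a packaged E. coli K-12 table, and flagged
rare when it falls below the lower quartile of sense codons. This is a
proxy for rare-tRNA decoding — a documented stand-in, since tRNA abundance
itself is not modelled; the table is user-replaceable via
`load_codon_usage(path)`.

## The synthetic-data generator

The simulator exists so that every pipeline stage is testable end to end
without downloads, and its defaults define the package's standard
validation conditions: 200 genes of 150–450 codons, log-normal per-gene
expression (meanlog 0, sdlog 1), 30 planted stall sites with dwell
multiplier 15 in the Δ*efp* condition, 100 decoy PPX sites with
multiplier 1, depth 20 reads/codon at unit expression, and two replicates
per condition. Per-codon counts are negative binomial with size 10 —
moderate overdispersion typical of ribo-seq count data (Poisson is the
`dispersion → Inf` limit) — and each codon's count is spread randomly over
its three nucleotides. Genes are laid on both strands with random
intergenic spacers; proteins are back-translated with the most frequent
codon per residue (a flag forces rare A-site codons to exercise the rarity
annotation). Everything derives from one integer seed, and identical specs
produce byte-identical files.

Because the stall window inflates the gene mean that normalizes it, the
expected index of a planted site is not the multiplier *m* but

    E[PI] = m / (1 + (w/L)(m − 1)),    w = 3,

about 13.2 for m = 15 in a 300-codon gene (`expected_pausing_index()`).
The recovery tests compare against this closed form.

What the simulator does **not** emulate — and what passing tests therefore
do not show about real data: ribosome queuing upstream of stalls and the
loss of closely stacked ribosomes during footprinting, sequence-dependent
ligation/digestion biases, footprint-length variation, rRNA contamination,
UTRs and operon structure, and any coupling between codon identity and
dwell time outside the planted windows. Recovery results on synthetic data
bound the estimator's statistical behavior, not these systematic effects.

## Numerical choices and degenerate inputs

* Classification boundaries: strong is inclusive (≥ 10), non-pausing is
  inclusive (≤ 1), elevated is exclusive (> 2).
* A gene with zero mean occupancy has an undefined index; the site is
  dropped with a warning rather than scored 0.
* Histogram bins are left-closed, right-open with configurable edges
  (defaults 0, 1, 2, 5, 10, 20, 50, ∞ mark the classification regimes).
* Ratio orientation is normalized to Δ*efp*/WT everywhere; protein tables
  reported as WT/Δ*efp* are flipped with `invert_protein = TRUE`.
* Codons containing ambiguous bases translate to `X` and can never match a
  proline, so draft references degrade gracefully.
* Duplicate gene identifiers keep the longest CDS; overlapping genes are
  processed independently, and a footprint nucleotide inside two genes
  counts for both.
* De novo windows are maximal runs (adjacent super-threshold codons merge);
  ties for the peak codon resolve to the first.

## Problem sizes used in validation

The test suite validates scorers against independent brute-force
implementations on ~1300 randomized small instances, and runs the standard
200-gene fixture end to end (about 10 s): planted-site sensitivity,
decoy and WT false-call rates, closed-form index recovery, and replicate
correlation of log10 footprints/gene (≥ 0.95 at depth 20). The deep
coverage convergence test uses near-Poisson dispersion so that estimator
bias is not masked by overdispersion noise.

## Limitations

The pausing index inherits two caveats: a gene with several strong pauses
or a pause near the start has an inflated gene mean, deflating all its
indices; and very strong stalls may be under-counted in real libraries if
stacked ribosomes are lost during footprinting. Fixed thresholds, not
significance tests, define pause classes — this follows the field's
convention for this analysis, and means marginal sites near a boundary
should be read with the replicate-discordance flags. The aSD model scores
hybridization only; mRNA secondary structure effects beyond aSD pairing
are explicitly unmodelled.
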