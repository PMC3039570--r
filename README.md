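# centralproteome

Proteome-wide experiments across a panel of cell lines raise a simple
question with many moving parts: which proteins are expressed
*everywhere*, how abundant are they, and what do they do together?
`centralproteome` implements the full computational pipeline behind that
question for proteomics and systems-biology researchers:

* **Two-engine protein inference** — merging peptide-spectrum matches
  from two search engines (spectra assigned different peptides are
  discarded), score thresholds with single-peptide-hit and coverage
  rules, parsimony grouping by shared peptides, a splice-variant
  filter, and threshold **calibration to a protein-group FDR bound**
  estimated from reversed-sequence decoys
  (FDR = decoy groups / target groups ≤ 0.25%).
* **emPAI abundance** — emPAI = 10^(observed/observable) − 1 with the
  observable tryptic peptides restricted to the 698–2370 Da instrument
  range; median across cell lines; the **central proteome** (proteins
  detected in all lines) and the abundance classes Top.CL,
  Low.C.Prot, Top.C.Prot.
* **Interactome topology** — degree, betweenness, eigenvector
  centrality, clustering coefficient and k-core score; shortest-path
  distance distributions; induced subnetworks (the *central
  interactome*); OLS power-law exponents of degree distributions.
* **Pathway positions** — the relative position
  d_s/(d_s + d_e) of each node between pathway sources (0) and ends
  (1), two-level averaging per protein, and binned positional profiles
  of protein sets.
* **GO fluxes** — counting biological-process term pairs over PPI
  edges (after pruning each protein's annotation to its most specific
  terms), standardized as
  NScore = (flux − mean_random)/sd_random against ensembles of
  degree- and frequency-preserving randomized annotated networks, with
  an empirical 1% significance cutoff and three network regimes.
* **Comparative statistics** — the bootstrapped χ² distribution
  comparison (1,000 resamples of 500 points, 10 equal-probability
  bins, median statistic), length-matched bootstrap shift estimates,
  ortholog-species counting, set-association tests and term-coverage
  ratios.
* **Synthetic data with ground truth** — generators for every input
  (proteome, two-engine PSM tables with planted false matches and
  decoys, scale-free annotated interactomes with a planted flux pair,
  source-to-sink pathway DAGs), so every stage is testable end to end
  without downloads.

Everything is tidyverse-native: functions take data frames first and
return tibbles, results have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures.

## Worked example

```r
library(centralproteome)
library(dplyr)

cfg  <- sim_config(seed = 3, n_proteins = 1000)
prot <- sim_proteome(cfg)
tabs <- sim_psm_tables(prot, cfg)
pa <- filter(tabs$psm, engine == "A")
pb <- filter(tabs$psm, engine == "B")

cal <- calibrate_group_fdr(pa, pb, prot, default_thresholds_grid(),
                           gene_map = tabs$ground_truth$gene_map)
cal
#> <fdr_calibration>
#>   candidate 1 of 5 chosen; achieved group FDR 0.0006726 (bound 0.0025, met)
```

The calibration walked five threshold sets from least to most stringent
and kept the least stringent one whose decoy-estimated protein-group
FDR stays under 0.25% — here 0.067%, i.e. roughly 3 decoy groups
against ~4,460 target groups.

```r
groups <- infer_proteins(pa, pb, prot, thresholds = cal$thresholds,
                         gene_map = tabs$ground_truth$gene_map)

summ <- groups |>
  filter(!is_decoy) |>
  transmute(protein_id = group_id, cell_line, n_observed = n_peptides) |>
  abundance_matrix(prot) |>
  abundance_summary()
central <- central_proteome(summ, n_cell_lines = 7)
length(central)
#> [1] 299
```

299 protein groups were identified in all seven synthetic cell lines —
the recovered central proteome (the generator planted 300 of 1,000
proteins as commonly expressed; one fell below the identification
thresholds in at least one line).

```r
net <- sim_annotated_interactome(sim_config(seed = 7, flux_multiplier = 3))
res <- withr::with_seed(11, go_flux(net$graph, n_networks = 40))
glance(res)
#> # A tibble: 1 × 7
#>   n_pairs n_significant cutoff alpha n_fit n_heldout n_excluded
#>     <int>         <int>  <dbl> <dbl> <dbl>     <dbl>      <int>
#> 1     120             1   2.58  0.01    36         4          0
```

One term pair clears the 1% NScore cutoff learned from the held-out
null replicates — exactly the pair whose flux the generator enriched
threefold.

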