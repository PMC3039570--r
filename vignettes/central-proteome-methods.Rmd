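---
title: "Methods: defining and characterizing a central proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defining and characterizing a central proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

The package implements, as a tested and reusable pipeline, the
computational analysis used to define a *central proteome* — the set of
proteins detected in every one of a panel of cell lines — and to
characterize it through abundance classes, interactome topology, pathway
positions and coordination of biological processes.  This vignette
explains the models and procedures, the parameters that matter, what the
synthetic-data generators emulate, and the numerical choices made where
the design was genuinely open.

## Two-engine protein inference with group-FDR control

Peptide-spectrum matches (PSMs) from two database search engines are
merged by spectrum: a spectrum assigned *different* peptide sequences by
the two engines is discarded outright, agreeing assignments collapse
into one record carrying both engines' scores, and spectra seen by a
single engine are kept.  Identification rules are then applied per
engine:

* engine A (ion-score scale): a protein is accepted with **two distinct
  peptides at score ≥ 18**, after which all its peptides at score ≥ 10
  are exported; a **single peptide hit** (SPH) needs score ≥ 50;
* engine B (z-score scale): two peptides with **z ≥ 4.5 and P ≤ 0.001**,
  additional peptides at z ≥ 3.5, SPHs at z ≥ 6;
* every SPH additionally needs **sequence coverage ≥ 2.5%** of the
  protein sequence.

The union of the two engines' acceptances feeds protein grouping:
proteins with identical accepted-peptide sets are indistinguishable and
form one group, and a protein whose peptide set is a strict subset of
another's is absorbed into that protein's group (Occam-style parsimony;
`absorb_subsets = FALSE` switches to identical-set merging only — the
convention is not fully determined by the verbal description "grouped
according to shared peptides", so both are available and the parsimony
form is the default).  Groups left without a *specific* peptide — one
mapping to no other group — are discarded, as are groups whose members
span more than one gene (the splice-variant rule).  When several strict
supersets could absorb a protein the lexicographically smallest group is
chosen, keeping grouping deterministic and order-independent.

Group coverage uses the longest member sequence as the representative —
a deterministic and conservative choice.

Thresholds are data, not constants: `calibrate_group_fdr()` walks a grid
of candidate threshold sets ordered from least to most stringent, runs
the entire merge/rules/grouping chain for each, estimates the
protein-group FDR from reversed-sequence decoy matches as
decoys/targets (the single-decoy convention of the reverse-database era;
2D/(T+D) is available as `estimator = "two_decoy"`), and returns the
least stringent candidate meeting the bound, 0.25% by default.  The
defaults of `inference_thresholds()` are the printed operating point the
calibration is expected to reproduce on data resembling the study
conditions.

## emPAI abundance and the central-proteome classes

A protein's abundance in one cell line is the exponentially modified
protein abundance index, emPAI = 10^(observed/observable) − 1, where
*observable* counts the distinct tryptic peptides (cleavage after K/R
except before P, at most one missed cleavage, length ≥ 6 residues) whose
monoisotopic mass falls in the instrument range 698–2370 Da.  The digest
convention for the denominator is configurable because it is a search
setting, not a law; the defaults mirror the identification settings.
One number per protein is the **median over the cell lines in which it
was detected** — absence is "not detected", never zero, since
zero-imputation would collapse exactly the proteins whose classes the
analysis needs.

The central proteome is the strict intersection (detected in all lines);
`required = 6` of 7 gives the robustness variant.  Three comparison
classes are cut at the 25% quantile of median emPAI: `top_cl` among
proteins detected in at most five lines, and `low_cprot`/`top_cprot`
within the central set.  Values tied at a quantile boundary are excluded
from the class, which is why a nominal 25% class can hold slightly fewer
members than its ceiling — the same mechanism that makes the bottom and
top quartiles of one list differ in size.

## Interactome topology

Five standard measures profile node sets: degree, betweenness,
eigenvector centrality, local clustering coefficient, and the k-core
score (the largest k such that the node survives in a k-core).
Betweenness is reported as raw shortest-path counts with even splitting
among equal-length paths; because all comparisons are distributional, a
common normalization constant is irrelevant, and the ratio form is a
flag.  Eigenvector centrality is computed on the largest connected
component and scaled to unit Euclidean norm (nodes outside get 0),
avoiding the degenerate multi-component eigenproblem; the ARPACK start
vector is pinned so results are reproducible to the byte.  All five
measures are verified in the test suite against brute-force oracles on a
thousand random graphs of up to eight nodes.

Power-law exponents of degree distributions are the OLS slope of
log10 frequency against log10 degree with empty bins omitted — the
convention behind exponents read off log-log plots — with a
maximum-likelihood Pareto fit available as an alternative.  The fitting
convention is a reporting choice, not a testable scientific claim.

## Pathway positions

In a pathway graph the relative position of a node is d_s/(d_s + d_e),
with d_s the directed shortest-path distance from the closest source
(in-degree 0) and d_e the distance to the closest end (out-degree 0):
sources sit at 0, ends at 1, and a five-node chain maps to
0, .25, .5, .75, 1.  The two boundary anchors force this form up to
monotone reparameterization; its internal consistency test is the exact
reversal symmetry p → 1 − p when all edges are flipped.  Replacing the
closest source/end by the mean over all shortest paths to all
sources/ends (`method = "average"`) changes positions by less than 0.1
mean absolute difference on synthetic pathway graphs, reproducing the
robustness of the measure at synthetic scale.

Cycles are handled by condensing strongly connected components before
positioning — every member inherits its component's position — which
guarantees sources and ends exist.  Complex nodes assign their position
to every member protein, and a protein's positions are averaged first
within a pathway, then across pathways, with equal weight per pathway.
Protein sets are profiled in five equal bins, with membership lists for
the source (0–0.2), center (0.4–0.6) and end (0.8–1) regions.

## GO fluxes against randomized annotated networks

Communication between biological processes (BPs) across the interactome
is scored by counting term pairs over edges: an interaction between a
protein annotated {A, B} and one annotated {C, D, E} contributes one
count to each of AC, AD, AE, BC, BD, BE, summed over all edges.  Before
counting, each protein's annotation is pruned to its most specific
terms (all transitive ancestors of co-annotated terms are removed), so
the flux map does not simply rediscover the ontology.  Pairs are
unordered; an edge contributes at most one count to any pair, including
same-term pairs — the worked example above uses disjoint sets and does
not settle this corner, so the full cross-product multiplicity is
available as `per_edge = "cross"`.  Pruning is applied within each
protein only; removing ancestors shared *between* two interacting
proteins is a stricter variant that is noted but not implemented.

Observed fluxes are standardized against an ensemble of randomized
annotated networks in which node degrees and term frequencies are
preserved individually but decoupled: topology is rewired by
degree-preserving double edge swaps (10 × |edges| *accepted* swaps per
replicate), and the per-node term *sets* are permuted whole across
nodes — preserving each term's total frequency and within-protein term
correlation, the stricter null.  Membership labels stay on their nodes,
whose degrees are unchanged, so the label-degree structure matches the
original data.  The first 90% of replicates estimate each pair's null
mean and standard deviation; NScore = (flux − mean)/sd; the held-out
10% provide the empirical null distribution of NScores whose 99th
percentile is the significance cutoff (a Gaussian fit to the held-out
scores, which are bell-shaped, is the alternative).  The 90/10 split
generalizes proportionally for ensembles other than 100.  Pairs with
zero null variance are excluded and reported.  Three regimes — edges
within the central set, from the central set to proteins detected in at
most five lines, and outside — are analyzed with three separate
ensembles; whether one shared ensemble would do is unstated upstream,
and separate ensembles are the cleaner null.

Under the null the expected number of significant pairs is simply the
significance level times the pair universe: 50 terms with self-pairs
give 1,275 pairs and an expectation of 12.75 at the 1% level, which the
reduced-ensemble Monte-Carlo confirmation reproduces within binomial
error.

## The bootstrapped chi-squared comparison

Large proteome-scale samples make the plain chi-squared test reject on
trivial differences.  The remedy used throughout: resample 500 points
with replacement from each of the two sets, bin both into 10
equal-probability bins defined on the pooled draw, compute the
two-sample chi-squared statistic, repeat 1,000 times, take the median,
and read the P-value from the chi-squared distribution with bins − 1
degrees of freedom (the reference distribution is stated upstream
without degrees of freedom; bins − 1 is the two-sample convention).

Because the median of many resampled statistics is a *concentrated*
estimator, this procedure's null P-values are not uniform.  Its measured
operating characteristics, which the test suite asserts: rejection at
close to the nominal 5% when each parent sample holds about twice the
subsample size (~4–5% at n = 1000, m = 500 over hundreds of null runs);
increasingly conservative behavior for larger parents; and essentially
unbounded power under real separation (disjoint supports give
P < 1e-10).  The same machinery drives `set_association()` on 2×2
membership tables (df = 1), which is conservative under independence.
Wilcoxon rank-sum comparisons, where wanted, are delegated to
`stats::wilcox.test()`.

The length-matched bootstrap controls for sequence-length bias when
estimating feature shifts (exon counts, ortholog-species counts):
the reference collection is stratified by the target set's length
deciles and each draw matches the target's length distribution stratum
by stratum; the shift is the target mean minus the mean of draw means,
with a percentile interval.  Decile stratification is the
operationalization of "appropriate length distributions"; empty
reference strata are dropped with a warning.

## What the synthetic data emulate — and what they do not

The generators produce every input with known ground truth, at the
study conditions used throughout the tests:

* **Proteome** (1,000 proteins by default): random sequences built from
  tryptic blocks, so digestion is guaranteed productive; ~4% of proteins
  come as splice-variant pairs sharing a gene and all base peptides,
  exercising grouping and the splice rule.
* **PSM tables** (7 cell lines, 2 engines): a planted common set
  (30% of proteins) observed in every line, others in a strict subset of
  lines; engine A scores are ion-score-like Gaussians
  (targets N(45, 12), incorrect matches N(8, 4)), engine B z-score-like
  (N(8, 1.5) vs N(1.5, 1)) — two threshold regimes without modeling
  spectra.  5% of spectra are decoy matches against reversed-sequence
  accessions and 5% are planted *false target* matches the FDR machinery
  must exclude; 2% of two-engine spectra conflict.
* **Interactome**: preferential attachment (600 nodes, m = 2 by
  default), giving the heavy-tailed degree distribution expected of
  PPI networks; 1–4 BP terms per node from a Zipf-like frequency
  vector; central labels sampled with degree-proportional bias so the
  central set has elevated connectivity; an optional planted flux pair
  enriched to a chosen multiple of its unplanted count, preferentially
  between singly-annotated nodes so the planting perturbs no other
  pair.
* **Pathways**: random in-trees plus forward edges — connected DAGs
  with guaranteed sources and ends; node-to-protein assignments reuse a
  deliberately small protein pool so proteins recur across pathways.

They do **not** model fragment spectra, retention times, mass accuracy,
sequence homology, protein complexes' internal structure, or
database-version drift.  Passing tests therefore demonstrate the
*procedures* — FDR control against planted truth, set recovery,
flux calibration — under clean Gaussian score separation and idealized
annotation structure, not performance on real LC-MS/MS data, where
score distributions overlap more and annotations are biased.

## Numerical choices and problem sizes

All randomness funnels through explicit seeds (`withr::with_seed`
internally; one seed determines every artifact byte-exactly).  The
suite and the acceptance script run at deliberately modest sizes chosen
as the package's own demonstration scale: 250–1,000-protein proteomes,
200–600-node interactomes, ensembles of 15–40 randomized networks, 20
seeds for the FDR study.  The end-to-end `run_pipeline()` demo defaults
to 200 proteins and a 250-node interactome with a 20-network ensemble.
Degenerate inputs fail loudly: empty proteomes, constant samples in the
chi-squared procedure, terms without annotations, graphs too constrained
to rewire (a star rejects every double edge swap), and isolated pathway
nodes are all explicit errors or warnings rather than silent zeros.

## Known limitations

* The realized-FDR guarantee is as good as the decoy model: with decoys
  and false targets drawn from the same score distribution the
  decoys/targets estimator is nearly unbiased, which is the point of the
  construction but also its limit.
* OLS power-law slopes depend on binning at the tail; they are a
  reporting convention and the MLE flag gives systematically different
  (steeper) values.
* The bootstrapped chi-squared P-value is not a calibrated frequentist
  P-value across all sample sizes (see above); treat it as the upstream
  analyses do — a conservative screen at large n.
* The flux null preserves degrees and term-set multisets but not, e.g.,
  community structure; strongly modular real interactomes may need a
  stricter null.
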