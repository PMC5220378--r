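---
title: "Map-based genome bin refinement and RBH comparative genomics"
author: "parcubin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Map-based genome bin refinement and RBH comparative genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`parcubin` addresses two linked tasks in genome-resolved metagenomics.

The first is **bin refinement**: given assembled scaffolds, an existing
draft genome bin, and per-sample read-coverage (abundance) estimates over a
short time series, decide which additional scaffolds belong to the bin and
whether the bin itself is coherent. The signal is the classic combination
used for differential-coverage binning: genome-specific tetranucleotide
composition and covariation of abundance across samples. Both are embedded
in one feature space and clustered on an emergent self-organizing map
(ESOM), whose U-matrix makes bin boundaries visible and whose
best-matching-unit (BMU) distances give a quantitative recruitment rule.

The second is **comparative genomics of the refined genome**: reciprocal
best-hit (RBH) orthology from exact pairwise protein alignment, average
amino-acid identity (AAI) and ortholog-fraction matrices over a genome set,
and the partition of a focal proteome into genes shared with at least one
comparison genome versus genes unique to the focal organism.

Every stage is exercised end-to-end on synthetic communities and synthetic
proteome pairs with known ground truth, generated by the package itself.

# The feature space

Scaffolds are cut into non-overlapping 5 kb windows. A terminal remainder
of at least half a window (2.5 kb) becomes its own fragment; a shorter
remainder is merged into the last window, and scaffolds shorter than
2.5 kb are excluded (with a warning) because their 4-mer frequency
estimates are too noisy. The half-window floor is a design choice: it
avoids discarding informative scaffold tails while bounding the variance
of the frequency estimates. Coordinates are 0-based and half-open
throughout.

Each fragment contributes:

* **Composition block** — frequencies of the 136 canonical
  tetranucleotides (each 4-mer folded with its reverse complement, because
  assembly strand is arbitrary; 16 palindromes plus 120 pairs). 4-mers
  containing `N` are not counted.
* **Abundance block** — the scaffold's mean coverage in each of the `S`
  samples (a six-sample series in the default simulations), transformed as
  `log10(x + 1)`. Coverage is multiplicative across orders of magnitude,
  and the log keeps high-abundance genomes from dominating the distance
  metric; the transform can be disabled
  (`abundance_transform = "none"`).

Both blocks are z-scored per column over the training fragments, which
puts heterogeneous scales (frequencies vs coverages) on a common footing
and makes the subsequent weighting well defined. The abundance block is
then multiplied by `weight = 5`, weighting abundance five-fold relative
to composition — appropriate when few samples carry the abundance signal
against 136 composition coordinates. Scalar multiplication by 5 makes an
abundance coordinate count 25× in squared Euclidean distance; replicating
each abundance column five times would instead give 5×. We implement the
scalar reading and expose the weight as a parameter, since either
convention is defensible. Zero-variance columns get `sd = 1` and become
all-zero (logged, never silent). The fitted column means and standard
deviations are stored so held-out scaffolds can be projected into exactly
the training space (`transform_features()`).

# The map

`esom()` trains a batch SOM: each epoch assigns every fragment to its BMU
(Euclidean distance; ties broken by lowest neuron index), then sets every
neuron to the Gaussian-neighborhood-weighted mean of the assigned
fragments. The neighborhood radius decreases linearly from
`max(rows, cols)/2` to 1 over the (default 10) epochs. Batch training is
deterministic given the data and the initial codebook, which is what makes
byte-identical reruns possible; online SOM updates would depend on
presentation order.

Defaults that matter:

* **Grid size** — about `5 * sqrt(n_fragments)` neurons, aspect ratio from
  the ratio of the first two principal-component standard deviations
  (capped at 3:1). Oversized ("emergent") maps leave room for cluster
  boundaries to appear as U-matrix ridges rather than forcing one neuron
  per cluster.
* **Topology** — toroidal by default, so no fragment is penalized for
  landing at a map edge; planar is available.
* **Initialization** — PCA: the codebook spans a regular grid over ±2 sd
  of the scores along the first two principal components. This is fully
  deterministic. If the feature covariance has rank < 2 the initializer
  falls back to seeded random draws from per-column empirical ranges, with
  a warning.
* **k-means limit** — with radius 0 the batch update is exactly Lloyd's
  step (empty neurons keep their weights). The test suite checks equality
  against an independent Lloyd implementation.

The U-matrix (`umatrix()`) is each neuron's mean distance to its
8-neighborhood (wrapping on the torus); `plot()` renders it with fragments
at their BMUs.

# Recruitment and confirmation

Given a trained map and a target bin:

1. **Threshold** — the bin fragments' BMU distances are sorted and the
   highest 2% (`ceiling(0.02 * n)` values) removed; the threshold is the
   maximum of the remainder. Trimming the tail makes the cutoff robust to
   a few atypical bin fragments (chimeras, edge windows). With fewer than
   50 fragments nothing is dropped — dropping even one value would remove
   more than 2% — so the cutoff is the plain maximum.
2. **Recruit** — a candidate scaffold's distance to the bin is the minimum
   over its fragments of the minimum distance to any *bin-associated
   neuron* (a neuron that is BMU of at least one bin fragment). Minimum
   aggregation is the most generous reading — one convincing fragment
   suffices; `aggregate = "median"` demands that a majority of the
   scaffold look bin-like. Candidates are projected with the training
   normalization, never re-fitted.
3. **Confirm** — a single confirmatory retraining on original plus
   recruited fragments (fresh seed). Neurons are labelled by the majority
   bin membership of the original fragments they attract; a recruit is
   confirmed iff the majority of its fragments land on bin-majority
   neurons. One round, not iteration to a fixed point: repeated
   self-recruitment risks bin drift.

# Orthology and AAI

Protein pairs are aligned with an exact Smith–Waterman local alignment
(affine gaps: a gap of length *k* costs 11 + *k*; BLOSUM62, with `X`
scoring 0 against everything), implemented in C++ and verified in the
tests against an independent naive full-matrix dynamic program and against
`Biostrings::pairwiseAlignment()`. Alignment statistics follow
Karlin–Altschul with the standard gapped BLOSUM62/11/1 parameters
(λ = 0.267, K = 0.041), search space m·n per pair:

* bits = (λ·raw − ln K) / ln 2
* E = K · m · n · e^(−λ·raw)

A hit passes if E ≤ 0.01, bits ≥ 40, and the local alignment spans at
least 0.65 of the protein — of **both** proteins by default
(`coverage_mode` can relax this to `query` or `shorter`). All thresholds
are inclusive at the boundary. An E-value *ceiling* of 0.01 is the
conventional direction for calling orthologs; the package exposes it as
`evalue_max` so other conventions can be configured. Best hits are ranked
by bit score (ties: higher identity, then lexicographic id), and an
ortholog pair is a mutual best hit. Identity is computed over aligned
residue–residue columns (gap columns excluded).

AAI between two genomes is the unweighted mean identity over their RBH
pairs — one alignment per pair, since local alignment is symmetric. Matrix
output rounds AAI and ortholog fractions to integers, the customary
printed precision; full precision is retained internally. The
ortholog-fraction matrix is deliberately asymmetric: entry (i, j) divides
the shared-pair count by genome *i*'s ORF count.

# The synthetic generators

The community generator emulates the data a time-series groundwater
metagenome provides to a binning analysis:

* **Genomes** — order-3 Markov chains with per-genome transition matrices
  drawn from a seeded Dirichlet prior (concentration 12). Order 3 makes
  4-mer signatures genome-specific *by construction* — exactly the signal
  the binner exploits. After the Dirichlet draw, each context row is
  rescaled so the probability of emitting G or C equals the GC target;
  observed GC then recovers the target to binomial noise (sd ≈ 0.0016 at
  100 kb) while within-GC-group preferences stay genome-specific.
* **Scaffolds** — log-normal lengths (mean 15 kb on the natural scale,
  σ = 0.45 on the log scale, minimum 5 kb so every scaffold yields at
  least one window), partitioning each genome exactly.
* **Abundance** — each genome has a 6-sample profile; a scaffold's
  coverage is its genome's profile times one log-normal noise factor
  (CV 0.2) shared across samples. Scaffold-level (not sample-level) noise
  preserves the time-series *shape* within a genome, which is the
  assumption differential-coverage binning rests on.
* **Proteome pairs** — genome A gets random 20-letter proteins
  (log-normal lengths, mean 300); a chosen fraction is copied into B and
  mutated by single-site substitutions, proposed proportional to BLOSUM62
  exchangeabilities (2^(s/2) off the diagonal), until the realized
  identity reaches the target. Iterating and measuring avoids any
  closed-form back-substitution correction. Indels are off by default so
  planted identity is exact; a per-site `indel_rate` is available.

What the generator does **not** emulate: read-level sequencing error,
assembly artifacts and chimeras, strain-level microheterogeneity, shared
mobile elements, compositionally atypical regions (rRNA operons, recent
horizontal transfers), or genomes at near-identical abundance with
near-identical composition. Passing tests therefore demonstrate that the
algorithms are implemented correctly and behave as designed on separable
communities; they do not certify recovery rates on real assemblies, where
these confounders dominate the error budget.

Reference conditions used by the tests and the acceptance script: five
genomes of 1.25 Mb (≈250 windows each), GC targets 0.30–0.62 (0.08
spacing), six samples with strongly distinct abundance profiles, 20% of
each genome's scaffolds held out as recruitment candidates; proteome
experiments use 100 proteins per genome at planted identities 0.9/0.7/0.5.
These sizes are large enough for stable frequency estimates and stable
AAI means while keeping a full run in the order of a minute.

# Completeness

`completeness()` reports the percentage of a universal single-copy marker
set detected at least once, plus the markers seen twice or more as a
contamination signal. Marker *detection* is upstream annotation and is
consumed as a hit table, not implemented. The default 43-id list shipped
in `inst/extdata/cpr_markers43.txt` is an editable stand-in configuration
of broadly conserved single-copy genes; substitute the marker collection
appropriate for your lineage.

# Numerical and degenerate-case choices

* BMU ties break to the lowest neuron index; best-hit ties break by
  identity then id, so all outputs are reproducible.
* `recruitment_threshold()` on a single distance returns it (the drop rule
  never empties the list).
* All-`N` genomes have undefined GC and error out; 4-mer vectors with no
  valid 4-mer are zero vectors.
* Candidate scaffolds shorter than the minimum fragment are skipped with a
  warning, not silently dropped.
* Every simulation entry point takes an explicit integer seed and restores
  the caller's RNG state; identical configurations give byte-identical
  outputs.

# Limitations

* The SOM is single-threaded and dense; communities beyond ~10^5 fragments
  would need mini-batch or parallel training.
* Exact all-vs-all Smith–Waterman is quadratic in proteome size; it is
  meant for genome sets of CPR scale (hundreds of proteins), not for
  thousands of large proteomes. A seed-and-filter heuristic would change
  E-value calibration and is deliberately not the default.
* AAI from RBH pairs is conditioned on the ortholog thresholds; genomes
  sharing only fast-evolving genes can have undefined AAI (no passing
  pairs), reported as `NA` rather than extrapolated.
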