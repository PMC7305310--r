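---
title: "Multi-engine PSM aggregation with strict FDR control"
author: "ProteoCombine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-engine PSM aggregation with strict FDR control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoCombine)
```

## The problem

Deep proteome surveys of prokaryotes aggregate peptide-spectrum matches
(PSMs) from several database search engines and many independent
datasets. Every aggregation step multiplies the opportunity for false
positives, so error rates have to be controlled deliberately at three
levels: per spectrum (posterior error probabilities), per peptide
sequence, and per protein. ProteoCombine implements that chain for
archaeal-scale proteomes — a few thousand proteins on a handful of
circular replicons — together with the downstream interpretation stages:
physicochemical annotation, localization categorization from stacked
predictor outputs, signal-peptide cleavage-site validation from
semi-enzymatic peptides, cross-dataset overlap, arCOG class enrichment,
and sliding-window detection of genomic regions that yield conspicuously
few identifications.

Raw spectra never enter the package. The inputs are per-engine PSM
tables (with per-engine PEPs from upstream statistical post-processing),
a FASTA proteome with per-entry annotations, and summarized outputs of
localization predictors, consumed as data.

## The error-control model

**Combined PEPs from engine overlap.** PSMs are partitioned by the exact
set of engines that produced the match. Within each engine-set group,
PSMs are ranked by joint score (the sum of $-\log_{10}$ engine PEPs) and
the combined PEP at each rank is a windowed decoy-density estimate:
twice the number of decoys in a centered window of 249 PSMs, divided by
the window size. The factor two reflects the target-decoy symmetry
assumption — every decoy match stands in for one false target match.
Groups smaller than the window use the whole-group ratio; estimates are
floored at $10^{-6}$ (so $-\log_{10}$ scores stay finite), capped at 1,
and made monotone along the ranking with a bottom-up minimum-so-far
traversal. The traversal runs bottom-up rather than top-down so that the
truncated windows at the top edge of a group — which overstate the decoy
density for the very best PSMs — cannot propagate downward. PSMs matched
by several engines inhabit groups with few decoys and therefore receive
small combined PEPs; this is the quantitative form of "shared PSMs are
more trustworthy". The exact estimator behind the original combined-PEP
idea is not published in detail; the windowed estimator used here is an
explicit, testable stand-in with the same structure.

**Spectrum sanitization.** When engines disagree about one spectrum, the
best PSM is kept only if it is unambiguous or at least an order of
magnitude better (combined PEP ratio $\le 0.1$) than the best
conflicting peptidoform; otherwise the spectrum is discarded outright.
The same peptide with different modifications counts as a conflict.

**Peptide q-values, grouped by length.** PSMs collapse to peptide
sequences (best PEP, PSM count, dataset union). Peptides are ranked by
best PEP and the empirical q-value is the cumulative decoy count divided
by the cumulative target count, followed by a bottom-up pass replacing
each value with the minimum seen so far — the two-traversal scheme.
Because very short and very long peptides show systematically higher
error rates, q-values are computed per peptide-length group; bins with
fewer than 100 peptides merge with the nearest length bin so no estimate
rests on a handful of observations. Ties rank decoys first
(conservative). Peptide lengths outside 6–50 are excluded before FDR
computation.

**Protein inference.** The inference rules are deliberately simple,
appropriate for a proteome with few shared peptides: proteotypic
peptides assign directly; a shared peptide is assigned to the one
protein among its candidates that carries other evidence in the same
scope, kept as a counted protein group if none does, and discarded as
ambiguous if several do.

**Picked protein FDR.** Each protein's score is the sum of
$-\log_{10}$-transformed best PEPs over its peptides at peptide q
$\le 1\%$. Every target competes against its own shuffled decoy (paired
by the `decoy_` accession prefix); the lower-scoring member of each pair
is discarded before ranking, and q-values follow the same two-traversal
scheme. Compared with classical joint ranking, picking removes the
losing decoys of well-identified targets from the decoy tally, giving a
cleaner target/decoy separation that affords a protein threshold of
0.5% rather than the customary 1%.

**Confidence filters.** A peptide is confident at q $\le 1\%$ with at
least two PSMs; a protein at q $\le 0.5\%$ with at least two PSMs and an
unambiguous inference status. Identification fractions are always
reported against the counted database size: targets after merging
identical duplicate sequences to one representative (seeded random
choice, members recorded) and excluding entries flagged as spurious
annotations.

Per-dataset and combined runs are both supported; because q-value
estimation is scope-dependent, the two scopes can disagree on marginal
identifications, and the pipeline reports the discrepancy set rather
than merging silently.

## Decoy construction

Decoys are built per protein by shuffling residues within each fully
cleaved peptide of the protease digest, keeping the enzymatic terminal
residue (K/R for trypsin, E for GluC) fixed. This preserves residue
composition, the digest's peptide length spectrum, and the cleavage
structure, making decoy peptides statistically exchangeable with false
target matches — the premise of every decoy-based estimate in the
package. Shuffling operates on fully cleaved units (not on
missed-cleavage variants), a choice that keeps the decoy digest
consistent at every missed-cleavage setting.

## The synthetic-data generator

The generator stands in for raw data at desk scale and carries a full
truth record (per-PSM correctness, per-dataset presence, planted
cleavage sites, planted absent gene runs, all generator parameters).
Design choices:

* **Exact-count allocation.** Presence, spurious and duplicate fractions
  allocate exact counts rather than Bernoulli draws, so tests are
  deterministic given the seed; infeasible fractions error out.
* **PEP model.** True-match PEPs are Beta(0.7, 300) (median well below
  1%), false-match PEPs Beta(1, 1); false matches hit target and decoy
  peptides with equal probability, and their PEPs are exchangeable — the
  decoy-symmetry premise, verified by a Kolmogorov–Smirnov test in the
  suite. True matches are seen by more engines on average
  (`overlapBias`).
* **Study dimensions for calibration.** The calibration study uses 1200
  proteins with 25% present per dataset. The ratio matters: the target
  peptide space must be large relative to the set of true peptides,
  as in real searches, or false target matches frequently coincide with
  true peptides and get absorbed into them at collapse time — decoys
  have no such sink, which would bias the decoy-based estimate
  conservative and break exchangeability.
* **Planted cleavage sites.** Proteins carrying a planted signal-peptide
  cleavage site (CS) are engineered: the background alphabet excludes
  K/R/P and lysines are placed explicitly, so the semi-tryptic peptide
  starting at the CS (or at the planted ±1..3 offset), the contradicting
  fully tryptic peptide for incorrect-case proteins, and two
  mature-region tryptic peptides are all guaranteed to exist with
  lengths in 5–50.
* **One circular replicon by default**; gene order is a random
  permutation, and planted islands force a run of genes absent from
  every dataset.

What the generator does *not* emulate: spectrum-level properties
(retention time, intensity, charge-state effects), dataset-specific
modification patterns, and correlated engine errors. Passing tests
therefore certify the statistical machinery and its calibration under
the stated model, not performance on any particular instrument's data.

## Downstream analyses

**Physicochemistry.** Monoisotopic molecular weight is the sum of
residue masses plus one water; the isoelectric point is the unique zero
of the net-charge function (bisection to $|z| < 10^{-4}$), using the
EMBOSS pK set with distinct N-terminal, C-terminal and side-chain
values (swappable via an argument); GRAVY is the mean Kyte–Doolittle
hydropathy. Sequence coverage is the union of peptide intervals
(computed with `IRanges`) over the protein length.

**Localization.** Each protein receives exactly one category from a
fixed predictor precedence — TatLipo, LipoP, TatFind, FlaFind, SignalP —
with transmembrane topology deciding the remainder: $\ge 2$ TM segments
is integral membrane; one TM segment entirely within the first or last
50 residues is TM-N-term or TM-C-term respectively. A single TM segment
elsewhere is not named by the precedence scheme; it is assigned to the
integral-membrane bucket by default (configurable), keeping the
categories exhaustive. "Within the first/last 50 residues" is
interpreted as the whole segment lying inside the terminal window.

**Cleavage-site validation.** Semi-enzymatic searches are validated in
groups: fully and semi-enzymatic PSMs each get their own combined-PEP
and q-value computation, and semi results never count toward headline
identifications. A predicted CS is *correct* if a qualifying
semi-tryptic peptide (peptide q $\le 1\%$, $\ge 5$ PSMs) starts exactly
there, *refined* if one starts within ±3 residues (nearest start wins;
upstream on ties), *incorrect* if instead a fully tryptic peptide starts
at least three residues N-terminal of the CS (boundary inclusive: a
start at exactly CS−3 counts, though refined evidence takes precedence),
and *unclassifiable* when no theoretical tryptic peptide of 5–50
residues can start at the CS or the pathway implies an N-terminal lipid
anchor. GluC datasets and enrichment-derived datasets are excluded;
proteins with more semi- than fully tryptic peptides are skipped as
digestion artifacts.

**Genomic islands.** Genes are ordered by coding-region start along each
replicon; for every gene the number of identified proteins among the 51
genes centered on it (25 on each side, indices wrapping on circular
replicons) is computed, and maximal runs of genes with at most 20
identifications (39.2%) are reported as low-identification islands,
joined across the origin where applicable. Printed percentages round
half-up to one decimal. A run qualifies from length 1; the focal gene
itself need not be unidentified.

**Enrichment.** arCOG class enrichment uses two-sided Fisher's exact
tests on in-group/in-class tables against the counted background, with
Bonferroni correction over the classes tested; unlabeled proteins count
outside every class.

## Numerical and interface choices

* All protein coordinates are 1-based inclusive; a peptide's start is
  the position of its first residue. Gene indices are 0-based along the
  replicon. Isoleucine and leucine are distinct throughout.
* Trypsin cleaves after K/R except before proline; GluC after E by
  default (E/D selectable).
* Target/decoy peptide sequence collisions are labeled target and the
  decoy occurrence is dropped (rare by construction).
* A peptide q-value threshold, protein threshold, PSM minima and length
  bounds live in a single declarative configuration with the defaults
  named above; every run reports a configuration hash so outputs are
  traceable.
* Seeded operations (duplicate representative choice, decoy shuffling,
  the generator) restore the caller's RNG state.

## Problem sizes in the test suite

The suite exercises the full pipeline on studies of 100–320 proteins
and $10^3$–$10^4$ PSMs, the q-value estimators against a brute-force
oracle on 1000 random instances of up to 50 items, and the calibration
of the nominal 1% peptide threshold on a 1200-protein study with 9000
true and 1000 false PSMs over 20 seeds. These sizes were chosen so the
whole suite completes in minutes while every estimator still operates
in its intended regime (thousands of peptides per length group,
hundreds of proteins per ranking).

## Known limitations

* The windowed combined-PEP estimator is a stand-in for the original
  (unpublished) estimator; its window width trades variance against
  resolution and is exposed as a parameter.
* The empirical FDR of a decoy-anchored q-value cutoff necessarily has
  larger variance than a binomial draw at the nominal rate: the
  accepted set's boundary is itself estimated from the decoy counts.
  Calibration is excellent in expectation (mean empirical FDR within a
  few percent of nominal) but individual runs scatter ~1.3–1.4× wider
  than the binomial band around the nominal level, so occasional
  excursions outside that band are expected behavior, not estimator
  bias.
* Protein inference implements the simple evidence rules described
  above, not global parsimony; for proteomes with extensive peptide
  sharing a parsimony-based inference would be preferable.
* The pI calculation assumes independent ionizable groups and standard
  pK values; it ignores structural context, as all sequence-based pI
  estimates do.
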