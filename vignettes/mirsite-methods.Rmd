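---
title: "Seed-agnostic microRNA target prediction: models and methods"
author: "mirsite authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-agnostic microRNA target prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsite)
```

## The problem

Animal microRNAs repress protein production by pairing, usually
imperfectly, with sites in the 3'UTR of their target mRNAs.  Most
predictors demand a perfect *seed match* — contiguous Watson-Crick
complementarity to microRNA positions 1–7 or 2–8 — and often additionally
demand that the match be conserved across species.  Both filters buy
precision at the price of an entire class of biology: species-specific
sites and 3'-compensatory sites (imperfect seed, extensive 3' pairing)
are invisible to them.  `mirsite` predicts target sites with neither
filter.  Candidate regions are found purely by hybridization energy,
described by a catalogue of duplex and sequence features, and ranked by a
boosted classifier; seed and conserved-seed calls are *post-filters* that
carve stricter subsets out of the same ranked predictions, never inputs
to the model.

## Duplex energy model

All energies come from an explicit intermolecular nearest-neighbor model
over the six admissible pair types (four Watson-Crick plus G:U).  A
duplex structure is an ordered pair list (microRNA position increasing,
target position decreasing — antiparallel, no pseudoknots); its energy is

```
E = init + sum(stacking terms) + sum(bulge/interior penalties)
         + terminal AU/GU penalties
```

The bundled table (`inst/extdata/nn_params_v1.tsv`, version
`mirsite-nn-1.0`) uses Turner-style Watson-Crick stacking free energies
at 37 °C.  Stacks containing a wobble pair take the value of their
Watson-Crick analog (G:U → G:C, U:G → U:A) scaled by 0.45 per wobble.
That scaling is a deliberate simplification: it keeps every stack
non-positive, keeps wobble pairing strictly weaker than Watson-Crick
pairing position-for-position, and therefore makes the perfect
reverse-complement duplex a provable global energy lower bound for a
given microRNA — a property the zone thresholds rely on and the tests
assert.  The pipeline depends only on energy *ratios*, so fidelity to
measured wobble parameters matters less than these orderings.  Loop
penalties are affine-growing lookup tables (one-sided bulges 1–15 nt,
two-sided interior loops of total length 2–30 nt); per-strand loop runs
are capped at `max_loop_side = 15`.  Structures must not contain lonely
pairs: every helix has length at least two.  An adapter seam exists for
substituting another energy backend — any object with the same component
list as `energy_parameters()` is accepted throughout — but the package
deliberately ships self-contained.

Two hard admissibility filters mirror how duplexes are vetted before
anchoring: a structure is discarded if any of its first eight pairs is a
G:U wobble, or if it carries five or more G:U pairs in total.

### Anchored optimization

The *anchor* of a duplex is the target position paired with the 5'-most
paired microRNA nucleotide.  For every UTR position `p`,
`anchored_minimum()` finds the minimum-energy admissible structure
anchored at `p`, searching the window `[p − span, p]` with
`span = microRNA length + 15` — enough to accommodate the largest
tabulated target bulges with margin while keeping the dynamic program
small.  The DP (in C++) tracks, per cell, the last pair, whether the
current helix already has length ≥ 2, and a 12-state G:U bookkeeping
(pair count capped at 8 × wobble count 0–4) so the two discard rules are
enforced *inside* the optimization, not post hoc.  Energy ties break
toward fewer pairs, then a fixed scan order, making results
deterministic.  The suite proves the DP equal to exhaustive enumeration
of all admissible structures on hundreds of random small instances.

At anchors where a perfect 5'-end helix of at least seven consecutive
pairs from microRNA position 1 exists (a seed region), seedless
structures at the same anchor are discarded before the minimum is taken
(`prune_anchor_group()`); the DP runs a seed-forced variant first to
implement this exactly.

## Candidate zones

`build_profile()` turns per-anchor minima into an attraction profile:
`raw_energy[p]` is the anchored minimum at `p`, or 0 kcal/mol where no
admissible structure anchors (0 is maximally unfavorable since all
relevant energies are negative; such positions break sub-threshold
runs).  The profile is smoothed with a centered window of length three,
truncated to two values at the sequence ends.

Zones are defined relative to `E_perfect`, the energy of the microRNA
against its perfect reverse complement: a candidate zone is a maximal
run of positions with `smoothed ≤ x_ratio · E_perfect`, containing at
least one anchored optimum with `raw ≤ y_ratio · E_perfect` whose
5'-most pairing uses microRNA position 1 or 2 — the *representative*
(minimum energy; ties to the smaller anchor).  Defaults are the
deliberately permissive `x = 0.24`, `y = 0.25`: a ratio of 0.25 means
the duplex has a quarter of the perfect hybrid's energy.  Note the
convention: a *larger* `x_ratio` demands deeper energy and is the
stricter cut-off.  The zone interval is the run extended to cover the
representative's target footprint, which makes downstream overlap
merging well defined; after scoring, overlapping zones merge and the
highest-scoring representative represents the union.

## Feature catalogue

`extract_features()` computes 43 named features per representative:
pairing extent (seed 8-mer pairings, 3'-end pairings, longest stacked
stretch, a 3'-end run tolerating two unpaired positions, totals, G:U
count, binding asymmetry over the terminal 8 nt of each end), bulge
geometry per strand (counts, total/mean/second-largest lengths, size
histograms — microRNA sizes 1–5, target sizes 1–6 and ≥ 7, symmetric
bulges), positional features (the anchor's bin among 100 equal UTR bins;
the target nucleotides opposite microRNA positions 1 and 9, read along
the pairing register and interpolated from the nearest 5'-side pair when
position 9 is unpaired, plus their A/U indicators), and composition
(G+C of site and 50-nt flanks, microRNA/site G+C ratio, site-vs-20-nt
upstream flank difference, first-vs-last-8 difference, CpG counts in
site and 20-nt flanks).

Conventions worth stating: the A/U "S/W" indicator features follow the
lettering used for them historically (S = A or U), which is swapped
relative to IUPAC — the names `t1_sw_anchor`/`t9_sw_anchor` keep that
behavior explicit.  CpG is counted (C followed by G, 5'→3'), not
boolean, the count being strictly richer.  The site-vs-flank G+C
difference uses the upstream flank only.  When a site contains no G or C
the G+C ratio denominator is replaced by half a count to stay finite.
Binding asymmetry with an empty 5' side returns `(paired3' + 1)/1`, a
pseudocount for an otherwise undefined ratio.

**Compactness**, the headline feature, rewards duplexes with few
unpaired nucleotides on either strand:

```
compactness = 0.5 * (n_pair / miRLen + n_pair / tsLen)        tsLen >= miRLen
            = 0.5 * (n_pair / miRLen + n_pair / tsLen) * tsLen / miRLen   otherwise
```

The penalty branch for sites shorter than the microRNA multiplies by
`tsLen/miRLen`; among penalty forms this one preserves the range
`[0, 1]` and is continuous at `tsLen = miRLen`.  Compactness is 1
exactly when every nucleotide of both strands is paired.

RISC-accessibility features require an intramolecular folding backend
and are not part of the catalogue; `accessibility_hook()` is a named
extension point through which a user-supplied function can add them.

## Feature selection

`relieff_rank()` implements ReliefF with range-normalized Manhattan
distance, `k = 10` nearest hits and misses, and all instances sampled —
common defaults, fully deterministic without subsampling.
`cfs_select()` implements correlation-based feature selection: subset
merit `k·r̄cf / sqrt(k + k(k−1)·r̄ff)` with both correlations measured as
symmetrical uncertainty on equal-frequency discretized features
(`min(10, floor(sqrt(n)))` bins), searched best-first from the empty set
with a stop after five consecutive non-improving expansions.  On small
tables the search provably attains the exhaustive-search merit (tested
against full subset enumeration).  The default model feature set is the
seven-feature subset this procedure selects on training data:
compactness, microRNA/site G+C ratio, longest stretch, binding
asymmetry, site G+C, seed 8-mer pairings, and UTR position bin.

## Classifier and calibration

`train_multiboost()` is MultiBoosting with decision stumps: AdaBoost.M1
weight updates inside subcommittees; at subcommittee boundaries (and on
base-learner error 0 or ≥ 0.5) instance weights are redrawn from the
continuous Poisson approximation (standardized exponential deviates).
Committee size defaults to 200 with `ceiling(sqrt(200)) = 15`
subcommittees, the cited algorithm's parameterization; the subcommittee
count is a configuration knob.  With one subcommittee the procedure *is*
AdaBoost, bit for bit — the suite checks stumps and alphas against an
independent plain AdaBoost implementation.  Stump splits are midpoints
between consecutive distinct values; ties break toward the lower feature
index, then the lower split.  Scores are the normalized committee vote
`(margin/Σα + 1)/2 ∈ [0, 1]`; an empty committee abstains at 0.5.

Stratified 10-fold cross-validation pools out-of-fold scores into a ROC
curve whose trapezoidal AUC equals the Mann-Whitney rank statistic
(asserted to 1e-12).  Thresholds: the *sensitive* threshold is the
smallest score with empirical out-of-fold FPR strictly below 5%, the
*specific* threshold the smallest with FPR at or below 1%.  Specific
predictions are nested inside sensitive ones by construction.  Because
the specific threshold is chosen at the boundary from ~1000 negative
scores, its fresh-sample FPR carries binomial noise plus a small upward
selection bias (about a quarter of a percentage point at these sizes);
this is a property of boundary calibration itself, not of the committee.

## Prediction classes

Every merged, scored zone is a class-I (no-seed) prediction.  The
*seed* subset contains records whose zone interval holds a perfect
Watson-Crick 7-mer match to microRNA positions 1–7 or 2–8.  The
*conserved seed* subset additionally requires, through a per-transcript
multi-species alignment, a 6-mer match (positions 2–7) whose six
alignment columns are gap-free and identical across all species, with
the reference also matching microRNA base 1 or 8 — the standard
conserved-7-mer background definition, applied here as the prediction
filter since no separate definition exists for the prediction subset;
the species panel is whatever the supplied alignments contain.  Class
and stringency subsets nest: conserved-seed ⊆ seed ⊆ all, specific ⊆
sensitive.

Training sets built from validated binding intervals follow the
energetically-extreme rule: per validated site and microRNA family, the
most stable overlapping candidate (≥ 1 shared position) is the positive
and the most stable non-overlapping candidate of the same interaction
the negative — at most one of each per interaction.  Evaluation against
proteomic fold changes reports the fraction of measured predicted
interactions with log2 fold change below −0.1 (a positive predictive
value); unmeasured interactions are excluded from both counts.

## Synthetic data: what it emulates and what it does not

`generate_corpus()` builds i.i.d. background UTRs at a configurable G+C
fraction (default 0.45, typical of mammalian 3'UTRs; lengths uniform on
a configurable range, default 200–1000 nt; 22-nt microRNAs) and implants
sites of controlled quality: `perfect` (full reverse complement),
`seed_only` (reverse complement of positions 1–8 only),
`compensatory_3prime` (seed broken at positions 3–5, 3' block intact)
and `shuffled` (dinucleotide-preserving shuffle of the complement, a
composition-matched decoy).  `generate_alignments()` adds per-species
point substitutions at a configurable rate (default 5%, no indels).
`generate_labeled_table()` draws Gaussian feature vectors with a mean
shift on the model features for positives; the default shift of 0.4
standard deviations yields a cross-validated AUC of about 0.76 (printed
by the acceptance script), chosen to emulate the moderate separability
real training data exhibits rather than an artificially clean split.  `generate_psilac_table()`
assigns fold changes so a stated fraction of interactions is
down-regulated.

These generators exercise every pipeline contract, but i.i.d. (or
first-order) background with clean implants does not reproduce real UTR
composition, repeat structure, site clustering, or crosslinking biases;
passing tests demonstrate algorithmic correctness and calibration
behavior, not genome-scale accuracy.

## Numerical choices and problem sizes

Determinism throughout: every stochastic step takes an explicit seed,
RNG state is saved and restored around generator calls, and two
identical pipeline runs produce byte-identical output files.  Energy
comparisons use a 1e-9 tie tolerance.  The test suite scales its
simulations to desk size by choice: duplex-oracle equivalence on 200
instances with microRNAs ≤ 9 nt against windows ≤ 14 nt (exhaustive
enumeration stays below ~10^5 structures), implant recovery on 500
single-implant corpora of 120-nt UTRs, classifier checks on tables of
600–2000 rows, and the acceptance script on a 2000-row table with a
fresh 2000-negative evaluation sample.

## Known limitations

Intramolecular structure is ignored (intermolecular duplex only); no
partition function or suboptimal ensembles beyond per-anchor optima; no
temperature dependence; the wobble stacking values are a documented
simplification rather than measured parameters; conserved-seed calls
require user-supplied alignments with substitutions only (gap columns
inside a seed disqualify it, but the reference row must degap to the
UTR); and genome-scale behavior (site counts per UTR, realistic
precision) is outside what synthetic corpora can certify.
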