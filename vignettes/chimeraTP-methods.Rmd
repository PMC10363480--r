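---
title: "Peptide models and methods in chimeraTP"
author: "chimeraTP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide models and methods in chimeraTP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraTP)
```

## Scope

Chloroplast transit peptides (cTPs) and mitochondrial presequences (mTPs)
are cleavable N-terminal import signals with confusingly similar
physicochemistry: both are cationic, depleted of acidic residues, and
organised around an amphipathic alpha-helix. Helical amphipathic
ribosomally-produced antimicrobial peptides (HA-RAMPs) share that same
chassis, which makes them a natural experimental substrate for asking
which sequence features switch a peptide from killing bacteria to
delivering cargo into an organelle. `chimeraTP` provides the
computational layer for this kind of study: featurization of peptides
(amphipathic-helix detection, Z-scale auto-cross-covariance descriptors,
charge, Boman index, motif scans), a grammar for assembling chimeric
constructs from targeting-peptide (TP) elements and peptide cores with
systematic lysine/arginine exchange, a resampled cross-validated
penalized logistic-regression protocol for mTP/cTP discrimination,
bookkeeping for grids of construct-targeting outcomes, and seeded
synthetic-data generators so that every stage is testable without any
external download.

## Amphipathic-helix detection

A candidate stretch of residues is wrapped onto an ideal helical wheel at
100 degrees per residue (3.6 residues per turn; configurable). Its
per-residue hydrophobic moment is

$$\mu_H = \frac{1}{N}\left|\sum_{n=0}^{N-1} H(r_n)\,
  (\cos n\delta,\ \sin n\delta)\right|,$$

computed on the Fauchere--Pliska octanol/water scale shipped with the
package. `findAmphipathicHelices()` searches for the longest stretch with
identifiable hydrophobic and hydrophilic faces, records it, masks it, and
recurses on both flanks, so several non-overlapping helices can be
annotated per peptide. Ties between equally long stretches go to the
higher moment, then to the leftmost start, making the output
deterministic.

A stretch of at least 9 residues qualifies when all of the following hold
(defaults in `helixConfig()`; all constants are configuration keys):

1. global moment $\mu_H \ge 0.35$;
2. face identifiability: among residues whose wheel position falls within
   90 degrees of the moment direction, at least 60% belong to
   {L, I, V, F, M, W, Y, A}, and the opposite face carries at least two
   residues from {R, K, D, E, S, T, N, Q, H, G, P};
3. local amphipathicity: every contiguous 9-residue subwindow reaches the
   moment threshold as well.

The third clause is a deliberate design choice. Conditions 1--2 alone
admit a failure mode in which two genuine amphipathic helices separated
by a short indifferent spacer (for example a poly-serine linker) merge
into a single long "stretch": the spacer contributes almost nothing to
the vector sum, the global moment still scrapes past the threshold, and
the face test cannot see that ten consecutive residues have no face
structure at all. Requiring every turn-scale subwindow to be amphipathic
removes exactly these spurious bridges while leaving uniformly
amphipathic stretches untouched. The thresholds themselves are declared
defaults, calibrated qualitatively (designed amphipathic peptides are
recovered; unstructured poly-serine and random controls are not), not
recovered from any external tool.

Two summary quantities feed the class comparisons: the helix fraction
(annotated residues divided by the evaluated length, which for TPs is
cut at the cleavage site) and the upstream length (residues before the
longest helix). A helix-free peptide reports its whole evaluated length
as upstream, placing it at the maximally unstructured end of that axis;
the `helix_free` flag marks the convention. Externally established
helices (for example from an NMR structure, relevant for cTPs whose
helix only forms in membrane-mimetic environments) can be injected via
the `external` argument and take precedence over prediction, labelled
`EXTERNAL`.

## Z-scale ACC featurization

Each residue is described by the classical three Z-scale values
(hydrophobic, steric, electronic). For scales $j,k \in \{1,2,3\}$ and
lags $d \in \{1,\dots,4\}$ the auto-cross-covariance terms

$$ACC_{j,k,d} = \frac{1}{N-d}\sum_{i=1}^{N-d} z_j(r_i)\, z_k(r_{i+d})$$

give a fixed-length, 36-dimensional representation of a peptide of any
length above the lag. Terms are uncentred products normalised by $N-d$;
a centred variant (subtracting each scale's within-sequence mean) is one
flag away, since conventions differ between implementations and the
choice is isolated behind a single function. The (j, k, d) lexicographic
ordering is persisted in the `acc_j_k_d` column names so downstream
models remain portable. Similarity to a TP reference cloud is the
Euclidean distance to the coordinate-wise mean (barycenter) of the
reference ACC vectors.

## Construct grammar

Chimeric constructs are written `["^c"] CORE ["_K"|"_R"] ["^c"|"^m"]`:
a leading `^c` prepends the cTP N-terminal element (the cTP's first 15
residues, upstream of its helix), the subscript names the basic-residue
variant (all K replaced by R, or the reverse; peptides natively lacking
the source residue pass through unchanged), and a trailing `^c`/`^m`
appends a C-terminal element from the cTP or mTP. C-elements span 10
residues upstream to 23 residues downstream of the donor's cleavage
site, so an assembled construct carrying one has its cleavage index 23
residues before its end. Special cores: `CH`/`MH` are the bare TP
helical fragments, `AA` is a poly-alanine of the same length as `CH`,
and `-` fuses the flanking elements directly. Assembly is plain
concatenation — no linkers — and `parseConstructCode()` /
`formatConstructCode()` are exact inverses on canonical codes.

The packaged peptide library (`fig1_peptides_synthetic.fasta`) is a
synthetic stand-in, as its name says: it carries the canonical 17 record
ids (13 HA-RAMP codes, a reference cTP and mTP with cleavage indices and
annotated helix spans, and two random-peptide controls) with realistic
lengths and compositions produced by the package's own generator. The
construct grammar, element extraction and all grid bookkeeping are
sequence-agnostic, so every worked example runs identically on real
sequences supplied by the user. The same applies to the Hsp70 affinity
table: the shipped `hsp70_affinity_synthetic.tsv` is a constructed,
hydrophobicity-correlated stand-in (higher for L-rich windows, strongly
negative for acidic residues); users with access to experimentally
derived per-residue affinities can pass them directly to `scanHsp70()`.

## Targeting-outcome grids

`TargetingGrid` stores one mitochondrial and one chloroplast call per
construct, each `NONE < PARTIAL < FULL`; dual targeting is derived (both
at least `PARTIAL`), never stored. Rows A--L encode the modification
scheme — K/R variant, presence of the cTP N-element, choice of C-element
— and columns a--s the core (a--m the 13 HA-RAMPs, n--s controls, which
are excluded from HA-RAMP tallies). `compareKRPairs()` classifies each
K-to-R switch as GAIN, IMPROVE, LOSS, DECREASE or UNCHANGED, flagging
gains that newly produce dual targeting; the five classes partition the
evaluated cells, and swapping the rows of every pair maps GAIN to LOSS
and IMPROVE to DECREASE exactly. The packaged grid fixture encodes the
curated microscopy outcomes for the full chimeric series; its `note`
column distinguishes cells fixed by explicit outcome enumerations from
cells that are only implied by consistency of the aggregate counts
(`inferred_low_confidence`), so downstream users can weigh them
accordingly.

## Classification protocol

The mTP/cTP discrimination protocol featurizes 15-residue N-termini
(the region carrying localization information) and fits a binomial
logistic regression with an elastic-net penalty: mixing parameter
`l1_ratio` (default 0, pure ridge, so all 36 ACC terms participate) and
inverse regularization `C` (default 0.1). Because class sizes are
typically unequal, each of 100 runs draws the same number of peptides
per class without replacement, splits them into 5 stratified folds, and
records held-out accuracy; accuracy is averaged over folds, then over
runs, and per-run values are retained so either aggregation can be
audited. Features are standardized with training-fold statistics only —
penalized models are scale-sensitive, and letting test data into the
scaling would leak. Fits use `glmnet`; the `C` convention maps onto
glmnet's per-observation objective as $\lambda = 1/(C\,n_{train})$, and
the convergence threshold is tightened (`thresh = 1e-10`) so that
reported solutions are at the penalized optimum for practical purposes;
non-convergence is an error, never silent. Under a fixed seed the whole
report — subsampling, folds, coefficients — is reproducible bit for bit,
and the protocol restores the caller's RNG state.

`tuneHyperparameters()` evaluates an (l1_ratio, C) grid exhaustively by
10-fold cross-validation under one shared fold assignment and returns the
full table with all ties for the best accuracy reported, not silently
broken. `tpSimilarityScore()` ranks candidate peptides by the fitted
probability of the TP class from an elastic-net model (mixing 0.15)
separating HA-RAMPs from TPs; it featurizes whole peptides, not
N-termini, because HA-RAMPs have no cleavage sites and no natural
N-terminal anchor for such a cut.

## Synthetic data: what it emulates and what it does not

`generatorSpec()` defines four peptide classes whose defaults mirror the
contrasts the analyses are about: mTP-like (mean length 37, sd 8;
R-rich; amphipathically helical from residue 1 over ~80% of the
sequence), cTP-like (mean 49; an unstructured prefix of mean 15 residues
— the cTP-N length — before a central helix and a short tail; R-rich),
HA-RAMP-like (mean 28; fully helical; K-rich) and random controls. All
classes are depleted of acidic residues (rate 0.01). Helix design places
hydrophobic-arc positions (180 degrees wide by default) on the wheel
from {L, I, V, F, A} and the polar face from the basic residue (weight
0.5) and {S, T, N, Q, G}. Datasets are pure functions of their specs:
every class carries its own seed, and truth tables record designed spans
and upstream lengths for recovery tests.

These generators reproduce the statistical *structure* of the real
peptide classes — length contrasts, helix placement, K/R usage, acidic
depletion — not their detailed composition, family structure, cleavage
site motifs, or any property the generator does not explicitly encode.
Passing recovery and separability tests on synthetic data therefore
demonstrates that the algorithms do what they claim on data with the
assumed structure; it does not certify performance figures on real
proteome-derived TP sets, which are deliberately not bundled.

## Statistics

Group comparisons use Welch's unequal-variance t-test by default (a
pooled-variance flag exists); one-sided tests are available for small
preference sets tested along a direction established by a reference
pair. Amino-acid distribution contrasts across more than two groups use
Kruskal--Wallis followed by pairwise Dunn z-tests on tie-corrected mean
ranks, written in-package and cross-checked against an independent
rank-based implementation; Dunn p-values are Holm-corrected by default
(Bonferroni and uncorrected are options; the correction can only raise
p-values). With all observations tied the omnibus is reported as
undefined rather than erroring.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: peptides shorter than a scan
window yield empty results with a message (not an error); peptides too
short for the ACC lag, missing cleavage indices, or out-of-range element
extractions are errors naming the offender; single-class folds trigger a
counted re-draw. Validation of the test suite runs the helix invariants
and ACC-oracle comparisons on 1000 fuzzed peptides each, span recovery
on 200 designed amphipathic peptides (mean Jaccard against designed
spans at least 0.8), the classifier protocol at 40 peptides per class
with 100 resampling runs, and the class-contrast recovery on 100 seeded
replicates; these sizes give stable pass/fail behaviour while keeping a
full run around a minute on one core.

## Known limitations

* The helix finder is a helical-wheel heuristic, not a secondary
  structure predictor; helices that only form on membrane contact can be
  missed (hence the `external` injection route).
* The qualification thresholds are declared defaults, not values
  recovered from any published tool; conclusions that hinge on absolute
  helix fractions should sweep them.
* The shipped Hsp70 affinities and the peptide library are synthetic
  stand-ins (flagged in their filenames); quantitative motif counts on
  them are illustrative only.
* Disorder and interactivity predictions (IUPred/ANCHOR-style) are out
  of scope; such values can be supplied as pre-computed columns but are
  never computed here.
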