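---
title: "Screening proteomes for linear cationic alpha-helical antimicrobial peptides"
author: "lcampscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for linear cationic alpha-helical antimicrobial peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcampscan)
```

## The screening problem

Linear cationic alpha-helical antimicrobial peptides (LCAMPs) are short,
cysteine-free host-defense peptides that kill microbes by disrupting their
membranes. Their sequences diverge too quickly for homology search to find
new family members, but their *physicochemical* signature is conserved: the
precursor is a short secreted protein, and the mature peptide folds into an
amphipathic alpha-helix whose polar face is strongly cationic. `lcampscan`
implements a screening funnel that exploits exactly this signature.

The funnel applies eight stages in fixed order to every protein in a
proteome:

1. **length** — precursors of 50-100 residues (inclusive);
2. **secretory** — a signal peptide must be present; its predicted cleavage
   point defines the mature sequence;
3. **tm** — records with a membrane-spanning stretch in the mature region
   are eliminated;
4. **cys** — any cysteine in the mature region eliminates the record
   (LCAMPs are linear, without disulfide architecture);
5. **amphipathic** — an 18-residue window slid along the mature sequence
   must produce at least one window inside the cationic threshold box;
6. **helical** — candidate segments must look helix-competent;
7. **aggregation** — the AGGRESCAN-style Na⁴vSS summary of the segment must
   lie in [-30, 30];
8. **localization** — optional gating on external subcellular-localization
   predictions.

Stages may be disabled but never reordered; per-stage in/out counts are
returned (`FunnelCounts`-style, always non-increasing).

## Helical-wheel physicochemistry

Three quantities drive the amphipathicity screen, all computed on the
Fauchère–Pliska hydrophobicity scale by default:

* mean hydrophobicity $\langle H \rangle = \frac{1}{N}\sum_i H_i$;
* the Eisenberg hydrophobic moment per residue at the ideal helical twist
  $\delta = 100^\circ$,
  $$\mu_H = \frac{1}{N}\sqrt{\Big(\sum_{i=0}^{N-1} H_i \sin i\delta\Big)^2 +
  \Big(\sum_{i=0}^{N-1} H_i \cos i\delta\Big)^2};$$
* net charge $z = \#K + \#R - \#D - \#E$ (histidine neutral).

The phase convention places residue $i$ at angle $i\delta$ starting from 0;
$\mu_H$ is invariant to a global phase offset, so any consistent convention
is equivalent — this one is fixed for reproducibility. $\delta$ is
configurable for 3₁₀/π-helix exploration.

Whole-sequence means computed this way reproduce HeliQuest's published
values for known *Ciona* LCAMPs to three decimals (the acceptance suite
recomputes all of them), which is why Fauchère–Pliska ships as the default
scale. Scales are plain two-column text files and user-overridable.

The cationic box is inclusive on every bound: hydrophobicity 0-0.6, moment
0.1-1.0, charge +3-+10, at least 6 polar residues, at least 1 of S/T/N/Q/H,
at most 12 charged residues, no cysteine. "Between X and Y" thresholds are
read inclusively — the conservative choice, regression-locked by tests.
The minimum-glycine rule (0) is vacuous but kept for configuration
symmetry. The anionic proregion box (hydrophobicity -0.7-0.4, moment
0-0.5, charge -10--3) applies no composition rules except cysteine
exclusion, matching how the two searches are parameterized differently.

Two choices deserve a note:

* **Polar set.** The composition rule needs a definition of "polar" that
  the screening parameters do not pin down; the package defaults to
  {D,E,K,R,H,N,Q,S,T,Y} and exposes the set as a configuration knob.
* **Short sequences.** Mature peptides shorter than the 18-residue window
  are evaluated as a single whole-sequence window; known active peptides as
  short as 14 residues are meaningfully scored this way, and their
  published whole-sequence values confirm the convention.

Windows containing `X` fail every gate (no scale value exists — the screen
fails closed rather than guessing).

## Segments and the in-order architecture flag

Overlapping or adjacent passing windows of one class merge into maximal
segments; each segment records its best window (highest $\mu_H$, ties to
the smaller start). The canonical LCAMP precursor is signal peptide →
cationic amphipathic region → anionic helical proregion, and the report
flags precursors whose regions appear strictly in that order
(`architecture`).

A known limitation: when the cationic region and the anionic proregion are
immediately adjacent, windows straddling the junction pass one box or the
other, so the two merged segments overlap by a few residues and the strict
flag reads `FALSE` even though the regions are ordered. The flag therefore
identifies precursors whose proregion is cleanly separated; boundary
overlap is visible in the reported coordinates.

## Helicity and aggregation conventions

The helicity stage is a propensity stand-in, not a secondary-structure
predictor: mean Chou–Fasman helix propensity ≥ 1.03 and ≥ 50% of residues
with propensity ≥ 1.0. Per-residue H/E/C strings from any external
predictor can be supplied instead (`method = "external"`), in which case
the helix fraction is computed from the prediction.

Aggregation scoring follows the AGGRESCAN construction: per-residue
propensities `a3v` (shipped scale), window-averaged `a4v` (window 5 for
sequences under 75 residues, then 7/9/11 by length band), summed to
`a4vSS` and normalized per 100 residues, `Na4vSS = 100·a4vSS/N`. At the
termini the default is *truncated* (asymmetric) windows so every residue
receives a value and the normalization stays well-defined for short
peptides; `end_mode = "full_windows_only"` restricts the sum to complete
windows. Recomputing Na⁴vSS on published synthetic *Ciona* LCAMP peptide
sequences yields values differing from the published server scores under
every end-mode and window convention, consistent with those scores having
been computed on the full precursor proteins (which are not publicly
printed and not available offline); the package therefore documents its own
exact convention, and the aggregation engine is validated against per-position
averaging oracles and algebraic identities instead (window-1 identity,
reversal invariance, homopolymer invariance).

## Predictor stages are contracts, not models

Trained predictors (signal peptide, transmembrane topology, subcellular
localization) are deliberately not re-implemented. Each stage accepts
external results through a tabular adapter, and ships an honest rule-based
stand-in so the funnel runs end-to-end offline:

* **Signal peptide** — classic n/h/c-region rules: non-negative n-region
  charge (first 5 residues), a 7-residue h-region of mean hydrophobicity
  ≥ 1.0 within positions 3-25, small residues (A/G/S/C/T) at the −3/−1
  positions of the best candidate cleavage site in positions 15-35.
* **Transmembrane** — any 19-residue window with mean Kyte–Doolittle
  hydropathy ≥ 1.6 eliminates the record.
* **Localization** — keeps records whose external class is in the accepted
  set (default Extracellular/Secreted, configurable since class
  vocabularies differ between predictors); without external results the
  stage can run as an explicit pass-through (it warns once per run) or be
  disabled.

Every prediction carries a `source` field (`heuristic` or `external`) so
reports are honest about their provenance. The heuristics approximate but
do not reproduce the trained models, which is why genome-scale candidate
counts from studies that used the servers are not comparable to funnel
counts obtained with the stand-ins.

## Upstream motif scanning

NF-κB-responsive antimicrobial-peptide genes carry κB sites upstream of the
start codon. `match_scan()` implements Match-style scoring: per-position
information $I(i) = \sum_b f_{ib}\ln(4 f_{ib})$ (natural log, $0\ln 0 = 0$)
weights the frequency of the observed base, and the sum is rescaled between
the per-position minimum and maximum to give `matrix_sim` in [0,1];
`core_sim` is the same score over the 5 consecutive most-informative
positions (leftmost on ties). Default cut-offs are core 0.75 and matrix
0.8. Both strands are scanned; positions are reported as negative offsets
from ATG of the site's 5'-most base on the + strand (last upstream base =
−1). Count matrices receive a pseudocount (1% of the position total) before
normalization.

The default matrix is a *synthetic* NF-κB-like count matrix constructed
from the canonical GGGRNNYYCC κB consensus (the curated TRANSFAC matrix is
license-encumbered); it exercises the scanner and is explicitly not
suitable for biological interpretation of hit positions. The scanner
itself is validated by brute-force oracle equivalence, strand-symmetry and
cut-off monotonicity properties, and by recovery of sites planted in
synthetic upstream regions.

## The synthetic-data generator

`make_fixture_proteome()` builds the offline validation set: planted
precursors assembled from a consensus-derived signal peptide (`X` positions
filled from A/V/L/S), an 18-24-residue cationic helix with K/R placed on
one wheel face (residues within ±90° of the azimuth at δ=100°) and L/A/F/I
on the other, and an anionic E/D-faced tail — plus one decoy per funnel
stage, each constructed to pass every stage before its label and fail
exactly there (over-long record, hydrophilic N-terminus, 19-leucine TM
stretch, a single mature-region cysteine, a charge-free polar region, a
proline/glycine-rich amphipathic segment, an I/F/Y-faced
aggregation-extreme segment).

The generator does not trust its construction arithmetic: every record is
verified against the real pipeline (`run_funnel()`) and resampled until it
behaves as labelled, so fixtures stay valid if scales or thresholds change.
This also means planted-precursor recall is a closed-loop property — it
validates the funnel's internal consistency and the generator's coverage of
each stage, not performance on real proteomes. The background model is
uniform over residues; real proteomes have biased composition, longer
repeats and homologous families, none of which the generator emulates, so
passing fixtures say nothing about false-positive rates in real screens.

Default study conditions used by the tests and the acceptance script:
5 planted precursors and 7 stage-labelled decoys per fixture proteome,
window-scan oracle equivalence on 200 random sequences of length 20-120,
PWM oracle equivalence on 200 random 50-bp instances, aggregation oracle
agreement on 100 random sequences. The full suite runs in well under two
minutes on one CPU.

## Numerical choices and degenerate inputs

* All threshold comparisons are inclusive; ties in best-window selection
  break to the smaller start; the information-core tie breaks leftmost.
* Internal coordinates are 0-based half-open; all report output is 1-based
  inclusive; upstream motif positions are negative offsets from ATG.
* H and μH are reported to 3 decimals; tests compare at 5×10⁻⁴.
* Empty sequences, residues missing from a scale, even aggregation
  windows, sequences shorter than 3 residues, degenerate PWMs (Max = Min)
  and gap-length mismatches in alignments are all hard errors, not silent
  defaults.
* `aggregation_profile()` accepts sequences shorter than the window in
  truncated mode (the asymmetric windows simply shrink); the
  full-windows-only mode refuses them.

## Limitations

* Heuristic predictor stages are coarse stand-ins; use external adapter
  files from real predictors for production screens.
* The architecture flag is strict about segment separation (see above).
* The default PWM is synthetic; supply a curated matrix for real motif
  analysis.
* Genome-scale funnel counts depend on the exact predictor versions used;
  only the structure of the funnel (stage order, monotone counts) is
  reproducible offline, not any particular study's per-stage totals.
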