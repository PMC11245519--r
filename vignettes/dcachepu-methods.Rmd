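---
title: "Methods: deriving and applying the dCache_1 purine-binding motif"
author: "dCachePU package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and applying the dCache_1 purine-binding motif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dCachePU)
```

# Scope and model

Bacterial transmembrane receptors -- chemoreceptors, sensor histidine
kinases, diguanylate cyclases/phosphodiesterases and Ser/Thr
phosphatases -- frequently sense their ligands through an extracellular
dCache_1 domain.  A subfamily of these domains (dCache_1PU) binds purine
derivatives through a small set of binding-pocket residues.  `dCachePU`
implements the full desk-scale analysis around that observation:

1. **Structural evidence layer.** From a protein--ligand co-structure,
   extract the residues whose heavy atoms lie within a distance cutoff
   of the bound ligand, with light-weight interaction labels.
2. **Alignment layer.** Anchor homologous sensor-domain sequences to the
   McpH reference, track reference positions through pairwise or
   multiple alignments, compute per-column conservation, and trim
   alignment columns by gap fraction.
3. **Motif layer.** Combine contacts and conservation into a motif --
   an ordered set of positions, allowed residue sets and spacing
   windows -- and scan sequences for it, either at tracked alignment
   columns or by spacings along the raw sequence.
4. **Cohort layer.** Classify receptor type from domain architecture
   and roll up motif variants by receptor class and taxonomy.
5. **Assay layer.** Fit one-binding-site isothermal titration
   calorimetry (ITC) isotherms and call thermal-shift melting
   temperatures with the strict >2 degC significance rule.
6. **Synthetic-data layer.** Generate planted-motif cohorts, one-site
   titrations and two-state melt curves with known ground truth, so
   that every stage is testable without any database access.

# The motif and its defaults

The default motif (`purineMotif()`) has five positions.  In McpH
numbering these are Y121, R129, W140, F167 and D169; the residues
between consecutive positions number 7, 10, 26 and 1.  The allowed sets
are the unions observed across experimentally characterized receptors:

| position | allowed | role |
|---|---|---|
| P1 | Y, F | hydrogen bond to the purine ring (Y121) |
| P2 | R, K, H | hydrogen bond to a ring carbonyl (R129) |
| P3 | W, F | aromatic stacking below the ligand (W140) |
| P4 | F, Y | aromatic stacking above the ligand (F167) |
| P5 | N, D | hydrogen bond to ring nitrogens (D169) |

A *companion* aromatic (F, Y or W) one residue after P3 (F141 in McpH)
is structurally conserved but does not contact the ligand; it is
required by default (`requireCompanion = TRUE`) and can be disabled.

In linear (spacing-window) mode each inter-position gap may deviate
from its center by up to 4 residues (1 for the adjacent P4--P5 pair),
absorbing small indels between motif positions.  Alignment-anchored
mode reads residues at the tracked reference columns and needs no
tolerance.  Both tolerances and residue sets are configurable
(`motifDefinition()`, YAML via `readMotifYaml()`), because the exact
bracket contents of the published motif figure are not machine-readable
and should remain data-driven.

When several position tuples satisfy the windows, the scanner reports
the tuple with the smallest total absolute spacing deviation, ties
resolved toward the leftmost positions -- a deterministic rule that
makes scans reproducible and is exercised against an independent
regular-expression oracle in the tests.

# Deriving the motif from data

`deriveMotif()` rebuilds the definition from a cohort: ligand-contact
positions (from `findLigandContacts()` on a structure) are kept when
their alignment columns are *consistently conserved*.  The source
analysis reports conservation qualitatively; we operationalize it as:
the residues individually reaching frequency `tauRes` (default 0.05)
among non-gap rows must together cover at least `tau` (default 0.9) of
the non-gap rows **and** number at most `maxSetSize` (default 4).  The
set-size cap encodes the biological reading of a motif position --
a site admitting only a few alternatives -- and cleanly separates
conserved binding positions from unconstrained contact positions in
cohorts; both thresholds are exposed as arguments.  Spacing windows are
set from the reference gaps with the default tolerances (gaps of two or
fewer residues get the adjacent tolerance).

# Structural contacts

Contacts are heavy-atom only: the 1.95-Angstrom-class structures this
rule is aimed at do not place hydrogens reliably.  A residue is a
contact when any of its non-hydrogen atoms lies within the cutoff
(default 3.5 Angstrom) of any non-hydrogen ligand atom; the contract is
the exhaustive all-pairs result, checked against a brute-force oracle.
Labels are deliberately light-weight bookkeeping: `hydrogen-bond-capable`
when the minimal-distance pair is N/O vs N/O at 3.5 Angstrom or less,
`aromatic-proximal` when an F/Y/W/H side-chain ring atom lies within
cutoff + 1 Angstrom of a ligand ring (C/N) atom.  Ring-plane geometry
is *not* verified -- stacking in the source analysis was assessed
visually, and a plane-angle test would add machinery without a ground
truth to validate against.  Protonation states are out of scope.

# Alignment choices

Pairwise anchoring uses BLOSUM62 with affine gap penalties (open 11,
extend 1), the standard protein defaults.  The default mode is
semi-global: terminal gaps in the query row are free, so a domain-sized
query anchors inside the full-length reference without penalty.  Scores
are verified against an independently written three-state affine-gap
dynamic program on exhaustively small problems.  Position tracking
requires the alignment's reference row to equal the anchor sequence;
a mismatch is an error rather than a silent misnumbering.

Column trimming follows the rule used for phylogeny preprocessing:
columns with gaps in 10% or more of rows are removed ("or more" is a
closed bound, matching the stated wording), unless fewer than 60% of
the columns would survive, in which case the 60% of columns with the
fewest gaps are kept (ties to the lower column index).

# ITC analysis

Raw injection heats (microcalories) are corrected by the
ligand-into-buffer dilution heats and normalized by the moles of ligand
injected; the first (small pre-)injection is excluded from fitting, as
is conventional.  The model is the single-site total-heat (Wiseman)
isotherm with displaced-cell concentrations

$$M_t = M_0\,\frac{1 - dV/2V_0}{1 + dV/2V_0},\qquad
  X_t = X_0\,\frac{dV/V_0}{1 + dV/2V_0},$$

$$Q = \frac{n M_t \Delta H V_0}{2}\left[\,b - \sqrt{b^2 -
      4X_t/(nM_t)}\,\right],\quad
  b = 1 + \frac{X_t}{nM_t} + \frac{1}{nK_A M_t},$$

with per-injection heats
$\Delta Q_i = Q_i - Q_{i-1} + (v_i/V_0)(Q_i + Q_{i-1})/2$, normalized
per mole of injectant.  Parameters $(n, K_A, \Delta H)$ are fitted by
Levenberg--Marquardt least squares on $(\log n, \log K_A, \Delta H)$
from three deterministic starts (a c-heuristic start, an $n=1$ start
and a weak-binding start); the best sum of squares wins, making the fit
seed-free and reproducible.  $K_D = 1/K_A$; standard errors are
asymptotic.  Units are centralized: concentrations mol/L, volumes L,
raw heats microcal, enthalpies kcal/mol.  The cell volume defaults to
1.4 mL, typical for the calorimeter class used for such titrations, and
is an explicit argument because published methods rarely state it.
A series whose corrected normalized heats span less than `flatTol`
(0.1 kcal/mol) is reported as "no binding detectable" rather than
fitted -- mirroring how flat titrations are reported in practice.
KD fold changes round half-away-from-zero, which reproduces published
integer fold reductions (e.g. 151/2.6 -> 58).

# Thermal shift analysis

Melt curves are smoothed with a centered moving average (window 7
points; the exact smoothing used upstream of published first-derivative
Tm values is unstated, so the window is an argument), differentiated by
central differences, and Tm is the temperature of the derivative
maximum over the scan interior, refined by three-point parabolic
interpolation.  A transition is only called when the peak exceeds three
times the median absolute derivative -- a ratio test, so calls are
invariant under affine transforms of the fluorescence, and linear
drifts or flat traces yield "no transition".  A ligand-induced shift is
significant only when Tm rises *strictly more than* 2 degC over the apo
protein; decreases are never significant.

# What the generators emulate -- and what they do not

`simulateCohort()` plants exactly one motif instance per positive
(variant drawn from configurable weights, spacings jittered within the
windows) in i.i.d. background sequences of 180--220 residues, the size
of a dCache_1 sensor region; positives are rejection-sampled until the
scanner provably recovers the planted tuple, and decoys until the
scanner finds nothing, so sensitivity/specificity checks are exact
rather than probabilistic.  Background composition is uniform by
default with a globular-domain preset available.  The generator does
*not* emulate phylogenetic correlation, compositional biases around the
pocket, or real indel processes -- so passing tests demonstrate the
correctness of the scanning logic under the stated geometry, not
real-database precision.  The published database-scale count of
motif-carrying proteins depends on a RefSeq snapshot and is explicitly
not a target.

`simulateItc()` produces heats from the same isotherm the fitter uses
(plus a constant dilution heat and Gaussian noise scaled to the largest
injection heat); round-trip tests therefore validate the optimizer and
parameterization, while the noisy-recovery tests (2% noise at
Wiseman c of about 10, the regime of the published titrations)
characterize statistical precision.  The default protocol is a 1.6 uL
pre-injection followed by eighteen 12.8 uL aliquots of 300 uM ligand
into 18 uM protein in a 1.4 mL cell.  `simulateMelt()` draws a
two-state sigmoid with a linear baseline on the 23--85 degC, 0.5 degC
grid of a standard plate-reader scan.

The bundled reference sequence is a synthetic stand-in: the published
binding-site, companion and ligand-contact residues sit at their
published full-length McpH positions over a fixed background (see the
FASTA header).  All position arithmetic, scanning and mapping behave
identically on the real sequence; only the non-site residues differ.

# Problem sizes and numerical notes

The shipped tests and the acceptance script use desk-scale sizes chosen
to characterize each stage: 16 noiseless titrations across
$K_D \in [0.5, 500]$ uM and $c \in [1, 1000]$ plus 200 noisy
replicates; 200 random pairs (length <= 8) against the alignment
oracle; 500 random blocks (<= 30 columns) against the trimming oracle;
100 positives + 1000 rejection-sampled decoys for scanning; 200 noisy
melt curves.  Degenerate inputs are handled explicitly: empty
sequences, absent ligands, ragged alignments, all-gap columns,
zero-enthalpy titrations and flat melt curves all produce typed errors
or explicit "no binding"/"no transition" outcomes rather than numeric
garbage.

# Known limitations

- The heavy-atom distance rule need not reproduce the exact published
  contact count for a given structure; interaction-viewer criteria
  differ in detail.
- One motif match is reported per sequence (minimal-deviation rule);
  genuine tandem sites would need `allCandidates = TRUE`.
- The one-site model does not cover multi-site or sequential binding,
  and melt curves are not analyzed thermodynamically (no van 't Hoff
  step).
- Receptor classification is rule-based on domain names; architectures
  with none of the trigger domains fall into "other".
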