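---
title: "From cysteine spacing to sequence space: methods behind hydrin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cysteine spacing to sequence space: methods behind hydrin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrin)
```

## The scientific problem

Hydrophobins are small (5–20 kDa) secreted fungal proteins defined by eight
conserved cysteines that form four disulfide bridges. Their classical
subdivision into Class I (amyloid-rodlet formers, highly variable sequences)
and Class II (compact, highly conserved, Ascomycota-only) rests on the
spacing of those cysteines and on assembly behaviour. Genome-scale surveys
have made it clear that "Class I" is heterogeneous: in particular, a
high-identity cluster of Basidiomycota Class I sequences (Class IB, typified
by *Schizophyllum commune* SC16 and SC3) is separable from Ascomycota Class I
(IA) and from the Class II cluster when sequences are projected into a
low-dimensional "sequence space".

hydrin implements that computational route end to end, with a synthetic-data
module standing in for the database mining that a survey would perform:

1. **Motif scanning** — find the canonical arrangement C, CC, C, C, CC, C
   (C1…C8 with adjacent doublets C2C3 and C6C7) and extract the seven
   inter-cysteine segment lengths plus tail lengths.
2. **Alignment** — global pairwise alignment (Needleman–Wunsch, affine
   gaps), identity/similarity over biologically meaningful spans, and a
   desk-scale progressive multiple aligner.
3. **Sequence-space PCA** — a pairwise substitution-score similarity matrix
   over alignment columns, double-centred and eigendecomposed; sequences get
   coordinates on PC1, PC2, …
4. **Subdivision** — an equal-sized rectangular grid over the PC1/PC2 plane,
   per-region composition labels (IA / IB / II / mixed / sparse) and
   majority-consensus sequences.
5. **Structure metrics** — Shrake–Rupley solvent accessible surface area
   (SASA) and its hydrophobic (carbon + sulfur) fraction, geometric
   disulfide detection, Kabsch superposition RMSD, average-mass molecular
   weight, principal-axis bounding dimensions, and the hydrophobic area
   buried between a helix and the β-barrel it packs against.
6. **Rodlet morphometry** — the four-step AFM image chain (unsharp mask,
   despeckle, threshold, ellipse-fit particle analysis with a 0–0.7
   circularity window) and distribution summaries of rodlet
   length/width/height.

## Canonical pattern and connectivity

A sequence is *strictly* canonical when it has exactly eight cysteines whose
consecutive spacings are (≥1, 0, ≥1, ≥1, ≥1, 0, ≥1) residues — the two zero
gaps are the CC doublets. A *tolerant* mode accepts sequences with more than
eight cysteines when some 8-subset forms the arrangement, and reports every
matching subset; this suits mining noisier collections where the strict rule
would discard borderline records. The published mining rule's minimum flank
counts are not recoverable from the source text, so both modes are provided
and documented rather than guessing thresholds.

Disulfide connectivity follows the family rule C1–C6, C2–C5, C3–C4, C7–C8.
For SC16 (cysteines at 33, 40, 41, 76, 89, 95, 96, 109 in precursor
numbering, reachable through `numbering_offset = 18`) the rule reproduces
all four experimentally observed bridges, two of which (C3–C4 = 41–76 and
C7–C8 = 96–109) connect β-strands within the barrel.

## Alignment conventions

Defaults are BLOSUM62, gap open 10, gap extend 0.5, with a gap of length
*k* costing `open + (k − 1) · extend`. Percent identity over a span is
*identical columns / all alignment columns in the span* (gapped columns
count in the denominator; a flag restricts to ungapped columns). Published
pairwise identity figures in this family rarely state their program or
span convention, so identity values carry a few points of
convention-dependent slack; the spans `"first_to_last_cys"` and `"core"`
(first cysteine to the C-terminus) are provided because those are the spans
such figures quote. Traceback ties prefer diagonal, then up, then left,
making alignments deterministic.

The progressive aligner builds a neighbour-joining guide tree (via
\pkg{ape}) from pairwise alignment distances (1 − fractional identity) and
merges profiles leaf-to-root, scoring profile columns by expected
substitution score with gap symbols contributing zero. It is intended for
simulated or curated sets of a few hundred sequences; larger or
publication-grade alignments should be produced externally (e.g. MAFFT) and
imported with `read_fasta_msa()` or `read_clustal()`.

## PCA of the alignment matrix

The similarity matrix is `S[i, j] = Σ_c score(row_i[c], row_j[c])` with
residue–gap and gap–gap columns contributing zero. `eigen_project()`
double-centres S (row means, column means, grand mean), eigendecomposes,
and scales eigenvector *m* by `sqrt(max(λ_m, 0))`. The original survey used
a GUI tool "with default parameters" whose internals are not printed; the
definition above is this package's normative, fully testable statement of
the computation. Its discriminative behaviour — Class II tightly clustered,
Class I spread, IA/IB separated — is what the acceptance checks assert, not
bit-level replication of any particular GUI. Components are ordered by
descending eigenvalue; signs are fixed so each component's
largest-magnitude loading is positive; eigenvalues below 1e-9 of the
largest are reported as zero.

## Region grid, labels and consensus

The occupied PC1/PC2 extent (padded by 1% of each range, split between the
two sides; degenerate ranges padded by 0.5) is covered by an `nx × ny` grid
of equal cells, half-open except the last cell along each axis. The
published figure drew 14 equal-sized rectangles by hand; their layout is
not recoverable, so the grid is configurable (default 7 × 2 = 14) and all
correctness claims are property-based (class recovery), not layout
replication.

Region labels use configurable purity thresholds (default 80%): II, then
IA (Class I + Ascomycota), then IB (Class I + Basidiomycota), then sparse
(fewer than 3 members), else mixed. Consensus letters are per-column
majorities (threshold 0.5 by default, `x` below threshold); the gap symbol
wins a column only as a strict majority, so half-gapped columns still
report their majority residue.

## Structure metrics

SASA uses the classic Shrake–Rupley test-point method with a deterministic
Fibonacci sphere (960 points/atom by default), probe 1.4 Å, and radii
C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å. "Hydrophobic" means carbon plus
sulfur atoms. The published 53% figure was produced with POPS, a
parameterised method; Shrake–Rupley with standard radii is used here as
the transparent, closed-form-testable computation, and tolerances on that
figure absorb the parameterisation difference. Ensemble metrics default to
model 1 of a deposited ensemble. Disulfides are detected geometrically
(Sγ–Sγ ≤ 2.5 Å, greedy by distance). Superposition uses Kabsch's SVD
solution with reflection excluded; degenerate (rank < 2) point sets error.
Molecular weight uses average residue masses plus one water, cysteines
reduced. Bounding dimensions rotate coordinates onto principal axes and
report extents ascending; for near-isotropic shapes the principal axes are
not unique, so dimensions are meaningful only for anisotropic molecules
(which hydrophobin monomers are). The published backbone RMSD values
against the two Class II reference structures depend on an unstated
superposition atom set; `kabsch_rmsd()` therefore requires an explicit
pairing and those values are not asserted anywhere.

## Rodlet morphometry

The chain reproduces the standard ImageJ sequence with documented,
deterministic operators: unsharp mask
`(img − w · gaussian(img, σ = radius)) / (1 − w)` with radius 2 px and
weight 0.6; a 3 × 3 median despeckle with replicate padding; Otsu's
threshold on a 256-bin histogram (the GUI default threshold is not
documented in the source; Otsu is the recorded choice, with a fixed
threshold available); 8-connected components; ellipse axes from
area-matched second central moments (each pixel contributes 1/12 px²
variance); perimeter from Moore boundary tracing with √2 diagonal steps;
circularity `4πA/P²` clipped at 1; mean height above the median of the
background (non-foreground) pixels — the deterministic analogue of manual
cross-sections.

Two measurement conventions are exposed by `summarize_particles()`. The
`"ellipse"` convention reports raw fit-ellipse axes, exactly as the GUI
chain would. The `"capsule"` convention inverts the analytic moment mapping
from a capsule (rectangle + semicircular caps) to its area-matched ellipse:
a 5:1 capsule's moment ellipse overstates its end-to-end length by ~9%, so
when the goal is recovering physical rod dimensions the inversion is the
appropriate estimator. The remaining biases of the full chain on simulated
fields are selection effects of the printed 0–0.7 circularity window
(short, low-aspect rods are censored, raising the measured length mean by
a few percent) and edge-exclusion of censored particles; both are inherent
to the published protocol and stay within the 15% recovery band asserted
by the acceptance checks.

## The synthetic-data generators

`gen_sequences()` emulates a mined hydrophobin collection with known truth.
Each class is a fixed residue template with class-specific inter-cysteine
segment lengths — Class II short and regular (7, 0, 11, 16, 8, 0, 6),
Class IA long-loop (10, 0, 26, 5, 18, 0, 18), Class IB with the SC16
spacing (6, 0, 34, 12, 5, 0, 12) — perturbed by per-site substitutions
(default 2%) and occasional single-residue indels (5% of sequences) that
never touch or fuse cysteines, so every record stays strictly canonical.
Phylum labels follow the class (IB Basidiomycota, IA/II Ascomycota). These
templates are stylized: they encode the field's qualitative description
(classes separable by spacing alone, Class II most conserved), not any
measured segment-length distribution, and sequences within a class are far
more homogeneous than real Class I families. Passing tests therefore
demonstrate that the pipeline recovers class structure *when it exists at
the stated noise levels*, not that real mined sets are this clean.

`gen_rod_image()` renders capsule-shaped rodlets with lengths ~N(15, 3²) nm,
widths ~N(5, 1²) nm and heights ~N(2, 0.4²) nm — the published distribution
centres for SC16 rodlets — at 0.5 nm/pixel on a 512² grid, lightly smoothed
(σ = 1 px) with Gaussian background noise (sd 0.1 nm, a typical AFM
roughness on graphite). Rods are placed without overlap and flagged when
they touch the border. Tip convolution and instrument artefacts are not
modelled. `gen_toy_structure()` provides ideal geometries (sphere pairs,
an ideal α-helix CA trace, a flat sheet) whose SASA and RMSD have closed
forms. All generators are bit-reproducible given a seed.

## Problem sizes and numerical choices

The shipped analyses and checks use 100 sequences per class (300 total) for
the sequence-space run, 60 rods per simulated field, 960 SASA points per
atom, and a few thousand randomized cases per property check (the scanner
is verified against an exhaustive 8-subset oracle on random ≤60-residue
sequences; the aligner against full alignment enumeration on all ≤3-length
pairs over a 3-letter alphabet plus sampled 4–6-length pairs). These sizes
keep a complete run in minutes on one core while leaving the statistical
margins of every assertion wide.

Known limitations: the progressive aligner is O(n²) in sequence count and
not intended beyond desk scale; identity values are convention-dependent at
the level of a few points; PCA coordinates are unique only up to component
sign; the morphometry chain inherits the censoring behaviour of the 0–0.7
circularity filter; and the published accession-based figures (53%
hydrophobic SASA, 10.8 kDa construct mass, 56%/42% identities) can only be
recomputed when the third-party deposits (PDB 2NBH; the SC16, SC3 and
PcaHyd1 sequence records) are supplied locally, as they are not
redistributed with the package.
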