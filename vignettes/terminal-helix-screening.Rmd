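---
title: "Terminal-helix screening and ICL3 fusion design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terminal-helix screening and ICL3 fusion design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixfuse)
```

## The problem and the model

A fusion tag destined for a GPCR's third intracellular loop must bridge the
cytoplasmic ends of TM5 and TM6 with two continuous helices. Geometrically
that reduces to three measurable properties of the candidate domain: it must
*have* terminal helices (long enough to carry a splice, close enough to the
chain termini that no flexible tail intervenes), those helices must run
close to antiparallel (TM5 points into the cytoplasm, TM6 back out), and
their splice-side ends must sit roughly as far apart as the TM5/TM6 ends
they will replace — about 10 Å. `helixfuse` turns each property into an
explicit measurement on the chain's Cα trace and screens structure corpora
chain by chain.

The screen's measurements are deliberately simple and fully deterministic:

* **Helix segments** come from the file's own secondary-structure
  annotation when present (`HELIX` records, `_struct_conf`), clipped to
  residues present in the coordinates. Only when a file carries no
  annotation — typically predictor output — does the package fall back to a
  geometric assignment; every record states which source was used.
* **Geometric assignment** marks residue *i* helical when the three forward
  distances Cα(i)–Cα(i+2), (i+3), (i+4) all fall inside conventional
  α-helical windows (5.5 ± 0.6 Å, 5.3 ± 0.6 Å, 6.4 ± 0.7 Å), and keeps
  maximal runs of ≥ 5 residues. The rule is windowed *forward*, so the last
  four residues of a helix are untestable and a geometrically assigned
  segment ends four residues short of the visual helix end. This is a known
  and accepted property of the estimator: the screen's thresholds are
  calibrated on annotated helices, and the geometric path exists to triage
  annotation-free models, where the same rule is applied uniformly to every
  model being compared.
* **The terminal pair** is the N-terminal-most and C-terminal-most segment;
  the screen does not search inner helices for a better-placed pair,
  because an inner helix cannot be spliced without leaving a dangling
  terminal segment.
* **Axes** are fitted per segment as the dominant principal direction of
  the centered Cα coordinates, sign-oriented N→C. A finite helix's circular
  component couples weakly to its axial coordinate, so the fitted axis of
  an ideal 12-residue helix tilts ~2.3° from the true axis (~9° at 8
  residues, vanishing as 1/n). This bias is inherent to the single-line
  estimator, affects both helices of a pair roughly equally, and is far
  smaller than the 40° margin between an antiparallel pair and the 140°
  gate; we accept it rather than introduce a curvature-aware fit.
* **Separation** is the distance between the Cα of the *first* residue of
  the N-helix and the Cα of the *last* residue of the C-helix. These are
  the chain-terminal-most ends — the atoms that actually splice onto TM5
  and TM6. The opposite reading (the inner, loop-facing ends) measures a
  different quantity and is not what junction geometry constrains.
* **The angle** is direction-aware: θ = arccos(d̂_N · d̂_C) with N→C unit
  axes, so antiparallel means θ → 180°, not |cos θ| → 1. A pair of parallel
  helices (θ ≈ 0) cannot bridge TM5→TM6 even though its axes are
  "aligned".

## Gates, score, and why both exist

Candidates pass through hard gates (helix length ≥ 8 residues, terminal
offset ≤ 5 residues, |d − 10 Å| ≤ 8 Å, θ ≥ 140°) and are then ranked by the
continuous score

$$S(d, \theta) = \max\left(0,\, 1 - \frac{|d - d_0|}{\Delta d}\right)
  \cdot \max\left(0,\, \frac{\theta - \theta_{\min}}{180° - \theta_{\min}}\right)$$

with d₀ = 10 Å, Δd = 8 Å, θ_min = 90°. The defining criteria fix the
length, offset and ~10 Å targets but no explicit antiparallelity tolerance
or distance window; those two defaults (140°, ±8 Å) are this package's
choices, exposed in `screen_criteria()` and echoed into every report so a
pure-threshold screen is reproducible by construction. Gates and score are
kept separate deliberately: the gates define *eligibility* (and let a user
reproduce a threshold-only screen), while the score orders eligible
candidates smoothly so a shortlist of any size can be cut without moving a
threshold. The score's maximum sits exactly at (10 Å, 180°); both factors
are piecewise-linear because nothing in the data justifies a sharper shape.

Every gate is evaluated and recorded even after the first failure, so a
report line is self-contained: the stored geometry plus the stored criteria
reproduce every verdict. Metadata curation (membrane/micelle/designed
keywords, deposited assembly size) automates the deterministic part of
manual curation; unknown metadata is reported `unknown` and never
silently passes or fails a chain, because most deposited files simply do
not state what a curator would know. A metadata *failure* withdraws the
score; an `unknown` leaves it, flagged for the user's judgement —
annotation tables (`thermophile`, `known_binder`) exist for exactly that
judgement, and the package does not attempt to infer thermophily from
taxonomy.

## Chimera design

Entry/exit semantics follow the splice itself: *entry* is the last retained
receptor residue before the tag, *exit* the first retained after it, so
replacing loop residues 235–244 is written entry 234 / exit 245 and the
deleted span is always `entry+1 … exit−1`. With this convention the
canonical bRIL-style control construct (tag in place of loop residues
235–244) is expressible verbatim, and the identity
splice (empty tag, exit = entry + 1) returns the receptor unchanged — a
useful degenerate case the tests rely on. Default candidate generation
takes the declared ICL3 span and steps both junction sets *inward* (entries
from span_start − 1, exits down from span_end + 1), five per side; the
actual residue choices per tag are user input, since no universal rule
survives contact with real loop architectures. All residue bookkeeping uses
author numbering; internal indices never appear in outputs. Expression-
cassette elements (signal peptides, purification tags) are outside the
chimera core on purpose — they do not affect junction geometry and belong
to cloning, not design.

## Model triage

Predicted chimera models are assumed renumbered 1..n (the dominant
predictor convention) with per-residue confidence in the B-factor column;
no separate confidence-file parser is provided. Junction windows cover
k = 4 residues on each side of each splice point — one helical turn plus
one residue — which is wide enough to catch a fraying junction and narrow
enough not to dilute it with bulk helix; `k` is a parameter. Helicity is
the fraction of window residues the geometric rule assigns helical
(1.0 ⇔ continuous); confidence is the plain mean of the window's Cα
B-factors. The superposition is the standard SVD construction with the
determinant sign guard, so a degenerate (near-planar) mapping can never
return a reflection. Clashes are heavy-atom pairs across the declared
tag/receptor domains closer than 3.0 Å — far below van der Waals contact,
so every hit is an unambiguous problem, not a judgement call — with pairs
< 3 residues apart in sequence excluded as bonded neighborhood; a
vdW-overlap mode was considered and deferred, since the hard cutoff is
already conservative. The composite ranking is lexicographic (continuity,
clash count, mean junction confidence, RMSD, name) rather than a weighted
sum: the four criteria are incommensurable, and a lexicographic key is
reproducible and explainable to the person choosing one construct per tag.
The membrane/micelle is not modelled; a clash against the bilayer is
outside this package's scope and must be judged on the model.

## Structure I/O policies

Only model 1 of multi-model files is read — the screen measures a single
conformer, and mixing NMR models would average incompatible geometries.
Alternate locations resolve to the highest occupancy, ties to the
alphabetically first altloc id, making repeated runs byte-reproducible.
Waters and het entities are stripped before measurement; chemically
modified amino acids (MSE and kin) stay in the polymer and map to their
parent one-letter codes, unknowns to `X`. Deposited assembly size is read
from the file's assembly records when present and is otherwise `unknown` —
never assumed monomeric. The PDB writer refuses chains that overflow the
fixed-width format (> 9999 residue numbers) and points to mmCIF instead.

## What the synthetic fixtures do and do not show

The generator builds ideal helices (1.5 Å rise, 100°/residue, 2.3 Å Cα
radius — textbook α-helix constants), hairpins whose anchor Cα atoms are
*placed* at the requested separation so `terminal_separation` has an exact
expected value, mock fusion models realized as one continuous ideal helix
(broken junctions are made by displacing the four tag-side window residues
off the helical curve), and seeded corpora in which every negative violates
exactly one named criterion. Manifests record the ground truth, and the
test suite's central property is that the measurement modules reproduce
every manifest value within stated tolerances.

What passing these tests shows: the measurements, gates, score, splice
arithmetic and ranking implement their definitions exactly, deterministically,
and stably under rigid motions, file order and re-runs. What it does not
show: performance on real deposited structures — real helices kink, fray
and bend; real files have gaps, insertion codes and inconsistent
annotation; real curation involves literature judgement. The fixtures have
none of these properties by design (no sidechains, no Ramachandran
validity), so results on real corpora should be spot-checked, and the
`unknown` metadata flags exist precisely because the automatable part of
curation ends where the files' self-description ends.

## Problem sizes and numerical details

The test suite runs hairpins of 20–40 residues, corpora of 6–10 files,
chimeras of ~300–380 residues and superpositions of ≤ 380 Cα pairs; the
calibration scan in `scripts/acceptance.R` covers 37 hairpins on a 0.5 Å
separation grid. These sizes make every expected value checkable by brute
force while exercising the same code paths a real corpus would.
Floating-point policies: axis directions are unit to 1e-9 and equivariant
under rotation to 1e-6; fixture coordinates are written at PDB precision
(1e-3 Å), so measured separations agree with declared ones to ~2e-3 Å;
score ties cannot occur on the scan grid because the separation factor is
strictly unimodal. Degenerate inputs are errors with typed conditions
(< 4 Cα for an axis fit, < 3 pairs for a superposition, empty structures,
overlapping domains), not silent results; absence of a terminal pair is a
value (`reason` code), not an error, because a screen must keep walking the
corpus.

## Known limitations

Single straight-axis fits (no kink decomposition); forward-windowed SSE
assignment truncates geometric segments by four residues; only Cα RMSD is
computed (predictor-internal alignment metrics are not read); no membrane
plane; no automated thermophily or oligomer-state inference beyond the
file's own records; the shortlist produced on any real corpus is a
*candidate* list — the literature work that turns candidates into a final
set of tags is out of scope by design.
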