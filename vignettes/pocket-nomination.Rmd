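---
title: "Nominating a ligand-binding pocket by conservation-weighted consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating a ligand-binding pocket by conservation-weighted consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketcons)
```

## The model

The package addresses a recurring situation in computational toxicology and
off-target discovery: a small molecule (the motivating case is TCDD, the
prototypical dioxin) is suspected of binding a receptor (a VEGFR1 domain)
for which no co-crystal structure exists, while a well-characterized
reference ligand-binding domain (the AhR LBD) is known to bind the same
ligand. The working hypothesis is that the true binding pocket on the new
receptor is *enriched in residues that are evolutionarily compatible with
the reference domain*: if pocket detectors propose several candidate
cavities, the one whose lining atoms disproportionately belong to residues
identical or conservatively substituted in a reference-domain alignment is
the best candidate.

Formally, let $T_a$ be the number of heavy atoms of the receptor polymer,
$TC_a$ the heavy atoms belonging to residues classed identical or conserved
in a global alignment with the reference domain, and $P_a$ the heavy atoms
lining a candidate pocket, of which $OP_c$ are conserved. If conserved atoms
were spread uniformly, a pocket of $P_a$ atoms would contain

$$EP_c = \frac{TC_a \cdot P_a}{T_a}$$

conserved atoms. Each pocket is scored by the enrichment ratio $OP_c/EP_c$,
by the Poisson probability mass at the observed count,

$$p = e^{-EP_c}\,\frac{EP_c^{OP_c}}{OP_c!},$$

and by a descriptor that re-applies the Poisson form to the ratio itself,
$\lambda^{r}e^{-\lambda}/\Gamma(r+1)$ with $r = OP_c/EP_c$ and $\lambda$ the
mean ratio over the candidate set. The nominated pocket maximizes the ratio,
with ties broken by the lowest $p$, then the largest $P_a$, then pocket
identifier.

Two modelling caveats are deliberate and documented rather than hidden. The
Poisson mass is a *point* probability, not a calibrated tail probability: it
ranks pockets but should not be read as a significance level (an
`upper_tail` mode, $P(X \ge OP_c)$, is provided for users who want a proper
tail). And the descriptor's "factorial of a ratio" is only meaningful
through the gamma function, $\,(r)! \equiv \Gamma(r+1)$; the printed formula
it descends from is typographically ambiguous, so both the ratio and the
descriptor are reported and either can be ranked on — selection uses the
ratio.

## Consensus before conservation

Pocket detectors score in incommensurable units (contact areas, cavity
volumes, grid counts). Before conservation scoring, each detector's raw
scores are standardized within the detector — $z_i = (s_i - \bar s)/\hat s$
with the sample ($n-1$) standard deviation — and the top $k=3$ pockets per
detector are taken forward. Because a z-score is invariant under strictly
increasing affine transforms, selection depends only on each detector's
internal ordering; this invariance is property-tested with random affine
rescalings. Detectors that emit no comparable score (solvent-mapping
servers) load with `NA` scores and are excluded from the ranking rather
than silently given z = 0. Degenerate cases are defined, not accidental: a
single-pocket detector gets $z=0$ and rank 1; zero-variance scores warn and
fall through to the tie-break (larger lining set, then lexicographic
pocket id).

## Alignment conventions

The reference domain is aligned to the receptor with Needleman–Wunsch and
affine gaps, frozen to the EMBOSS Needle defaults: BLOSUM62, gap open 10,
gap extend 0.5, end gaps free. The gap cost convention is
$\mathrm{cost}(L) = \mathrm{open} + \mathrm{extend}\cdot L$ — a length-1 gap
costs 10.5 — which is also the convention of
`Biostrings::pairwiseAlignment`, so alignment scores can be (and are)
cross-checked against an independent implementation exactly; with
`gap_open = 0` the model degenerates to a linear gap penalty, which is how
the aligner is validated against a brute-force linear-gap dynamic program.
Traceback is deterministic with tie-break diagonal > gap-in-target >
gap-in-reference. A column is *identical* when both letters agree,
*conserved* when they differ but score strictly positively (the EMBOSS
"similar" convention — the source chain never defines "conserved", so the
definition is fixed here). Percent identity uses the full alignment length
including gap columns, the Needle convention; note that BLAST-style
identities (matches over aligned columns only) run slightly higher, which
matters when comparing against identity values quoted from other tools.

Heavy atoms only are counted everywhere ($T_a$, $TC_a$, $P_a$, $OP_c$):
crystal structures typically lack hydrogens, and mixing conventions would
silently rescale the enrichment statistic. Nonstandard residues map to `X`
for alignment (never identical, never conserved — `X` scores −1 against
everything including itself) but keep their heavy atoms in all counts.
Residues are publicly identified by author numbering (`chain:res_seq`, plus
insertion code when present) with no renumbering, because pocket-server
output uses author numbering. Alternate locations resolve to the highest
occupancy conformer, first on ties.

## Docking and trajectory operators

Binding free energies convert to inhibition constants with
$K_i = e^{\Delta G/RT}$, $R = 1.98720425864083\times10^{-3}$ kcal/mol/K and
$T = 298.15$ K by default — the reporting convention of the docking engine
whose outputs the converter consumes; both are parameters. The conversion
round-trips with its inverse to $10^{-12}$ relative. The printed literature
pairs it is checked against carry ~1% slack because published $K_i$ values
derive from unrounded energies while the check starts from the rounded
printed value.

Hydrogen bonds use the common geometric criterion: donor–acceptor distance
≤ 3.5 Å and, when a hydrogen is assigned to the donor, H–D–A angle ≤ 30°,
both boundaries closed (the g_hbond defaults). Structures without hydrogens
are evaluated in distance-only mode and each record says so.

Trajectory metrics take multi-MODEL PDB frames (internally Å, reported nm).
RMSD fits each frame to a reference frame by Kabsch superposition (SVD,
proper rotation enforced; near-collinear selections are refused rather than
silently fit). RMSF fits frames to the iterated time-average structure (two
passes) and reports per-residue root-mean-square fluctuation. The radius of
gyration is mass-weighted by default. The mean smallest-distance matrix
caps residue-pair minimum heavy-atom distances at 1.5 nm (the g_mdmat
default) and averages over frames; both the off-diagonal mean and the plain
sum are reported, because aggregate values quoted in the literature for
such matrices do not always state their normalization.

## What the generator emulates — and what it does not

The synthetic module exists so every stage has ground truth without network
access. `make_toy_structure` builds an ideal α-helical backbone (1.5 Å
rise, 100°/residue, Cα–Cα ≈ 3.8 Å, backbone + CB heavy atoms): valid
geometry for atom counting, superposition and distance matrices, but no
side-chain rotamers, no packing, no secondary-structure diversity.
`make_homolog_pair` implants an exact per-position truth — requested
fractions of identical positions and of conservative (BLOSUM62-positive)
substitutions, everything else non-conservative; glycine and proline admit
no positive-scoring partner, so conservative positions are sampled only
where feasible. It is indel-free by default so conservation projects onto
residues exactly; an indel mode exists for aligner stress tests.
`make_pocket_fixture` implants one pocket whose conserved-residue count is
exactly the rounded target density (background density ρ for decoys,
min(1, enrichment·ρ) for the true pocket) and emits two detectors' scores
on different scales; pocket labels are randomly permuted so lexicographic
tie-breaks cannot favour the implanted pocket — at enrichment 1 the
construction is fully exchangeable across pockets, which is what makes the
null calibration meaningful. `make_trajectory` applies per-frame rigid
motion plus iid isotropic Gaussian coordinate noise.

The noise model has closed-form expectations, which the tests use: with
per-coordinate noise σ, post-fit RMSD against a (equally noisy) reference
frame tends to $\sigma\sqrt{6}$ — the factor $\sqrt 2$ relative to the
often-quoted $\sigma\sqrt 3$ comes from the reference frame's own noise —
and RMSF about the time-average structure tends to $\sigma\sqrt 3$. The
superposition fit absorbs 6 of $3N$ degrees of freedom, so measured values
sit a percent or two below these limits at the test sizes; the tests allow
5%. Passing these tests demonstrates correctness of the operators on this
noise model; it says nothing about force fields, solvent or conformational
sampling, which are outside the package entirely.

## Problem sizes and defaults

The demo workspace defaults were chosen once as a realistic, clearly
detectable scenario: a 100-residue single-chain target, 35% identical + 15%
conservatively substituted positions against the reference domain (at
twilight-zone identities the alignment stage cannot recover implanted
conservation, and the demo is meant to exercise the full chain, alignment
included), five candidate pockets of 8 residues (~40 heavy atoms), 2×
conservation enrichment in the implanted pocket, and 100-frame trajectories
with 0.3 Å coordinate noise at 2 ps spacing. Recovery statistics use 200
replicates of the 5-pocket/80-residue configuration; trajectory
expectations use 2000 frames at σ = 0.1 Å; the brute-force mdmat oracle
runs on 6 residues × 3 frames where exact equality (not approximation) is
asserted.

## Known limitations

- mmCIF, bond perception, assembly generation and binary trajectory
  formats are out of scope; trajectories travel as multi-MODEL PDB.
- Donor/acceptor roles are supplied explicitly, not perceived from
  chemistry.
- The Poisson mass is not corrected for testing multiple pockets, matching
  the scoring scheme it implements; treat the p-values as ranking scores.
- Sequence identity follows the Needle convention; comparisons against
  BLAST-derived identities can differ by a few points.
- The aligner is quadratic-time, pure R: fine for domain-scale sequences
  (hundreds of residues), not for proteome scans.
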