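---
title: "Methods: event-driven DMD and the misfolding analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-driven DMD and the misfolding analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqdmd)
```

## Scope and model

`polyqdmd` studies the misfolding propensity of polyglutamine peptides and
huntingtin exon1 constructs with a pipeline of six stages: construct
assembly, event-driven discrete molecular dynamics (DMD) under replica
exchange, WHAM thermodynamics, compact-ensemble screening, dihedral
secondary-structure profiling, and single-linkage RMSD clustering.

Three constructs are modelled at glutamine repeat lengths n = 23, 36, 40
and 47: the isolated homopolymer Q_n; full exon1 (XN1), which is the
17-residue N-terminal segment (Nt17), the polyQ tract, an 11-proline run,
a 17-residue proline-rich tether, a 10-proline run and a 12-residue
C-terminus (n + 67 residues in total, 90 for n = 23); and the
polyproline-deleted variant (n + 46 residues). The deletion variant is
built by removing the P11 and P10 runs *seamlessly* — no linker is
inserted; this is the natural reading of "identical except that it does
not contain the polyproline regions", and it is asserted by the test that
deleting both runs from XN1 reproduces the variant exactly. Residue
indexing is 0-based half-open internally and 1-based in report output.

### Units

Energies are kcal/mol, lengths Å, temperatures kcal/mol/k_B (one unit is
1 kcal/mol ÷ k_B ≈ 503.22 K, i.e. "about 500 K"; the rounded 500 K/unit
conversion is also provided since either may be used for a Kelvin axis),
and times are simulation time units (tu) with 1 tu ≈ 50 fs, so 500 tu
≈ 25 ps and 10⁶ tu ≈ 50 ns.

## The DMD engine

Each residue contributes three beads (N, Cα, C). Every continuous pair
potential is reduced to square wells: strictly ascending boundary
distances, one energy per shell, zero outside the outermost boundary, a
hard core inside the innermost. `discretize_potential()` evaluates a
continuous potential at shell midpoints. Between events beads travel with
constant velocity; at a boundary the radial component `v_r` of the
relative velocity of the two colliding beads is updated with the reduced
mass `mu`: a step of height `dU` transmits with
`v_r' = sign(v_r) * sqrt(v_r^2 - 2 dU / mu)` when the radial kinetic
energy suffices, otherwise it reflects (`v_r' = -v_r`). Hard cores and
bond walls always reflect. Because the impulse is central and only the
two partners change, linear momentum, angular momentum about the pair
midpoint, and total energy are conserved to round-off; the test suite
checks ≤ 1e-6 relative drift over ≥ 1e4 collisions (observed: ~1e-14).

The force field is deliberately minimal — the published all-atom
force-field results are not the target, the algorithms are:

* bonds N–Cα 1.46 ± 0.03 Å, Cα–C 1.53 ± 0.03 Å, C–N(next) 1.33 ± 0.03 Å
  (hard walls both sides);
* 1–3 pseudo-angle wells at the ideal-geometry distance ± 0.12 Å, fixing
  bond angles near 111–122° while leaving torsions free;
* a 2.0 Å hard core for all pairs separated by ≥ 3 bonds;
* a single attractive well (outer edge 6.0 Å) of depth 0.15 kcal/mol for
  generic pairs and 0.5 kcal/mol for glutamine Cα–Cα pairs.

These defaults were chosen once so that the attraction scale sits inside
the replica temperature ladder, giving a genuine coil–globule collapse
(mean Rg at low temperature below high temperature; heat-capacity peak in
range) — they are the package's study conditions, not tuning knobs.

The thermostat is Andersen-style: ghost collisions at exponentially
distributed intervals (default rate 1 event/tu; higher in equilibration
tests) redraw one random bead's velocity from the Maxwell–Boltzmann
distribution. The box is periodic with edge 1.2 × the fully extended
contour length, satisfying "large enough to fit the extended polypeptide"
with margin; pair vectors use the minimum-image convention, and saved
chains are unwrapped by walking the backbone. Each run starts from the
fully extended (all-trans) conformation; frames saved during the first
500 tu are flagged as equilibration and excluded from analysis by
default. The alternative reading of the discard span as the first 0.5% of
the trajectory (i.e. 5000 tu of 10⁶) differs by a factor of ten; the
package defaults to 500 tu and exposes the span as the `discard`
argument, so either convention is one keystroke away.

Numerical choices: event times are the earliest positive roots of
|r + v t|² = d², computed per pair against the current shell's inner and
outer boundaries only (any other boundary requires crossing these first);
per-pair shell indices are tracked explicitly so that a pair sitting
exactly on a boundary is never misclassified; events closer than 1e-12 tu
process in queue-insertion order (deterministic tie-break); stale events
are discarded lazily via per-bead collision counters. All randomness
flows through R's RNG, so a single `set.seed()` reproduces a run
bit-for-bit.

## Replica exchange

Defaults mirror the study protocol: eight replicas at
{0.85, 0.75, 0.68, 0.64, 0.6, 0.57, 0.53, 0.5}, swap attempts every
500 tu, 10⁶ tu per replica, one saved conformation per 10 tu per replica
(800,000 structures per simulation). A swap between temperatures T_i and
T_j with energies E_i, E_j is accepted with probability
min(1, exp[(1/T_i − 1/T_j)(E_i − E_j)]) — detailed balance for
temperature exchange. Two details are unstated in the protocol and were
decided here: at each swap epoch *all* adjacent pairs of alternating
parity are attempted (odd epochs 1–2, 3–4, …; even epochs 2–3, 4–5, …),
which is standard and improves mixing; and the swap exchanges
temperatures rather than coordinates, rescaling both replicas' velocities
by sqrt(T_new/T_old) — the ensembles are equivalent and per-replica
trajectory bookkeeping stays simple.

## WHAM

`solve_wham()` iterates the two coupled equations (k_B = 1)

> Ω(E) = Σ_k h_k(E) / Σ_k N_k exp(f_k − E/T_k),
> exp(−f_k) = Σ_E Ω(E) exp(−E/T_k)

from f_k = 0, in log-domain arithmetic throughout, with gauge f_1 = 0,
until max |Δf_k| < 1e-7 (cap 1e5 iterations). Replicas with
non-overlapping energy support are refused. Heat capacity follows from
the fluctuation formula C_V(T) = (⟨E²⟩_T − ⟨E⟩_T²)/T², with moments
computed by log-sum-exp and centred for stability. The energy bin width
defaults to Freedman–Diaconis on the pooled energies; it is a nuisance
parameter exposed as config. (The supplementary description of a
"1 cal/mol" energy bin alongside kcal/mol force-field energies is treated
as a units typo; nothing is hard-coded.)

`find_transition()` takes the grid argmax refined by a local quadratic
through the three surrounding points; ties go to the lower temperature; a
curve with no interior maximum returns an explicit no-peak result; and a
peak whose prominence is below 10% of the curve range is flagged
non-cooperative — the operational version of a "broad and shallow" peak,
with the threshold exposed. `average_transition_temperature()` is the
arithmetic mean over models of one construct, with reduced→Kelvin
conversion at either 503.22 or the rounded 500 K/unit.

## Compact-ensemble screening

The analyses focus on compact, low-energy conformations. Since no
algorithm is published for either cutoff — only histograms with dashed
lines — the package declares reproducible rules and logs the chosen
values, with manual override:

* **Rg cutoff** — histogram at 1 Å bins; the cutoff is the smallest bin
  edge above the mode where counts first fall below 10% of the modal
  count. On a Gaussian Rg sample shaped like the worked instance (mode
  ~16 Å), the rule lands at 19–21 Å, consistent with the published 20 Å.
* **Energy cutoff** — a two-component Gaussian mixture on pooled energies
  ("the lowest energy Gaussians"); cutoff = μ_low + 2σ_low. When the
  components overlap within twice the larger σ the fit is degenerate and
  a lowest-decile fallback applies, with a warning.

Membership is inclusive (Rg ≤ cutoff AND E ≤ cutoff; equality counts as
compact). Errors on ensemble probabilities use
sqrt(p(1−p)/n_events), where n_events counts the crossings of the energy
cutoff by the time-ordered energy series — both entries and exits, the
literal reading of "enters or exits the compact domain"; values exactly
at the cutoff attach to the preceding sign. Crossings are counted per
replica and summed.

## Secondary structure

φ (C(i−1)–N–Cα–C) and ψ (N–Cα–C–N(i+1)) follow the IUPAC sign convention
in (−180°, 180°]; termini have undefined φ or ψ and are excluded with the
denominator adjusted. The Ramachandran basin rectangles are declared
defaults (no boundaries are published): α φ∈[−100,−30], ψ∈[−80,−5];
β φ∈[−180,−45], ψ∈[90,180] ∪ (−180,−160]; turn φ∈[30,100], ψ∈[−20,80];
coil elsewhere. The four classes partition the torus (asserted by a 1°
grid scan). Polyproline-II (φ∈[−90,−55], ψ∈[120,170]) is carved out of
the β basin only when explicitly enabled, because the published
probability scheme is four-class — whether its β basin included the PPII
region cannot be determined from the text, so the flag defaults to off
and `BETA(off) = BETA(on) + PPII(on)` pointwise is a tested identity.
Region averages are arithmetic means of per-residue probabilities over a
region mask.

## Clustering

Structures entering clustering are time-separated by ≥ 50 ps (1000 tu),
selected greedily earliest-first, then capped at a target count
(default ≈ 2000, matching the study's ~1500–2000 with ~1% of compact
structures). RMSD is computed on Cα beads after optimal superposition
(proper rotations only); whether the published RMSD was superposed or on
raw coordinates is unstated, but raw RMSD on freely rotating simulation
frames is meaningless, so superposition is assumed, and Cα-only is the
common convention for a backbone model. Single linkage at cutoff c is
implemented as union-find connected components over edges with D < c
(strict), which is exactly the minimum-distance criterion; the
independent oracle in the tests is flood-fill components and
`hclust`/`cutree`. Default cutoffs: 2.0 Å, with 2.5 Å for the longest
no-polyP model. Centroids minimize the within-cluster distance sum; all
ties (centroid, merge order) break to the lowest index for determinism.
The cutoff-vs-cluster-count curve is monotone non-increasing from n to 1;
the suggested cutoff is the midpoint of the widest merge-height gap —
after similar structures join, before dissimilar ones do.

## Synthetic data: what it does and does not show

The generators provide ground truth for every stage: ideal backbones with
prescribed dihedrals (canonical α −57/−47, β −120/130, PPII −75/145,
turn 60/30) built by NeRF-style internal-to-Cartesian construction with
shared geometry constants, so dihedral computation is validated by exact
round-trip; telegraph energy series with recorded switch times for the
crossing counter; i.i.d. Boltzmann draws from a known density of states
for WHAM recovery; and perturbed template blobs with known labels for
clustering. All generators are bit-reproducible under a fixed seed.

Passing these tests shows the *algorithms* are correct. It does not show
that the simplified force field reproduces published force-field-dependent
numbers — heat-capacity peak heights, β-strand percentages, cluster
counts and fractions all depend on the original all-atom energy model and
~50 ns sampling, and are explicitly out of scope. The quantities that are
reproduced exactly are the protocol arithmetic (frame counts, construct
lengths, unit conversions) and the in-text averages of the published
per-model transition temperatures (311 K for XN1, 340 K for the no-polyP
construct).

## Problem sizes

The test suite and acceptance script run at desk scale by choice: Q_8
(24 beads) for engine and pipeline checks (NVE conservation over ~1e5
collisions; equipartition over 4000 tu; smoke pipelines of 2 replicas ×
2000–3000 tu), WHAM recovery at 1e5 samples per replica across the eight
study temperatures, clustering oracles up to n = 200 structures, and 1°
torus scans for the classifier. The full study protocol (8 replicas ×
10⁶ tu × 12 models) is expressed by the same defaults
(`replica_schedule()`, `run_config()`) and differs only in duration.

## Known limitations

* No electrostatics, hydrogen bonding, side chains or implicit solvent:
  the backbone force field produces collapse, not realistic secondary
  structure propensities.
* Masses default to uniform 1 (united-atom N = 15, Cα = 13, C + O = 28
  available as an option); the mass convention does not affect any
  reported observable.
* WHAM reports no error bars on C_V (none are published to compare
  against) and no MBAR-style binless estimator is provided.
* The minimum-image convention is applied at event-scheduling time; with
  the default box (1.2 × contour length) and short-ranged wells this is
  exact for all interacting pairs, but very small boxes are not
  supported.
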