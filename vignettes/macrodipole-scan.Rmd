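---
title: "Transition-state macrodipole stabilization scans: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition-state macrodipole stabilization scans: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipolescan)
```

## The problem

Enzyme catalysis is differential stabilization: the protein environment
must stabilize the transition state (TS) of the rate-limiting step more
than the reactant (R). When the step is an internal charge rearrangement —
here modelled after a proton transfer in which a substrate oxygen develops
negative charge while a catalytic carboxylate is partially neutralised —
every charged or polar residue around the active site tilts the barrier one
way or the other. Residues that stabilize the *reactant* charge
distribution more than the TS one are **anticatalytic**: replacing their
charged side chain with a neutral isosteric one is predicted to speed the
enzyme up. This package implements the computational mutagenesis ledger
that finds them.

## The ledger

For the wild type, the electronic barrier is
$\Delta E_\mathrm{wt} = E_{TS} - E_R$. Deleting residue $m$ from the model
in both states and recomputing single-point energies gives
$\Delta E_m$, and the residue's contribution is

$$\Delta\Delta E_{m-\mathrm{wt}} = \Delta E_m - \Delta E_\mathrm{wt}.$$

A residue with $\Delta\Delta E < 0$ was holding the barrier *up*
(anticatalytic); one with $\Delta\Delta E > 0$ was helping. Candidates for
rate-enhancing mutation are charged residues with
$\Delta\Delta E < -1$ kcal mol⁻¹ (strict inequality throughout). The
ledger applies no zero-point, thermal, or entropic corrections: it compares
raw state energies, which is the appropriate scale for a conceptual
deletion experiment. `compute_barriers()` implements exactly this
arithmetic on externally supplied energy tables (CSV, kcal/mol or hartree
with the factor 627.509474).

## The point-charge surrogate

Full deletion experiments run hybrid QM/MM single points. The surrogate in
`deletion_scan()` replaces the quantum core with its per-state point-charge
distribution and evaluates each residue's interaction with it by vacuum
Coulomb sums,

$$V = k \sum_{i \in \mathrm{res}} \sum_{j \in \mathrm{QM}}
\frac{q_i q_j}{r_{ij}}, \qquad k = 332.0637\
\mathrm{kcal\,Å\,mol^{-1}\,e^{-2}},$$

with no cutoff and no periodicity, matching the embedding-field character
of electrostatic embedding. Under the **rigid-environment assumption** —
environment coordinates and charges identical in R and TS — all residue-
internal and residue-environment terms cancel exactly in
$\Delta\Delta E_m$, leaving only the residue–QM terms:

$$\Delta\Delta E_m = -(V_{TS}(m) - V_R(m)).$$

This is the surrogate's defining approximation. It preserves the physics
the selection rule relies on — the sign and distance dependence of each
residue's differential stabilization — but it makes no attempt to
reproduce absolute QM/MM magnitudes for any real enzyme, and the wild-type
barrier is therefore an *input* (`dE_wt`, default 10.6 kcal mol⁻¹, a
typical electronic barrier for the class of proton-transfer steps this
models), not a computed quantity.

Two consequences are tested as invariants: per-residue shifts sum to the
negated total environment differential (additivity of pairwise sums), and
shifts are linear in the transferred charge fraction $\lambda$.

### The sign law

When a unit charge moves from a donor site to an acceptor site between R
and TS, a probe charge $q$ at distances $r_d, r_a$ from the two sites has

$$\Delta\Delta E = k\,\lambda\,q\left(\frac{1}{r_d} - \frac{1}{r_a}\right),$$

so a *positive* residue nearer the acceptor (or a negative residue nearer
the donor) is anticatalytic, and the magnitude decays as the probe
retreats. This is the macrodipole selection rationale, and it is enforced
as a property test over randomised geometries.

## Eligibility

`select_eligible_residues()` operationalizes "within 10 Å of the active
site" as: minimum distance from any residue atom (hydrogens included) to
any QM-region atom, evaluated on the reactant structure, ≤ radius. Gly and
Pro are excluded (no charged, freely mutable side chain), as are residues
overlapping the QM region. The QM atom set — rather than a larger pocket
definition — was chosen as the distance reference because it is the only
unambiguous, input-defined notion of "active site region"; the radius is a
plain argument, so a pocket-based caller can pass its own list instead.

## The synthetic study system

`make_toy_enzyme()` generates the fixture the validation suite runs on:

* a 5-atom QM core with a donor site and an acceptor site 4 Å apart;
  between R and TS, charge $\lambda$ (default 0.5 — a transition state with
  the transferring proton halfway along the coordinate) moves donor →
  acceptor; total charge is conserved to < 1e-12 e by construction;
* 30 environment residues: six planted charged residues reproducing the
  expected candidate pattern (acidic near the donor, basic near the
  acceptor, at 8–9.5 Å so all sit inside the 10 Å shell with
  $|\Delta\Delta E| \gg 1$), one neutral dipolar tyrosine-like residue
  with a large negative shift (a large-effect residue that must *not* be
  proposed, since no charge can be cancelled), one charged-but-buried
  control caged by neutral dummies on the bisecting plane, and random
  polar/apolar residues on a 12–18 Å shell with small partial charges;
* per-residue ground-truth $\Delta\Delta E$ evaluated by an explicit
  two-centre double loop over the QM charge *increments* — a code path
  independent of the scan engine, which evaluates two full state energies.

What the generator deliberately does not emulate: conformational response
to deletion or mutation, polarization and charge transfer, solvent
screening, and MM-internal energetics. Passing tests therefore demonstrate
the correctness of the ledger arithmetic, the scan engine, and the
selection logic — not the accuracy of a point-charge model for any real
protein.

`make_trajectory()` produces i.i.d. Gaussian positional jitter around a
reference (frame 1 is the reference itself), enough to validate RMSD and
distance-monitor statistics; it has no dynamics, correlations, or
thermostat. `make_energy_table()` plants known shifts in a state-energy
table, optionally with Gaussian noise per energy, for ledger round-trip
and robustness checks.

## Geometry analyses

`kabsch_rmsd()` performs least-squares rigid superposition via the SVD
construction with the determinant correction (proper rotations only),
unweighted per-atom, with separate fit and measure selections — fitting on
a backbone-like set and measuring on an active-site set is the intended
use. Degenerate fits (< 3 atoms, collinear sets) are rejected. The test
oracle is a numeric optimisation over Euler angles from a grid of starts,
sharing no algebra with the implementation.

`monitor()` tracks fixed atom pairs or min-over-set pairs per frame.
Min-over-set monitors also report each member's own mean, which is how the
asymmetry of a carboxylate (one oxygen consistently nearer the probe than
the other) or the equivalence of ammonium protons is exhibited.

## The advisor

`build_report()` applies three filters: $\Delta\Delta E < -$threshold
(strict), charged residue type, and absence from the exclusion list of
mechanistically required residues. Charged types are ASP/GLU/LYS/ARG by
name, plus HIS only when its recorded charges sum to a nonzero integer
(protonation is an input property, not something the package infers).
Large-effect residues failing the last two filters are reported in a
separate ineligible section with the reason — they are informative even
when unmutatable.

Substitutions cancel the side-chain charge while retaining size and
polarity: Glu→Gln, Asp→Asn, Lys→Gln. Arg has no conventional neutral
isostere; the shipped default maps Arg→Gln rather than silently dropping
arginine candidates, and the mapping is config-overridable.

Exposure and hydrogen-bond freedom are geometric proxies, reported as
annotations (never filters): a charged group is "exposed" when at most 16
heavy atoms of other residues lie within 8 Å of its centroid, and "H-bond
free" when no polar heavy atom of another residue is within 3.5 Å of the
group. The defaults are deliberately permissive and the raw counts are
always emitted, because these properties argue mutability qualitatively
rather than quantitatively.

## Numerical choices

* Coulomb pairs closer than 1e-6 Å are an error (overlapping atoms), with
  the offending pair named.
* `deletion_scan()` computes `dE_m` first and then `ddE = dE_m - dE_wt`,
  the same floating-point path the ledger takes, so exporting a scan as an
  energy table and re-running `compute_barriers()` reproduces the scan
  bitwise.
* Scan output is sorted ascending by `ddE` with residue-key tie-break;
  reports are deterministic given (scan, structure, config) and carry a
  config hash in their provenance header.
* Machine outputs (TSV/CSV) carry full precision (`%.17g`); only
  human-readable summaries round to 0.1 kcal mol⁻¹.
* A uniform dielectric `eps` is available but defaults to 1 (vacuum), the
  value consistent with an embedding-field interpretation.

## Validation problem sizes

The shipped suite validates the scan against a naive double-loop oracle on
50 random fixtures (≤ 200 atoms each), the sign law on 100 randomised
probe geometries, noise robustness over 1000 replicated tables
(σ = 0.1 kcal mol⁻¹ per energy; planted shifts of −1.7 to −2.6 kcal mol⁻¹,
i.e. ≥ 3.5 noise standard deviations of classification margin), and
monitor statistics on 2000-frame jitter trajectories. These sizes keep the
full suite inside a few minutes on a single core while leaving the
statistical assertions comfortable margins.

## Limitations

The surrogate is a fixed-charge, rigid-geometry model: no polarization, no
induced dipoles, no structural relaxation upon deletion or mutation, no
solvent. Its candidate lists are hypotheses ranked by a physically
motivated score, not predictions of mutant activation free energies, and
the package makes no claim that suggested mutants are experimentally
validated. For real systems, the ledger module is the intended entry
point: export deletion single-point energies from the QM/MM engine of
choice and let `compute_barriers()` + `build_report()` do the arithmetic
and the filtering.
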