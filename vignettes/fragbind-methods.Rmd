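---
title: "Per-residue interaction energies by conjugate-cap fragmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-residue interaction energies by conjugate-cap fragmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragbind)
```

## The problem

A protein--ligand binding energy is a single number, but medicinal
chemistry questions are local: *which* pocket residues hold the ligand,
and by how much?  fragbind decomposes the binding energy of a
protein--ligand complex into per-residue contributions with the
molecular fractionation with conjugate caps (MFCC) scheme, and wraps the
decomposition in the bookkeeping that makes it usable as an analysis: a
distance-shell definition of the binding pocket, a convergence scan of
the total interaction energy against pocket radius, dielectric screening
of the electrostatics, and ranking/grouping utilities for the resulting
per-residue profile.  The package was built around the binding-pocket
analysis of the orexin receptor OXR1 with its three marketed dual
antagonists (daridorexant, lemborexant, suvorexant), but nothing in the
machinery is specific to that system.

## The four-fragment energy

For a target residue $R_i$ in a peptide chain, cutting the two flanking
peptide bonds produces unphysical dangling valences.  MFCC therefore
evaluates the residue *capped* by its two sequence neighbours
($C_{i-1}$, $C_{i+1}$), and cancels the caps' own interaction with the
ligand by a second pair of calculations in which $R_i$ is removed (the
*concap*).  The ligand--residue interaction energy is

$$E_I(L\!-\!R_i) \;=\; E_{L\,+\,C_{i-1} R_i C_{i+1}}
  \;-\; E_{C_{i-1} R_i C_{i+1}}
  \;-\; E_{L\,+\,C_{i-1} C_{i+1}}
  \;+\; E_{C_{i-1} C_{i+1}} .$$

The third term removes the cap--ligand interaction, which subtracts the
cap-only contribution twice; the fourth term restores it once.
`build_quartet()` constructs the four atom systems, and
`mfcc_interaction_energy()` combines any backend's energies of them.

Construction rules (all geometry is used *as found* -- single-point
energies on fixed coordinates, no re-optimization):

* **Caps are whole neighbouring residues**, side chains included, at
  their source coordinates.
* **Junction hydrogens** replace the two bonds that went to $R_i$: one
  on the carbonyl carbon of $C_{i-1}$ along the former
  $C(i\!-\!1)\!\to\!N(i)$ vector at the C--H length, one on the amide
  nitrogen of $C_{i+1}$ along $N(i\!+\!1)\!\to\!C(i)$ at the N--H
  length.
* **Outer hydrogens** terminate the caps' outward bonds (to residues
  $i-2$ / $i+2$) the same way, and only where such a bond was actually
  cleaved: a cap that is a true chain terminus keeps its terminus.
  Outer hydrogens appear identically in every system that contains the
  cap, so they cancel in the four-term combination.
* **Concap geometry.** The two capped neighbours are *not* covalently
  adjacent, so the concap is simply both individually hydrogen-capped
  caps evaluated together at source geometry -- no fusion, no new bond.
  This is a genuine design choice (the combination above does not fix
  the concap's internal geometry); the cancellation analysis below is
  stated for it.
* **Terminal residues** get a cap only on the side where a bonded
  neighbour exists.  A gap in sequence numbering, or a
  $C(i)\!-\!N(i+1)$ distance above 2.0 Å, is treated as a chain break.
* **Proline** at the N-junction is treated like any other residue: the
  hydrogen replaces the $R_i$-ward bond; ring atoms are untouched.

Default bond lengths (`cap_spec()`): C--H 1.090 Å, N--H 1.010 Å,
standard organic values.  Hydrogens are placed exactly on the former
bond vector; nothing is relaxed afterwards.

## Energy backends

The decomposition is agnostic to how a fragment's energy is computed;
`energy_backend()` is the contract (atom system + dielectric $\to$
kcal/mol).  Two backends ship:

**Classical pairwise backend.**  `classical_energy()` sums Coulomb and
Lennard-Jones terms over unordered atom pairs,

$$E = \sum_{i<j} \frac{332.0637\, q_i q_j}{\varepsilon\, r_{ij}}
 + \epsilon_{ij}\!\left[\Big(\tfrac{r_{min,ij}}{r_{ij}}\Big)^{12}
 - 2\Big(\tfrac{r_{min,ij}}{r_{ij}}\Big)^{6}\right],$$

with $\epsilon_{ij}=\sqrt{\epsilon_i\epsilon_j}$ and
$r_{min,ij}=r_{min,i}/2+r_{min,j}/2$.  The uniform dielectric
$\varepsilon$ divides the Coulomb term only, a deliberately simple
stand-in for continuum solvation: Coulomb-only systems obey
$E(\varepsilon)=E(\varepsilon_0)\,\varepsilon_0/\varepsilon$ exactly,
which is the backbone of the dielectric-trend checks.  No bonded terms
and no 1-2/1-3 exclusions exist, on purpose: the four-term combination
evaluates identical-geometry subsystems, so *every* intra-fragment term
-- bonded or not -- cancels analytically, and exclusions would only
break that cancellation.

Because the backend is strictly pairwise additive, the four-term
combination collapses algebraically to

$$E_I(L\!-\!R_i) = \mathrm{pairsum}(L, R_i)
 - \mathrm{pairsum}(L, \text{junction H}),$$

and with junction hydrogens as ghosts
(`classical_backend(exclude_junction = TRUE)`, and new cap hydrogens
carry zero charge/LJ depth anyway) it equals the direct ligand--residue
pair energy.  `pairsum()` implements the brute-force double loop
independently, so this identity is a *test* of the fragmentation
bookkeeping, not a tautology: any error in junction placement, atom
partition or system assembly breaks it.  The test suite asserts it to
1e-8 kcal/mol on randomized synthetic complexes.

**External quantum codes.**  Real applications of the scheme evaluate
the four fragments with dispersion-corrected DFT (the reference setup
for the orexin work is B97D/6-311+G(d,p) with a CPCM continuum at
$\varepsilon$ = 10, 20, 40).  fragbind does not run quantum chemistry;
`emit_qm_input()` writes a generic route/title/charge-multiplicity/
coordinates single-point input per fragment and `parse_qm_energy()`
reads a final energy (Hartree, configurable regular expression,
converted at 627.509474 kcal/mol per Hartree) back into the same
backend contract.  The fragment net charge defaults to the rounded sum
of partial charges; a sum more than 0.3 e from any integer is refused
rather than guessed, since fragment protonation states are a modelling
decision the user must own.

## Pocket definition and convergence scan

A residue belongs to the shell of radius $r$ iff the minimum over all
(ligand atom, residue atom) Euclidean distances is $\le r$, hydrogens
included (`residues_within()`).  Shells are nested by construction.
`run_scan()` evaluates every residue of the largest shell once (the
quartet does not depend on the shell, so per-residue energies are
cached and shell totals are exact partial sums), accumulates

$$T(r,\varepsilon) = \sum_{R_i \in \text{shell}(r)} E_I(L\!-\!R_i),$$

and declares convergence at the smallest successor radius $r'$ with
$|T(r')-T(r)|/|T(r)| < \text{tol}$ *simultaneously at every dielectric*
(a zero predecessor total skips that comparison, logged).  Defaults:
radii 2.0--8.0 Å in 0.5 Å steps, tolerance 0.10, dielectrics 10, 20,
40.  The radius schedule reading "half-integer steps from 2 to 8 Å"
reconciles the two conventions in circulation (pure $n/2$ series
starting at 0.5 Å would spend six empty shells below any realistic
contact distance); it is config-overridable.  The multi-dielectric
simultaneity requirement is the stricter reading of a single-series
rule and is the package's choice.

No energy-sign filter is applied to shell membership: repulsive
residues count toward the total exactly like attractive ones.

## Descriptors and docking scores

`descriptors_from_orbitals()` computes the conceptual-DFT set from
frontier-orbital energies (eV): $I=-E_{HOMO}$, $A=-E_{LUMO}$,
gap $=I-A$, hardness $\eta=(I-A)/2$, softness $\sigma=1/\eta$,
electronegativity $\chi=(I+A)/2$, chemical potential $\mu=-\chi$, and
the electrophilicity index in two conventions:
$\omega_{std}=\mu^2/2\eta$ (the Parr definition) and
$\omega_{alt}=\mu^2\eta/2$.  Published descriptor tables for the orexin
antagonists print the *alt* values (and flip the signs of $\mu$ and
$\chi$); both conventions are always computed and exposed, with
`mu_printed`/`chi_printed` carrying the flipped orientation, rather
than silently matching one table.  For the lemborexant row the printed
$\omega$ (19.84586 eV) differs from either convention recomputed from
its printed $I$ and $A$ ($\approx$ 19.866 eV via $\mu^2\eta/2$) --
almost certainly intermediate rounding upstream; fragbind reports the
recomputed value and leaves the discrepancy visible.

`haddock_score()` is the fixed linear pose-ranking combination
$HS = 1.0\,E_{vdw} + 0.2\,E_{elec} + 1.0\,E_{desolv} + 0.1\,E_{air}$
(kcal/mol).

## The synthetic-data generator

Validating the pipeline needs complexes with *known* per-residue
energies, which no real structure provides.  `generate_complex()`
builds a glycine-like extended chain (5 atoms per residue: N, H, CA, C,
O; 3.8 Å CA--CA spacing; peptide C--N distance 1.4 Å; optional one-atom
CB pseudo-side-chain), and docks a small rigid ligand cluster (3--10
atoms, ring layout with $\ge$ 1.5 Å interatomic spacing) by rigid-body
optimization (translation + rotation, Nelder-Mead with deterministic
multi-start and jitter polish) until every requested minimum
ligand--residue distance is met within 0.05 Å; non-target residues are
kept $\ge$ 1.5 Å away.  Charges come in three schemes -- `random`
(uniform $\pm$0.4 e, 4 decimals, ligand net charge made exact on the
last atom), `zero`, and `decaying` (per-residue magnitudes falling
exponentially with ligand distance, signed to attract the ligand) --
with element-level Lennard-Jones parameters (`amber_like`) or none
(`none`, pure Coulomb).

Ground truth is computed by an intentionally naive scalar double loop
(`.naive_pair_energy`) that shares no code with the vectorized backend,
covering pair energies per residue and dielectric, shell membership,
shell totals, and the converged radius under an independently coded
copy of the 10% rule.  `decaying_energy_fixture()` packages the
convergence scenario: 10 residues, ligand 2.2 Å from residue 3, net
charge +1.

What the fixtures deliberately do *not* emulate: real force-field
parameterization, side-chain diversity, protonation chemistry, solvent
or membrane atoms, and conformational flexibility.  Passing tests
therefore demonstrate the correctness of the fragmentation bookkeeping,
shell logic and energy assembly -- not the accuracy of any particular
energy model on real proteins.  Reference-scale numbers (tens of
kcal/mol per residue) require the external-QM route on MD-relaxed
coordinates.

## Numerical choices

* Electrostatic constant 332.0637 kcal·Å/(mol·e²); 1 Hartree =
  627.509474 kcal/mol.
* Pair distances below 0.1 Å are a hard error (clash), naming the pair.
* Energy ties in `rank_residues()` break by (chain, sequence number).
* The PQR writer uses fixed PDB-like columns with charges and radii at
  4 decimals; parse-then-rewrite is byte-identical, and generator
  charges live on the 4-decimal grid so write/read round trips preserve
  them exactly.  Coordinates are written at 3 decimals (PDB
  convention), so file round trips carry $\le$ 5e-4 Å coordinate
  rounding; validation against ground truth always uses the in-memory
  complex.
* PQR radii are stored in the `rmin2` slot; LJ well depths are not
  representable in PQR and must come from `assign_parameters()`.
* Alternate locations: first/blank altloc kept (bio3d `rm.alt`), others
  dropped with a warning.
* Fragment quartets with both neighbours missing (single-residue
  chains) are an error; one-sided termini are handled.

## Problem sizes

The shipped tests and analysis scripts run on deliberately small
systems -- chains of 3--10 five-atom residues, ligands of 3--10 atoms,
20 randomized complexes in the oracle-equivalence check, 1000 random
orbital pairs in the descriptor-identity check -- chosen so the whole
suite completes in well under a minute while still exercising every
code path (terminal residues, chain breaks, side chains, empty shells,
zero totals).

## Known limitations

* The classical backend is a validation instrument, not a scoring
  function: no polarization, no charge transfer, no dispersion beyond
  LJ, a distance-independent uniform dielectric.
* mmCIF is not read; structures with gaps are not repaired.
* Disulfide-linked side chains are not cleavable (the fragmenter only
  cuts backbone peptide bonds).
* The emitted quantum input is a generic dialect; adapting to a
  specific code's syntax is the caller's one-line job, and the energy
  parser pattern is configurable for the same reason.
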