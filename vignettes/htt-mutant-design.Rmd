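---
title: "Designing stabilizing mutants of the huntingtin N-terminal helix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing stabilizing mutants of the huntingtin N-terminal helix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httscan)
```

## The problem

The 17-residue N-terminal segment of huntingtin exon 1
(`MATLEKLMKAFESLKSF`, preceding the polyglutamine tract) is implicated
in aggregation through two routes: self-association of the
alpha-helical segment into oligomer-seeding bundles, and hydrophobic
cross-talk between the segment and the polyQ domain. `httscan`
implements a desk-scale version of the corresponding design procedure:
map the full single-point mutational stability landscape of the helix,
estimate multi-point mutants additively, and filter top-ranked
combinations by three criteria — helical stability, replacement of a
hydrophobic residue by a charged one, and disruption of the
intermolecular lysine contact at positions 6 and 15.

## The energy model

Stability is scored by a decomposed total energy

$$E = E_\mathrm{solv} + E_\mathrm{LJ} + E_\mathrm{Coul},$$

with the mutant effect expressed relative to the native structure,
$\Delta E = E - E_0$. Positive $\Delta E$ means destabilizing, negative
stabilizing; that sign convention is used everywhere (classification,
ranking, selection).

The terms are evaluated on a united-atom heavy-atom model:

* **Lennard-Jones**: $4\epsilon_{ij}[(\sigma_{ij}/r)^{12} -
  (\sigma_{ij}/r)^{6}]$ with Lorentz–Berthelot combining, over atom
  pairs that are in different residues *and* at least three bonds
  apart (1-2/1-3 exclusions, full 1-4 interactions). A 10 Å distance
  cutoff is applied to both LJ and Coulomb terms; there is no periodic
  boundary or Ewald summation — the model is a vacuum/implicit-solvent
  one by construction.
* **Coulomb**: $k\,q_i q_j/(\epsilon_r r)$ with $k = 332.0636$
  kcal·Å/(mol·e²) and $\epsilon_r = 1$ by default.
* **Solvation**: the default backend is a SASA-weighted atomic model,
  $\sum_i \sigma^\mathrm{solv}_i \, A_i$, where $A_i$ is the
  solvent-accessible surface area of atom $i$ for a probe radius of
  1.4 Å. Apolar atoms carry positive solvation parameters (exposure is
  penalized), polar and charged atoms negative ones. `SolvationConfig`
  also records the descriptors of a dipolar-solvent model (dipole
  moment 3.0 D, concentration 55 M, lattice spacing 2.8 Å, 300 K); the
  default backend does not consume them, but they define the interface
  for alternative backends registered with
  `register_solvation_model()`, e.g. a grid Poisson–Boltzmann–Langevin
  solver, which is deliberately out of scope here.

All parameters live in a single versioned table
(`atom_parameter_table()`, version `httscan-ua-1`): per-class LJ
$\sigma/\epsilon$, van der Waals radii, atomic solvation parameters,
and per-residue partial charges that sum exactly to each residue's
formal charge (K/R +1, D/E −1, H neutral, termini uncharged). The
charges are deliberately coarse — they are chosen for internal
consistency and reproducibility, not to match any published force
field; absolute energies from this package are on their own scale and
are not comparable to explicit-solvent force-field results.

### Numerical choices

* **SASA** uses Shrake–Rupley sampling with a deterministic
  golden-section spiral of 960 points per atom (no RNG anywhere in the
  energy path). Sphere points are laid out in a canonical
  principal-axes frame of the molecule, with axis signs fixed from the
  projection skewness of the coordinates; this makes all three energy
  terms exactly invariant under proper rigid motions rather than
  invariant only to the point-sampling resolution.
* **Minimization** is steepest descent on the LJ + Coulomb gradient
  with adaptive step halving (initial maximum per-coordinate
  displacement 0.05 Å, growth ×1.5 on acceptance, cap 0.5 Å).
  Solvation is held constant during each line search and re-evaluated
  when a step is accepted; a step counts as accepted only if the full
  three-term total does not increase, so the total is non-increasing
  across the step log by construction. Convergence is declared when
  the largest gradient component falls below `force_tol`; the default
  of 0.1 kcal/(mol·Å) is this package's own documented choice, as is
  the 200-step cap used by the landscape scan.
* A configuration with near-coincident atoms is rejected before
  minimization starts (divergent energy), naming the remedy rather
  than producing NaN trajectories.

## Building and mutating peptides

`build_ideal_helix()` generates coordinates from sequence alone:
backbone dihedrals $\varphi = -57^\circ$, $\psi = -47^\circ$, standard
bond lengths and angles, and one side-chain template rotamer per
residue type, placed by natural-extension (NeRF) internal coordinates
with the L-chirality constant (C–N–CA–CB $= -120^\circ$). A single
most-common rotamer per residue (gauche⁻ $\chi_1$ except where trans is
the common one) keeps mutation deterministic; clash relief is delegated
to `minimize()`. Protonation is fixed at neutral pH and termini are
modelled uncharged — the printed charge column of the reference tables
is reproduced exactly under exactly this convention.

`apply_mutation()` swaps the side chain at one position on a frozen
backbone: backbone coordinates are bit-identical before and after, and
all other residues keep their atoms verbatim. PDB input is renumbered
1..N on read (so a fragment extracted with author numbering such as
371–387 maps onto the 1-based `L4K` notation), and all force-field
parameters are re-assigned from the embedded table, since PDB files
carry none of them.

## The landscape and additive estimates

`scan_single_point()` relaxes the native once to obtain $E_0$, then for
each of the 17 positions mutates into the 19 alternative residues,
relaxes side chains, and records $\Delta E$. The result is a 17 × 20
table whose identity cells are zero by construction; the scan is
deterministic and order-independent, and the table carries a provenance
string of the energy configuration so estimates cannot silently mix
incompatible landscapes.

Multi-point mutants are estimated additively,
$\widetilde{\Delta E} = \sum_i \Delta E(m_i, p_i)$, with no
re-evaluation of structure energies. `enumerate_top_k()` returns the
$k$ best $n$-point combinations over pairwise-distinct positions by
lazy best-first expansion of per-position sorted candidate lists; the
result provably equals exhaustive enumeration (this is asserted against
a brute-force oracle in the test suite, including tie cases), with ties
broken lexicographically by (position, residue) for reproducible
rankings.

The additive approximation ignores pairwise interactions between the
introduced mutations. Rather than assume an error bound, the test suite
measures it on this package's own model: for two mutations more than
10 Å apart on the 17-mer helix (positions 2 and 16), the directly
recomputed 2-point $\Delta E$ agrees with the additive estimate within
the documented tolerance of 10% or 2 kcal/mol, whichever is larger.
Combinations of adjacent positions should be treated with more caution.

## Sequence features

`sequence_features()` computes compositional stand-ins for external
aggregation predictors: net formal charge ((#K + #R) − (#D + #E),
histidine neutral, termini ignored — this column reproduces the printed
reference exactly), mean hydrophobicity on the embedded Kyte–Doolittle
hydropathy scale, mean Chou–Fasman helix and sheet propensities, and a
composite aggregation score

$$w_h z(H) + w_q z(-|\bar q|) + w_b z(P_\beta) - w_a z(P_\alpha),$$

z-scored against the 20-residue table statistics, with default weights
(1, 1, 1, 1) exposed in the interface. The score is an explicit
stand-in: it is monotone in hydrophobicity and penalizes net charge and
helix propensity, but it does not reproduce the numbers of Zyggregator,
TANGO or PASTA, whose outputs are embedded verbatim for display only
(`table2()`–`table4()`). All features are permutation-invariant
(compositional); window-based aggregation profiles are out of scope,
and that is the main limitation relative to the external tools. The
printed native hydrophobicity (4.91) is on an unstated external scale
and no attempt is made to match it.

## The three selection criteria

`select_candidates()` flags each ranked combination with:

1. **Stability** — membership in the ranked input (the filter is
   applied to an already top-ranked list, so no threshold is imposed by
   default; `stability_max_rank` can tighten it).
2. **Hydrophobic→charged replacement** — at least one mutation with
   wild type in the hydrophobic set and mutant in {D, E, K, R}. The
   default hydrophobic set is the *aliphatic* set {A, V, I, L, M}, not
   the broader set including F/W: the printed reference list includes
   the A2R combinations but excludes all combinations whose only
   hydrophobic-loss mutation is F17→D/E, and the aliphatic default
   reproduces that printed behaviour exactly. The reference never
   explains the phenylalanine exclusion; the set is config-overridable
   and the discrepancy is flagged rather than resolved.
3. **Contact breaking** — any substitution at position 6 or 15.
   Position 6 is included in the default even though no printed
   combination mutates it, since both lysines are described as forming
   the intermolecular contact. The criterion is position-based only; no
   structural model of the oligomer interface is attempted.

Under the defaults, the triple mutant L4K E12K K15E passes all three
criteria, and the hydrophobic-replacement flag reproduces the printed
12-combination list as a set equality (asserted in the tests).

## Recovering single-point values from printed sums

The printed ranked-mutant table reports only 3-point sums over nine
distinct single-point mutations. Because the estimate is linear,
`fit_single_point()` recovers the nine single-point values by
unweighted least squares (all rows are rounded to the same 0.1
precision, and no heteroscedasticity information exists to justify
weights). The design rank is computed, not assumed: the full 20 × 9
design has rank 9, anchored by the one row (T3K L4K E5K) that carries
three non-position-15 mutations. Every remaining row has exactly one
position-15 mutation, so excluding that anchor row leaves a
one-dimensional null space (+δ on the eight non-15 parameters, −2δ on
K15D/K15E) and its own combination is not estimable; the fit then
fails loudly, naming the unidentifiable parameters, rather than
returning a pseudo-inverse number. Leave-one-out predictions for the
other 19 rows reproduce the printed sums to within 0.1, an order of
magnitude inside the ±0.5 acceptance band.

## Trajectory statistics

`rmsd()` superposes frames with the closed-form least-squares rotation
(3 × 3 covariance SVD, reflection-corrected) before taking the RMS
deviation; superposition is applied per frame by default, and the SVD
route is cross-checked in the tests against an independent
quaternion-based implementation. `rmsf()` computes per-atom
$\sqrt{\langle |x_i(t) - \tilde x_i|^2 \rangle_t}$; the reference
$\tilde x_i$ is the time-averaged position by default (the
variance-minimizing choice), with first-frame and user-supplied
alternatives. CA-only selections are the convention for both
statistics, and results are reported in Å (1 nm = 10 Å).

`synthetic_trajectory()` generates frames as the reference plus i.i.d.
per-coordinate Gaussian noise at 10 ps spacing, seeded and
reproducible. It emulates *stationary, isotropic, uncorrelated*
fluctuation about a fixed structure — sufficient to validate the
estimators (e.g. RMSF converges to $\sigma\sqrt{3}$, verified at
10,000 frames within 3%), but it has no anharmonicity, no correlated
collective motions, no conformational transitions and no
position-dependent stiffness. Passing these tests therefore certifies
the *operators*, not the dynamical behaviour of real MD trajectories.

## Problem sizes and runtime

The package's standard workloads are desk-scale by design: the full
landscape scan evaluates 323 mutants with a 200-step relaxation cap
(about half a minute with the compiled kernels), the enumeration tests
compare against exhaustive oracles on 5-position toy tables, and the
RMSF calibration uses 10,000 frames over small atom sets. The analysis
scripts under `analysis/` run the whole pipeline end to end in a few
minutes.

## Known limitations

* Absolute energies are on the package's own parameter scale; only
  signs, orderings and internal differences are meaningful, and the
  landscape will not numerically match results from explicit-solvent
  force fields.
* One template rotamer per residue means side-chain packing is crude;
  minimization relieves clashes but does not search rotamer space.
* The solvation backend is area-based; no dielectric screening beyond
  the constant $\epsilon_r$, no salt, no pH titration.
* Aggregation features are compositional and cannot see sequence
  windows or gatekeeper placement.
* The contact-breaking criterion is positional; it does not model the
  oligomer interface structurally.
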