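---
title: "Coarse-grained free-energy landscapes for lipid flippases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained free-energy landscapes for lipid flippases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flipscape)
```

# The problem

P4-ATPases (flippases) translocate phospholipids from the exoplasmic to
the cytosolic membrane leaflet, coupling a large conformational cycle of
a ten-helix transmembrane domain (plus the CDC50 chaperone subunit) to
the movement of a charged lipid headgroup through a protein channel.
Estimating the energetics of that coupled process from structures of
the two end states requires four ingredients, each of which this
package implements:

1. a **coarse-grained (CG) folding free energy** that is accurate enough
   on the electrostatics of ionizable residues to compare conformations
   of a large membrane protein;
2. a **ligand-binding free energy** cheap enough to evaluate on a grid
   of (conformation, lipid position) cells;
3. a **conformational pathway** connecting the two experimental end
   states; and
4. the **coupled two-dimensional landscape** with a least-energy path
   and per-residue attribution of the barriers.

# The coarse-grained model

## Representation

Each residue keeps its backbone explicitly and carries one side-chain
interaction centre **X** plus a dummy site **D** on the CA--X segment
(`coarse_grain()`). X sits at the geometric centre of the side-chain
heavy atoms; for ionizable residues it is displaced toward the centroid
of the charged functional group by `shift_fraction` of the separation,
so the electrostatics acts where the charge actually sits. The
displacement magnitude is not fixed by the model we follow; we default
to `shift_fraction = 0.5` (halfway), exposed in the configuration. D
carries no interactions; it marks the side-chain/main-chain boundary
for rotational bookkeeping.

The ionizable set is Asp, Glu, His, Lys, Arg, with aqueous reference
pKas 4.0, 4.4, 6.5, 10.5, 12.5. Cys, Tyr and the chain termini are
excluded by default (the CG electrostatic sign rule covers the five
canonical ionizables only); the pKa table is replaceable.

## Folding free energy

The total is assembled (`total_folding_energy()`) as

$$\Delta G_{fold} = \Delta G^{elec} + \Delta G^{polar} + \Delta G^{hyd}
  + c_1\,\Delta G^{vdw}_{side} + c_2\,\Delta G^{solv}
  + c_3\,\Delta G^{HB} + \Delta G^{vdw}_{main\text{-}side}$$

with the empirical scalings $c_1 = 0.10$, $c_2 = 0.25$, $c_3 = 0.15$.
The electrostatic term is the model's centrepiece; the remaining
side-chain and main-chain terms are **documented surrogates**: the CG
force field we follow names these components but does not print their
functional forms, so we use minimal forms with the right sign and
monotonicity, each unit-tested against its closed form:

* *hydrophobic*: burial reward $-k_{hyd}\min(N_{np}+N_{mem}, N_{sat})$
  for nonpolar residues ($k_{hyd} = 0.2$ kcal/mol, $N_{sat} = 8$);
* *polar*: membrane desolvation penalty
  $+k_{pol} N_{mem}\,s(R_{min})$ for polar residues
  ($k_{pol} = 0.05$), with $s$ the same Gaussian solvent switch used in
  the self-energy;
* *van der Waals*: an 8--6 soft pair potential on X--X and X--backbone
  distances with per-class contact radii; its minimum is exactly
  $-\varepsilon$ at the radius sum, clashes are capped at 0.5 Å;
* *hydrogen bonds*: $-1$ kcal/mol per backbone N--O contact in the
  2.6--3.4 Å window with a C--O$\cdots$N acceptor angle of at least
  120°. The angle gate matters: in an ideal helix the bent
  $i{+}3$ contact also falls inside the distance window (3.23 Å at
  104°) and only the angle separates it from the canonical $i{+}4$
  bond (2.95 Å at 154°);
* *main-chain solvation*: $+k_{solv}$ per membrane grid point around
  the CA.

These parameters are calibration knobs, not claims; every analysis
that matters downstream (barrier ordering, decomposition, coupling) is
also exercised with the terms switched off or at closed-form fixtures.

## Ionization electrostatics

The electrostatic term is built from in-protein pKas and Monte-Carlo
averaged charges:

$$\Delta G^{elec}_{side} = -2.3RT \sum_i Q_i^{MC}
  (pK_{a,i}^{b} - pK_{a,i}^{w}) + \Delta G_{QQ}^{f}
  - \Delta G_{QQ}^{uf} + \Delta G_{Qdev}$$

The in-protein pKa shifts by the charging self-energy,
$pK_a^b = pK_a^w - \mathrm{sgn}(Q^{ion})\,\Delta G_{self}/(2.3RT)$,
with sign $+1$ for Arg/Lys/His and $-1$ for Asp/Glu: a buried acid
titrates up, a buried base down. We use $\ln 10$ for the "2.3"
prefactor so Metropolis sampling reproduces Henderson--Hasselbalch
exactly.

$\Delta G_{self}$ sums a polar-neighbour term ($U_p = -0.15$ kcal/mol
per neighbour, stabilising), a nonpolar term ($U_{np} = +0.35$,
destabilising) and the membrane grid term (`membrane_self_energy()`).
The membrane term has a plateau of **15 kcal/mol** for a deeply buried
site, attenuated in two ways: a Gaussian switch
$\exp(-((R_{min}-18)/12)^2)$ when the site is within 18 Å of solvent,
and an exponential factor $\exp(-0.2\,(28-N_{mem}))$ when fewer than 28
membrane points surround it. **A caveat worth stating prominently**:
the published branch conditions for this expression are typographically
corrupted (both branches read "$R_{min} \le 18$", and the exponential
as printed would grow as membrane contact shrinks). We implement the
physically monotone reading - the penalty increases with burial,
saturates at 15, and vanishes at zero membrane contact - and treat it
as a judgment call, not a settled fact.

The charge-charge interaction is screened Coulomb,
$332\,Q_iQ_j/(\varepsilon_{eff}\,r_{ij})$ on X--X distances with
$\varepsilon_{eff} = 40$ by default, consistent with the CG model's
effective-dielectric philosophy; the functional form is ours, as the
source model does not print one. The unfolded-state reference is an
extended fully solvated chain: $\Delta G_{QQ}^{uf} = 0$ and
$\Delta G_{Qdev} = 0$ by default, both overridable.

## Monte-Carlo proton transfer

`mcpt_sample()` runs Metropolis over protonation configurations: each
step either exchanges a proton between one site and the bulk (charge
toggle) or transfers a proton between a site pair. Acceptance uses
$\exp(-\Delta E / RT)$ at the run temperature (default 300 K, pH 7).
The chain stops early when the 2000-step window mean of the
electrostatic free energy changes by less than 0.01 kcal/mol - but
never before the burn-in (first 20% of the requested steps) plus twenty
windows, so averages always rest on a substantial sample. Averaged
charges, the minimum energy visited, configuration frequencies (up to
12 sites) and acceptance statistics are returned; runs are
bit-reproducible for a fixed seed.

For ledger decomposability the folded charge-charge term enters the
folding energy at the *mean-field* value (evaluated at the averaged
charges), so per-residue entries sum exactly to the structure total;
the ensemble-average value is also reported.

# The membrane environment

The bilayer interior is a cubic lattice of membrane pseudo-atoms
filling the slab (default $z \in [-15, 15]$ Å, spacing 3 Å), with
points within 4 Å of any protein heavy atom removed - no grid inside or
against the protein. Solvent is represented implicitly by the same
lattice outside the slab; it is used only for the distance-to-solvent
$R_{min}$ of the self-energy switch, and is excluded from the protein
with a fixed 2 Å contact radius (a tighter radius than the membrane
exclusion, so that a residue sitting in bulk water reads
$R_{min}$ on the order of the lattice spacing). Spacing, exclusion and
the 10 Å neighbour cutoff are configuration values; the model we
follow states none of them. The membrane normal is fixed to z: input
structures must be membrane-oriented, as cryo-EM membrane-protein
depositions conventionally are. We deliberately avoid a Langevin-dipole
solvent grid; the grid-only treatment avoids double-counting the
self-energy penalty mid-membrane.

# Ligand binding

`pdlds_potential()` implements a semi-macroscopic effective potential
for the lipid-bound and unbound states: scaled solvation difference
between the charged- and uncharged-ligand complex
($1/\varepsilon_P - 1/\varepsilon_W$), ligand solvation
($1 - 1/\varepsilon_P$), the vacuum charge-dipole interaction between
ligand charges and protein main-chain dipoles ($1/\varepsilon_P$), and
the intramolecular ligand term. The unbound variant simply drops every
protein-containing term; as printed in the source model, the unbound
line contains an apparently redundant term difference, and we read it
this way. Defaults $\varepsilon_P = 4$, $\varepsilon_W = 80$.

The solvation estimator is a Born-style surrogate (per-charge
$-166 q^2/r_{eff}$ with an effective radius growing with heavy-atom
burial); no estimator is printed in the source. All the relations the
analysis relies on - the linear-response half-sum
$\Delta G^{elec}_{bind} = \tfrac12[(\langle U^P\rangle_l +
\langle U^P\rangle_{l'}) - (\langle U^W\rangle_l +
\langle U^W\rangle_{l'})]$ and the scaled-vdW closure
$\Delta G_{bind} = \Delta G^{elec}_{bind} + \beta\,\Delta\langle
U^{vdw}\rangle$ with $\beta = 0.25$ - are independent of the
surrogate's parameters, and the test-suite checks them on fixtures
where the surrogate cancels. The charge-dipole sum carries a 25 Å
cutoff so every interaction has finite range: a ligand pulled 30 Å
away binds with exactly zero energy.

Ensemble averaging (`configuration_ensemble()`) stands in for
force-field relaxation: `n_conf` (default 20) configurations generated
by Gaussian jitter of the side-chain atoms (scale 0.3 Å, truncated at
two sigma), ligand-jittered for the unbound state, seed-reproducible.

# Conformational pathway

`morph()` drives one structure into the other under the targeted
restraint $U = \frac{k}{2N}(RMS - \rho)^2$, where $RMS$ is the best-fit
RMSD to the target (Kabsch superposition via SVD) and $\rho$ shrinks
linearly from the initial separation to zero - by default over **21
frames** with $k = 100$ kcal/mol/Å². The printed prefactor of the
restraint in the source is typographically ambiguous ("12kN"); we use
$k/(2N)$, the standard normalisation that keeps the restraint per-atom
intensive. Whether the source's 21 structures are equally spaced in
time or in RMSD is also unstated; we space them equally in $\rho$.
Frames are produced by Cartesian interpolation onto the schedule
(monotone RMSD decrease by construction), with optional
steepest-descent relaxation under the restraint plus a soft bonded
regulariser; `relax_steps = 0` (pure interpolation) is the default and
is what the bundled analyses use, since the rigid-subdomain fixtures
need no repair.

# The coupled landscape

`build_landscape()` combines the per-frame conformational energies and
the per-(frame, offset) binding energies additively,
$G(i,j) = G_{conf}(i) + G_{bind}(i,j)$, calibrated so a reference cell
is zero. How the source assembles its two energy sets into a map is
not stated; additive coupling is the simplest construction consistent
with combining them, and it is exact arithmetic - no tolerance needed.

`least_energy_path()` finds the route minimising the **maximum** energy
crossed (minimax criterion) over 8-connected lattice moves, with ties
broken by the lower path integral and then lexicographic cell order,
so results are deterministic. We chose minimax over least-integral
because a transport bottleneck is set by the highest point crossed;
both readouts are available (the path object carries `max_g` and
`sum_g`). The barrier is the path maximum minus the start-cell energy.
The search permits non-monotone paths in the conformational coordinate.
`profile_barriers()` gives the 1D readout: for each local maximum, the
peak minus the minimum reached since the previous peak.

# Synthetic study systems

The generators in this package are first-class, tested code - they
define the conditions every statistical claim is tested under.

* `make_bundle()`: ideal membrane-spanning helix bundles (default 4
  helices × 20 residues ≈ 80 residues, on an 8 Å circle), one chain
  per helix, backbone N/CA/C/O plus a single CB-like pseudo side-chain
  atom. The backbone is built from internal coordinates with standard
  bond lengths/angles and torsions solved once (Newton on the screw
  parameters) so the CA trace has **exactly** 1.5 Å rise and
  100°/residue twist; the resulting $i{+}4$ H-bond distance is 2.95 Å.
  The default sequence is a leucine background with threonine every
  seventh position and one ionizable residue mid-helix (Asp/Lys
  alternating between helices) - ionizables at controlled mid-membrane
  burial.
* `make_two_state_pair()`: state B displaces designated helices
  rigidly (default: helix A, 5 Å radially outward), opening the
  channel by a known amount with identical topology.
* `make_toy_lipid()`: a linear pseudo-lipid, charged head bead(s) plus
  neutral tail at 1.5 Å spacing (default net −1 e, emulating a
  phosphatidylserine-like headgroup).
* `make_titration_system()`: isolated ionizable pseudo-residues with
  prescribed pKas - the harness for closed-form titration checks.

What these fixtures do **not** emulate: real side-chain rotamers,
sequence realism, loop regions, lipid chemistry, or the absolute
energy scales of a 1000-residue transporter. Passing tests on them
demonstrates that the machinery - pKa shifts, sampling, coupling,
path search - is correct, not that the toy barriers match any
experimental system. In particular the published barrier magnitudes
for flippase conformational cycles depend on the full force-field
parameterisation and repaired experimental structures and are outside
what a fixture of this size can or should reproduce.

# Numerical choices

* Gas constant 0.0019872041 kcal/mol/K; "2.3RT" is $RT\ln 10$.
* MCPT convergence: window 2000 steps, tolerance 0.01 kcal/mol,
  burn-in 20%, early stop never before burn-in + 20 windows.
* Default problem sizes in the bundled analyses: 21 frames, 7 lipid
  offsets, 50 000 MC steps per frame, 10-configuration binding
  ensembles - the full workflow completes in about a minute on one
  core. Statistical acceptance checks use 2×10⁵ steps per titration
  point.
* Degenerate inputs: glycine's X is its CA; residues with no carbonyl
  O simply contribute no H-bonds; an empty membrane grid is a warning
  (small peptides), not an error; clashes are capped, never infinite;
  an all-clashing ligand ladder is an error suggesting wider offsets.
* Insertion codes are rejected with a clear error so that
  `chain:resnum` selectors stay unambiguous.
* Seeds: every stochastic stage takes an explicit integer seed and is
  bit-reproducible; the pipeline derives per-frame and per-cell seeds
  from the run seed by fixed offsets.

# Known limitations

The surrogate terms are not a validated force field: absolute folding
energies are not comparable across unrelated proteins. The jitter
ensemble explores only small harmonic-like fluctuations, not side-chain
rotamer flips. The membrane is a flat slab along z with no leaflet
asymmetry or curvature. His tautomers are not distinguished. The
landscape's additive coupling ignores any conformational response to
the bound lipid beyond what the jitter captures.
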