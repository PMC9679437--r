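---
title: "The implicit-nanoparticle curvature model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The implicit-nanoparticle curvature model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvnp)
```

## The model

A nanoparticle of effective radius $r_0$ is represented implicitly, as a
pair of restraint potentials around a virtual sphere, with no explicit
surface atoms.  Two index groups of solute atoms play different roles:

* **NANO** (the anchors; for peptides, the N-terminal heavy atoms) feel an
  *attractive spherical harmonic potential*
  $$E(r) = \tfrac{1}{2}\,k\,(r - r_0)^2 ,$$
  where $r = |\mathbf{x} - \mathbf{c}|$ is the atom's distance from the
  sphere center $\mathbf{c}$ and $k$ is the force constant.  The minimum
  is the whole spherical shell $r = r_0$: the anchor can slide freely
  along the surface but is pulled back whenever it leaves it, on either
  side.

* **PEPTIDE** (every solute atom) feels the *flat-bottom excluded-volume
  potential*: the same harmonic term applied only where $r < r_0$, and
  exactly zero otherwise.  The particle interior is therefore softly
  forbidden while the exterior is untouched.  The term is $C^1$ at the
  wall — energy and radial force both vanish continuously as $r \to r_0$
  from inside — so no integrator sees a force discontinuity.

Varying $r_0$ changes the surface curvature that an adsorbed, preformed
oligomer experiences; varying $k$ changes the binding strength.  Because
only the anchors are attracted while the whole molecule is volume-excluded,
a small sphere (high curvature) forces the anchor geometry to bend around
it, stressing the stacked arrangement, while a large sphere approximates a
flat wall.

Two conventions matter in practice and are encoded in `nominalToRadius()`
and `nanoparticleCenter()`:

* nominal size labels ("5 nm", "20 nm") are **diameters**; the model
  parameter is the radius ($r_0 = 2.5$ and $10$ nm respectively).  This is
  the only reading consistent with the published parameter value
  `userreal1 = 2.5` for the 5 nm case and with the drawn sphere radii
  (25 Å and 100 Å).
* the sphere center sits at $(L_x/2 - r_0,\; L_y/2,\; L_z/2)$ for box
  $(L_x, L_y, L_z)$, so the **surface passes through the box center**,
  where the placement step puts the central monomer's anchor atom.  The
  center's $x$ coordinate is linear in $r_0$ with slope $-1$; this is why,
  in the VMD visualisation commands, every large-sphere line is the
  small-sphere line shifted by $-75$ Å in $x$ (the difference of the two
  radii), which `vmdCompanionSphere()` exploits to reconstruct one line
  from the other.

The nanoparticle is exempt from periodic boundary conditions: field
distances are computed in absolute coordinates, never minimum-image, and
the box built by `soluteBox()` (solute extent plus a 2 nm margin per face)
is sized so the solute never crosses a boundary.  Rectangular boxes only;
triclinic cells are out of scope.

## Parameters and defaults

| parameter | meaning | unit | default | note |
|---|---|---|---|---|
| `r0` | effective particle radius | nm | — | 2.5 and 10 are the published cases |
| `kAttract` | shell force constant | kJ nm$^{-2}$ mol$^{-1}$ | 500 | published value |
| `kRepel` | excluded-volume force constant | kJ nm$^{-2}$ mol$^{-1}$ | `kAttract` | the published formulas use one symbol $k$ for both terms; two fields are kept for flexibility |
| `margin` | box clearance per face | nm | 2 | keeps solute off the periodic boundary |
| `temperature` | bath temperature | K | 300 | study temperature |
| `friction` | Langevin $\gamma$ | ps$^{-1}$ | 1 | the implicit solvent |
| `dt` | time step | ps | 0.005 | $\approx 1/25$ of the fastest bond period |

Degenerate geometry: an atom exactly at the sphere center has no defined
radial direction, so both force routines return the zero vector there.
Any fixed direction would break rotational invariance, and the
configuration has measure zero.

## The coarse-grained oligomer

The published simulations are atomistic (OPLS-AA, explicit SPC water,
150 mM NaCl, 100 ns), with oligomers built from deposited fibril
structures.  Reproducing that is not this package's goal; what the model
question needs — does surface curvature destabilise a stacked oligomer? —
is exercisable at coarse-grained resolution.  `buildFibrilOligomer()`
therefore constructs a synthetic Gō-type stand-in:

* one bead per residue (mass 110 amu, an average residue);
* chains are straight strands of beads 0.38 nm apart (the C$\alpha$
  virtual bond length), stacked in parallel 0.47 nm apart (the cross-β
  strand spacing);
* harmonic bonds ($k_b = 8000$ kJ nm$^{-2}$ mol$^{-1}$) and straightening
  angles ($k_a = 40$ kJ rad$^{-2}$ mol$^{-1}$, $\theta_0 = \pi$) along
  each chain;
* every inter-chain bead pair closer than 0.6 nm in the built lattice
  becomes an attractive 12–10 native contact,
  $\varepsilon[5(\sigma/r)^{12} - 6(\sigma/r)^{10}]$ with $\sigma$ the
  built distance and $\varepsilon = 4$ kJ/mol.  With the default spacings
  this is exactly the same-position pairs of adjacent chains — the
  hydrogen-bond ladder of a fibril — because the diagonal distance
  $\sqrt{0.47^2 + 0.38^2} \approx 0.604$ nm falls just outside the cutoff;
* all remaining pairs (beyond bonded 1–2 and 1–3 neighbours) share a soft
  $\varepsilon_{rep}(\sigma_{rep}/r)^{12}$ repulsion
  ($\sigma_{rep} = 0.4$ nm, $\varepsilon_{rep} = 1$ kJ/mol).

These are standard Gō-model magnitudes, chosen once; they are arguments,
not constants, so other regimes can be explored.  What the generator does
*not* emulate: sequence specificity, side chains, electrostatics and salt,
explicit solvent, and the twist of real fibrils.  Passing tests on this
system show that the restraint physics and the integrator are correct and
that curvature stress behaves qualitatively as designed — they do not
certify quantitative agreement with any atomistic or experimental system.

## Dynamics

`langevinRun()` integrates with the BAOAB splitting, chosen for its
configurational sampling accuracy per step.  With $\gamma = 0$ the
Ornstein–Uhlenbeck substep is the identity and the scheme reduces exactly
to velocity Verlet, which the test suite uses for an energy-conservation
check (drift below 0.1 % of the initial kinetic energy over $10^4$ steps
at $dt = 10^{-4}$ ps).  With $T = 0$ and large $\gamma$ it is gradient
flow.  The equipartition identity
$\operatorname{Var}(r - r_0) = k_B T / k$ for a shell-restrained bead is
the package's statistical-mechanics anchor: at $T = 300$ K and $k = 500$
kJ nm$^{-2}$ mol$^{-1}$ the predicted variance is
$0.0083144621 \times 300 / 500 = 0.0049887$ nm$^2$, and a sampled
trajectory must land within a few percent of it.  (For a shell of radius
2.5 nm the radial Jacobian shifts the mean displacement by
$\mathcal{O}(k_BT/(k r_0))$ but perturbs the variance only at
$\mathcal{O}((\sigma/r_0)^2) \approx 0.1\%$, far below the test
tolerance.)

Each replicate draws Maxwell–Boltzmann initial velocities and its own
thermostat stream from seed `baseSeed + i` (`runReplicates()`, default
three replicates, mirroring the triplicate design of the original study);
trajectories are bit-reproducible for a fixed seed, and the seed is stored
in the trajectory object.

`minimizeSystem()` is plain steepest descent with a backtracking step
(grow 20 % on acceptance, halve on rejection), terminating on a maximum
force component below `tol` or on `maxSteps`.  For the rugged but small
systems here this is robust and fast enough; its contract — a
non-increasing energy sequence — is what the tests assert.

The angle term's gradient has the usual $1/\sin\theta$ factor; at
$\theta \to \pi$ (the builder's rest geometry) the guard takes the exact
$\theta_0 = \pi$ limit of $(\theta - \theta_0)/\sin\theta \to -1$, keeping
forces finite and correct where the lattice actually sits.  Overlapping
beads (pair distance below $10^{-6}$ nm) are rejected with an error rather
than silently producing huge forces, and a trajectory whose coordinates
leave a 1 µm ball or turn non-finite aborts naming the step.

## Stability metrics

`nativeContactFraction()` (Q) counts the fraction of reference contacts
within $1.2\sigma$ (the usual Gō-analysis tolerance, configurable);
`rmsd()` is least-squares superposition RMSD via SVD with the determinant
correction; `surfaceDisplacement()` is the signed distance from the
shell, negative inside.  `restraintDistributionCheck()` compares the
empirical displacement variance against $k_BT/k$ and runs a
Kolmogorov–Smirnov test against the implied Gaussian; because KS assumes
independent samples, trajectory input should be thinned (the `thin`
argument) to the position autocorrelation time, and a $T = 0$ or
zero-variance input is reported as degenerate rather than scored.
Stationary statistics drop the first 20 % of frames by default (`burnIn`).
This instrument suite is this package's own choice of observables; it is
not tied to any particular published analysis protocol.

## Problem sizes

The shipped checks use a single restrained bead for the equipartition test
($2$–$4 \times 10^5$ steps at $dt = 0.05$ ps, $\gamma = 4$ ps$^{-1}$,
giving a variance estimate with sub-percent sampling error), a 5-chain ×
7-bead oligomer for the excluded-volume check (200 ps after minimisation,
scoring the fraction of bead frames deeper than 0.2 nm inside the
particle), and a 5-chain × 4-bead oligomer for the curvature-stress
property (mean Q non-increasing in $k$ at $r_0 = 0.5$ nm, three force
constants × three replicates).  These sizes give clean statistics in
minutes on one core while exercising every term of the model.

## Known limitations

* Rectangular boxes and spherical surfaces only.
* The flat-bottom term is applied per atom, not per molecule
  center-of-mass — deliberately, since the whole peptide is meant to feel
  the excluded volume.
* The coarse-grained stand-in cannot reproduce atomistic observables, and
  quantitative size-dependence results for real peptides are outside its
  reach; the package's claims are therefore property-based: analytic correctness
  of the potentials, exact reproduction of the published setup numbers
  (mdp block, VMD sphere lines), statistical-mechanical consistency of
  the sampler, and qualitative curvature-stress behaviour.
* GRO files carry no chain field; chains are inferred from
  residue-number resets, which mislabels files with globally increasing
  residue numbers (pass `chains` explicitly in that case).
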