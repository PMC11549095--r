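---
title: "Models and methods behind zipmtd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zipmtd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(zipmtd)
```

## The scientific problem

ZIP-family transporters import divalent metals (Zn2+, Fe2+, Mn2+) into the
cytoplasm.  The bacterial prototype is an elevator transporter: a mobile
transport domain carrying the metal slides and rocks against a static
scaffold domain to alternate access between the two sides of the membrane.
Three metal sites line the pathway: the binuclear transport site (M1 the
true transport site, M2 its neighbour about 4.4 A away) and a cytoplasmic
site M3 on the intracellular loop IL2, which folds upon metal binding.
Release from M1 into the cytoplasm can proceed through the M3 site (path 1)
or through a parallel water-filled channel (path 2), and enhanced-sampling
simulations of this system additionally observed backward release to the
periplasm accompanied by a combined hinge rotation plus vertical slide of
the transport domain.

`zipmtd` re-creates the computational side of that study at desk scale: the
collective variables and well-tempered metadynamics machinery, free-energy
reweighting and pathway analysis, rigid-body hinge decomposition, and the
four-scenario release experiment — all exercised on a synthetic
coarse-grained landscape with a brute-force Boltzmann oracle, so every
statistical estimate can be checked against exact quadrature.

## The coarse-grained transporter

The synthetic system replaces the all-atom protein with ~56 frozen
pseudo-atoms (scaffold and transport cages, coordination ligands around each
site, and a 4-atom reference group whose centroid defines the CV origin)
plus a smooth 3D potential for the single mobile ion:

* Gaussian wells at the sites: M1 (20 kJ/mol), M2 (16), the transient
  H177/E276 station (12), M3 (14 when pre-formed, 10 when only the acidic
  ligands are in place, i.e. IL2 unfolded);
* groove wells along the path-1, path-2 and periplasmic waypoint chains
  (6, 5 and 3 kJ/mol) so the channels are genuine valleys;
* barrier Gaussians forming the septum that separates the two cytoplasmic
  channels, a periplasmic gate (20 kJ/mol), and — when the IL2 is folded — a
  narrowing bump (8 kJ/mol) on path 2;
* a one-sided quadratic wall on the ion-reference distance at rho = 25 A
  (the sampling restraint of the emulated protocol) and a smooth cylindrical
  pore wall (radius 5.5 A, tapered in z) representing the protein body.
  Without the lateral confinement the ion leaves the pore sideways and
  release routes would be meaningless.

Occupied sites are modelled as Gaussian bumps of height equal to the removed
well depth — a minimal proxy for the strong electrostatic repulsion between
two divalent cations.  An occupied M3 bump is given a 3 A footprint because
a bound cation plus the folded loop obstructs the whole channel
cross-section; a narrow bump is simply circumnavigated in a 5.5 A pore.

Geometry conventions: the membrane normal is +z, periplasm up, cytoplasm
down, M1 near the origin; the reference centroid sits at (1.5, 0, 3) so that
no pathway station lies exactly on the polar axis of the spherical CVs.
Pseudo-atom masses are equal (the centre of mass is the centroid).  Units
are kJ/mol, angstrom and ps throughout, with kB = 0.0083145 kJ/mol/K and a
default temperature of 303 K.

## Collective variables

The biased CVs are the spherical coordinates (rho, theta, phi) of the ion
about the reference centroid, with theta measured from the membrane normal
and phi = atan2(y, x).  phi is undefined on the polar axis; there the
package returns phi = 0 with a zero phi-gradient and evaluates the theta
gradient on the phi = 0 meridian, so biased dynamics stay continuous
(the same convention used by common CV engines).

The coordination number uses the rational switching function

    CN = sum_j (1 - (r_j/r0)^n) / (1 - (r_j/r0)^m)

with r0 = 4 A, n = 8, m = 16 over all pseudo-atoms.  Because m = 2n the
term is evaluated as 1/(1 + (r/r0)^n), which removes the r = r0 singularity
exactly; at the cutoff the contribution is exactly 1/2 and at r = 2 r0 it is
1/257.  CN is recorded (and used as the second reweighting variable), not
biased.

## Dynamics

The ion moves by overdamped (Brownian) Langevin dynamics,

    x <- x + mobility * F * dt + sqrt(2 D dt) * xi,   D = mobility * kT,

with dt = 0.01 ps and D = 0.5 A^2/ps by default (the M1 basin then
decorrelates in about a hundred steps).  The equilibrium distribution in CV
space — the only quantity these analyses consume — is
integrator-independent, which is why the inertial thermostatted MD of the
all-atom system can be replaced by its overdamped limit.  Pseudo-atoms are
frozen; protein conformational changes are represented by the scenario
switches of the landscape, not sampled as events.  The explicit update is
stable for dt < 1/(mobility k); the stiff steered-pulling spring (1000
kcal/mol/A^2 = 4184 kJ/mol/A^2) therefore requires dt of order 1e-4 ps.

## Well-tempered metadynamics

Hills of initial height 1.0 kJ/mol are deposited every 5 ps at the current
(rho, theta, phi) with widths (0.5 A, pi/16, pi/8), tempered by

    h = w0 * exp(-V(s)/((gamma - 1) kB T)),  gamma = 10,

and evaluated directly from the hill list (no grid cache) with the phi
difference wrapped to (-pi, pi].  Bias forces reach the ion through the
chain rule over the CV gradients.  The long-time bias satisfies
V ~ -(1 - 1/gamma) F, which the tests verify on a 1D double well against
the quadrature oracle (RMS <= 0.3 kT).

## Reweighting and free-energy surfaces

Two standard estimators convert biased samples into unbiased surfaces over
(rho, CN): final-bias weights w ~ exp(+V_final(s_i)/kT), and time-dependent
weights w ~ exp(+(V(s_i, t_i) - c(t_i))/kT) with the tempered offset c(t)
evaluated on a CV grid after each deposition.  Both are exposed and
cross-checked (basin free-energy split within 0.2 kT on a long 1D run); the
time-dependent estimator converges faster on the 2D surface and is the one
used in the acceptance analyses.  F = -kT log of the weighted histogram,
min-shifted; empty bins stay masked, never zero-filled.

The oracle computes F(bin) = -kT log of the Boltzmann integral by dense
quadrature (0.25 A spacing) over a box that encloses the full rho <= 25 A
wall sphere — clipping that sphere biases the bulk-shell entropy and was the
largest error source before being fixed.  The rho-shell Jacobian
(F ~ -2 kT log rho on a flat landscape) is present in both routes and
checked against the closed form.

Basins are found by a watershed sweep in increasing F with
persistence-style merging: a minimum survives only if its lowest connecting
saddle lies at least `depth_threshold` (default 1 kT) above it, which
suppresses histogram-noise minima.  Pathways between basins are minimax
(watershed) paths — the path minimising the maximum F, found by a
Dijkstra-type search and verified against a threshold-connectivity oracle —
rather than steepest descent, which is unstable on coarse grids.

## Hinge + vertical-slide decomposition

After aligning two structures on the scaffold selection (Kabsch, proper
rotations only), the residual transport-domain motion y = R x + t is
decomposed as a hinge rotation about an axis line plus a translation v along
the membrane normal: (I - R) c + v n = t.  For a horizontal hinge axis this
decomposition is mathematically non-unique — a vertical translation can be
absorbed into an offset of the pivot — so the package canonicalises it by
choosing the axis line closest to the reference transport-domain centroid.
`make_conformer_pair()` pivots about that centroid by default, so planted
(angle, slide) pairs are recovered to 1e-6 in the round-trip checks; with an
arbitrary pivot the fitted transform is still exact (residual RMSD < 1e-8)
but the split between pivot offset and vertical slide is representation-
dependent, which is a property of the motion, not of the algorithm.

## Scenarios and route classification

The four experiments mirror the study design: (1) M1/M2 occupied, IL2
unfolded, no metal at M3; (2) M1-M3 occupied, IL2 folded; (3) M1/M2
occupied, pre-formed empty M3, IL2 folded; (4) like 2 but M2 empty.  Routes
are classified geometrically because the original assignment was by
inspection: waypoint spheres of radius 3 A, exit half-planes at the exit-site
z levels, a majority rule over visited waypoints for the two cytoplasmic
paths (the earlier exit crossing wins; with both majorities the better-
covered path wins, ties to path 1).  With the default landscape, scenario 1
releases through path 1 in essentially every replicate, occupying M3
(scenario 2) strictly reduces path-1 releases at paired seeds and lets
path 2, periplasmic escape and retention appear, and removing the M2 metal
(scenario 4) increases retention — the qualitative fingerprint of the
original experiment.  No quantitative correspondence with the all-atom
per-scenario counts is claimed.

## Problem sizes and numerical choices

The shipped analyses use, as the package's own working sizes: 4e6 Langevin
steps (40 ns) for the 2D surface comparison, 1e6 steps for 1D convergence
and occupancy checks, 10 replicates of 2e5 steps per scenario, quadrature
spacing 0.25 A, and a 100 x 80 (rho, CN) grid over [0, 25] x [0, 8].  With
these sizes the reweighted scenario-1 surface agrees with the oracle to
about 0.4 kT RMS over all bins within 5 kT of the minimum.  Degenerate
inputs are handled explicitly: the ion at the reference centroid is a
degeneracy error, empty selections and empty basins raise, out-of-order
hill times raise, and trajectories leaving the bounding box are truncated
and flagged rather than fatal.

## What the synthetic system does and does not show

Passing tests demonstrate that the machinery — CVs, tempered deposition,
reweighting, basin/path analysis, hinge decomposition, route classification
— is internally consistent and exact where closed forms exist.  They do not
validate the all-atom results themselves: the toy landscape has no explicit
protein flexibility, solvent, or electrostatics beyond the bump proxy, the
elevator motion is encoded in scenario switches rather than sampled, and
deposited-structure checks require the real coordinate files, which are not
redistributed with the package.  The measurement pipeline for those checks
is exercised on a clearly-labelled synthetic stand-in
(`synthetic_transport_site()`) instead.
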