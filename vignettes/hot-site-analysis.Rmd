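---
title: "Locating hot sites of a helix-to-beta transition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating hot sites of a helix-to-beta transition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helix2beta)
```

## The scientific problem

Amyloidogenic proteins such as alpha-synuclein convert from helical or
disordered monomers into beta-sheet-rich fibrils.  The earliest step of
that conversion is local: a few short segments of the helical chain - the
*hot sites* - lose their helical structure first and seed the transition
to extended, beta-prone conformations.  Identifying those segments matters
because they are natural targets for aggregation-blocking peptides.

`helix2beta` attacks the question from two independent directions:

* **sequence evidence** - secondary-structure propensities, chameleon
  segments (windowed extended-state propensity above 1 inside
  helix/coil context), hydropathy cores on the Roseman scale, and
  glycine-valine (G-V) flexibility hinges, all computed with a sliding
  window;
* **dynamical evidence** - a coarse-grained targeted-MD (TMD) simulator
  that drives a single chain from a helical to an extended reference
  structure under a harmonic restraint on the collective CA RMSD, followed
  by residue-by-frame kymographs, hot-site detection, and dihedral PCA
  with density-peak clustering.

## Propensity estimation

For residue type $R$ and structure class $S \in \{H, E, C\}$ the
propensity is the fractional-occurrence ratio

$$P(R,S) = \frac{F(R,S)/F(R)}{N_S/N},$$

where $F(R,S)$ counts occurrences of $R$ in class $S$, $F(R)$ all
occurrences of $R$, $N_S$ the residues in class $S$ and $N$ all residues.
`compute_propensities()` implements exactly this on annotated sequence
sets; by construction $\sum_S P(R,S)\,N_S/N = 1$ for every observed
residue, an identity the test-suite checks against a brute-force counting
oracle.  Residues that never occur - or classes that never occur - yield
*undefined* cells which error on lookup rather than silently becoming
zero: imputing 0 would deflate every window average touching the residue.

A reference 20x3 table estimated from a modern culled set of protein
chains ships as `load_builtin_table()`.  Its extremes carry the story:
valine has the largest extended-class propensity (1.87) and alanine the
largest helical propensity (1.41), which is why valine-to-alanine
scanning (`alanine_scan()`) is the natural in-silico probe for the role
of the G-V hinges: the mutation can only lower the windowed beta
propensity (a monotonicity the tests assert).

## Sliding-window scans

All per-residue properties are averaged over a 7-residue window and
assigned to the middle residue (`window_average()`); the usable window
range is 3-11, and 7 is the default because very short fragments have
negligible amyloid-seeding probability at biological concentration.  A
140-residue chain is therefore covered at residues 4-137.

Chameleon regions are maximal runs (at least 2 center residues) with
windowed $P_\beta$ above 1 whose observed secondary-structure context is
helix or coil.  The context string is an explicit input: it is derived
from whatever start structure the user trusts, because published
assignments differ.  For alpha-synuclein we use helix through residue 97
and coil beyond - with a helical start structure the context never
contains strand, so the call reduces to the propensity condition, and the
sensitivity to the exact helix/coil boundary is nil unless the boundary
cuts through a high-$P_\beta$ run.

Hydrophobic cores are above-zero runs of the windowed Roseman (1988)
side-chain hydropathy; the minimum run length is 1 because genuine
two-residue cores exist.  On the bundled alpha-synuclein sequence the
scan reproduces the canonical cores, including the NAC-region span
66-76, and the windowed hydropathy correlates positively with
$P_\beta$ (r about 0.67) and negatively with $P_\alpha$ (r about -0.37)
over the 134 covered residues.

## The coarse-grained targeted-MD simulator

The synthetic-data stage generates the trajectories that the analysis
stages must decode.  It deliberately lives in backbone dihedral space:
the state of an $n$-residue chain is its $(\phi, \psi)$ vector, and
Cartesian coordinates are rebuilt on demand with ideal bond lengths and
angles (N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A, omega fixed trans).
This keeps covalent geometry perfect without constraint algorithms and
makes dihedral PCA directly applicable.  One geometric calibration: the
N-CA-C angle is set to 110.0 degrees, the lower end of the observed
range, so that the canonical alpha-helix at $(\phi,\psi) = (-57, -47)$
reproduces i,i+4 hydrogen-bond geometry (O...N about 2.96 A, N-H...O
within 20 degrees of linear).  At the tabulated generic value of 111.2
degrees the ideal helix misses the 3.0 A donor-acceptor cutoff by less
than 0.1 A, which would make every hydrogen-bond kymograph of a helical
state empty.

### Potential energy

Every torsion sits in a *double-minimum* cosine potential anchored at its
start-state and target-state values (nearest-anchor form):

$$V_i(\theta) = k_i\,\bigl[1 - \max(\cos(\theta - \theta_i^{start}),
                                 \cos(\theta - \theta_i^{target}))\bigr].$$

Both endpoints of the transition are minima of the true Ramachandran
map, so a local backbone potential should not treat the target basin as
strained.  The ridge between the two anchors is the residue's *opening
barrier*; its height $k_i = k_{dih}/f_i$ is controlled by the per-residue
flexibility $f_i \in (0,1]$: $f = 1$ is a fully flexible (chameleon-like)
residue, $f = 0.1$ a stiff one with a tenfold barrier.  We found that a
single well anchored only at the start state cannot complete the
transition at desk scale - any well strength strong enough to produce
hot-site ordering leaves the restraint fighting the wells forever, and
the final RMSD floors at 5-10 A.

On top of the wells acts the TMD restraint on the alpha carbons,

$$U_{TMD} = \tfrac{1}{2} N K \left(R - \rho(t)\right)^2,$$

with $N$ the number of CA atoms, $K = 200$ (reduced energy per
Angstrom squared), $R$ the current best-fit (proper-rotation Kabsch) CA
RMSD to the target and $\rho(t) = \rho_0 (1 - t/\mathrm{steps})$ a
linearly decreasing reference that reaches zero at the final step;
$\rho_0$ defaults to the start-target RMSD, so the restraint starts
unstrained.

### Integration and stability

The dynamics are overdamped Langevin in the torsions:
$\Delta\theta = -\mathrm{dt}\,\partial_\theta V - \alpha (R-\rho)\,
\partial_\theta R + \sqrt{2 k_B T\,\mathrm{dt}}\,\xi$, with the restraint
gradient taken by 0.5-degree central finite differences through backbone
rebuilding.  The bare overdamped restraint factor
$\alpha = \mathrm{dt}\,N K$ cannot be used directly: the effective
restraint stiffness is $N K |\nabla R|^2$ and $|\nabla R|^2$ was measured
to vary from about 0.4 to about 200 A^2/rad^2 along a 40-mer transition,
so an explicit update that is stable early in the run is violently
unstable late.  Two caps make the update stable at any $K$:

* $\alpha \le 0.5/|\nabla R|^2$ - half the Newton step that would land
  $R$ exactly on $\rho$ under the linear model;
* a trust region $\alpha\,|R-\rho|\,\max_i |\partial_{\theta_i} R| \le$
  `max_dr` (default 0.1 rad) limiting the restraint-driven motion of any
  single dihedral per step, because the linearisation of $R$ fails for
  large angular moves.

Below the caps the $K$-dependence survives: with weak wells the *median*
tracking deviation $|R - \rho(t)|$ is about 1.9 A at $K = 20$, 0.18 A at
$K = 200$ and 0.03 A at $K = 2000$ (seeded 20-mer runs), which is the
band-narrowing property the tests assert.  The *maximum* deviation is
dominated by a $K$-independent mid-transition episode where the gradient
field is strongly curved; we report the median as the band statistic for
that reason.

### Default study conditions

The shipped defaults are a 40-residue chain, 5000 steps, $K = 200$,
$k_{dih} = 40$, $k_B T = 1$, $\mathrm{dt} = 10^{-5}$, frames saved every
25 steps (201 frames).  They were calibrated once so that (i) a
uniform-flexibility chain completes the transition - mean final CA RMSD
1.94 A over three seeds, with single-run values between about 1.5 and
2.2 A - and (ii) segments planted at flexibility 1.0 against a 0.1
background open visibly earlier.  A full 40-mer run takes roughly 10 s on
one core; the 140-residue scale is supported but not required by any
test.  Reverse runs (extended to helical) converge less tightly (about
3.3 A): refolding into a compact target is genuinely harder for
RMSD-gradient-driven dynamics because many tangled conformations share
similar $R$ near the end, and the forward and backward pathways differ -
the reversed trajectory is not a time-reversed copy of the forward one,
which the tests also assert.

### What the generator does and does not emulate

It reproduces the *logic* of the all-atom experiment - a biased
transition whose locally flexible segments open first - with planted,
known ground truth, so recovery can be scored.  It does not emulate side
chains, solvent, real energy scales or time scales, tertiary packing, or
inter-chain interactions.  Passing the recovery tests therefore shows
that the analysis stack (kymographs, opening times, region calling,
clustering) correctly decodes early-opening segments from trajectories of
this kind; it does not by itself validate conclusions about any real
protein.

## Kymographs and hot-site detection

All three kymographs are residue-by-frame matrices over 7-residue
windows:

* **local RMSD**: each window is superposed *locally* between frame $t$
  and frame 0, so rigid displacement of an intact segment scores zero and
  only internal deformation registers (a global-superposition variant is
  available by flag; published per-residue RMSD maps rarely state their
  alignment frame, and the local choice is what makes the band pattern a
  readout of opening rather than of lever-arm motion);
* **delta-Rg**: windowed CA radius-of-gyration change against frame 0;
* **hydrogen bonds**: backbone N-H...O bonds counted by donor window,
  with donor-acceptor distance at most 3.0 A and N-H...O within 20
  degrees of linearity; amide hydrogens are inferred geometrically
  (1.01 A along the bisector of the N-C(prev) and N-CA directions)
  because the model carries none.

Hot-site detection turns the RMSD kymograph into an opening-time profile:
a residue opens at the first frame where its cell reaches half
(`threshold_frac`) of its own final deformation; residues with zero final
deformation never open.  Hot regions are contiguous runs (at least 4
centers) of residues opening strictly before the earliest quartile
(`early_frac = 0.25`) of all finite opening times, ranked into priorities
by median opening time.  The strict inequality makes the degenerate case
- every residue opening simultaneously - yield no regions instead of one
chain-wide region.  Before thresholding, opening times are smoothed with a moving median
over the same 7-center width as the kymograph window
(`smooth_radius = 3`): the kymograph columns are already window-averaged,
and smoothing the derived statistic at the matching scale stops single
noisy centers from fragmenting or truncating a region.  Both the threshold and the quantile
are exposed because the choice of statistic is ours; published analyses
identify the bands visually.

## Dihedral PCA and clustering

`dihedral_pca()` embeds every defined torsion as $(\cos\theta,
\sin\theta)$ - removing the 360-degree wrap-around that breaks linear PCA
on raw angles - mean-centers the columns, and eigendecomposes the
covariance (via SVD through `prcomp`).  The first three components span
the space used for clustering, following the convention of keeping the
three largest dPCs.

`peak_pick_clusters()` histograms the 3-D projections on a 32-bin-per-axis
grid, smooths the counts with a separable Gaussian of 2 cells, and takes
as peaks the local maxima (26-neighbourhood) above 10% of the global
maximum.  Every occupied cell is assigned by steepest ascent; frames
whose ascent ends below the floor stay unassigned, so populations need
not sum to 100%.  Two numerical notes: (i) without smoothing, a
2000-frame histogram in 32^3 cells has single-digit counts and hundreds
of spurious local maxima - the smoothing width is the resolution limit,
and blobs closer than about a cell merge (a documented floor, exercised
in the tests); (ii) the floor gates which *maxima* count as clusters
rather than which *frames* get assigned - applying it to frames would
unassign the entire low-density shell of every 3-D Gaussian cluster
(about 20% of mass at a 10% floor) and make recovered populations
systematically and badly low, which contradicts recovering known mixture
weights to a few points.  With the defaults, 20/50/30 mixtures at
n = 2000 are recovered with every population within about 2.5 points.

Cluster representatives are the assigned frames nearest (Euclidean, in
the kept components) to their cluster centroid, ties to the lowest frame
index; `rmsd_matrix()` then places the representatives between the
helical and extended endpoints, and on toy transition runs the
temporally intermediate cluster sits strictly between the endpoint RMSD
extremes.

## Known limitations

* The simulator's reduced units do not map onto kcal/mol or nanoseconds;
  only orderings and dimensionless comparisons transfer.
* Hot-site recovery is stochastic: with the default study conditions the
  three-seed mean Jaccard against planted loci is typically 0.5-0.8, and
  an occasional run resolves only one of two planted segments.
* The chameleon caller inherits whatever helix/coil context it is given;
  with a strand-containing context the same profile yields fewer calls.
* Backbone-only hydrogen bonds undercount relative to all-atom counts;
  the kymograph is meant for relative (residue-vs-residue) reading.
* `read_pdb_chain()` keeps the first alternate location and drops
  insertion-code subtleties; it is a backbone extractor, not a general
  PDB model.
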