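---
title: "Detecting hinge residues from coarse-grained normal modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hinge residues from coarse-grained normal modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingescan)
```

## The problem

Many two-domain proteins move: their domains pivot about a small set of
residues — a hinge — and that motion can be functionally decisive (for
example, a conformational change required for receptor-mediated
endocytosis of an inhibitor such as TIMP-1). Candidate hinge residues
are attractive mutation targets precisely because they sit outside
binding epitopes and outside regular secondary structure, yet control
the interdomain motion.

hingescan identifies such residues from a single structure. The
reasoning chain is:

1. coarse-grain the structure to one C-alpha bead per residue;
2. connect the beads by harmonic springs whose stiffness reflects chain
   connectivity, secondary structure and disulfide bonds (an elastic
   network model, ENM);
3. solve the normal modes of the resulting Hessian; discard the six
   null-frequency rigid-body modes; take the lowest-frequency internal
   mode (mode 7 in the 1-based all-mode numbering), preferring the most
   *collective* of the low modes;
4. profile every residue along that mode by two complementary scalars —
   **deformation energy** (how much elastic strain the residue absorbs)
   and **C-alpha fluctuation** (how far it actually moves);
5. call hinge regions where deformation is high but fluctuation low —
   the signature of a pivot — after min-max normalizing and superposing
   the two tracks;
6. exclude residues inside helices and sheets (mutating those risks
   misfolding); what survives are the candidate residues;
7. check whether candidate-stabilizing hydrogen bonds survive along one
   full period of harmonic motion in the chosen mode; and
8. cross-validate against principal component analysis (PCA) of any
   available conformational ensemble.

## The elastic network model

Beads $i$ and $j$ at reference distance $r_{ij}$ are joined by a spring
of stiffness $k_{ij}$:

* chain neighbours ($|i-j| = 1$): $k_{ij} = k_\mathrm{bond}$
  (default 1000);
* disulfide-bonded residue pairs: $k_{ij} = k_\mathrm{ss}$ (default
  500), regardless of distance;
* helix 1–4 pairs ($2 \le |i-j| \le 4$ inside one helix span) and
  beta-bridge pairs (both beads in sheet spans, $r_{ij} \le
  r_\mathrm{bridge} = 5.5$ Å): $k_{ij} = \gamma_\mathrm{sse}\, c /
  r_{ij}^6$ with $\gamma_\mathrm{sse} = 5$;
* all other pairs within $r_\mathrm{cut} = 15$ Å:
  $k_{ij} = c / r_{ij}^6$ with $c = 10^4$;
* pairs beyond the cutoff: 0.

The units are an arbitrary consistent energy/Å² scale; every quantity
the pipeline reports is either normalized, a ratio, or compared within
one run, so only the *ratios* between these constants matter. The
published parameterizations of secondary-structure-aware C-alpha force
fields differ in detail between implementations and versions; the
constants above are this package's defaults and are echoed into every
run manifest, so a validation run documents exactly what it used.

The ENM potential is $E = \tfrac12 \sum_{ij} k_{ij} (|r_{ij}| -
|r^0_{ij}|)^2$, and the Hessian at the reference is the standard
pairwise form: off-diagonal $3\times3$ blocks $-k_{ij}\,\hat r_{ij}
\hat r_{ij}^{\mathsf T}$ with compensating diagonal blocks, so
translations are exact null vectors. Tests verify the analytic Hessian
against central finite differences of $E$ (agreement $\le 10^{-5}$ at
step $10^{-4}$ Å).

No mass weighting is applied (uniform beads); reported "frequencies"
are $\sqrt{\lambda}$ in model units.

## Mode classification and numerical choices

* **Rigid-mode flagging.** Modes with $\lambda < \texttt{zero\_tol}
  \cdot \lambda_{\max}$ are flagged rigid. The default is
  $10^{-9}$: true null modes of a well-built Hessian sit at
  $10^{-16}$–$10^{-13}$ relative to $\lambda_{\max}$, while genuinely
  soft internal motions of a two-domain system can reach
  $10^{-7}$–$10^{-6}$ relative — a looser threshold silently swallows
  the very interdomain modes the analysis is after. A warning (not an
  error) is raised when more than six modes fall under the threshold,
  since degenerate geometries legitimately have extra near-zero modes.
* **Sign convention.** Eigenvector sign is fixed so each mode's
  largest-magnitude component is positive; all profiles are invariant
  to the sign, but fixed signs make runs byte-reproducible.
* **Deformation energy** uses the axis-projected pair term
  $\tfrac12 k_{ij} (\hat r_{ij} \cdot (u_i - u_j))^2$, each pair's
  energy split equally between its two beads. This is the same
  quadratic form as the Hessian, so per-mode profiles close exactly:
  $\sum_i d_i = \lambda_m / 2$ for a unit eigenvector (tested at
  $10^{-9}$ relative). The full-distance-change variant is deliberately
  not implemented; mixing it with the Hessian's quadratic form would
  break the closure identity.
* **Fluctuation** of mode $m$ is $f_i = \lVert e_{m,i}\rVert^2 /
  \lambda_m$; summed over all internal modes it equals the diagonal of
  the Hessian pseudo-inverse (tested at $10^{-6}$ against an
  independent generalized-inverse route).
* **Collectivity** is the exponential-entropy measure
  $\kappa = N^{-1}\exp(-\sum_i p_i \ln p_i)$ with $p_i$ the normalized
  per-bead squared amplitude, using the convention $0 \ln 0 = 0$;
  $\kappa = 1$ for a perfectly delocalized mode and $1/N$ for a
  single-bead mode.
* **Normalization** for the superposed hinge plot is min–max (min to 0,
  max to 1). A constant profile cannot be normalized and is an error
  rather than a silent all-zero track.

## Hinge calling

Residue $i$ qualifies when $d^{\mathrm{norm}}_i \ge \tau_\mathrm{def}$
and $f^{\mathrm{norm}}_i \le \tau_\mathrm{fluct}$. Qualifying residues
merge into regions, bridging runs of at most `max_gap` non-qualifying
residues. Defaults: $\tau_\mathrm{def} = 0.4$, $\tau_\mathrm{fluct} =
0.25$, `max_gap = 1`. Published hinge analyses typically display the
superposed tracks and mark regions by eye; fixed numeric thresholds
make the call reproducible, and because any threshold choice is
somewhat arbitrary every report also carries the threshold-free
combined score $S_i = d^{\mathrm{norm}}_i (1 - f^{\mathrm{norm}}_i)$ so
rankings can be inspected independently. Raising $\tau_\mathrm{def}$ or
lowering $\tau_\mathrm{fluct}$ can only shrink the qualifying set
(tested as a monotonicity property).

The secondary-structure exclusion then removes region residues inside
helix/sheet spans; spans come from the PDB HELIX/SHEET records (or an
override table — no DSSP-style recomputation is attempted, since
assignments differ between tools and the input records are the
convention most structures ship with).

## Hydrogen bonds and persistence

The bond criterion is a heavy-atom donor–acceptor distance strictly
below 3.2 Å between polar atoms (N/O) of residues at least two apart in
sequence. No hydrogens are placed and no angle term is applied: the
coarse-grained pipeline has no hydrogen positions, and the distance
criterion is reported as exactly that.

Persistence along a mode is measured on one full period of harmonic
motion $x(\phi) = x_0 + A \sin(\phi)\, e_m$, sampled at 21 uniformly
spaced phases over $[0, 2\pi]$ (21 frames keep the motion smooth and,
because $21 - 1$ is divisible by 4, the grid contains the peak phases
$\pi/2$ and $3\pi/2$ exactly, so the trajectory attains its nominal
maximum RMSD $A/\sqrt N$ exactly). The default amplitude is calibrated
so that peak C-alpha RMSD from the reference is 2.0 Å — large enough to
strain a marginal hydrogen bond, small enough to stay within the
harmonic regime. Since no published amplitude convention exists for
such intermediate structures, persistence is best read as a function of
amplitude; the analysis scripts report it at several cutoffs for the
same reason.

Heavy atoms move rigidly with their residue's C-alpha displacement
(the trajectory is C-alpha-resolution). This captures backbone
separation across a hinge but **not** side-chain reorientation; a bond
broken by a rotamer flip would be missed.

## Trajectory PCA

Frames are rigid-body fitted onto the first reference frame
(least-squares rotation + translation), then the $3N \times 3N$ sample
covariance **about the trajectory mean** is eigendecomposed. The
reference frame defines only the fitting target, not the expansion
point — using the mean is standard PCA and keeps the eigenvalue sum
equal to the total variance. Per-residue contributions of component $p$
are the squared per-residue norms of the unit component vector (each
profile sums to 1). Three components are retained by default. PCA is
C-alpha-only, matching the rest of the pipeline; an all-atom ensemble
must be reduced to C-alpha before import (multi-model PDB).

## What the synthetic generators emulate — and what they do not

`make_helix` gives an ideal alpha-helix (rise 1.5 Å, 100°/residue,
radius 2.3 Å) with idealized backbone N/C/O offsets and optional
Gaussian coordinate noise: a generic, connected, well-behaved fold for
null-mode counts and oracle checks.

`make_dumbbell` is the ground-truth hinge system: two compact domains
joined by an extended linker, with the linker span recorded as truth.
Three construction choices matter and were made once, on physical
grounds:

* **Domains are jittered close-packed (fcc) clusters** at protein-like
  density (~120 Å³/residue), chained by a greedy nearest-neighbour
  path. Loosely packed random walks leave dangling beads whose
  transverse motion is nearly free, polluting the low-frequency
  spectrum with local soft modes that have nothing to do with
  interdomain motion.
* **The linker bows over the gap** (compaction 0.6: the straight
  attachment distance is 60% of the linker contour) and carries a small
  alternating out-of-plane offset. A straight single-strand tether
  leaves torsion about its own axis with essentially no harmonic
  restoring force — an exact or near-exact mechanism of a central-force
  network — which again no compact folded protein shows; the bow brings
  the domain surfaces within the interaction cutoff so torsion is
  braced by many weak interface springs while the interdomain bend
  remains the softest internal motion.
* **Domains are annotated as sheet spans**; the linker is coil. This
  mirrors a folded two-domain protein, engages the beta-bridge
  stiffening inside the domains, and exposes only the linker to the
  secondary-structure exclusion — exactly how the real protocol treats
  a crystallographic structure.

The canonical study condition used across the analysis scripts and the
acceptance script is 24 residues per domain, a 5-residue linker and
compaction 0.6 (53 residues total); the helix fixture uses 100 residues
with 0.3 Å noise. These sizes keep every eigendecomposition dense and
fast while leaving a clear spectral separation between rigid, soft
interdomain and internal modes.

`sample_trajectory` draws frames as the reference plus independent
Gaussian amplitudes along planted internal modes — an ensemble whose
covariance is known exactly ($\sum_k \sigma_k^2 e_k e_k^{\mathsf T}$),
so PCA recovery is checkable against ground truth (sample covariance
verified at 2000 frames; mode recovery at 500; subspace recovery of two
planted modes at 1000 frames within 10° principal angle).

What the generators do **not** emulate: real side-chain packing,
sequence-dependent stiffness, crystallographic disorder, anharmonicity,
solvent damping, or the time correlation structure of genuine MD
(frames are i.i.d., not a trajectory in time). Passing tests therefore
demonstrate the machinery is mathematically correct and the hinge logic
sound on a system whose hinge is known — not that any particular
force-field parameterization reproduces a specific protein's published
per-residue profiles. For a crystallographic validation the package
reads any PDB entry; the residue-numbering offset between the crystal
and the mature-protein convention, and the chain to analyse, are
configuration (`numbering_map()`), never hard-coded, because those
conventions vary per entry.

## Degenerate inputs and tie-breaks

* Altloc duplicates: highest occupancy wins, ties by file order.
* Residues ordered by (chain, residue number, insertion code);
  insertion-coded numbering handled via explicit overrides in the map.
* Coincident beads (< $10^{-6}$ Å) are an error naming the pair;
  collinear geometries warn about extra near-null modes.
* A disconnected spring network is an error naming component sizes
  (mode math would be ill-posed).
* Rigid modes requested for fluctuation are an error ($1/\lambda$
  undefined); for deformation energy they return the flagged all-zero
  profile, which is itself used as a test case.

## Limitations

* Force-field constants are package defaults, not a fit to any specific
  published parameter set; per-residue profiles on real structures are
  expected to be close in shape but not numerically identical to other
  ENM implementations (tests cross-check fluctuation profiles against
  an independent implementation at correlation > 0.9 on the same
  structure).
* Hinge thresholds are a reproducible operationalization of a call
  that is usually made by eye; region counts on real structures are
  threshold-sensitive, which is why every report prints its thresholds.
* Hydrogen-bond treatment is distance-only at heavy atoms, with rigid
  per-residue atom displacement along modes.
* Dense eigendecomposition targets structures up to roughly 1000
  residues; larger systems would need a sparse/iterative solver, which
  is out of scope.
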