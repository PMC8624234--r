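---
title: "Interpreting single-molecule pulling experiments with elastic-network normal modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting single-molecule pulling experiments with elastic-network normal modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsnma)
```

## The problem

In an optical-trap force-spectroscopy experiment a protein is tethered
between two beads through DNA handles attached at two engineered
residues, and force is applied along the line joining the attachment
points.  The experiment yields a one-dimensional force spectrum:
unfolding "rips", intermediates, refolding events.  What it does not
yield is a structural assignment — *which* domain came apart first,
*which* segments form the intermediates.  Steered molecular dynamics
can provide that assignment but is expensive.  `fsnma` implements a
much cheaper route: harmonic normal-mode analysis of a coarse-grained
elastic network, combined with a buried-core volume analysis, to rank
the mechanical integrity of domains and candidate unfolding segments.

The method is interpretive, not predictive in a quantitative sense: it
asks which internal motions of the folded state are geometrically
aligned with the applied force, amplifies the structure along those
motions, and watches which domain loses its packed core first.

## The model

The protein is reduced to one bead per residue at the C-alpha
position.  Beads closer than a cutoff $R_c$ in the reference structure
are joined by identical harmonic springs, giving the anisotropic
elastic network potential

$$ V = \sum_{d^0_{ij} < R_c} \frac{\gamma}{2}\,(d_{ij} - d^0_{ij})^2 , $$

where $d^0_{ij}$ are reference distances.  `build_hessian()` assembles
the $3N \times 3N$ second-derivative matrix of this potential: the
off-diagonal super-element of a contact is
$-\gamma\,\hat e_{ij}\hat e_{ij}^{\!\top}$ with $\hat e_{ij}$ the unit
bond vector, and diagonal super-elements enforce translation
invariance.  `compute_modes()` diagonalizes it; the six zero
eigenvalues are the rigid-body motions, and every mode index reported
anywhere in the package is 1-based over the *non-zero* modes.

Note the potential is written without a conventional $\tfrac12$ on the
per-contact term in much of the literature; we keep the explicit
$\gamma/2$ form so that $\gamma$ is the spring constant proper (the
two-bead network has its single internal eigenvalue at exactly
$2\gamma$, and the effective force constant between the two beads is
exactly $\gamma$).  A uniform-force-constant network has no absolute
energy scale: all fluctuation and stiffness outputs are in
$\gamma$-normalized units and only *comparisons* within one
parameterization are meaningful.  The package deliberately does not
pretend to absolute Å² fluctuations.

### Parameters that matter

* `cutoff_rc` (Å, default 15): contact cutoff.  Customary values run
  from 8 to 20 Å; 15 Å is the mid-range and the common anisotropic
  network default.  Values outside 8–20 warn.
* `gamma` (default 1): spring constant; rescales eigenvalues linearly
  and leaves eigenvectors untouched.
* `n_modes` (default 50 non-zero): enough for fluctuation profiles
  and mode selection.  Mechanical stiffness integrates over *all*
  modes, so `residue_stiffness()` and `effective_force_constant()`
  refuse truncated mode sets rather than silently underestimating
  compliance.
* `zero_tol` (relative, default 1e-8): eigenvalues below
  `zero_tol * max(lambda)` are rigid-body modes.  A safety assertion
  requires three orders of magnitude between the largest discarded
  and smallest retained eigenvalue; an ambiguous split raises an
  error instead of guessing.  A connected network must produce
  exactly six zero modes; any other count triggers a structural
  warning (it almost always means a disconnected contact graph or a
  floppy mechanism).

## The five-step procedure

`run_pipeline()` drives the workflow from a YAML/JSON configuration:

1. **Survey.**  Coarse-grain the structure and compute the static
   buried core (below).  The survey often already suggests which
   terminal segments are weakly packed and whether truncated forms
   should be analysed as well; truncations are configured explicitly,
   never guessed by the code.
2. **Align.**  `align_pulling_axis()` rotates the model so the unit
   vector between the two attachment C-alphas coincides *exactly*
   with the target axis (+z by default) and zeroes the centroid.
   Only the direction is pinned; spin about the axis is left free.
   Alignment is a rigid motion, so the spectrum is unchanged — the
   point is purely that "motion along the force" becomes "motion
   along z".
3. **Modes.**  ENM normal modes of the (possibly truncated) model.
4. **Analyse and select.**  Per-residue square fluctuations
   ($f_i = \sum_k \lambda_k^{-1}\lVert a_{k,i}\rVert^2$, first 100
   modes by default), per-residue stiffness (mean Eyal–Bahar
   effective force constant over all partners), mode collectivity
   (Brüschweiler entropy measure, in $[1/N, 1]$), and the signed
   z-components of each candidate mode.  Candidate modes are the
   first 10 non-zero modes plus the 10 most collective of the first
   50.  A mode is *separating* when the two domains' mean
   z-components have opposite signs; among those, modes whose
   separation $\lvert\bar c_A - \bar c_B\rvert$ reaches at least 25%
   of the best candidate's are selected, ranked by separation.  The
   published procedure makes this choice by visual inspection of
   z-component plots; the rule above is our reproducible
   codification, and `select_separating_modes()` always returns the
   full per-candidate report so a human can override it.  Domain
   means are computed on the raw orthonormal eigenvectors, not
   $1/\sqrt\lambda$-scaled ones: scaling would mix "how aligned" with
   "how soft", and softness is already honoured at the sampling
   stage.
5. **Deform and rank.**  `sample_ensemble()` draws, per conformation,
   a random coefficient for every selected mode (standard deviation
   $\propto 1/\sqrt{\lambda_k}$ by default, so softer modes dominate
   as they would thermally; `equal` weighting is available because
   published tooling behaviour varies), then rescales the combined
   displacement so the raw RMSD from the reference equals the target
   exactly.  `rmsd_ramp()` repeats this at increasing targets
   (2–12 Å by default).  Ensemble burial statistics then rank the
   domains: the domain with the lowest mean buried volume has the
   lowest structural integrity and is expected to come apart first.

### Deformation semantics

Deformation is purely linear: frames are the reference plus a vector
in the span of the selected eigenvectors.  At 12 Å RMSD such frames
are not physically realizable chains — bonds stretch, side-chain
packing is meaningless.  That is intentional and consistent with the
method's qualitative use: the frames are probes of *which contacts
survive* large motion along force-aligned modes, not candidate
structures.  No minimization or rebuilding is attempted.  Exactness
contracts: a single-mode deformation at target $t$ uses amplitude
$s = t\sqrt N$ (unit eigenvector), every stochastic frame's RMSD
equals its target to 1e-6 Å, and the logged per-frame coefficients
reproduce every frame bit-exactly.  Because the rescale couples the
coefficients of one frame, their per-frame squared ratios (not their
marginal variances) carry the $1/\lambda$ weighting signature.

Randomness is seeded everywhere: ensembles take an explicit seed, and
ramps derive per-step sub-seeds as `seed + 7919 * step` so any single
step can be reproduced in isolation.  The generator state of the
session is saved and restored around every draw.

## The buried-core model

The integrity proxy is the summed volume of *buried* residues: the
complement of the solvent-exposed surface.  Because deformed frames
contain only C-alpha positions, burial must be computable from
C-alpha traces — so the same unified model is used for intact and
deformed structures: each residue is a sphere centred on its C-alpha
whose radius derives from its literature mean residue volume
($r_i = (3V_i/4\pi)^{1/3}$, Zamyatnin's table, bundled as data and
swappable).  Exposure is measured by deterministic quadrature: points
are placed on each probe-inflated sphere by a golden-spiral rule
(no RNG, bit-reproducible), and the exposed fraction is the share of
points not covered by any neighbour's inflated sphere.  A residue is
buried when its exposed fraction falls below `exposure_threshold`
(default 0.05, probe 1.4 Å, 960 points — doubling the point count
moves fractions by less than 0.01 on the bundled fixtures).

The published analyses do not state their burial criterion or volume
table, so absolute buried volumes depend on this convention; the
pipeline therefore always reports the threshold next to the volumes,
and comparative statements (lobe A vs lobe B, wild-type vs mutant)
are the supported use.  Ensemble statistics are reported both over
all frames and restricted to frames with non-zero buried volume: once
a domain's core is fully dispersed in most frames, the all-frame mean
mostly counts zeros, and the non-zero-restricted mean is the better
measure of how compact the surviving frames are.

## Synthetic fixtures: what they emulate and what they don't

Three generators provide models with analytically known mechanics so
the whole pipeline is testable without any downloaded structure:

* `make_dimer()` — one spring; eigenvalue $2\gamma$, five zero modes,
  pair stiffness $\gamma$, all in closed form.
* `make_helix()` — ideal α-helix trace (rise 1.5 Å, 100° per residue,
  radius 2.3 Å, hence consecutive C-alpha distances of ~3.8 Å);
  exercises connectedness, end effects and finite-difference
  Hessian checks.
* `make_dumbbell()` — two rejection-sampled bead clusters (uniform in
  a sphere, minimum bead distance 3.4 Å) joined by a short linker
  along x, with tether points at the outer extremes.  The linker
  beads are given an off-axis zig-zag: a perfectly collinear linker
  would leave relative lobe torsion about the tether axis as a
  zero-energy mechanism (and with only two linker beads such a
  mechanism exists regardless, which is why the default linker has
  three).  Making one lobe's packing radius larger at equal bead
  count produces a measurably looser lobe — a known-answer system
  for separating-mode selection and integrity ranking.  With a 30%
  radius difference the pipeline recovers the engineered weak lobe
  essentially always; this parameter-recovery experiment (20
  replicate seeds) is part of the test suite.

What the fixtures do *not* emulate: real secondary-structure
topology, sequence-dependent packing, chain connectivity constraints
in the deformed frames, or the sequence-discontinuous domains of real
two-domain proteins.  A passing suite therefore demonstrates that the
machinery is correct and that the procedure recovers engineered
packing asymmetry — not that any particular real protein will show a
particular ranking.  The case-study analyses on the published
structures (T4 lysozyme wild-type vs circular permutant, DnaK
nucleotide-binding and substrate-binding domains, glucocorticoid
receptor LBD) are included in the test suite but require the PDB
entries 2LZM, 2O4W, 2KHO, 4B9Q and 1M2Z, which are not redistributed
with the package; `scripts/fetch_structures.R` materializes compact
C-alpha extracts for users with network access.

## Numerical and design choices

* **Structure input.**  Fixed-column PDB via `bio3d`; alternate
  locations resolved by highest occupancy (ties: first encountered);
  multi-model files honoured; HETATM excluded from the coarse model
  by default (retained as beads on request).  Residue numbering is
  author numbering, 1-based, inclusive ranges, everywhere — the same
  convention used in the experimental literature.  Missing residues
  are simply absent beads; no gap modelling.  Multi-chain entries
  default to the first/selected protein chain, configurable.
* **Superposition.**  Kabsch via SVD with reflection correction;
  collinear inputs are rejected as degenerate rather than silently
  reflected.
* **Stiffness.**  `residue_stiffness()` evaluates the all-partner
  mean through the Hessian pseudo-inverse (an $O(N^2)$ reorganization
  of the same mode sum; the two routes agree to 1e-8 in the tests).
* **Degenerate inputs.**  Coincident beads, coincident attachment
  points, empty selections, out-of-range residue ranges, and
  truncated mode sets for stiffness all raise errors; a disconnected
  contact graph warns at Hessian build time and again at
  mode-counting time.
* **Problem sizes.**  The shipped tests and the acceptance script run
  on fixtures of 2–51 beads with ensembles of 10–10000 frames and
  ramps of 3–6 steps; these sizes were chosen so each statistical
  check has comfortable resolution for its tolerance while the whole
  suite stays fast.

## Known limitations

* Harmonic modes of the folded minimum cannot describe unfolded
  states; everything here is about the *first* stages of mechanical
  disassembly.
* Results inherit the starting structure: with a compact and an
  extended conformation of the same domain the method can reach
  opposite conclusions, and when parallel unfolding pathways exist it
  will usually surface only one per starting structure.
* The buried-volume proxy has no absolute calibration; only
  comparisons under a fixed parameterization are meaningful.
* Tether attachment is modelled at C-alpha resolution; the real
  linkage chemistry (engineered cysteines, DNA handles) is outside
  the model.

## A minimal end-to-end run

```{r example, eval = FALSE}
db <- make_dumbbell(lobe_radius_b = 10.4, seed = 2)  # loose lobe B
al <- align_pulling_axis(db$model, db$pulling)
modes <- enm_modes(al$model, n_modes = "all")
sel <- select_separating_modes(modes, db$domains)
ens <- sample_ensemble(modes,
  deformation_spec(sel$selected, target_rmsd = 6,
                   n_conformations = 50, seed = 1))
ensemble_burial(ens, db$domains)
```

The same analysis, file-driven, is `fsnma run --config run.yaml`
through the installed command-line script, or `run_pipeline()` from R.
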