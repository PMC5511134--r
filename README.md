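# hingescan

Hinge-residue detection from coarse-grained protein normal modes.

Two-domain proteins often work by moving: their domains pivot about a
small set of hinge residues, and disrupting that motion can switch off a
biological activity without touching binding or stability. hingescan
finds such residues from a single structure. It builds a C-alpha elastic
network model (ENM) whose spring constants respect chain bonds, helix
1–4 contacts, beta bridges and disulfide bridges, solves the normal
modes, and profiles each residue along the lowest-frequency internal
mode (mode 7, after the six null-frequency rigid-body modes) by two
complementary tracks:

* **deformation energy** `d_i = Σ_j ¼ k_ij (r̂_ij · (u_i − u_j))²` —
  the elastic strain residue *i* absorbs under the mode displacement
  *u* (per-mode profiles sum exactly to λ/2);
* **C-alpha fluctuation** `f_i = ‖e_i‖² / λ` — how far the residue
  actually moves.

Hinge residues are those with *high* deformation but *low* fluctuation:
locally strained pivots that barely translate. After min-max
normalization the two tracks are superposed, contiguous regions
satisfying `d ≥ τ_def` and `f ≤ τ_fluct` are called, and residues inside
helices/sheets are excluded (poor mutation targets). For surviving
candidates the package measures whether stabilizing hydrogen bonds
(heavy-atom distance < 3.2 Å) persist along one full period of harmonic
motion in the mode, and cross-validates the mode against PCA of any
supplied conformational ensemble. Mode collectivity
`κ = exp(−Σ p ln p)/N` guides the choice among the low-frequency modes.

Seeded synthetic generators (an ideal helix; a two-domain dumbbell whose
flexible linker is the recorded ground-truth hinge; ensembles sampled
along planted modes) make every stage testable end to end.

## Worked example

```r
library(hingescan)

db <- make_dumbbell(24, 5, seed = 1, compaction = 0.6)  # linker = 25..29
model <- build_force_constants(extract_calpha(db$structure))
modes <- compute_modes(build_hessian(model))
modes
#> <mode_set> 159 modes over 53 beads; 6 rigid; first internal mode: 7

report <- hinge_report(model, modes)
report
#> <hinge_report> mode 7: 1 regions, 5 candidate residues (tau_def = 0.4, tau_fluct = 0.25, max_gap = 1)
#>   candidates: 25 26 27 28 29
db$linker_span
#> [1] 25 26 27 28 29
```

The five candidate residues are exactly the constructed linker: the
deformation/fluctuation signature localizes the hinge. The same call on
a PDB file goes through `run_pipeline()`:

```r
run_pipeline(list(structure = "protein.pdb", chain = "B",
                  numbering_offset = 0, out = "results/run1", seed = 1))
```

which writes per-residue tables, the mode table, a JSON hinge report,
the mode trajectory as multi-model PDB, optional PCA tables, and a run
manifest echoing every parameter used.

## Analysis workflow

The `analysis/` directory holds the study as numbered thin drivers over
the package (each regenerates its inputs and writes text tables under
`results/`):

```sh
Rscript analysis/01_build_structures.R    # helix + dumbbell study systems
Rscript analysis/02_normal_modes.R        # ENM modes, profiles, collectivity
Rscript analysis/03_hinge_detection.R     # hinge calling vs ground truth
Rscript analysis/04_contact_persistence.R # contact survival along mode 7
Rscript analysis/05_trajectory_pca.R      # PCA recovery of the planted mode
```

Stage 3 prints, for the canonical dumbbell, candidates `25 26 27 28 29`
against ground-truth linker `25–29`; stage 5 reports
`|cos(PC1, planted mode 7)| = 1.0000` with a top-eigenvalue error of
2.2% at 500 frames.

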