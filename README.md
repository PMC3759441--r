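# rmrscore

Knowledge-based scoring and essential dynamics for ligand-bound protein
conformational ensembles.

## Who this is for

Structural bioinformaticians and molecular modellers who have an
MD-style ensemble of a ligand-bound complex (e.g. a cytochrome P450 with
its substrate and heme cofactor) and need to answer: *which snapshot best
represents the native-like bound complex, which pocket residues drive the
interaction, is the catalytically decisive contact geometrically
feasible, and what are the ensemble's dominant collective motions?*

## What it computes

**Scoring.** A distance-binned, mean-reference-state pair potential is
trained from a table of intermolecular contact observations
`(type_a, type_b, distance)`. With per-type-pair bin probabilities
`P_ab(k)` (pseudocount-smoothed histograms on half-open 0.2 Å bins over
[0, 6) Å by default) and the type-pooled reference `P_ref(k)`, an atom
pair at distance `d` in bin `k` scores

    s = -ln( P_ab(k) / P_ref(k) )

(negative = favourable; exactly 0 outside the contact range). A frame's
total is the sum over all ligand × pocket/cofactor atom pairs; the frame
with the lowest total is the most native-like representative. Totals
decompose exactly per pair and per residue, residues classify by
substrate recognition site (SRS), and the reactive pair (e.g. ferryl
oxygen ↔ hydroxylation carbon) is reported with its distance and a
2.9 Å catalytic-feasibility annotation.

**Trajectory analysis.** Kabsch superposition and RMSD series,
trailing-window frame extraction (last 4 ns at 10 ps ⇒ exactly 400
frames), C-alpha covariance PCA (eigenvalues = principal amplitudes,
eigenvectors = collective modes), and porcupine-arrow export.

**Synthetic data.** Seeded generators for contact databases (truncated
normal laws), labelled pose ensembles (near-native vs decoy frames with
planted contact-distance laws), and trajectories with planted collective
modes — so every pipeline property can be exercised without external
structural databases.

## Worked example

```r
library(rmrscore)

# 1. a contact database with a favourable C-O contact law and a broad
#    C-N background, and the potential trained from it
contacts <- generate_contact_db(contact_db_spec(
  data.frame(type_a = c("C", "C"), type_b = c("O", "N"),
             mean = c(3.0, 4.5), sd = c(0.25, 1.2), count = c(2000, 2000)),
  seed = 42))
potential <- build_potential(contacts, distance_binning(0, 6, 0.2))
potential
#> <rmr_potential> 2 type pairs, 30 bins of 0.2 A over [0, 6), alpha = 1, 3787 contacts used

# 2. a 400-frame pose ensemble: 10% of frames are near-native (contacts
#    drawn from the favourable law), the rest decoys
sim <- generate_pose_ensemble(pose_ensemble_spec(
  n_frames = 400, near_native_fraction = 0.1, n_contacts = 8, seed = 42))
pocket <- select_pocket(sim$ensemble$frames[[1]], cutoff = 8)
reports <- score_ensemble(sim$ensemble, potential, pocket, sim$reactive_pair)

# 3. the representative (lowest-total) frame
best <- select_representative(reports)
reports[[best + 1]]
#> <rmr_score_report> frame 258 (t = 2590 ps): total -4.7038 over 90 pairs, 9 residues
#>   reactive pair 19-17: 3.085 A, score -0.5244
sim$labels$label[sim$labels$frame_index == best]
#> [1] "near_native"

# 4. reactive-pair feasibility (2.9 A minimum allowed distance)
r <- reactive_distance(sim$ensemble$frames[[best + 1]],
                       sim$reactive_pair[[1]], sim$reactive_pair[[2]])
sprintf("reactive distance %.2f A, feasible: %s", r$distance, r$feasible)
#> [1] "reactive distance 3.09 A, feasible: TRUE"

# 5. essential dynamics of a trajectory with three planted modes
traj <- generate_modal_trajectory(modal_trajectory_spec(
  n_atoms = 30, n_frames = 400, amplitudes = c(1.0, 0.5, 0.25),
  noise_sd = 0.025, rigid_motion = TRUE, seed = 42))
compute_pca(traj)
#> <rmr_modes> 90 modes over 30 atoms; top eigenvalues: 1.132 (74.6%), 0.2719 (17.9%), 0.06404 (4.2%)
```

Reading the output: the selected frame's total of −4.70 over 90 scored
atom pairs is strongly favourable relative to the pooled reference, the
scoring function picked a genuinely near-native frame (it never sees the
labels), and the reactive pair sits at 3.09 Å — above the 2.9 Å
catalytic floor. The PCA recovers the planted amplitude hierarchy
(variance fractions ≈ 75/18/4%) despite per-frame rigid-body motion,
which the superposition stage removes.

## Command line

A thin CLI wraps the same functions (`inst/cli/rmr` after install):

```sh
rmr build-potential --contacts contacts.tsv --out potential.json
rmr score --ensemble ens.pdb --potential potential.json \
    --config config.json --out scores.tsv --summary summary.json --name WT
rmr rmsd --ensemble ens.pdb --out rmsd.tsv
rmr pca --ensemble ens.pdb --modes-out modes.json --arrows-out arrows.csv
rmr compare --summaries wt.json,mut.json --out comparison.tsv
rmr simulate --spec sim.json --out-prefix fixtures/run1
```

`config.json` names the ligand/cofactor residues, reactive serials,
cutoffs and binning; see `inst/extdata/config_example.json`.

## Documentation

The methods vignette (`vignettes/rmrscore-methods.Rmd`) documents the
scoring model and its assumptions, the parameter defaults, what the
synthetic generators do and do not emulate, and the package's numerical
choices.
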