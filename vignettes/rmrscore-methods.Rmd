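---
title: "Methods: knowledge-based ensemble scoring and essential dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-based ensemble scoring and essential dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Molecular-dynamics simulation of a ligand-bound enzyme — the motivating
system is a cytochrome P450 bound to its substrate, with an oxyferryl heme
cofactor — produces an ensemble of hundreds of snapshots. Not all of them
are equally representative of the native-like bound complex: the binding
pocket breathes, the ligand drifts, and the catalytically decisive contact
(here, the ferryl oxygen against the substrate's hydroxylation carbon) is
made and broken. `rmrscore` implements the analysis chain that turns such
an ensemble into a defensible "representative complex": a knowledge-based
pair potential scores every frame, the lowest-total frame is selected, the
score is decomposed per residue and classified by substrate recognition
site (SRS), the reactive-pair distance is annotated against a catalytic
feasibility threshold, and the ensemble's collective motions are
characterised by C-alpha covariance PCA.

# The scoring model

## Form

The potential is a distance-binned log-ratio score with a **mean reference
state**. Training data are intermolecular contact observations
$(a, b, d)$: an unordered atom-type pair and a distance. Distances are
histogrammed on half-open bins $[d_\min + kw,\ d_\min + (k+1)w)$, by
default $[0, 6)$ Å with $w = 0.2$ Å. With per-pair bin counts $c_k$ and a
pseudocount $\alpha > 0$,

$$P_{ab}(k) = \frac{c_k + \alpha}{\sum_j (c_j + \alpha)},$$

and the reference table $P_\mathrm{ref}$ applies the identical rule to all
contacts pooled over type pairs — the "mean" of the type-specific
distributions in the sense of a type-averaged expectation. A single atom
pair at distance $d$ in bin $k$ scores

$$s = -\ln \frac{P_{ab}(k)}{P_\mathrm{ref}(k)},$$

negative when that pair sits at a distance more enriched for its type pair
than for the average pair (favourable), positive when depleted. Any
distance outside $[d_\min, d_\max)$ scores **exactly zero** — "no
interaction" — and an unseen type pair falls back to the reference table,
also scoring zero. A complex is scored by summing over all (ligand atom ×
pocket/cofactor atom) pairs; additivity is what makes the per-residue
decomposition well defined, and the frame with the lowest total is the
most native-like representative.

## Why this form

The original function this emulates is cited, not printed, in its source
literature; two readings of "log of the sum of a distribution function"
are possible (log of a sum, or sum of logs). The sum-of-logs (additive)
reading is forced by two facts the application depends on: per-residue
score bars must sum to a meaningful total, and cumulative scores over
residue subsets are reported as plain sums. The mean-reference-state name
fixes the denominator. This is a documented interpretation, not a numeric
reimplementation of the original tables — those derive from a licensed
structural database and are out of scope.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `d_min`, `d_max` | 0, 6 | Å | 6 Å keeps a ~10 Å separated pair at score 0, the documented no-interaction contract |
| `width` | 0.2 | Å | resolves the first-shell contact peak (~0.3–0.5 Å wide) without starving bins |
| `pseudocount` | 1 | counts | Laplace smoothing; guarantees finite logs for every bin |
| pocket `cutoff` | 5.0 | Å | common heavy-atom contact cutoff for pocket membership |
| `min_allowed` | 2.9 | Å | proposed minimum distance between a hydroxylation site and the heme center; used as an annotation, never a filter |
| H-bond `max_da` | 3.5 | Å | standard heavy-atom donor–acceptor cutoff |
| H-bond `min_angle` | unset | degrees | applied only when hydrogens exist (MD frames have them; crystal-derived fixtures may not) |

Atom typing is a configuration knob (`element` or `element_context`); the
granularity used with the original database-trained function is unknown,
so both are provided and both feed identical scoring machinery. The
context scheme uses covalent-distance heuristics only (neighbour within
1.8 Å); it distinguishes carbonyl O/C, amide N, and a three-neighbour
"aromatic-like" carbon, and makes no claim of full bond-order perception.

## A caveat on the enrichment property

"More evidence in a bin lowers the score in that bin" holds only when the
enriched type pair is a minor contributor to the pooled reference bin.
Because the reference is rebuilt from the same pool, a pair that *is* the
pool in some bin dilutes itself: adding $k$ counts raises its own
normaliser proportionally faster than the pool's. In a realistic
many-type-pair database the property holds; the test suite pins down
exactly that regime rather than asserting the false general claim.

# Trajectory analyses

**Superposition.** Kabsch's closed-form least-squares rigid alignment
(SVD of the 3×3 cross-covariance, reflection excluded by a determinant
correction). Degenerate (collinear) selections are refused. The RMSD
series selection `mainchain_CON` is literally atoms named C, O, N —
C-alpha *excluded* — because the source analysis states exactly that;
the conventional `calpha` and custom selections are offered alongside,
and the oddity is deliberate, not an oversight.

**Window extraction** uses the half-open convention $(T_\mathrm{end} -
W,\ T_\mathrm{end}]$ anchored at the final frame, so a 25 000 ps
trajectory sampled at 10 ps yields exactly 400 frames for a 4 ns window —
no boundary double-counting.

**PCA.** Every frame is fitted to the reference over C-alpha atoms (the
fit reference is an explicit argument, defaulting to the first frame,
since no crystal structure ships with the package); the $F \times 3N$
coordinate matrix is column-centred and the covariance
$\frac{1}{F-1}X^\top X$ diagonalised via SVD of the centred matrix.
Eigenvector signs are fixed (largest-magnitude component positive) so
reports are reproducible; the $F-1$ denominator is the conventional
unbiased choice. Porcupine arrows add a single arbitrary scale factor
times each atom's eigenvector components to the reference coordinates, so
relative arrow lengths are scale-invariant.

# What the synthetic generators emulate — and what they do not

The generators replace three inputs the original analysis obtained
elsewhere: a licensed contact database, MD trajectories, and a crystal
reference.

- **Contact databases** draw per-type-pair distances from truncated
  normals on $(0, d_\mathrm{max,gen}]$ — simple, seeded, and analytically
  checkable (the bin probabilities of the law are available in closed
  form). Real contact distributions are multimodal with excluded-volume
  structure; nothing here depends on that.
- **Pose ensembles** realise a stated world geometrically: each ligand
  contact atom sits directly above its own pocket residue, residues are
  spaced 25 Å apart, and the cofactor/reactive site is placed on its own
  distant site. Consequently the *realised* ligand–pocket distances are
  exactly the drawn law (favourable for a known near-native subset,
  decoy for the rest), and every unplanned cross pair falls beyond the
  scoring range. Contact laws are floored at 0.8 Å — a physical contact
  floor below which no heavy-atom pair is generated. Frame labels live in
  a sidecar table, never in the PDB, so the scoring pipeline cannot see
  them. This tests discrimination of the *statistical* signal; it does
  not emulate ligand chemistry, pocket shape, or correlated contacts.
- **Modal trajectories** superpose up to three orthonormal collective
  modes (orthogonalised against the rigid-body subspace of an idealised
  helical C-alpha trace) with strictly ordered amplitudes, isotropic
  Gaussian noise, and optionally a random rigid motion per frame that the
  superposition stage must remove.

A green discrimination or recovery test therefore establishes that the
implementation extracts a signal it is mathematically entitled to
extract — not that the method would rank real MD snapshots of a real
enzyme correctly; that depends on training data and force fields outside
this package.

One global seed expands into independent per-stream seeds via a
documented label-keyed splitting rule (`split_seed`), so adding a
generator never perturbs existing streams.

# Numerical and design choices

- Bin lookup is `floor((d - d_min)/width)` with the right edge excluded;
  a one-ULP float guard clamps to the last bin, and exact boundary values
  behave per the half-open contract.
- Scores of out-of-range or unseen pairs are returned as literal 0, not
  as a computed `-ln(1)`, so the zero contract is exact.
- Potential serialization stores bin *counts* (integers, exactly
  representable in JSON) and recomputes probabilities on load with the
  same arithmetic as construction, making round trips bitwise lossless
  regardless of JSON float formatting.
- Representative selection breaks ties by earliest frame. Variant ranking
  is by reactive-pair score ascending with ties broken by reactive
  distance ascending, then input order: both reactive pairs can sit in
  pseudocount-floored bins and tie exactly, and the ranking must still be
  total and deterministic.
- The 2.9 Å feasibility threshold annotates frames; it never drops them.
- The pocket is defined once on a reference frame (default: first) and
  held fixed across the ensemble, so per-residue trajectories are
  comparable frame to frame; per-frame pocket redefinition would change
  the residue key set silently.
- Per-residue reports always include every pocket residue (zero-score
  rows included) so the key set is constant across frames; the cofactor
  is reported on its own row, keeping protein and heme contributions
  separable.
- All writers format numbers deterministically and embed no timestamps;
  identical inputs give byte-identical artifacts.

# Known limitations

- No mmCIF or binary trajectory formats; multi-model PDB is the
  interchange format (with `REMARK 250 TIME_PS` records carrying frame
  times through round trips).
- The context typing scheme is a distance heuristic; aromatic detection
  in particular is a neighbour-count proxy.
- The shipped SRS map is an explicitly labelled example configuration,
  not computed, and the exact ranges used in any given study are the
  user's responsibility.
- The potential shares one table set for ligand–protein and
  ligand–cofactor contacts; the reactive pair is additionally reported
  separately so heme-specific behaviour stays visible.
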