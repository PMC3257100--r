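---
title: "Scoring docking decoys with a weighted residue network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring docking decoys with a weighted residue network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrndock)
library(dplyr)
```

## The model

`wrndock` scores candidate protein–protein complex structures (decoys) by
the global topology of their residue contact network. Every residue is one
node, placed at the unweighted geometric centre of its side-chain heavy
atoms. Two nodes are linked when their centres lie closer than a cutoff
$r_c$; each link is weighted by the magnitude of the Miyazawa–Jernigan
(1996) contact energy $|e_{ij}|$ for the two residue types, and
peptide-bonded neighbours are always linked with a fixed weight of 2.55,
the magnitude of the average collapse energy from the same statistical
potential. All entries of that contact-energy set are negative, so their
magnitudes form a consistent positive weight scale: a stronger favourable
contact is a heavier edge.

Two global network quantities are computed per structure. The
whole-network **strength** $S$ — half the sum of all node strengths
$S_i = \sum_j a^w_{ij}$ — grows with the number and quality of contacts
and tracks how stably the complex is packed. The **weighted average
nearest-neighbours degree**
$k^w_{nn,i} = \frac{1}{S_i}\sum_j a^w_{ij}\,k_j$, averaged over all $N$
nodes to give $\langle k^w_{nn} \rangle$, measures how residues of
different connectivity are wired together; for natively packed protein
structures it sits near 6 and varies little with system size. The score is

$$ S_n \;=\; -\,S \times \langle k^w_{nn} \rangle $$

Both factors correlate negatively with ligand RMSD, so near-native decoys
get the most negative scores. The product form is deliberate: $S$ scales
with system size while $\langle k^w_{nn} \rangle$ does not, so a *linear*
combination would need a size-dependent coefficient per system; the
product needs none.

### Assumptions

* The whole complex (receptor and ligand together) forms one network;
  inter-chain contacts are ordinary weighted links, never covalent.
* A single residue-type pair table suffices — no secondary-structure or
  burial dependence, and no distinction between hydrophobicity classes.
* Coordinate quality at residue resolution: side-chain centres are robust
  to small atomic errors, which is what makes the score cheap and stable
  on docking decoys.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 6.5 | Å | contact distance between side-chain centres; strict `<`, a pair at exactly 6.5 Å is not a contact |
| `covalent_weight` | 2.55 | — | weight of every peptide bond, replacing (not adding to) the pair's contact weight when the neighbours are also within the cutoff |
| `hit_threshold` | 4.0 | Å | inclusive ligand-RMSD bound defining a near-native decoy (hit) |
| `n_permutations` | 100 | — | random rankings averaged for the baseline success-rate curve |
| `max_np` | decoy-set size | — | largest number of top predictions scanned by success-rate curves |

The contact-energy table ships as a plain-text file
(`inst/extdata/mj1996_eij.txt`, the all-negative $e_{ij}$ set of Miyazawa
& Jernigan 1996, Table 3 upper triangle) and can be replaced by any
20×20 symmetric table via `read_energy_table()` or the CLI's
`--energy-table` flag; only magnitudes are used.

## Design choices where the definitions leave room

**Side-chain centre.** The unweighted centroid of side-chain heavy atoms
(everything except N, CA, C, O and terminal OXT; hydrogens ignored
throughout, since decoys rarely carry them consistently). Glycine — and
any residue whose side-chain atoms are entirely missing from the file —
falls back to its CA coordinate. A mass-weighted centroid would differ by
fractions of an Ångström and was not adopted.

**Degree in the weighted model.** The neighbour-degree averages need a
node degree $k_j$. We count the nonzero entries of the *weighted*
adjacency, so peptide-bonded neighbours always contribute to the degree
even when their centres are farther apart than the cutoff — consistent
with the covalent links being installed into the adjacency matrix itself.
The alternative reading (degree from cutoff contacts only) is available
as `build_network(..., degree_from = "contact")`; on compact structures
the two differ only at chain termini and unusually extended backbones.

**Sequence adjacency is positional.** Covalent links connect residues
that are consecutive in parse order within a chain, not consecutive in
author numbering; insertion codes and numbering gaps therefore do not
create or destroy peptide links. Cross-chain pairs are never covalent.

**Degenerate networks.** An isolated node has $S_i = 0$ and its
$k^w_{nn,i}$ is defined as 0 (avoiding a 0/0); a single-residue structure
scores $S_n = 0$. The empty network has no defined mean and errors.

**Ranking ties.** Scores tie only in contrived inputs (e.g. two copies of
the same file); ties are broken lexicographically by decoy id so rankings
are deterministic and reruns byte-identical.

**Correlation estimator.** The score–RMSD correlation is Pearson's $r$ by
default (`cor_method = "spearman"` switches to rank-based). A decoy set
with zero variance in either variable gets `NA` with a warning rather
than a fabricated 0.

**First-rank RMSD above 10 Å.** A rank-1 decoy with L_RMSD beyond 10 Å is
effectively a wrong prediction; per-system reports flag this
(`rank1_gt10`) but keep the value, leaving any exclusion to the analyst.

## Ligand RMSD

`ligand_rmsd()` superimposes the decoy's receptor backbone (N, C, CA, O)
onto the native receptor with a least-squares rigid fit (SVD-based, with
the determinant sign corrected so reflections are never returned), applies
the fitted transform to the decoy ligand, and takes the RMSD over matched
ligand backbone atoms. Residues are matched by chain and parse-order
position; if the per-chain residue counts disagree (e.g. a truncated
decoy), matching falls back to author residue numbering. Atoms missing on
either side are skipped; fewer than three matched receptor atoms is an
error, since the superposition would be underdetermined.

## What the synthetic generator does and does not emulate

The generators exist so that every layer is testable against known ground
truth without downloading structures. `make_polypeptide()` builds chains
with realistic CA spacing (3.8 Å) in extended, helix-like or random-coil
geometry, with side-chain centres placed explicitly at ~1.5–1.7 Å from
the backbone; coordinates are rounded to PDB precision (3 decimals) so
serialisation round-trips exactly. `make_complex()` separates a receptor
and a ligand chain by a controllable gap, and `make_decoy_set()` displaces
the ligand rigidly along random directions so every decoy's true ligand
RMSD is known to machine precision (a uniform displacement of all ligand
atoms; an optional random rigid transform of the whole decoy exercises
the superposition step without changing that truth).

These fixtures reproduce the *geometry and bookkeeping* of docking decoys
— chain partitions, exact RMSD ground truth, controllable hit fractions —
but not the *chemistry* of real interfaces: side-chain packing, rotamer
states, shape complementarity and realistic decoy diversity are absent.
Passing tests therefore demonstrate that the network mathematics, the
RMSD protocol and the ranking indicators are implemented correctly, not
that the score discriminates on any particular real benchmark. As a
bridge to real data, the test suite also computes
$\langle k^w_{nn} \rangle$ on crystallographic structures shipped with
bio3d (two lysozymes and the HIV-protease dimer) and checks that it sits
in the characteristic band around 6.

The end-to-end harness uses 10 systems × 100 decoys with 30 + 15 residue
chains and per-system decoy RMSD ranges drawn from 10–30 Å; these sizes
keep a full run in tens of seconds while leaving every indicator
non-trivial (hit fractions vary across systems, some systems rank hits
late). The random-ranking baseline uses the same 100 permutations as the
evaluation protocol it accompanies and is checked against its
hypergeometric closed form $1 - \binom{M-h}{n}/\binom{M}{n}$.

## Numerical notes

* Score invariance under rigid motion of the complex holds to ~1e-6
  relative tolerance (the only float sensitivity is pair distances near
  the cutoff; a contact at distance $r_c \pm \epsilon$ can flip under
  rotation, which is inherent to any hard cutoff).
* Hit calling is inclusive at the threshold, but a decoy engineered to an
  RMSD of *exactly* 4 Å measures back with ~1e-15 numerical noise after
  superposition and can land on either side; real decoys are never at the
  boundary.
* Network quantities agree with naive double-loop evaluation to ~1e-16
  relative; the uniform-weight identity $k^w_{nn,i} = k_{nn,i}$ holds to
  the last bits of floating-point rounding.

## Limitations

* The score is a *ranking* device within one system; absolute $S_n$
  values are not comparable across systems of different size (the
  strength factor scales with residue count).
* No CAPRI-style interface-quality tiers (fnat, iRMSD); hit calling is by
  ligand RMSD only.
* No decoy generation: the package scores and evaluates structures
  produced elsewhere (or by its own synthetic generators).
* Residue matching between native and decoy assumes docking-style decoys
  that preserve residue order; arbitrary sequence alignment is out of
  scope.

## A complete run

```{r pipeline}
set.seed(1)
native <- make_complex(20, 10, separation = 4, seed = 1)
ds <- make_decoy_set(native, rmsd_targets = runif(50, 0, 15), seed = 2)
per <- evaluate_decoys(native, ds$structures,
                       receptor_chains = "A", ligand_chains = "B")
evaluate_system(per, system_id = "demo")
```

```{r curve, fig.width = 5, fig.height = 3.2}
bm <- make_benchmark(n_systems = 5, n_decoys = 50,
                     n_receptor = 20, n_ligand = 10, seed = 3)
evs <- purrr::map2_dfr(bm$native, seq_len(nrow(bm)), function(nat, i) {
  evaluate_system(evaluate_decoys(nat, bm$decoys[[i]], "A", "B"),
                  system_id = bm$system_id[i])
})
plot_success_rate(success_rate_curve(evs, 50),
                  random_baseline_curve(evs, 50, seed = 4))
```
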