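---
title: "Site-moiety maps: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-moiety maps: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitemoiety)
```

## The model

A *site-moiety map* summarizes how an ensemble of docked ligands interacts
with a binding site. The premise is statistical: if thousands of diverse
compounds are docked into one pocket and a particular residue is contacted by
far more of them than chance allows, that residue marks an interaction
*hotspot* — a feature of the pocket, not of any single ligand. Spatially
clustered hotspot contacts of one interaction type, together with the
functional groups (moieties) that make them, form an **anchor**. Comparing
anchors across a panel of superimposed proteins separates **core** anchors
(present in nearly all panel members; in kinases, the ATP-site anchors) from
**specific** anchors (present in a subset; in kinases, the C-terminal-hinge
anchors that distinguish inhibitor selectivity classes). Proteins can then be
classified by which specific anchors they possess, and screening compounds
scored by how many anchors they satisfy.

The pipeline has five stages, each exposed as ordinary functions:

1. **Contact typing and scoring** (`call_interactions()`, `pose_energy()`).
   Every (ligand heavy atom, site heavy atom) pair is assigned exactly one
   class — electrostatic if the atoms carry opposite formal charges,
   hydrogen-bond if their donor/acceptor roles are complementary, steric
   otherwise — and scored with a piecewise linear potential (PLP).
2. **Interaction profiles** (`build_profiles()`). Per interaction type, a
   binary P x C matrix over P compounds and C binding-site residues: cell
   (p, c) is 1 iff compound p makes at least one called interaction of that
   type with residue c.
3. **Consensus detection** (`zscore_profile()`). For each residue, the
   observed interaction frequency f is compared with a permutation null:
   each compound's row is independently shuffled across the site's columns
   (preserving the compound's promiscuity), 1,000 times by default; with the
   null mean mu and standard deviation sigma, Z = (f - mu)/sigma, and
   residues with Z >= 1.645 (one-sided 95%) are consensus.
4. **Anchor construction** (`cluster_anchors()`, `moiety_preferences()`).
   Midpoints of all events at consensus (residue, type) pairs are
   single-linkage clustered at 3.5 A; each sufficiently supported cluster
   becomes an anchor whose center is the event centroid, and the functional
   groups of the contributing ligand atoms give its moiety preferences with
   mean pair energies.
5. **Panel alignment and screening** (`align_maps()`, `label_clusters()`,
   `classify_groups()`, `rank_library()`). Anchors from different proteins
   merge when their centers are closer than 2 A (same type); clusters present
   in more than 90% of the panel are core, smaller multi-protein clusters
   specific. Compounds are ranked by the total score below.

## The piecewise linear potential

Each pair class has four distance knots d1 < d2 < d3 < d4 (Angstrom), a well
depth (kcal/mol) and a clash penalty. The energy rises linearly from the
penalty at d = 0 to 0 at d1, falls to the well depth at d2, stays flat to d3,
returns to 0 at d4 and vanishes beyond. Defaults
(`default_plp_params()`):

| class | d1 | d2 | d3 | d4 | well | penalty |
|---|---|---|---|---|---|---|
| steric | 3.3 | 3.6 | 4.5 | 6.0 | -0.4 | +20 |
| hbond | 2.3 | 2.6 | 3.1 | 3.4 | -2.5 | +20 |
| electrostatic | 2.0 | 2.3 | 3.2 | 4.0 | -4.0 | +20 |

These are shipped defaults, editable via `read_plp_params()`: the well depths
keep the conventional ordering (electrostatic < hydrogen bond < van der
Waals per contact) and the distance bands bracket the usual heavy-atom
donor–acceptor (2.6–3.1 A) and nonbonded-contact (3.6–4.5 A) geometries.
Because poses and many crystal structures carry no hydrogens, hydrogen bonds
are called on heavy-atom donor–acceptor distance alone, with no angular term.

**Call rules.** An H or E event is called for the best (lowest-energy)
complementary pair whose energy is favorable, i.e. whose distance lies inside
the attractive band (d1, d4) — a pair *below* d1 is a clash, not a bond, so
the nominal "distance below cutoff" rule is refined at the inner edge. A van
der Waals event is called when the summed steric energy over all of a
residue's pairs is at or below `vdw_threshold` (-0.3 kcal/mol by default):
van der Waals contacts are collective, so the call thresholds the residue
sum rather than any single pair. At most one event per (residue, type) per
pose; that binarity is what makes the profiles binary.

## The permutation null

Shuffling within rows (compounds) rather than columns preserves each
compound's interaction count, so the null asks: *given how promiscuous each
compound is, how often would this residue be contacted if contacts fell
uniformly across the site?* For profiles with constant row sums k the null is
exactly Bernoulli(k/C) per cell, which gives the closed-form check used in
the tests: with P = 100 compounds each contacting 5 of 20 residues, a column
at frequency 0.60 has Z = (0.60 - 0.25)/sqrt(0.25 * 0.75/100), about 8.08.
Degenerate columns with sigma = 0 (e.g. a fully saturated profile) are
consensus only when f exceeds mu, which resolves the division by zero while
still flagging genuine saturation. The shuffle count (1,000), the confidence
level (0.95, i.e. Z >= 1.645) and the seed are recorded in every map's
provenance block.

## Anchor clustering and panel alignment

Single-linkage clustering with a 3.5 A cutoff groups event midpoints into
anchors; `min_support` (5% of profiled compounds) discards incidental
clusters and `member_fraction` (0.25) keeps a residue in an anchor only when
a quarter of its consensus events fall there. Panel alignment is greedy
nearest-pair agglomeration: the closest pair of same-type clusters from
disjoint protein sets merges while their center distance is below 2 A, with
centers recomputed after each merge and ties broken lexicographically, which
makes the result independent of input order. Only the pairwise 2 A rule is
inherent to the method; greedy agglomeration with recomputed centers is this
package's deterministic operationalization of it. A cluster is **core** when
its presence fraction strictly exceeds `core_threshold` (0.90) and
**specific** when it has at least `min_specific` (2) members; region names
such as CH or CHG are user-assigned labels (anatomical, not algorithmic), via
`label_clusters(region_names = )` or, for generated panels,
`assign_truth_regions()`.

## The total score

Screening compounds are ranked by

TS(x) = (1/K) * sum_k [ E_k(x) * (1 + sum_a AS_ka(x) / A_k) ] / sqrt(M),

where AS_ka(x) is 1 iff compound x matches anchor a of protein k, A_k is
protein k's anchor count, E_k(x) its docked energy (kcal/mol; the pose-file
value when present, otherwise the internal PLP rescoring), K the number of
panel proteins and M the compound's heavy-atom count. A compound matches an
anchor when a heavy atom sits within `match_radius` (3 A) of the anchor
center *and* an event of the anchor's type links it to an anchor residue;
strict mode additionally demands a preferred functional group. Matching every
anchor doubles the weight of the docked energy; sqrt(M) tempers the bulk
advantage of large molecules. Compounds are binned by their specific-anchor
pattern (a specific anchor counts when matched in at least half of the panel
proteins carrying it) before sorting by TS, so occupancy of the
selectivity-conferring pockets takes precedence over raw score.

## What the synthetic generator emulates — and what it does not

`make_panel()` builds pocket panels whose *statistical* structure matches
what the method assumes: single-atom pseudo-residues with assigned roles
(donor/acceptor/charged/nonpolar) on a jittered 10 A grid; planted hotspots
contacted with probability 0.8 per compound; background residues contacted
with probability 0.05; specific hotspots present only in declared panel
subsets; contact atoms placed inside the attractive PLP band of the intended
class with 0.1 A positional noise. The defaults — 200 compounds per pocket, a
10-pocket panel, the CH-like hotspot in 7 pockets and the CHG-like in 4 —
are the package's reference conditions for all end-to-end tests, and the
`group1`/`ch_only`/`core_only` presets plant 7, 6 and 5 hotspots.

Two geometric choices matter and were made on first principles:

* **10 A residue spacing.** Any contact atom (at most ~4.3 A from its target
  residue) is then automatically beyond the 6 A steric range of every other
  residue, so planted contacts contribute *zero* energy elsewhere: no
  spurious calls, and event midpoints are unbiased estimates of the hotspot
  position. With tighter spacing, the clearance resampling needed to prevent
  cross-talk biases anchor centers outward by up to ~1 A.
* **Pocket mass balance.** The permutation null spreads each compound's
  contacts uniformly over the site, so a background residue behaves as
  background only if the null column mean (total per-type contact mass / C)
  stays at or above the 0.05 background rate. The 15-residue pocket (7
  hotspot slots + 8 typed background residues) keeps that inequality true
  for every interaction type in every preset; larger pockets with single
  hotspots of a type would make background columns *enriched* relative to
  the null — i.e. the generator would be planting weak hotspots everywhere
  instead of emulating background.

The generator does **not** emulate: real chemistry (fixture "molecules" are
small branched graphs with labeled functional groups, not valid conformers);
correlated contacts (real compounds contact neighboring residues together);
pocket flexibility or induced fit; docking-pose error; water-mediated or
halogen interactions. Passing end-to-end tests therefore demonstrates that
the statistical machinery recovers planted structure under the stated noise
model — not that the pipeline's calls are accurate for any particular real
protein, which depends on docking quality and the PLP parameterization.

## Numerical choices and degenerate inputs

* Residue identity is the triple (chain, residue number, insertion code)
  everywhere; alternate locations keep the highest-occupancy conformer.
* Binding-site inclusion is a closed ball: a residue at exactly the 10 A
  radius is inside.
* Superposition uses the SVD form of the Kabsch solution with a determinant
  correction against reflections; fewer than 3 pairs, or collinear guide
  atoms (second singular value below 1e-8 of the first), raise an error
  rather than returning an arbitrary rotation.
* Ties in top-pose selection break by compound id; ties in panel alignment
  by (protein id, anchor id); ranking ties by compound id — all orderings
  are deterministic given the inputs and seed.
* An all-zero profile yields an empty consensus set with a logged note;
  an empty anchor list is a valid map; a panel needs at least two maps.
* Z-scoring requires an explicit seed, and generation restores the caller's
  RNG state, so library code never silently consumes the global stream.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated data:
200-compound ensembles per pocket, 15-residue pockets, 1,000-shuffle nulls,
10-pocket panels, and 20-seed replicates for the statistical suites. These
sizes put every null distribution in its asymptotic regime (binomial standard
errors of ~0.015 on frequencies) while a full panel analysis completes in
about half a minute.

## Known limitations

* The PLP parameters are a documented default, not a fitted force field;
  absolute energies (e.g. moiety energies or wild-type/mutant deltas) are
  comparable within a parameterization only.
* Hydrogen-bond calls have no angular term and protein side-chain roles come
  from fixed per-residue templates (no pKa or tautomer modeling).
* The moiety classifier is a connectivity rule table covering ~20
  checkmol-style groups; exotic functional groups fall into "other", and
  aromaticity detection expects either aromatic bond orders or kekulized
  6-rings.
* Structure superposition requires a user-supplied residue correspondence;
  the package deliberately does not guess alignments, since hinge-region
  comparisons are sensitive to misalignment around conserved motifs.
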