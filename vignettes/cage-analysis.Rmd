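---
title: "Pore subtypes and symmetry of two-component ferritin nanocages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pore subtypes and symmetry of two-component ferritin nanocages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfrcage)
```

## The model

Ferritin-family nanocages assemble 24 subunits into a hollow, roughly
spherical shell whose proper symmetry group is the chiral octahedral group
432 (order 24). The shell is organised as 12 antiparallel homodimers, one
per edge-type two-fold axis, and is pierced by 38 channels: six pores on the
four-fold axes, eight on the three-fold axes, and 24 "B-pores" at the
asymmetric junction where one whole dimer abuts a single subunit of a
neighbouring dimer. In a heteromeric bacterioferritin the cage contains six
dimers of a heme-free subunit type (here called A) and six of a heme-binding
type (B, distinguished by the heme-ligand methionine at position 52). Because
every pore draws its wall from 3 or 4 subunits of possibly different types,
the pores of one geometric kind split into *subtypes* by subunit-type
composition, and the cage as a whole retains only the subgroup of rotations
that preserve the type assignment.

`bfrcage` models this at two levels that check each other:

* **Combinatorial** (`build_cage_graph`, `enumerate_labelings`,
  `composition_spectrum`, `labeling_automorphisms`, `find_arrangements`):
  an exact incidence structure with 12 dimer slots, 24 subunit slots and 38
  pore nodes, acted on by the 24 rotations. A cage variant is a *labeling*
  of the 12 dimer slots by {A, B}; its *spectrum* counts pores per
  (kind, composition) class.
* **Geometric** (`read_assembly`, `assign_subunit_types`, `detect_dimers`,
  `fit_octahedral_frame`, `map_assembly_to_graph`, `detect_pores`,
  `classify_subtypes`): the same quantities recovered from atomic
  coordinates, for deposited structures or for synthetic cages.

The central correctness property is *oracle equivalence*: for every strict
labeling (6 A + 6 B; there are choose(12,6) = 924), building an idealised
cage from the labeling and pushing it through the full geometric pipeline
must reproduce exactly the combinatorial spectrum. The test-suite verifies
this for all 924 labelings at zero noise.

## The incidence structure and one deliberate construction choice

The dimer, four-fold and three-fold incidences are forced by symmetry: the
cage is combinatorially a rhombic dodecahedron whose 12 faces are dimers,
whose 6 four-coordinate vertices are four-fold pores and whose 8
three-coordinate vertices are three-fold pores. Each subunit slot is one
face half, associated with exactly one four-fold and one three-fold vertex.

The B-pore incidence — *which* dimer donates its whole dimer to which pore —
is not forced by the axes alone. We construct it once from the geometric
realisation: the single donor of the reference dimer's pore is the
neighbouring-face subunit closest to the reference face axis, and the other
23 pores are the group orbit of that reference incidence, which
automatically satisfies the bookkeeping constraints (every dimer
whole-donates twice, every subunit single-donates once, every subunit sits
in three B-pores). For any subunit template of the assumed form the
"closest outside subunit" rule ties between exactly two candidates that are
mirror images of each other; we break the tie lexicographically. The two
choices give reflection-isomorphic graphs, so every count and every subtype
table reported by the package is independent of the choice; only the
handedness of pore identifiers changes.

## Conservation laws

For every strict labeling the spectrum obeys exact conservation laws, which
the suite checks over all 924 labelings:

* each subunit sits in one four-fold, one three-fold and three B-pores, so
  the type-A incidences sum to 12, 12 and 36 respectively;
* B-pores balance exactly: count(3:0) = count(0:3) and
  count(2:1) = count(1:2), because the whole-donor relation is a 2-in/2-out
  directed graph on the dimers;
* three-fold pores satisfy the sharper law
  count(1:2) − count(2:1) = 3·(count(3:0) − count(0:3)).
  The mixed compositions balance *only* when no pure three-fold pore is
  present. This is worth stating because the unconditional mixed balance is
  sometimes assumed; it fails for 368 of the 924 labelings (concentrating
  the six A-dimers around two opposite three-fold vertices gives
  3:0 ×2 + 1:2 ×6). The three-fold incidence is the cube graph, and the law
  above is the full content of the conservation argument.

## The hetero-cage arrangement

The experimentally observed arrangement is recovered by exhaustive search
(`find_arrangements`) under three constraints: four-fold compositions
exactly {4:0, 1:3, 2:2}; three-fold exactly {2:1, 1:2}; and a
label-preserving subgroup of order 2 whose generator is a 180° rotation
about a four-fold axis piercing one all-A and one 2:2 four-fold pore. The
search returns 12 labelings forming a single orbit of the rotation group
(orbit size 12 = 24 / |C2|), i.e. one arrangement up to rotation. Its
spectrum has nine classes:

```{r}
g <- build_cage_graph()
subtype_table(composition_spectrum(g, reference_arrangement(g)))
```

## The synthetic cage generator

`build_synthetic_cage` places a rigid pseudo-atom subunit template on each
of the 24 subunit slots by the slot's group rotation. The template emulates
the features the pipeline measures, not protein chemistry:

* a four-rod CA trace (44 atoms) standing in for the four-helix bundle,
  packed so that the two subunits of a dimer are antiparallel (oriented
  principal-axis cosine ≈ −0.93) and share ≈ 80 heavy-atom contacts at the
  5 Å cutoff, while non-partner chains share < 10 — the regime in which
  contact-weighted matching is unambiguous;
* a short C-terminal helix proxy running from the bundle to the subunit's
  four-fold pole, tipped by the conserved Asn/Gln pore-lining pair
  (numbered 148/151 in type A, 149/152 in type B, matching the one-residue
  register shift of the two subunit types);
* three-fold lining residues (Glu118/Glu121 vs Asn118/Glu121), an acidic
  B-pore lining cluster, a ferroxidase-centre cluster at a fixed interior
  offset (8 Å below the subunit centroid radius), and the heme-ligand
  discriminator (Lys52 in A, Met52 in B);
* type A and type B templates have *identical coordinates* and differ only
  in residue naming, so a typed cage's centroid set is exactly
  432-symmetric and frame-fit residuals reflect only added noise.

Default scale is a 50 Å subunit-centroid radius, the scale of a
bacterioferritin shell. Noise is isotropic per-atom Gaussian with explicit
seed; chain identifiers are shuffled deterministically from the same seed;
`radius_scale` and a global rotation exercise the scale- and frame-
equivariance of the pipeline. Output is byte-identical for identical
parameters.

What the generator does **not** emulate: side-chain chemistry (cage
fixtures carry CA pseudo-atoms only, so interface detectors correctly
report zero contacts on them; a separate two-chain fixture with full
charged/aromatic side-chain geometry exercises those), secondary-structure
detail, heme groups, and realistic shell thickness. Consequently, passing
tests demonstrate the correctness of the combinatorics, the symmetry
recovery and the classification logic — not the accuracy of, say, diameter
conventions on real density-derived models.

## Numerical conventions

* **Pore centres**: centroid of the designated lining-role residues' CA
  atoms of the contributing chains, gated to within 10 Å of the ideal
  graph position; if no role residue resolves, the centroid of contributing
  CA atoms near the ideal position is used and the pore is flagged
  "degraded". Printed distances from the source structure use an unstated
  centre convention, so comparisons carry a ±2 Å tolerance.
* **Pore–FC distances**: distance to the *nearest* ferroxidase centre of
  the requested type (centroid of side-chain terminal heavy atoms of the
  FC role residues); min, mean and spread over symmetric copies are
  reported because a single-copy convention is equally defensible.
* **Diameters**: 500 quasi-uniform directions, 8° half-angle cones;
  external/internal = twice the mean maximal/minimal radial heavy-atom
  distance over cones that pierce protein. Rigid-motion invariance holds to
  the grid resolution (≈ 1%).
* **Dimer detection**: 5.0 Å heavy-atom contact cutoff, minimum 50
  contacts per admissible edge, exact maximum-weight perfect matching
  (branch-and-bound; the admissible graph of a closed cage is nearly a
  perfect matching already). Antiparallelity threshold −0.8 on oriented
  principal axes.
* **Interface chemistry**: salt bridge = carboxylate O to Arg/Lys
  side-chain N within 4.0 Å, His excluded from the basic set; pi-cation =
  ring centroid to Lys NZ / Arg CZ within 6.0 Å and within 45° of the ring
  normal; residue pairs count once at their minimum distance.
* **Tolerances**: 1e-9 elementwise for rotation-matrix identities, 1e-6
  for axis identification, 15° for slot assignment, 2.0 Å centroid
  coincidence for point-group membership, 3.0 Å maximum frame residual.

## Problem sizes

The validation suite enumerates all 924 strict labelings wherever a claim
quantifies over labelings, and runs the full geometric pipeline per
labeling for the oracle-equivalence property (a 24-chain, ≈ 1400-atom cage
per labeling; the batch completes in a few minutes on one core). Geometric
unit tests use the reference arrangement, a homogeneous cage, noisy
variants at 0.5 Å (several seeds) and randomly rotated builds.

## Known limitations

* Assemblies are assumed to be single closed 24-mer cages; partial cages,
  fusion constructs and higher-order oligomers are rejected rather than
  modelled.
* Sequence-based typing assumes at most two subunit types; three-component
  cages raise an error by design.
* Formal charges are integer counts at neutral pH (His = 0); no
  electrostatics or pKa modelling stands behind the charge profiles.
* The deposited-structure checks (pore–FC distances, diameters, interface
  inventories of the real hetero-cage and its comparators) require the
  multi-megabyte coordinate files, which are not shipped; place them under
  `tests/testthat/structures/` to activate those tests.
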