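---
title: "chemspace3d: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemspace3d: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemspace3d)
```

This vignette is the package's own account of the science it implements:
the standardization model, the five fingerprints, the PCA projection and its
diagnostics, the 3D grid and its color coding, and the places where the
design was genuinely open and a choice had to be made.

## 1. The molecular model

`chemspace3d` carries its own molecular-graph layer (SMILES parser, V2000
SDF reader, valence model, kekulization, aromaticity perception, canonical
SMILES writer) because no chemistry toolkit is assumed at run time. The
model is deliberately conservative:

* **Valences.** Each element has a list of allowed total valences
  (bond-order sum plus attached hydrogens), shifted by formal charge for
  the common ions (N⁺ 4, O⁻ 1, and so on). Any atom outside its list is a
  `valence_error`; this is the "valency check" of the standardization
  stage. Elements without an entry (metals, counterion atoms) are not
  checked.
* **Aromaticity** is perceived with a simplified Hückel rule over SSSR
  rings of size 5–7: each ring atom contributes 1 π electron from an
  in-ring (or carbon–carbon fusion) double bond, 2 from a lone pair
  (pyrrole-type N/O/S, carbanion), 0 from a carbonyl-type exocyclic double
  bond or a carbocation; a ring with 4n+2 electrons is aromatic.
  Perimeter-aromatic systems whose individual SSSR rings fail the count
  (azulene-type) are kept as their Kekulé forms. This is a known,
  documented simplification.
* **Kekulization.** Aromatic input is converted to alternating single and
  double bonds by a backtracking perfect matching over the atoms that need
  one double bond. After canonical atom ranks are available, the aromatic
  system is *re*-kekulized with rank-ordered tie-breaking, so every
  equivalent input form yields the same Kekulé structure — this matters
  because the MQN bond-type counts are defined on the Kekulé structure.
* **Canonical SMILES** uses iterative neighborhood refinement
  (Weisfeiler–Lehman style) for atom ranks, resolves residual neighbor-order
  ties with order-independent subtree signatures, and takes the smallest
  output string over an invariant start-atom set (fewest branch
  parentheses, then lexicographic). Property tests assert invariance under
  random atom permutations.
* **Stereochemistry is parsed and discarded.** Canonical stereo perception
  was judged out of proportion for this package; as a consequence the
  deduplication key is constitution-level, so enantiomers and E/Z isomers
  collapse to one representative. This is the main known limitation of the
  standardization stage.
* **Rings** are an SSSR basis: the shortest cycle through every non-bridge
  edge, filtered to circuit rank by GF(2) independence, smallest first.
  SSSR is ambiguous for some fused systems; the deterministic, rank-ordered
  search pins one basis so counts are reproducible.

## 2. Standardization at pH 7.4

The published procedure ("adjusting the ionization state to pH 7.4") used a
proprietary pKa engine. This package replaces it with a deterministic rule
table, chosen so that the overwhelmingly dominant ionizable groups in
drug-like molecules are handled and every decision is testable:

* deprotonated: carboxylic acids, sulfonic/sulfinic acids,
  phosphates/phosphonates (one proton per phosphorus group), tetrazoles;
* protonated: aliphatic primary/secondary/tertiary amines (not amides, not
  anilines, not aromatic N), amidines and guanidines (at the imine
  nitrogen).

Where several equivalent protons exist (for example two phosphate OH
groups), the canonical atom rank picks one, keeping the result independent
of input atom order. Salt stripping keeps the fragment with the most heavy
atoms, breaking ties by molecular mass and then by lexicographically
smallest canonical SMILES. The heavy-atom cap defaults to 50, the value the
published procedure applied to DrugBank.

## 3. The five fingerprints

* **MQN (42 components).** Integer counts in a fixed order: 12 atom counts,
  7 bond counts (on the canonical Kekulé structure; rotatable bond = acyclic
  single bond between two non-terminal heavy atoms, excluding amide C–N),
  6 polarity counts and 17 topology counts (SSSR ring sizes 3–9 and ≥10,
  fusion atoms/bonds). H-bond donors are N/O bearing hydrogen; acceptors
  are N/O excluding pyrrole-type aromatic N, amide N and positive charge;
  acceptor *sites* count available lone pairs (O 2, O⁻ 3, N 1, N⁻ 2). The
  site multiplicities are this package's pinned convention — the original
  MQN definition is in the cited literature of the field, not restated in
  the source we implement from.
* **SMIfp (34 components).** Character counts over the *recomputed*
  canonical SMILES (never user input, so equivalent inputs agree). The
  pinned alphabet is 14 atom symbols (C, c, N, n, O, o, S, s, P, F, Cl, Br,
  I, B), 11 structural symbols (`= # ( [ + - . @ / \ %`) and ring digits
  1–9; `)` and `]` are redundant with their partners and not counted. The
  exact 34-symbol set of the original publication is not restated in our
  source; the alphabet is a package constant so any deviation is visible
  and stable.
* **APfp (20 components).** Component *d* is the number of unordered
  heavy-atom pairs at shortest-path distance exactly *d* bonds, divided by
  the heavy atom count. Pairs beyond 20 bonds are dropped, not accumulated
  into the last bin (the definition says "between 1 and 20 bonds").
* **Xfp (55 components).** Five 11-component blocks over distances 0–10 for
  the categories hydrophobic (C/halogen with no N/O neighbor), H-bond
  donor, H-bond acceptor, sp2 (aromatic or exactly one double bond), plus
  acceptor/donor cross-pairs. Same-category blocks count each category atom
  once as a self-pair at d = 0 (so a non-empty block starts at 1) and are
  normalized by the category size; the cross block counts atoms that are
  both acceptor and donor at d = 0 and is normalized by the size of the
  acceptor–donor union, the natural reading of "number of category atoms"
  for a two-category block.
* **Sfp (1024 bits).** All linear paths of 0–7 bonds over
  element/charge/aromaticity atom labels and bond-order labels, each path
  string canonicalized by direction, hashed twice (two polynomial string
  hashes) into a 1024-bit vector. Paths of zero bonds (single atoms) are
  included so that even methane sets bits. The reference substructure
  fingerprint is proprietary; no bit compatibility is claimed, and the
  parameters (7 bonds, 1024 bits, 2 bits per path) are package constants.

Scalar fingerprints are compared by city-block distance, Sfp by Tanimoto
(defined as 1 for two empty bit sets).

## 4. PCA and diagnostics

`fit_pca()` mean-centers (no unit-variance scaling by default — the
fingerprints are counts on comparable scales, and this matches the
established practice for MQN-type PCA maps; `scale. = TRUE` is available)
and eigendecomposes the D×D covariance matrix. D is at most 1024, so the
eigendecomposition is cheaper and simpler than an SVD of the data matrix;
the model invariants (orthonormal loadings, descending eigenvalues, trace
conservation) are asserted in tests either way. Loading signs are fixed by
making each column's largest-magnitude entry positive, so results are
reproducible across platforms. The model (means, scales, loadings,
eigenvalues) serializes to JSON and is reused verbatim when projecting
external overlay molecules — external points are never refit.

`distance_correlation()` samples unordered molecule pairs uniformly without
replacement (all pairs when there are no more than `n_pairs`, default 10⁶ —
full enumeration of the tens of millions of pairs in a large library is
possible but pointless for a diagnostic) and reports the Pearson correlation
between pair distances in the k-dimensional PC subspace and in the original
fingerprint space. Euclidean distance is used on both sides: the diagnostic
compares geometries, while city-block remains the similarity-search metric;
this is a deliberate, documented split, and the sampler is seeded so the
diagnostic is reproducible. At k = D the projection is an isometry and r = 1
to numerical precision — that identity is one of the test anchors.

## 5. The 3D grid and color coding

The grid range is **global**: one PC<sub>min</sub> and one PC<sub>max</sub>
over the pooled PC-1/PC-2/PC-3 values, bin size
(PC<sub>max</sub> − PC<sub>min</sub>)/`n_bins` identical on the three axes
(most visualization tools scale per axis; the global range is what the
method we implement prescribes, and it preserves the geometry of the
cloud). Cell index = floor((v − PC<sub>min</sub>)/bin); the top edge is
closed so a molecule exactly at PC<sub>max</sub> lands in index
`n_bins − 1`. A degenerate library whose points coincide gets bin size 0
and a single cell rather than an error. The 2D pixel statistic uses the
same construction over PC-1/PC-2; because its range differs from the 3D
range, 2D pixels are not strict unions of 3D cells, and the 3D ≥ 2D
resolution ordering is asserted statistically on libraries of ≥ 500
molecules rather than proven. (The other ordering — fingerprint-bin
resolution ≥ 3D cell resolution — *is* structural: molecules with identical
fingerprints always share a cell, so a singly occupied cell implies a
unique fingerprint.)

Color coding is HSL with lightness fixed at 0.5:

* **Hue** = 240° − 300°·t, where t min-max-normalizes the cell's mean
  property **over occupied-cell means**. The minimum cell is therefore
  exactly blue (240°) and the maximum exactly magenta (−60° ≡ 300°) on any
  dataset. Normalizing over molecule-level values instead would leave the
  ramp anchors unreachable whenever the extreme molecules share cells with
  others; the cell-mean convention makes the documented anchors exact. A
  constant property maps every cell to 240° by convention.
* **Saturation** = 1 − min(1, σ_local/σ_global), where σ_local is the
  population standard deviation of the property over all molecules within
  ±`radius` (default 5) grid cells in each direction (Chebyshev
  neighborhood, truncated at the borders, own cell included) and σ_global
  is the population standard deviation over the whole library. Molecule
  level, not cell-mean level, because the definition speaks of "all
  molecules within ±5 grid points". σ_global = 0 (constant property) gives
  saturation 1 everywhere.

Display properties (`compute_properties()`): SSSR ring count, aromatic
carbon count, rotatable bond count, fraction of aromatic heavy atoms,
H-bond acceptor count, heavy atom count, and the N–C=C substructure count
(nitrogen single-bonded to a carbon double-bonded to another carbon;
aromatic bonds match either role, so anilines and aminopyridines count).
Property normalization applies no outlier clipping.

## 6. Overlay and scenes

External molecules (≤ 1000, the documented interface cap, enforced with an
error that names the limit) run through the same standardization and
fingerprinting, are projected with the stored model and binned with the
stored grid range; out-of-range coordinates clamp to the boundary cell so
every external point is visible at the edge rather than silently dropped.
Overlay points are drawn in dark violet (RGB 148, 0, 211), a package
constant. Multi-member cells display the canonical SMILES of the member
with the smallest source index as their representative — averaging chemical
structures is not a defined operation, so a deterministic representative
plus the full member list replaces the historical "average molecule"
display. Scenes serialize to JSON (lossless round trip, integer cell
indices, 3-byte colors) and to a single self-contained HTML file whose
viewer is plain canvas JavaScript with no external assets, so it opens
offline.

## 7. The synthetic library generator

`make_library()` emulates the *structure* of a drug-like screening library
at desk scale: four template families (linear/branched alkanes, carbo- and
heterocycles, aromatic cores with 0–3 polar or halogen substituents, polar
chains with the ionizable groups the pH rules target), sizes of roughly
3–20 heavy atoms, mixed 20/20/35/25 by a seeded sampler. Planted
duplicates, salt forms and oversized molecules give the standardization
tests exact ground truth; the regular pool is kept collision-free at the
canonical-SMILES level so those planted events are the *only*
deduplication events. What the generator does **not** emulate: the size
distribution (real drugs average ~25–30 heavy atoms), stereochemistry,
charge diversity beyond the pH rules, and the long tail of rare scaffolds.
A green test on fixtures therefore establishes the correctness of the
machinery (counts, invariants, orderings, determinism), not any empirical
claim about a real database — reproducing published dataset-level numbers
requires the corresponding database export as input, for which the SDF
reader and `run_pipeline()` are provided.

## 8. Numerical and degenerate-input choices

* PCA eigenvalues are clipped at 0; all-identical rows fit without error.
* Orthonormality/trace tolerances: 1e−8 / 1e−6 relative (test anchors).
* `distance_correlation()` raises an error when either distance set has
  zero variance (correlation undefined), and is exact (all pairs) below the
  sampling cap.
* Zero-range property: hue 240°, saturation 1 (see above).
* Single-molecule libraries: grids and statistics work from n = 1
  (bin size 0 handled); PCA requires n ≥ 2; distance correlation n ≥ 3.
* Tie-breaks are deterministic everywhere: canonical ranks (kekulization,
  proton choice), library order (neighbor ranking), smallest source index
  (cell representative).

## 9. Known limitations

* No stereochemistry (see §1) — duplicates are constitutional.
* Simplified aromaticity (see §1) — borderline systems fall back to Kekulé
  forms consistently rather than matching any specific toolkit.
* The SMIfp alphabet and the MQN acceptor-site multiplicities are pinned
  package conventions; cross-package numeric identity with the original
  implementations is not claimed (their exact tables are proprietary or
  unrestated), only internal consistency and the documented semantics.
* `sfp` bits are not comparable across packages.
* The pH rules are a coarse approximation: no pKa arithmetic, no
  zwitterion resolution beyond independent group rules, no tautomer
  enumeration.
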