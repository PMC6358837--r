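---
title: "Methods: curation, diversity metrics and chemical-space profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, diversity metrics and chemical-space profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

npprofiler characterizes small-molecule compound libraries — natural-product
collections in particular — the way such libraries are routinely profiled in
chemoinformatics: structure curation, a six-property physicochemical profile,
Bemis–Murcko scaffold diversity, fingerprint-based diversity, chemical-space
embeddings, and a Consensus Diversity plot that fuses the views. This
vignette is the package's account of the underlying methods, the tunable
parameters, and the design decisions taken where the methodology left room.

## Structure curation ("wash")

`curate_library()` standardizes every record before any statistic is
computed:

1. **Parsing and canonicalization.** SMILES are parsed and canonicalized by
   the OpenBabel backend (through ChemmineR/ChemmineOB). Unparseable records
   are flagged invalid, never silently dropped.
2. **Salt stripping.** Multi-fragment structures are reduced to the largest
   *organic* fragment: among fragments containing carbon, the one with the
   most heavy atoms wins; ties go to the most total atoms, then to the
   lexicographically smallest canonical SMILES. Records with no organic
   fragment (e.g. a bare inorganic salt) cannot yield a parent structure and
   are counted with the invalid records.
3. **Neutralization.** Anionic acids are protonated and protonated amines
   deprotonated wherever a neutral valid valence exists; permanent charges
   (quaternary ammonium, charge-balanced nitro) are retained. This is
   OpenBabel's `neutralize` operation, which matches that rule set; e.g.
   sodium acetate `CC(=O)[O-].[Na+]` becomes acetic acid `CC(=O)O`, while
   tetramethylammonium keeps its charge.
4. **Duplicate removal.** Exact duplicates of the canonical parent — with
   stereochemistry included, so epimers are distinct compounds — are
   removed, keeping the first occurrence. Whether published duplicate
   analyses considered stereochemistry is usually unstated; stereo-aware is
   the conservative choice and is flagged in the curation metadata.

The report always satisfies
`n_output = n_input − n_invalid − n_duplicates_removed`, and curation is
idempotent: a curated library passes through unchanged, with zero removals.
3D geometry optimization is deliberately out of scope — every downstream
statistic here is two-dimensional.

## The six properties

`compute_properties()` returns, per compound: molecular weight (MW, g/mol),
calculated octanol/water partition coefficient (SlogP), topological polar
surface area (TPSA, Å²), rotatable bonds (RB), H-bond donors (HBD) and
H-bond acceptors (HBA). Because donor/acceptor conventions differ between
descriptor engines by roughly ±1 on count descriptors, the package fixes
one definition and records it in the table's `engine` attribute:

* MW uses **average atomic masses** (benzene 78.11 g/mol);
* SlogP is the Wildman–Crippen atom-contribution estimate; TPSA is Ertl's
  topological estimate;
* HBD counts O–H and N–H donor hydrogens' heavy atoms (ethanol 1, phenol 1);
* HBA is OpenBabel's pattern-based N/O acceptor count: pyrrole-type N is
  excluded, amide N is counted (phenol 1, pyridine 1, pyrrole 0);
* RB is computed in-package on the molecular graph: single, non-ring bonds
  between two non-terminal heavy atoms, excluding amide C–N (butane 1,
  ethylbenzene 1, acetanilide 1).

`box_summary()`/`summarize_properties()` produce box-plot statistics.
Quartiles use the midpoint-interpolation rule (`quantile(type = 5)`), chosen
so that `c(1, 2, 3, 4)` yields Q1 = 1.5 and Q3 = 3.5 — the convention under
which the package's frozen examples were derived. Whiskers are Tukey fences
(Q1 − 1.5·IQR, Q3 + 1.5·IQR) clipped to the most extreme observations inside
them ("adjacent values"); points beyond are reported as outliers, and
`autoplot()` draws them as red asterisks. A single observation has sd 0 by
definition here, not NA.

## Bemis–Murcko scaffolds and the recovery curve

`murcko_scaffold()` reduces a molecule to its molecular framework: all ring
systems, the linkers connecting them, and any atom attached to that core by
a double or triple bond (so cyclohexanone keeps its carbonyl oxygen, while
acetophenone's whole acyl side chain — not part of any ring-to-ring path —
is removed). Atom types and bond orders are retained; this is the
"molecular framework", not a carbon-skeleton abstraction. The
implementation works on an igraph molecular graph: ring bonds are the
non-bridge edges; terminal non-ring atoms are pruned to a fixed point;
multiply-bonded neighbors of the surviving core are restored. Scaffold
SMILES are re-canonicalized through a coordinate-free molfile, which means
E/Z bond stereo is not carried into scaffolds (frameworks are conventionally
reported without it). Acyclic molecules have no cyclic system and map to
`NA`; they are excluded from the scaffold table but counted (`n_acyclic`).

`scaffold_profile()` ranks scaffolds by frequency, breaking ties by
lexicographic order of the canonical SMILES so rankings are deterministic.
The **cyclic-system recovery curve** plots, for the top i of n scaffolds,
the cumulative fraction of scaffold-bearing compounds recovered; (0, 0) is
prepended. Because counts are sorted decreasingly the curve is concave, and
its trapezoidal area (`recovery_auc()`) lies in [0.5, 1]: 0.5 exactly when
all scaffold counts are equal (maximal scaffold diversity), approaching 1
when a single scaffold dominates. Lower AUC = higher scaffold diversity. A
single-scaffold profile produces the degenerate two-point diagonal; its AUC
of 0.5 is reported with a warning rather than replaced by an arbitrary
value. `top_n_coverage()` divides the top-n cumulative count by **all**
compounds, acyclic included, so coverage percentages remain comparable with
published whole-database figures.

## Fingerprint diversity

`maccs_fingerprints()` computes the 166-key structural fingerprint (MACCS
dictionary as implemented by OpenBabel; the key numbering follows the
published 1..166 dictionary). Different MACCS dictionary variants can shift
pairwise-similarity medians by a few hundredths; the engine is therefore
recorded in the result. `tanimoto()` is c/(a + b − c); the all-zero pair is
defined as similarity 1 (identical emptiness) with a warning, avoiding 0/0
and matching common toolkit behavior.

`similarity_stats()` summarizes the pairwise Tanimoto distribution. All
m(m−1)/2 unordered pairs are enumerated while they number at most
`max_pairs` (default 2×10⁶ — a 2,000-compound library is still exhaustive);
beyond that a uniform seeded sample of pairs is used and flagged. The
median is the Consensus-Diversity x-axis statistic and is used directly,
unreversed: lower median similarity means larger fingerprint diversity.

## Chemical-space embeddings

`subsample_library()` draws a uniform sample without replacement,
reproducibly for a seed (R's default generator, identical across
platforms); fractional requests are floored — published subset sizes
sometimes imply other rounding conventions, so exact reproduction of such
sizes is not targeted.

`scale_properties()` min–max scales each property column to [0, 1]. For
multi-library comparisons the default scope is the **union** of all
libraries — one shared min/max per column — since all sets are plotted in
one space; per-library scope exists but makes values incomparable. A
constant column maps to 0.5. PCA (`chem_pca()`) runs on the min–max scaled
data (not z-scores), with components ordered by decreasing eigenvalue and
a fixed sign convention (each component's largest-magnitude loading is
positive). Explained-variance fractions cover all components and sum to 1;
reconstruction from all components reproduces the centered data to
numerical precision.

`chem_tsne()` embeds fingerprints with Rtsne. Two input modes are provided
because published figures rarely state the metric: `"binary"` treats the
166 bits as 0/1 Euclidean coordinates; `"tanimoto"` feeds the precomputed
1 − Tanimoto distance matrix. Defaults: perplexity 30, 1000 iterations,
seeded; the choice is recorded in the result together with the optimizer's
KL-divergence checkpoints. `neighbor_report()` finds, for query compounds,
the nearest reference-library records in the embedding and attaches their
original-space Tanimoto similarity, so that apparent neighbors can be
checked against the fingerprints themselves.

## Consensus Diversity plots

`cd_table()` assembles one point per library:

* **x** — median pairwise Tanimoto of the 166-bit keys (lower = diverse);
* **y** — scaffold recovery AUC (lower = diverse);
* **colour** — whole-property diversity: the mean (median selectable)
  pairwise Euclidean distance between the library's six scaled properties,
  scaled with union scope across all compared libraries. "Euclidean
  distance of scaled properties" admits several readings; the intra-library
  pairwise-distance statistic is the one consistent with the CD-plot
  methodology this follows, and the choice is recorded in the output;
* **size** — number of compounds, drawn area-proportional
  (`scale_size_area()`), so visual impression scales with set size rather
  than with its square.

Axis orientation is never inverted. `cd_plot_data()` adds reference lines —
the median of each axis across the compared libraries by default, fixed
values on request (the methodology draws such lines but prescribes no
values) — and classifies each library into one of four quadrants; with a
single library no threshold is derivable and the quadrant is undefined,
with a warning. The colour scale runs dark (low diversity) to light (high
diversity), bounded by the observed range.

## The synthetic-library generator

`generate_library()` exists so that every stage is testable without
downloads, against *known* ground truth. A `library_spec()` fixes scaffold
templates (validated to be pure frameworks: extracting their own scaffold
changes nothing), a designed frequency vector, a substituent vocabulary,
the number of acyclic molecules, a metadata model and a seed. Molecules are
built by attaching one sampled acyclic substituent per compound to the
template's attachment atom by a single bond; the vocabulary is validated to
be ring-free and singly attachable, which *guarantees* that the
Bemis–Murcko framework of every generated molecule is its template. The
designed counts are therefore recovered exactly by `scaffold_profile()`,
and `closed_form_auc()` — the trapezoid computed directly from the sorted
counts — is an independent oracle for the measured AUC. Collisions (two
substituents yielding the same canonical molecule) are resolved by drawing
further substituents; exhaustion raises an error naming the scaffold.

Default study conditions: metadata mimics a natural-product database record
(years 2000–2018; kingdoms Plantae/Fungi/Other at 70/25/5%, genus pools per
kingdom; occasional activity annotations), and property spread is
controlled through the polar/apolar, small/large mix of the substituent
pool rather than by rejection sampling — simpler, and sufficient to
separate libraries in property space. What the generator deliberately does
**not** emulate: real natural-product ring-system complexity, stereocenter
density, or any specific database's property distributions. Passing tests
therefore demonstrate the correctness of the statistics and their
plumbing, not chemical realism of the inputs.

## Problem sizes, determinism and numerical choices

The test-suite and acceptance-script workloads are sized for a laptop-class
single core: ~100 generated libraries of up to ~25 molecules for the AUC
oracle; 50 random specs (≤10 scaffolds) for exact count recovery; one
500-molecule library (124,750 pairs, exhaustive) against a 20,000-pair
sample for the similarity median, which lands within ±0.02 of the
exhaustive value; PCA reconstruction checked to below 1e−8. All randomness
flows through explicit seeds (`withr::with_seed`), so no function disturbs
the caller's RNG state and identical inputs give identical outputs —
bit-for-bit for the deterministic stages, seed-for-seed for the stochastic
ones.

Degenerate inputs are defined, not improvised: empty columns error rather
than return silent zeros; an all-zero fingerprint pair has similarity 1
with a warning; a constant property column scales to 0.5; a single-scaffold
recovery curve warns; fewer than two molecules is an error for any pairwise
statistic.

## Known limitations

* Descriptor and fingerprint values are engine conventions (OpenBabel);
  other engines' HBA/HBD counts can differ by ±1 and MACCS medians by a few
  hundredths. Cross-database comparisons should profile every library with
  this one package, which is also why run artifacts embed the engine
  metadata.
* Scaffold SMILES drop E/Z stereo; duplicate detection on full molecules
  retains all stereo.
* t-SNE is a visualization, not a metric embedding; neighbor reports attach
  original-space similarities precisely because embedded distances can
  mislead.
* The generator's guarantee covers scaffold counts and metadata, not
  realistic chemistry (see above).
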