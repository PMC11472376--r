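---
title: "Common-label analysis of kinase conformational changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common-label analysis of kinase conformational changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gclkit)
```

## The problem and the model

G protein-coupled receptor kinases (GRKs) phosphorylate activated GPCRs and
switch between a *closed* and an *open* conformation. The switch is anchored
by an ionic lock between the bottom loop of the regulator-of-G-protein-
signaling homology (RH) domain and the bottom helix of the kinase domain
(KD). Because the seven GRK subtypes differ in sequence and numbering,
structures of different subtypes cannot be compared residue-by-residue
without a common coordinate system. gclkit implements such a system — the
GRK Common Label (GCL), a three-part identifier
`DOMAIN.ELEMENT.INDEX` (e.g. `RH.H6.3`, the third position of helix six in
the RH domain) — and the analysis built on top of it:

1. **State classification.** For each structure chain, the minimal
   heavy-atom distance between the `RH.H4H5` loop and the `KD.HK` helix is
   computed. A distance strictly under 3.3 Å calls the structure *closed*,
   strictly over 5.0 Å calls it *open*; everything in between (including
   the boundary values, which the strict inequalities exclude) is
   *intermediate* and excluded from group statistics.
2. **Contact scoring.** A labeled residue pair is *in contact* when the
   chain-position gap exceeds 5 (long-range) and the minimal heavy-atom
   distance is at most the cutoff (4.5 Å by default). Per state group, the
   Average Contact Score (ACS) of a pair is the fraction of structures
   showing the contact; at the element (SSE) level it is the mean count of
   contacting residue pairs between two elements. The
   Conformational-Change score is `CC = ACS_closed − ACS_open`; positive CC
   means the contact favors the closed state.
3. **Common-tendency networks.** CC tables from two subfamilies (GRK2/3
   and GRK4/5/6 in the study design) are joined; pairs whose CC scores are
   nonzero and share a sign in both subfamilies are *common tendency*
   pairs. At residue level, edges additionally require the absolute summed
   CC to exceed 1 strictly. Edge weight is the sum; node sets are edge
   endpoints only.
4. **Conservation.** Per-subtype vertebrate sequence sets are filtered to
   a common-species core (reference length ± 50, species present in every
   subtype), reduced to the reference's labeled columns, and scored on the
   0–11 physicochemical scale. The transition-residue set is compared
   against the background with a two-sided Mann–Whitney U test.
5. **Solvent accessibility.** Shrake–Rupley SASA with probe 1.4 Å,
   normalised per residue type to relative SASA, compared between the
   closed and open groups at caller-supplied positions.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `closedMax` / `openMin` | 3.3 / 5.0 | Å | the closed/open definitions of the lock distance; boundary equality is intermediate because the definitions are strict |
| `heavyAtomCutoff` | 4.5 | Å | the contact definition leaves the cutoff open; 4.5 Å is a standard heavy-atom contact threshold and the value is echoed in every output and manifest |
| `minSequenceGap` | 5 | positions | long-range rule, strict: a gap of exactly 5 never qualifies |
| `maxResolution` | 4.00 | Å | structures strictly above 4.00 Å are dropped; exactly 4.00 is kept |
| `minLabelCoverage` | 0.5 | fraction | operationalises "short fragment": chains mapping under half of the label table are dropped, since downstream scoring needs labeled positions |
| `residueThreshold` | 1.0 | CC sum | residue-level network rule, strict `|sum| > 1` |
| `probeRadius` / `spherePoints` | 1.4 Å / 960 | | Shrake–Rupley sampling; 960 points keep the isolated-sphere error well under 2% |

Sequence gaps are computed on renumbered chain positions (1-based,
sequential), not on label indices, because contacts are defined on the
chain before labels enter. Pairs involving unlabeled residues are excluded
entirely — only labeled positions are comparable across structures.
PH-domain pairs (the domain unique to GRK2/3) are kept in separate
`intra_ph` / `ph_cross` partitions and never pooled into cross-subfamily
comparisons.

## The conservation score

The 0–11 score follows the AMAS convention: 11 iff all non-gap residues in
a column are identical; otherwise the number of the ten physicochemical
property classes (hydrophobic, polar, small, proline, tiny, aliphatic,
aromatic, charged, positive, negative) on which all non-gap residues agree
— conserved presence or conserved absence both count, so residues sharing a
complete class profile score 10. We chose agreement counting over
intersection-only counting because only agreement counting can reach the
full-profile score of 10 that the scale requires; the class table ships in
code (`aaPropertyTable()`) so the choice is inspectable. Gaps are excluded
from the shared set; columns with more than 50% gaps are flagged
`low_confidence`, all-gap columns `undefined`.

The Mann–Whitney comparison uses exhaustive permutation enumeration
(tie-safe) whenever the group split is enumerable (≤ 2×10⁵ assignments),
the exact tie-free U distribution when samples are larger but untied, and
a tie-corrected normal approximation with continuity correction otherwise.
Exact-with-ties inference is only feasible by enumeration, which is why the
exact route is bounded by the number of assignments rather than by one
group's size alone.

## The synthetic generator

`generateFamily()` emulates the features of the study data that the
pipeline consumes, with defaults fixed at the study design: two subfamilies
(`GRK23`, `GRK456`) with 7+3 and 6+2 closed/open chains, lock distances
2.8 Å (closed) / 6.5 Å (open), resolution 2.5 Å, zero coordinate noise, and
three planted contact changes (one closed-only, one open-only, one
state-independent) shared by both subfamilies. Residues are rigid N/CA/C/O
(+CB) fragments on a line with 8 Å spacing, so non-planted long-range pairs
are far apart by construction; each controlled pair is relocated to an
isolated site where the two fragments face each other at an exact distance.
The lock residues carry Val (`RH.H4H5.2`) and Arg (`KD.HK.3`), the
conserved lock identities of the GRK4/5/6 subfamily.

What the generator does *not* emulate: realistic backbone geometry,
side-chain packing, crystallographic noise, partial occupancy, missing
loops, or correlated contact networks. Passing tests therefore demonstrate
algorithmic correctness of the scoring pipeline (state calls, ACS/CC
arithmetic, network rules, format round-trips), not robustness to the noise
structure of real crystallographic ensembles.

`generateMsa()` emulates the sequence panel: 37 species (the first being
the human reference) shared across seven subtypes, ten planted invariant
positions, and a background substitution rate of 0.3 per residue — enough
diversity that background columns score low on the 0–11 scale while
planted columns score 11, mirroring a conserved transition core against a
variable background.

## Numerical choices and degenerate inputs

* Distances are Euclidean in Å; all region/contact minima are over heavy
  atoms (hydrogens and deuteriums excluded). A CA-only mode exists for the
  lock distance but is not the default.
* Ties in the closest-pair search are broken by lexicographic label order,
  making outputs deterministic.
* The contact cutoff comparison is inclusive (`≤`), with a 1e-9 guard
  against floating-point representation of exact-boundary fixtures.
* Alternate locations collapse to the highest-occupancy conformer; ties go
  to altloc "A" (then first alphabetically).
* Polymer residues are those carrying a carbon CA atom, which keeps
  modified amino acids and drops waters, ions (including Ca²⁺, whose atom
  name is also "CA" but whose element is not carbon) and ligands.
* Empty state groups, missing regions, unknown elements, and empty species
  intersections are hard errors naming the offending item; residue-name
  mismatches between table and structure are warnings so engineered
  mutants map cleanly.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
54-residue chains (≈270 atoms), 18-structure families, 20–50-residue
random structures for the brute-force oracle comparisons, and
259-sequence alignment panels. These sizes exercise every code path while
keeping the full suite in well under a minute; the same functions run
unchanged on full-size PDB chains.

## Known limitations

* GCL tables are consumed as input (TSV), not derived: structure
  superposition and label assignment are upstream of this package.
* The element vocabulary is validated for grammar only (open set), since
  the full catalogue of element names is a moving target across GRK
  subtypes.
* The heavy-atom contact cutoff has no published anchor; conclusions that
  depend on it should be checked across 4.0–5.0 Å (the policy object makes
  this a one-line change).
* rSASA reference maxima are theoretical per-residue values; on synthetic
  fragment geometry the ratio can exceed 1 and is clamped to [0, 1.2].
* Insertion codes pass through but are not used in numbering.

## A worked run

```{r, eval = FALSE}
cfg <- runConfig(familySpec = familySpec(), msaSpec = msaSpec(), seed = 1L)
report <- runFullPipeline(cfg, "gcl-report", verbose = TRUE)
table(report$states$state)
networkEdges(report$networks$residue)
report$conservation$comparison$p.value
```

The report bundle written to `gcl-report/` contains the structure
inventory with filter reasons, the state calls (distance histogram data),
residue- and SSE-level score tables per subfamily, the common-tendency
networks (TSV and GraphML), the conservation profile, and a JSON manifest
echoing every policy value and the seed.
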