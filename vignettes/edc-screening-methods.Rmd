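---
title: "Methods: post-docking analysis of endocrine disruptors against nuclear receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-docking analysis of endocrine disruptors against nuclear receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcscreen)
```

## Scope and model

`edcscreen` implements the *analysis* half of a virtual-screening study of
persistent endocrine-disrupting chemicals (EDCs) — PFAS, plastic-associated
chemicals, phthalates, PBDEs, bisphenols and fluorinated pesticides —
docked against seven human nuclear receptors (PXR, CAR, PPAR&alpha;,
PPAR&gamma;, PPAR&delta;, AR, ROR&gamma;t). Docking itself (an AutoDock
Vina-compatible engine), conformer generation and receptor preparation are
external: the package consumes their outputs (compound × receptor score
tables in kcal/mol, PDB/PDBQT structures and poses) and produces the
derived analyses:

1. **Structural descriptors** from SMILES: molecular weight, Crippen-type
   atom-contribution logP, Ertl topological polar surface area,
   a functional-group profile over a 28-group SMARTS taxonomy, and the
   *longest fluorinated carbon chain*.
2. **Binding-strength stratification** of scores against reference-ligand
   means.
3. **Residue-contact profiling** of docked poses within a distance cutoff.
4. **Structure/affinity trends**: chain-length regression, per-group mean
   affinities, hydrophobicity of top binders.
5. **Top-binder ranking and cross-receptor prevalence.**
6. **Validation math**: symmetry-corrected pose RMSD and agreement with
   experimental potencies.

Throughout, docking scores are free-energy-like quantities where *more
negative means stronger binding*; "highest affinity" in prose always maps
to the minimum score.

## Key parameters (units, defaults, rationale)

| parameter | default | unit | role |
|---|---|---|---|
| molecular-weight window | [175, 1000], inclusive | g/mol | screening window for plastic chemicals; closed interval by design |
| contact cutoff | 5.0, inclusive | Å | residue counts as contacting when any atom is within the cutoff of any ligand atom |
| classification margin | 10% of \|m\| | — | moderate band `[m, 0.9·m]` below the reference mean `m` |
| top-N (residues, hydrophobicity) | 15 | compounds | profile depth for contact and logP summaries |
| top-N (prevalence) | 25 | compounds | per-receptor ranking depth for cross-receptor membership |
| short/long chain boundary | 6 / 7 | carbons | short = 1–6, long ≥ 7; length 0 reported separately |
| logP bioaccumulation flag | > 5 | — | conventional persistence/bioaccumulation threshold |

## Fluorinated chain length

The descriptor is the number of atoms on the longest *simple path* in the
subgraph induced by carbon atoms bearing at least one fluorine
substituent. Design choices:

* atoms, not bonds, are counted (a single CF~4~ carbon has length 1);
* a carbon qualifies regardless of other substituents, and aromatic
  carbons qualify when fluorinated;
* ring atoms may be traversed but never revisited (simple-path
  semantics — the most direct reading of "iterating through neighboring
  carbon atoms that have at least one attached fluorine", which leaves
  ring/branch handling open; we chose exact simple paths and test against
  an independent exhaustive enumeration);
* the search is an exact depth-first enumeration. It is exponential in
  the worst case but instantaneous at ligand sizes (≤ ~100 heavy atoms);
  no heuristic is used.

Consequently a perfluorooctanoic-acid-like molecule has chain length 7:
the carboxyl carbon bears no fluorine and breaks the chain.

## Functional-group taxonomy and precedence

Sources describing the screened compounds enumerate between 21 and 27
groups; the shipped taxonomy is the union (28 groups, adding `nitro` to
the tabulated 27). Patterns are SMARTS, matched by the OpenBabel backend
(`ChemmineR::smartsSearchOB`).

Precedence ("a carboxylic acid is not also an alcohol") is encoded
*context-exclusively in the patterns themselves*: the alcohol pattern
excludes hydroxyls on carbonyl carbons, the ester pattern excludes
anhydrides and carbamates, the amide pattern excludes urea and carbamate
nitrogens, the sulfone pattern requires two carbon substituents so a
sulfonic acid never reports it, and so on. This reproduces atom-level
suppression — a group occurring *elsewhere* in the molecule still
reports — without a separate match-and-subtract pass. The taxonomy CSV
(`inst/extdata/functional_group_taxonomy.csv`) carries a precedence rank
and an optional `suppresses` column so a user-edited taxonomy with
overlapping patterns can still express group-level suppression.

`halide` means any C–X bond (X ∈ F, Cl, Br, I), so essentially every
fluorinated compound reports it; that is intentional and matches how the
group is tabulated for PFAS.

## Binding-strength classification

Given the mean docking score `m < 0` of a receptor's reference ligands
(endogenous + synthetic):

* **strong**: `score < m` ("exceeding the mean" read as strictly more
  negative; equality is assigned to moderate, since "within a margin of
  10% below the average" most naturally includes the mean itself);
* **moderate**: `m ≤ score ≤ 0.9·m` (both boundaries inclusive);
* **weak**: `score > 0.9·m`.

The 10% margin is multiplicative on the (negative) mean; a
kcal/mol-offset reading would differ and is deliberately not the default,
but the margin is an argument so other conventions remain expressible.
`m ≥ 0` raises an error: the thresholds are undefined for non-binding
references. Percentages are computed over classified (non-missing) cells
by default; `denominator = "all"` divides by all compounds instead — the
distinction matters because published per-class tables mark undocked
compounds `#N/A`, and prose percentages "of the interacting ligands" use
the scored denominator.

## Contact profiling

Distances are plain Euclidean in the shared docking frame — no
superposition. Every atom present in the files counts (hydrogens
included, matching zone-selection behavior of structure viewers); a
heavy-atom-only switch exists because the original choice is not
documented. The 5.0 Å boundary is inclusive. Frequencies count each
contacted residue once per pose (a residue touching a pose with five
atoms still counts once); the alternative weighting — each residue *type*
at most once per pose — is available behind `per_pose_type` since
published frequency plots do not disambiguate the two.

## Pose RMSD

Redocking RMSD is computed in the receptor frame without superposition
(the convention under which redocking validation values are
reproducible), over heavy atoms only (docked PDBQT ligands typically
lack matching hydrogens). When the ligand bond graph is supplied, all
element-preserving graph automorphisms are enumerated by backtracking and
the minimum RMSD over mappings is reported alongside the identity-mapping
value: whether published values are symmetry-corrected is unstated, so
both are always available. Potencies are converted via
`ΔG = RT·ln(IC50/EC50)` at 298.15 K, R = 1.987×10⁻³ kcal·mol⁻¹·K⁻¹, and
both `sd(residuals)/√n` and RMSE are reported, because "standard error"
against experimental potencies is ambiguous between the two.

## Synthetic data: what it emulates, and what it does not

The generators provide every input with known ground truth:

* **SMILES**: perfluorinated linear chains (1–26 carbons) with optional
  terminal carboxylic acid / sulfonic acid / alcohol; the construction
  fixes the true chain length (an acid's carboxyl carbon is
  unfluorinated) and group set.
* **Score tables**: `score = β₀ᵣ + β₁ᵣ·L + ε`, `ε ~ N(0, σ²)`. The
  linear mean-trend mirrors the reported chain-length/affinity structure;
  Gaussian noise is the minimal assumption consistent with least-squares
  trend fitting. Default receptor slopes (see
  `default_receptor_panel()`) emulate the qualitative finding that PXR
  and the PPARs show a strong trend while AR and CAR show essentially
  none (small rigid pockets); σ defaults to 0.5 kcal/mol, a typical
  docking-score scatter. Reference means default to −8.0 kcal/mol per
  receptor, a representative nuclear-receptor reference-panel value
  (the study's own reference scores are not published in its main text).
* **Toy complexes**: a single-atom ligand with residues planted at exact
  minimum distances, so the contact set at any cutoff is known by
  construction.

Passing tests on these inputs demonstrates the *bookkeeping and
statistics* are right — boundary handling, oracle equivalence, parameter
recovery, determinism. They do not demonstrate anything about real
docking physics: synthetic scores are not Vina scores, toy complexes have
no receptor geometry, and linear SMILES do not span the polycyclic
chemistry of real top binders. Quantities that depend on the full
screening campaign (per-class strong/moderate/weak percentages, published
per-group averages, published R² values) are therefore *not* reproduced;
the pipeline's correctness on them is established by construction-based
and property-based checks at desk scale (problem sizes: 400–500 synthetic
compounds, 1000 random tables, 100–200 random graphs/complexes — sizes at
which every check completes in seconds).

## Numerical choices and degenerate inputs

* Ranking ties are broken by compound id (lexicographic), making every
  report deterministic; missing cells are excluded from ranking, never
  imputed.
* Score CSVs accept `""`, `"NA"`, `"#N/A"` as missing; writing uses
  `#N/A` and full precision by default (`digits = 1` reproduces the
  printed one-decimal dialect).
* Heat-map rendering maps the weakest score to green and the strongest
  to red; an all-equal matrix renders uniformly at the ramp midpoint.
* Fractions for a receptor with zero scored compounds are `NA`, not 0.
* All generators take an explicit integer seed, derive any sub-seeds by
  small fixed offsets, and restore the caller's RNG state on exit.
* The automorphism enumeration is capped (default 10⁴ mappings) as a
  safety valve; typical ligand graphs have far fewer.

## Known limitations

* Functional-group matching inherits OpenBabel's SMARTS semantics;
  exotic tautomers or charged species may match differently than under
  another toolkit. The parser is also lenient about some chemically
  impossible valences.
* The external docking adapter is exercised only against a stub engine
  in tests; driving a real engine requires it on `PATH`.
* `experimental_agreement` treats IC50/EC50 as a direct free-energy
  proxy; no Cheng–Prusoff correction is attempted.
* Interaction typing (hydrogen bonds, π-stacking) is out of scope — the
  contact profile is purely distance-based.
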