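# edcscreen

Post-docking analysis of persistent endocrine-disrupting chemicals (EDCs)
screened against seven human nuclear receptors (PXR, CAR, PPARα, PPARγ,
PPARδ, AR, RORγt).

Large virtual-screening campaigns dock tens of thousands of PFAS,
plastic-associated chemicals, phthalates, PBDEs, bisphenols and
fluorinated pesticides into nuclear-receptor ligand-binding domains and
then need a reproducible analysis layer on top of the raw scores. That
layer is what this package provides, for computational toxicologists and
cheminformaticians working with compound × receptor docking score tables
(kcal/mol, more negative = stronger):

- **Structural descriptors** from SMILES — molecular weight, Crippen-type
  logP, Ertl TPSA, a 28-group SMARTS functional-group taxonomy with
  precedence (a carboxylic acid is not also an alcohol), and the longest
  fluorinated carbon chain: the number of atoms on the longest simple
  path through carbons bearing ≥ 1 fluorine.
- **Binding-strength stratification** against the mean score *m* of each
  receptor's reference ligands: strong if `score < m`, moderate if
  `m ≤ score ≤ 0.9·m`, weak if `score > 0.9·m`.
- **Residue-contact profiles**: receptor residues with any atom within
  5 Å (inclusive) of a docked pose, aggregated over top-15 binders, with
  FASTA export of contacted residues.
- **Structure/affinity trends**: per-chain-length average affinity with an
  ordinary-least-squares fit and R², short (1–6) vs long (≥ 7) chain
  categories, per-functional-group mean scores, and the logP > 5
  bioaccumulation flag over top binders.
- **Prevalence**: per-receptor top-N rankings (deterministic tie-breaks),
  column extremes, cross-receptor membership counts, green→red heat
  matrices.
- **Validation math**: symmetry-corrected pose RMSD (minimum over graph
  automorphisms, no superposition) and predicted-vs-experimental
  agreement via `ΔG = RT·ln(IC50)` at 298.15 K.
- **Synthetic data generators** (seeded, bit-reproducible) for every
  input — fluorinated SMILES with known chain length/groups, score
  tables with a planted linear trend `β₀ + β₁·L + N(0, σ²)`, reference
  sets with exact means, toy complexes with planted contact distances —
  so the whole pipeline is testable without a docking campaign.

Chemistry plumbing uses ChemmineR/ChemmineOB (OpenBabel) and bio3d;
docking itself is external (an AutoDock-Vina-compatible engine can be
driven through a thin adapter, but no docking math is implemented here).

## Worked example

Rank the transcribed phthalate heat-map table, classify a synthetic
screen, and measure a redocking RMSD:

```r
library(edcscreen)

t9 <- read_score_table(system.file("extdata", "table9_phthalate_scores.csv",
                                   package = "edcscreen"), id_cols = 2)
column_extreme(t9, "CAR", "strongest")
#> $cas_id
#> [1] "84-61-7"     # dicyclohexyl phthalate
#> $score
#> [1] -9.7

pv <- cross_receptor_prevalence(read_top_binder_table(
  system.file("extdata", "table4_pfas_top25.csv", package = "edcscreen")))
pv$counts[pv$counts$cas_id == "662-28-2", ]
#>     cas_id count
#> 8 662-28-2     3   # top CAR binder, also in the PXR and AR top-25 lists

mol <- parse_smiles("OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F")
longest_fluorinated_chain(mol)   # PFOA: the carboxyl carbon breaks the chain
#> [1] 7
detect_functional_groups(mol)
#> [1] "carboxylic acid" "halide"

classify_binding(c(-9.1, -8.0, -7.5, -7.0), m = -8.0)
#> [1] strong   moderate moderate weak
#> Levels: weak < moderate < strong

p <- data.frame(element = "C", x = 0, y = 0, z = 0)
pose_rmsd(p, transform(p, x = 3, y = 4))$rmsd
#> [1] 5
```

The `analysis/` directory holds the numbered end-to-end drivers
(`01_annotate_compounds.R` … `06_validation.R`); each is a thin script
over the package functions that prints what it found and writes its
tables under `results/`.

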