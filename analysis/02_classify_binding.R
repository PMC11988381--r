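#!/usr/bin/env Rscript
# Stratify synthetic docking scores into strong/moderate/weak binders
# against reference-ligand means (strong: more negative than the mean;
# moderate: within 10% of the mean on the weak side; weak: beyond that),
# and summarize class fractions per receptor.

suppressMessages(library(edcscreen))
SEED <- 1L
out <- "results/02_classify"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- default_receptor_panel()
lib <- generate_fluorinated_smiles(400, seed = SEED)
scores <- generate_score_table(lib, receptors = panel$receptor,
                               beta0 = panel$beta0, beta1 = panel$beta1,
                               sigma = 0.5, seed = SEED + 1L)
refs <- generate_reference_sets(setNames(panel$ref_mean, panel$receptor),
                                seed = SEED + 2L)

fractions <- summarize_class_fractions(scores$table, refs)
write.csv(fractions, file.path(out, "class_fractions.csv"), row.names = FALSE)
write_score_table(scores$table, file.path(out, "scores_1dp.csv"), digits = 1)
write.csv(refs, file.path(out, "references.csv"), row.names = FALSE)

cat("per-receptor class fractions (%):\n")
print(fractions, digits = 3)
stopifnot(abs(rowSums(fractions[, c("strong_pct", "moderate_pct", "weak_pct")]) - 100) < 0.05)
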