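#!/usr/bin/env Rscript
# Structure/affinity trends: chain-length vs average-affinity curves with
# R^2 per receptor, short (1-6) vs long (>= 7) chain categories, average
# docking score per functional group, and the logP profile of top binders
# with the bioaccumulation flag (logP > 5).

suppressMessages(library(edcscreen))
SEED <- 1L
out <- "results/04_trends"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- default_receptor_panel()
lib <- generate_fluorinated_smiles(400, seed = SEED)
ann <- annotate_compounds(lib)
ann$fluorinated_chain_length <- ann$true_chain_length
scores <- generate_score_table(ann, receptors = panel$receptor,
                               beta0 = panel$beta0, beta1 = panel$beta1,
                               sigma = 0.5, seed = SEED + 1L)

trends <- lapply(panel$receptor, function(rc)
  chain_length_affinity_curve(ann, scores$table, rc))
names(trends) <- panel$receptor
fits <- data.frame(
  receptor = panel$receptor,
  slope = sapply(trends, `[[`, "slope"),
  intercept = sapply(trends, `[[`, "intercept"),
  r_squared = sapply(trends, `[[`, "r_squared"),
  true_slope = panel$beta1)
write.csv(fits, file.path(out, "trend_fits.csv"), row.names = FALSE)
pts <- do.call(rbind, lapply(trends, function(tr) cbind(receptor = tr$receptor, tr$points)))
write.csv(pts, file.path(out, "trend_points.csv"), row.names = FALSE)

cat("chain-length trend per receptor (slope kcal/mol per carbon, R^2):\n")
print(fits, digits = 3, row.names = FALSE)

cats <- table(categorize_chain_lengths(ann))
write.csv(as.data.frame(cats), file.path(out, "chain_categories.csv"),
          row.names = FALSE)
cat("\nshort (1-6) vs long (>=7) chains:\n"); print(cats)

ga <- functional_group_affinity_table(ann, scores$table)
write.csv(ga, file.path(out, "group_affinity.csv"), row.names = FALSE)

hydro <- do.call(rbind, lapply(panel$receptor, function(rc) {
  h <- hydrophobicity_summary(ann, scores$table, rc, n_top = 15)
  data.frame(receptor = rc, logp_min = h$logp_min, logp_max = h$logp_max,
             n_logp_over_5 = h$n_bioaccumulative)
}))
write.csv(hydro, file.path(out, "hydrophobicity_top15.csv"), row.names = FALSE)
cat("\nlogP range of top-15 binders per receptor:\n")
print(hydro, digits = 3, row.names = FALSE)
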