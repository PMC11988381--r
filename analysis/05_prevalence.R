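#!/usr/bin/env Rscript
# Prevalence analysis on the published per-class tables: per-receptor
# rankings and extreme binders from the pesticide/bisphenol/phthalate
# score heat maps, cross-receptor prevalence counts from the PFAS and
# PBDE top-25 lists, and heat-matrix exports with the green-to-red
# rendering convention (strongest = red).

suppressMessages(library(edcscreen))
out <- "results/05_prevalence"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
fx <- function(f) system.file("extdata", f, package = "edcscreen", mustWork = TRUE)

t7 <- read_score_table(fx("table7_pfas_pesticide_scores.csv"), id_cols = 2)
t8 <- read_score_table(fx("table8_bisphenol_scores.csv"), id_cols = 2)
t9 <- read_score_table(fx("table9_phthalate_scores.csv"), id_cols = 2)

extremes <- do.call(rbind, lapply(
  list(pesticide = t7, bisphenol = t8, phthalate = t9), function(tab) {
    do.call(rbind, lapply(colnames(tab), function(rc) {
      s <- column_extreme(tab, rc, "strongest")
      w <- column_extreme(tab, rc, "weakest")
      data.frame(receptor = rc, strongest_id = s$cas_id, strongest = s$score,
                 weakest_id = w$cas_id, weakest = w$score)
    }))
  }))
extremes <- cbind(class = sub("\\.\\d+$", "", rownames(extremes)), extremes)
write.csv(extremes, file.path(out, "column_extremes.csv"), row.names = FALSE)
cat("per-class per-receptor extreme binders:\n")
print(extremes, row.names = FALSE)

for (rc in colnames(t9)) {
  rl <- rank_binders(t9, rc, 25)
  write.csv(rl, file.path(out, sprintf("phthalate_rank_%s.csv", rc)),
            row.names = FALSE)
}
cat(sprintf("\ntop phthalate for every receptor: %s\n",
            paste(unique(sapply(colnames(t9), function(rc)
              rank_binders(t9, rc, 1)$cas_id)), collapse = ", ")))

pv4 <- cross_receptor_prevalence(read_top_binder_table(fx("table4_pfas_top25.csv")))
pv5 <- cross_receptor_prevalence(read_top_binder_table(fx("table5_pbde_top25.csv")))
write.csv(pv4$counts, file.path(out, "pfas_prevalence.csv"), row.names = FALSE)
write.csv(pv5$counts, file.path(out, "pbde_prevalence.csv"), row.names = FALSE)
cat(sprintf("\nPFAS 662-28-2 appears in %d top-25 lists; PBDE 366791-32-4 in %d\n",
            pv4$counts$count[pv4$counts$cas_id == "662-28-2"],
            pv5$counts$count[pv5$counts$cas_id == "366791-32-4"]))

hm <- heatmap_matrix(t7, csv = file.path(out, "pesticide_heatmap.csv"),
                     png = file.path(out, "pesticide_heatmap.png"))
cat(sprintf("heat matrix written: %d x %d cells\n", nrow(hm$matrix), ncol(hm$matrix)))
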