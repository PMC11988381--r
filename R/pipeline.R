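#' Receptor panel and study-condition defaults
#'
#' The seven-receptor panel screened in the study design this pipeline
#' implements, with the synthetic generator's default trend coefficients.
#' Slopes are chosen to emulate the reported structure: a clear linear
#' chain-length/affinity trend for PXR and the PPAR isoforms, essentially
#' no trend for AR and CAR (small rigid binding pockets), and an
#' intermediate trend for RORgt. Intercepts sit near the weakest observed
#' per-length averages (about -6.2 kcal/mol at one carbon).
#'
#' @return Data.frame with `receptor`, `beta0` (kcal/mol), `beta1`
#'   (kcal/mol per chain carbon), `ref_mean` (reference-ligand mean,
#'   kcal/mol).
#' @export
default_receptor_panel <- function() {
  data.frame(
    receptor = c("PXR", "CAR", "PPARa", "PPARg", "PPARd", "AR", "RORgt"),
    beta0 = c(-6.0, -6.4, -6.0, -6.2, -6.1, -6.1, -6.2),
    beta1 = c(-0.21, -0.01, -0.20, -0.22, -0.26, -0.005, -0.15),
    ref_mean = c(-8.0, -8.0, -8.0, -8.0, -8.0, -8.0, -8.0),
    stringsAsFactors = FALSE
  )
}

#' Run the full synthetic post-docking pipeline
#'
#' End-to-end driver over the synthetic-data generators: builds a
#' fluorinated compound library, annotates descriptors, plants a
#' chain-length/affinity trend with Gaussian noise, classifies binding
#' strength against synthetic reference sets, fits trend curves, compiles
#' group-affinity and hydrophobicity summaries, ranks top binders with
#' cross-receptor prevalence, and profiles residue contacts on toy
#' complexes. Every output is written as CSV/FASTA/JSON under `out_dir`;
#' identical `seed` and parameters give byte-identical numeric outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; sub-stages use fixed small offsets.
#' @param n_compounds Size of the synthetic library (default 400, a
#'   desk-scale stand-in for a full screening campaign).
#' @param panel Receptor panel with trend truth and reference means (see
#'   [default_receptor_panel()]).
#' @param sigma Docking-score noise sd in kcal/mol (default 0.5).
#' @param n_top Top-binder count for hydrophobicity and contact profiles
#'   (default 15).
#' @param n_rank Top-binder count for prevalence lists (default 25).
#' @return Invisibly, a list with the main in-memory results
#'   (`records`, `table`, `refs`, `fractions`, `trends`, `prevalence`).
#' @export
run_synthetic_pipeline <- function(out_dir, seed, n_compounds = 400L,
                                   panel = default_receptor_panel(),
                                   sigma = 0.5, n_top = 15L, n_rank = 25L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  records <- generate_fluorinated_smiles(n_compounds, seed = seed)
  ann <- suppressMessages(annotate_compounds(records))
  utils::write.csv(ann, p("compounds_annotated.csv"), row.names = FALSE)

  ann$fluorinated_chain_length <- ann$true_chain_length
  st <- generate_score_table(ann, receptors = panel$receptor,
                             beta0 = panel$beta0, beta1 = panel$beta1,
                             sigma = sigma, seed = seed + 1L)
  write_score_table(st$table, p("scores.csv"))

  refs <- generate_reference_sets(stats::setNames(panel$ref_mean, panel$receptor),
                                  seed = seed + 2L)
  utils::write.csv(refs, p("references.csv"), row.names = FALSE)

  fractions <- summarize_class_fractions(st$table, refs)
  utils::write.csv(fractions, p("class_fractions.csv"), row.names = FALSE)

  trends <- lapply(panel$receptor, function(rc) {
    chain_length_affinity_curve(ann, st$table, rc)
  })
  names(trends) <- panel$receptor
  trend_pts <- do.call(rbind, lapply(trends, function(tr) {
    cbind(receptor = tr$receptor, tr$points)
  }))
  utils::write.csv(trend_pts, p("trend_points.csv"), row.names = FALSE)
  fit_json <- lapply(trends, function(tr) {
    list(slope = tr$slope, intercept = tr$intercept, r_squared = tr$r_squared)
  })
  jsonlite::write_json(fit_json, p("trend_fits.json"), auto_unbox = TRUE,
                       digits = NA)

  ga <- functional_group_affinity_table(ann, st$table)
  utils::write.csv(ga, p("group_affinity.csv"), row.names = FALSE)

  hydro <- do.call(rbind, lapply(panel$receptor, function(rc) {
    hs <- hydrophobicity_summary(ann, st$table, rc, n_top = n_top)
    data.frame(receptor = rc, logp_min = hs$logp_min, logp_max = hs$logp_max,
               n_bioaccumulative = hs$n_bioaccumulative,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(hydro, p("hydrophobicity.csv"), row.names = FALSE)

  ranked <- lapply(panel$receptor, function(rc) rank_binders(st$table, rc, n_rank))
  names(ranked) <- panel$receptor
  pv <- cross_receptor_prevalence(ranked)
  utils::write.csv(pv$counts, p("prevalence_counts.csv"), row.names = FALSE)
  utils::write.csv(pv$membership, p("prevalence_membership.csv"), row.names = FALSE)

  # residue-contact profiling over toy complexes standing in for the
  # top-binder poses of one receptor
  contact_lists <- lapply(seq_len(n_top), function(i) {
    withr::local_preserve_seed()
    set.seed(seed + 100L + i)
    d <- stats::runif(12, 2.5, 7.5)
    tc <- generate_toy_complex(d, seed = seed + 200L + i)
    contacts_within_cutoff(tc$receptor, tc$pose, 5.0)
  })
  names(contact_lists) <- sprintf("top%02d", seq_len(n_top))
  prof <- aggregate_residue_frequencies(contact_lists, receptor = panel$receptor[1])
  utils::write.csv(as.data.frame(prof), p("residue_frequencies.csv"),
                   row.names = FALSE)
  export_contacts_fasta(contact_lists, panel$receptor[1], p("contacts.fasta"))

  invisible(list(records = ann, table = st$table, truth = st$truth,
                 refs = refs, fractions = fractions, trends = trends,
                 prevalence = pv))
}
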