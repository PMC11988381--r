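#' Pose RMSD with symmetry correction
#'
#' Root-mean-square deviation between a reference ligand pose (e.g. the
#' co-crystal ligand) and a candidate pose (e.g. the redocked ligand) in
#' their shared receptor frame — no superposition is performed, the
#' convention under which redocking RMSDs are reported. Heavy atoms only
#' by default (docked PDBQT ligands typically lack matching hydrogens).
#'
#' When the ligand's bond graph is supplied, all element-preserving graph
#' automorphisms are enumerated by backtracking and the minimum RMSD over
#' those atom mappings is returned alongside the identity-mapping value
#' (a benzene ring rotated in-plane by 60 degrees has symmetry-corrected
#' RMSD 0 but a large identity RMSD). Without a bond graph only the
#' identity mapping is available, which assumes both poses list atoms in
#' the same order.
#'
#' @param ref,cand Coordinates as data.frames with columns `element`,
#'   `x`, `y`, `z` (a `structure_model` works), in the same atom order.
#' @param bonds Optional 2-column matrix of 1-based atom indices (bonds
#'   of the ligand graph, valid for both poses).
#' @param heavy_only Drop hydrogens first (default `TRUE`).
#' @param max_mappings Safety cap on enumerated automorphisms (default
#'   10000).
#' @return List with `rmsd` (minimum over mappings, Angstrom),
#'   `identity_rmsd`, `n_mappings`, and `mapping` (the minimizing
#'   permutation of candidate atoms).
#' @examples
#' p <- data.frame(element = "C", x = 0, y = 0, z = 0)
#' q <- transform(p, x = 3, y = 4)
#' pose_rmsd(p, q)$rmsd  # 5
#' @export
pose_rmsd <- function(ref, cand, bonds = NULL, heavy_only = TRUE,
                      max_mappings = 10000L) {
  ref <- as.data.frame(ref); cand <- as.data.frame(cand)
  stopifnot(all(c("element", "x", "y", "z") %in% names(ref)),
            all(c("element", "x", "y", "z") %in% names(cand)))
  keep_r <- rep(TRUE, nrow(ref)); keep_c <- rep(TRUE, nrow(cand))
  if (heavy_only) {
    keep_r <- toupper(ref$element) != "H"
    keep_c <- toupper(cand$element) != "H"
  }
  if (!is.null(bonds)) {
    if (!all(keep_r) || !all(keep_c)) {
      # re-index bonds onto the heavy-atom subset
      bonds <- as.matrix(bonds)
      old2new <- cumsum(keep_r)
      b_keep <- keep_r[bonds[, 1]] & keep_r[bonds[, 2]]
      bonds <- cbind(old2new[bonds[b_keep, 1]], old2new[bonds[b_keep, 2]])
    }
  }
  ref <- ref[keep_r, , drop = FALSE]; cand <- cand[keep_c, , drop = FALSE]
  er <- toupper(ref$element); ec <- toupper(cand$element)
  if (nrow(ref) != nrow(cand) || !identical(sort(er), sort(ec))) {
    abort_composition(sprintf(
      "element composition differs: ref {%s} vs cand {%s}",
      paste(names(table(er)), table(er), collapse = " "),
      paste(names(table(ec)), table(ec), collapse = " ")))
  }
  rxyz <- as.matrix(ref[, c("x", "y", "z")])
  cxyz <- as.matrix(cand[, c("x", "y", "z")])
  if (any(!is.finite(rxyz)) || any(!is.finite(cxyz))) {
    abort_domain("coordinates must be finite")
  }
  rmsd_for <- function(perm) sqrt(mean(rowSums((rxyz - cxyz[perm, , drop = FALSE])^2)))
  identity_ok <- all(er == ec)
  identity_rmsd <- if (identity_ok) rmsd_for(seq_len(nrow(ref))) else NA_real_
  if (is.null(bonds)) {
    if (!identity_ok) {
      abort_composition("atom orders differ by element; supply `bonds` for mapping")
    }
    return(list(rmsd = identity_rmsd, identity_rmsd = identity_rmsd,
                n_mappings = 1L, mapping = seq_len(nrow(ref))))
  }
  maps <- graph_automorphisms(er, bonds, max_mappings = max_mappings)
  vals <- vapply(maps, rmsd_for, numeric(1))
  best <- which.min(vals)
  list(rmsd = vals[best],
       identity_rmsd = identity_rmsd,
       n_mappings = length(maps), mapping = maps[[best]])
}

# Enumerate element-preserving automorphisms of a molecular graph by
# backtracking (vertices colored by element + degree; adjacency must be
# preserved). Returns a list of permutations p with p[i] = image of i.
graph_automorphisms <- function(elements, bonds, max_mappings = 10000L) {
  n <- length(elements)
  adj <- matrix(FALSE, n, n)
  if (NROW(bonds)) {
    b <- as.matrix(bonds)
    adj[cbind(b[, 1], b[, 2])] <- TRUE
    adj[cbind(b[, 2], b[, 1])] <- TRUE
  }
  deg <- rowSums(adj)
  color <- paste(elements, deg)
  out <- list()
  perm <- integer(n)
  used <- logical(n)
  bt <- function(i) {
    if (length(out) >= max_mappings) return()
    if (i > n) {
      out[[length(out) + 1L]] <<- perm
      return()
    }
    for (v in which(!used & color == color[i])) {
      # adjacency consistency with already-mapped vertices
      prev <- seq_len(i - 1L)
      if (all(adj[i, prev] == adj[v, perm[prev]])) {
        perm[i] <<- v; used[v] <<- TRUE
        bt(i + 1L)
        used[v] <<- FALSE
      }
    }
  }
  bt(1L)
  out
}

#' Agreement between predicted scores and experimental potencies
#'
#' Converts experimental half-maximal potencies (IC50/EC50, molar) to
#' binding free energies via `dG = R * T * ln(potency)` at T = 298.15 K
#' with R = 1.987e-3 kcal/(mol K), computes residuals
#' (predicted - experimental dG), and reports the standard error of the
#' residuals (`sd(residuals) / sqrt(n)`) together with the RMSE. The two
#' summaries differ: the SE of residuals is sensitive to a shared shift
#' through the residual mean, RMSE penalizes it directly — both are
#' reported so either convention can be compared.
#'
#' @param predicted Numeric vector of predicted docking scores
#'   (kcal/mol).
#' @param potency Experimental potencies in molar units (> 0).
#' @param temperature Kelvin (default 298.15).
#' @return List with `n`, `dg_experimental`, `residuals`,
#'   `standard_error`, `rmse`, `mean_residual`.
#' @export
experimental_agreement <- function(predicted, potency, temperature = 298.15) {
  if (length(predicted) != length(potency) || length(predicted) < 2L) {
    abort_domain("need >= 2 (predicted, potency) pairs of equal length")
  }
  if (any(!is.finite(potency)) || any(potency <= 0)) {
    abort_domain("potencies must be positive finite molar values")
  }
  R <- 1.987e-3  # kcal / (mol K)
  dg <- R * temperature * log(potency)
  res <- predicted - dg
  list(n = length(res), dg_experimental = dg, residuals = res,
       standard_error = stats::sd(res) / sqrt(length(res)),
       rmse = sqrt(mean(res^2)), mean_residual = mean(res))
}
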