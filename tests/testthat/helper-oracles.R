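# Independent oracles and shared fixtures for the test suite.

extdata <- function(name) {
  system.file("extdata", name, package = "edcscreen", mustWork = TRUE)
}

# Exhaustive longest-simple-path oracle over the fluorinated-carbon
# subgraph, via igraph's all_simple_paths (independent of the package's
# own DFS).
oracle_longest_fluorinated_chain <- function(mol) {
  el <- mol$atoms$element
  b <- mol$bonds
  nbrs <- function(i) c(b$j[b$i == i], b$i[b$j == i])
  fluor <- which(vapply(seq_along(el), function(i) {
    el[i] == "C" && any(el[nbrs(i)] == "F")
  }, logical(1)))
  if (length(fluor) == 0L) return(0L)
  keep <- b$i %in% fluor & b$j %in% fluor
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(b$i[keep]), to = as.character(b$j[keep])),
    directed = FALSE, vertices = data.frame(name = as.character(fluor)))
  best <- 1L
  for (v in igraph::V(g)) {
    paths <- igraph::all_simple_paths(g, from = v)
    if (length(paths)) best <- max(best, max(lengths(paths)))
  }
  as.integer(best)
}

# All-pairs nested-loop contact scan (deliberately naive).
oracle_contacts <- function(receptor, pose, cutoff) {
  rec <- as.data.frame(receptor)
  lig <- as.data.frame(pose)
  hits <- list()
  for (i in seq_len(nrow(rec))) {
    dmin <- Inf
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                  (rec$z[i] - lig$z[j])^2)
      if (d < dmin) dmin <- d
    }
    key <- paste(rec$chain[i], rec$resno[i], rec$resid[i])
    if (is.null(hits[[key]]) || dmin < hits[[key]]) hits[[key]] <- dmin
  }
  keep <- vapply(hits, function(d) d <= cutoff, logical(1))
  out <- data.frame(
    key = names(hits)[keep], min_distance = unlist(hits[keep], use.names = FALSE),
    stringsAsFactors = FALSE)
  out[order(out$key), , drop = FALSE]
}

contacts_as_keyed <- function(ct) {
  out <- data.frame(key = paste(ct$chain, ct$resno, ct$resid),
                    min_distance = ct$min_distance, stringsAsFactors = FALSE)
  out[order(out$key), , drop = FALSE]
}

# Random molecule graphs (trees plus optional extra ring-closing edges)
# with C/F/O atoms, <= 30 heavy atoms, for property tests.
random_molecule <- function(n_atoms, p_fluor = 0.4, p_ring = 0.2) {
  n <- max(2L, n_atoms)
  elements <- sample(c("C", "F", "O"), n, replace = TRUE,
                     prob = c(0.6, p_fluor, 1 - 0.6 - p_fluor + 1e-9))
  # random spanning tree
  bonds <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  if (stats::runif(1) < p_ring && n >= 4L) {
    extra <- sample.int(n, 2L)
    bonds <- rbind(bonds, extra)
  }
  make_molecule(elements, bonds)
}

table9 <- function() read_score_table(extdata("table9_phthalate_scores.csv"), id_cols = 2)
table8 <- function() read_score_table(extdata("table8_bisphenol_scores.csv"), id_cols = 2)
table7 <- function() read_score_table(extdata("table7_pfas_pesticide_scores.csv"), id_cols = 2)
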