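#' Longest fluorinated carbon chain
#'
#' Length (in atoms) of the longest simple path through carbon atoms that
#' each bear at least one fluorine substituent — the chain-length
#' descriptor used to relate per-/polyfluoroalkyl structure to binding
#' affinity. A carbon qualifies regardless of its other substituents, and
#' aromatic carbons qualify if fluorinated; ring atoms may be traversed
#' but no atom is revisited. The search is an exact depth-first
#' enumeration of simple paths in the induced subgraph (exponential in the
#' worst case, which is immaterial at typical ligand sizes).
#'
#' @param mol A `molecule` (from [parse_smiles()] or [make_molecule()]).
#' @return Non-negative integer; 0 when no fluorinated carbon exists.
#' @examples
#' longest_fluorinated_chain(parse_smiles("FC(F)(F)F"))  # 1
#' @export
longest_fluorinated_chain <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  el <- mol$atoms$element
  adj <- molecule_adjacency(mol)
  fluorinated <- vapply(seq_along(el), function(i) {
    el[i] == "C" && any(el[adj[[i]]] == "F")
  }, logical(1))
  nodes <- which(fluorinated)
  if (length(nodes) == 0L) return(0L)
  # adjacency restricted to fluorinated carbons
  sub_adj <- lapply(nodes, function(i) intersect(adj[[i]], nodes))
  names(sub_adj) <- as.character(nodes)
  best <- 1L
  visited <- logical(nrow(mol$atoms))
  dfs <- function(v, depth) {
    if (depth > best) best <<- depth
    visited[v] <<- TRUE
    for (w in sub_adj[[as.character(v)]]) {
      if (!visited[w]) dfs(w, depth + 1L)
    }
    visited[v] <<- FALSE
  }
  for (v in nodes) dfs(v, 1L)
  best
}

#' Detect functional groups in a molecule
#'
#' Matches every taxonomy pattern against the molecule (SMARTS matching
#' via the OpenBabel backend) and returns the names of groups with at
#' least one substructure match. Precedence between chemically nested
#' groups is handled by the context-exclusive patterns of the shipped
#' taxonomy (see [default_group_taxonomy()]); any `suppresses` entries of
#' matching groups are additionally removed, in precedence order.
#'
#' @param mol A `molecule` with SDF backing (i.e. from [parse_smiles()]).
#' @param taxonomy Taxonomy data.frame; defaults to the shipped one.
#' @return Character vector of matched group names (taxonomy order).
#' @examples
#' detect_functional_groups(parse_smiles("NC(=O)N"))  # urea, not amide
#' @export
detect_functional_groups <- function(mol, taxonomy = default_group_taxonomy()) {
  stopifnot(inherits(mol, "molecule"))
  if (is.null(mol$sdf)) {
    abort_domain("molecule has no SDF backing; build it with parse_smiles()")
  }
  counts <- match_taxonomy(mol$sdf, taxonomy)[1, ]
  apply_suppression(counts > 0, taxonomy)
}

# batch SMARTS matching: matrix of match counts, molecules x groups
match_taxonomy <- function(sdfset, taxonomy) {
  m <- vapply(seq_len(nrow(taxonomy)), function(k) {
    as.integer(ChemmineR::smartsSearchOB(sdfset, taxonomy$pattern[k],
                                         uniqueMatches = FALSE))
  }, integer(length(sdfset)))
  m <- matrix(m, nrow = length(sdfset), ncol = nrow(taxonomy))
  colnames(m) <- taxonomy$name
  m
}

apply_suppression <- function(present, taxonomy) {
  hits <- taxonomy$name[present]
  for (k in seq_len(nrow(taxonomy))) {
    if (present[k] && nzchar(taxonomy$suppresses[k])) {
      drop <- trimws(strsplit(taxonomy$suppresses[k], ";")[[1]])
      hits <- setdiff(hits, drop)
    }
  }
  hits
}

#' Predicted hydrophobicity/polarity descriptors
#'
#' Atom-contribution logP (Wildman-Crippen scheme) and topological polar
#' surface area (Ertl group contributions), both as implemented by the
#' OpenBabel descriptor engine, so results are deterministic and
#' reproducible for a given molecule. logP > 5 is the conventional
#' bioaccumulation flag used downstream.
#'
#' @param mol A `molecule` with SDF backing.
#' @return Named list with `logp` (unitless) and `tpsa` (squared Angstrom).
#' @examples
#' compute_hydrophobicity_descriptors(parse_smiles("CCO"))$tpsa  # 20.23
#' @export
compute_hydrophobicity_descriptors <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  if (is.null(mol$sdf)) {
    abort_domain("molecule has no SDF backing; build it with parse_smiles()")
  }
  p <- ChemmineR::propOB(mol$sdf)
  list(logp = as.numeric(p$logP), tpsa = as.numeric(p$TPSA))
}

#' Filter compound records by molecular weight
#'
#' Keeps records with `lo <= mol_weight <= hi` (both bounds inclusive;
#' the standard screening window is 175 to 1000 g/mol). Order is
#' preserved and an empty result is allowed.
#'
#' @param records Data.frame with a `mol_weight` column (g/mol).
#' @param lo,hi Inclusive bounds in g/mol.
#' @return The filtered data.frame.
#' @export
filter_by_molecular_weight <- function(records, lo = 175, hi = 1000) {
  stopifnot(is.data.frame(records), "mol_weight" %in% names(records))
  if (lo > hi) abort_domain("`lo` must not exceed `hi`")
  keep <- !is.na(records$mol_weight) & records$mol_weight >= lo &
    records$mol_weight <= hi
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a compound table
#'
#' @param path CSV with columns `cas_id`, `smiles` and optionally
#'   `chem_class` (PFAS, plastic, phthalate, PBDE, bisphenol,
#'   pfas_pesticide, other).
#' @return Data.frame of compound records.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cas_id", "smiles") %in% names(df))) {
    abort_format("compound table must have columns cas_id, smiles")
  }
  if (is.null(df$chem_class)) df$chem_class <- "other"
  df
}

#' Annotate compound records with structural descriptors
#'
#' Parses every SMILES and adds `mol_weight` (g/mol), `logp`, `tpsa`
#' (squared Angstrom), `fluorinated_chain_length` and `functional_groups`
#' (semicolon-joined taxonomy names). Records whose SMILES fail to parse
#' are discarded with a message (mirroring the usual handling of source
#' lists that contain invalid SMILES); the number dropped is recorded in
#' the `n_discarded` attribute.
#'
#' @param records Data.frame with columns `cas_id`, `smiles` (and
#'   optionally `chem_class`).
#' @param taxonomy Functional-group taxonomy (see
#'   [default_group_taxonomy()]).
#' @return Annotated data.frame, one row per parsable record.
#' @export
annotate_compounds <- function(records, taxonomy = default_group_taxonomy()) {
  stopifnot(is.data.frame(records), all(c("cas_id", "smiles") %in% names(records)))
  sdfset <- smiles_to_sdfset(records$smiles)
  ok <- ChemmineR::validSDF(sdfset)
  if (any(!ok)) {
    message(sprintf("discarding %d record(s) without valid SMILES: %s",
                    sum(!ok), paste(records$cas_id[!ok], collapse = ", ")))
  }
  out <- records[ok, , drop = FALSE]
  sdfset <- sdfset[ok]
  if (nrow(out) == 0L) {
    out$mol_weight <- out$logp <- out$tpsa <- numeric(0)
    out$fluorinated_chain_length <- integer(0)
    out$functional_groups <- character(0)
    attr(out, "n_discarded") <- sum(!ok)
    return(out)
  }
  props <- ChemmineR::propOB(sdfset)
  out$mol_weight <- as.numeric(props$MW)
  out$logp <- as.numeric(props$logP)
  out$tpsa <- as.numeric(props$TPSA)
  counts <- match_taxonomy(sdfset, taxonomy)
  out$functional_groups <- vapply(seq_len(nrow(out)), function(r) {
    paste(apply_suppression(counts[r, ] > 0, taxonomy), collapse = ";")
  }, character(1))
  out$fluorinated_chain_length <- vapply(seq_len(nrow(out)), function(r) {
    longest_fluorinated_chain(molecule_from_sdf(sdfset[r], out$smiles[r]))
  }, integer(1))
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!ok)
  out
}
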