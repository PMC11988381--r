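# Seeded generators for every input the pipeline consumes: fluorinated
# SMILES with known chain length and groups, score tables with a planted
# linear chain-length trend, reference-ligand sets with a chosen mean, and
# toy receptor/ligand complexes with planted contact distances. All
# generators are bit-reproducible per seed (RNG state is restored via
# withr, so no global state leaks).

.terminal_groups <- list(
  none            = list(smiles = "",           groups = c("halide"), eats_carbon = FALSE),
  `carboxylic acid` = list(smiles = "OC(=O)",   groups = c("carboxylic acid", "halide"), eats_carbon = TRUE),
  `sulfonic acid` = list(smiles = "OS(=O)(=O)", groups = c("sulfonic acid", "halide"), eats_carbon = FALSE),
  alcohol         = list(smiles = "O",          groups = c("alcohol", "halide"), eats_carbon = FALSE)
)

# SMILES of a fully fluorinated linear chain of n carbons (terminal
# fluorines included unless capped on the left by a group)
perfluoro_chain <- function(n, cap_left = "") {
  if (n == 0L) abort_config("chain must have >= 1 carbon")
  units <- c(if (nzchar(cap_left)) "C(F)(F)" else "FC(F)(F)",
             rep("C(F)(F)", max(0L, n - 2L)),
             if (n > 1L) "C(F)(F)F")
  body <- paste(units, collapse = "")
  if (n == 1L) body <- if (nzchar(cap_left)) "C(F)(F)F" else "FC(F)(F)F"
  paste0(cap_left, body)
}

#' Generate fluorinated compound records with known ground truth
#'
#' Emits valid SMILES of perfluorinated linear chains with an optional
#' terminal group (carboxylic acid, sulfonic acid, alcohol, or none), and
#' records the true fluorinated-chain length and functional-group content
#' implied by the construction. `n_carbons` counts all carbons including
#' a terminal carboxyl carbon, so an acid of length L has a fluorinated
#' chain of L - 1 (the carboxyl carbon bears no fluorine); the other
#' terminals leave every carbon fluorinated.
#'
#' @param n Number of compounds.
#' @param lengths Candidate carbon counts (default 1:26), sampled
#'   uniformly.
#' @param group_probs Named sampling probabilities over `"none"`,
#'   `"carboxylic acid"`, `"sulfonic acid"`, `"alcohol"`.
#' @param seed Integer seed (required; generation is deterministic per
#'   seed).
#' @return Data.frame with `cas_id`, `smiles`, `chem_class`,
#'   `true_chain_length`, `true_groups` (semicolon-joined).
#' @export
generate_fluorinated_smiles <- function(n, lengths = 1:26,
                                        group_probs = c(none = 0.4,
                                                        `carboxylic acid` = 0.3,
                                                        `sulfonic acid` = 0.2,
                                                        alcohol = 0.1),
                                        seed) {
  if (missing(seed)) abort_config("a seed is required")
  if (any(lengths < 1L) || any(lengths > 26L)) {
    abort_config("lengths must lie in 1..26")
  }
  if (!all(names(group_probs) %in% names(.terminal_groups))) {
    abort_config(sprintf("unknown terminal group(s): %s",
                         paste(setdiff(names(group_probs),
                                       names(.terminal_groups)), collapse = ", ")))
  }
  withr::local_preserve_seed()
  set.seed(seed)
  L <- sample(lengths, n, replace = TRUE)
  grp <- sample(names(group_probs), n, replace = TRUE, prob = group_probs)
  # a 1-carbon acid would be a fluorinated carboxyl carbon; keep the
  # acid carbon unfluorinated by requiring >= 2 carbons
  grp[grp == "carboxylic acid" & L < 2L] <- "none"
  rec <- lapply(seq_len(n), function(i) {
    spec <- .terminal_groups[[grp[i]]]
    true_len <- if (spec$eats_carbon) L[i] - 1L else L[i]
    data.frame(cas_id = sprintf("SYN-%05d", i),
               smiles = perfluoro_chain(true_len, spec$smiles),
               chem_class = "PFAS",
               true_chain_length = true_len,
               true_groups = paste(spec$groups, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rec)
}

#' Generate a score table with a planted chain-length trend
#'
#' Scores follow `score = beta0[r] + beta1[r] * L + e`, `e ~ N(0,
#' sigma^2)`, per receptor — the linear mean-affinity-vs-chain-length
#' structure the trend analysis is designed to recover. Ground-truth
#' coefficients are returned alongside the table.
#'
#' @param records Data.frame with `cas_id` and `true_chain_length` (e.g.
#'   from [generate_fluorinated_smiles()]).
#' @param receptors Receptor names (columns).
#' @param beta0,beta1 Numeric vectors (recycled across receptors):
#'   intercept kcal/mol and slope kcal/mol per chain unit.
#' @param sigma Gaussian noise sd in kcal/mol (>= 0).
#' @param seed Integer seed.
#' @return List with `table` (a [score_table()]) and `truth` (data.frame
#'   `receptor`, `beta0`, `beta1`, `sigma`).
#' @export
generate_score_table <- function(records, receptors = c("PXR", "CAR", "PPARa",
                                                        "PPARg", "PPARd", "AR", "RORgt"),
                                 beta0 = -6.0, beta1 = -0.2, sigma = 0.3, seed) {
  if (missing(seed)) abort_config("a seed is required")
  if (sigma < 0) abort_config("sigma must be >= 0")
  stopifnot(all(c("cas_id", "true_chain_length") %in% names(records)))
  withr::local_preserve_seed()
  set.seed(seed)
  beta0 <- rep_len(beta0, length(receptors))
  beta1 <- rep_len(beta1, length(receptors))
  L <- records$true_chain_length
  m <- sapply(seq_along(receptors), function(k) {
    beta0[k] + beta1[k] * L + stats::rnorm(length(L), 0, sigma)
  })
  m <- matrix(m, nrow = length(L), ncol = length(receptors),
              dimnames = list(records$cas_id, receptors))
  list(table = score_table(m),
       truth = data.frame(receptor = receptors, beta0 = beta0, beta1 = beta1,
                          sigma = sigma, stringsAsFactors = FALSE))
}

#' Generate reference-ligand score sets with chosen means
#'
#' Draws `n_ref` reference scores per receptor from a Gaussian spread and
#' recenters them so each receptor's mean is exactly the requested value.
#'
#' @param means Named numeric vector: receptor -> reference mean
#'   (kcal/mol, negative).
#' @param n_ref Reference ligands per receptor (default 5).
#' @param spread Gaussian sd of the raw draws (default 0.5 kcal/mol).
#' @param seed Integer seed.
#' @return A [reference_set()].
#' @export
generate_reference_sets <- function(means, n_ref = 5L, spread = 0.5, seed) {
  if (missing(seed)) abort_config("a seed is required")
  if (is.null(names(means))) abort_config("`means` must be named by receptor")
  withr::local_preserve_seed()
  set.seed(seed)
  rows <- lapply(names(means), function(rc) {
    s <- stats::rnorm(n_ref, means[[rc]], spread)
    s <- s - mean(s) + means[[rc]]
    data.frame(receptor = rc, ligand_id = sprintf("%s-ref%02d", rc, seq_len(n_ref)),
               score = s, stringsAsFactors = FALSE)
  })
  reference_set(do.call(rbind, rows))
}

.toy_residues <- c("LEU", "PHE", "ILE", "MET", "VAL", "ALA", "GLY", "SER",
                   "THR", "TYR", "TRP", "HIS", "ASN", "GLN", "ASP", "GLU",
                   "LYS", "ARG", "CYS", "PRO")

#' Generate a toy receptor/ligand complex with planted contact distances
#'
#' Places a single-atom ligand at the origin and one residue per
#' requested distance along a random direction, with `atoms_per_residue`
#' atoms marching outward so the residue's minimum atom-atom distance to
#' the ligand is exactly the requested value. The set of residues at
#' distance <= cutoff is therefore known by construction.
#'
#' @param distances Numeric vector of planted minimum distances
#'   (Angstrom, >= 0).
#' @param resids Residue names (3-letter), recycled; defaults to a cycle
#'   over the 20 standard amino acids.
#' @param atoms_per_residue Atoms per residue (default 3; spaced 0.8 A
#'   further out along the same ray).
#' @param seed Integer seed (random directions).
#' @return List with `receptor` and `pose` (`structure_model`s) and
#'   `truth` (data.frame `resid`, `resno`, `chain`, `min_distance`).
#' @export
generate_toy_complex <- function(distances, resids = NULL,
                                 atoms_per_residue = 3L, seed) {
  if (missing(seed)) abort_config("a seed is required")
  if (length(distances) < 1L || any(distances < 0)) {
    abort_config("distances must be non-negative")
  }
  withr::local_preserve_seed()
  set.seed(seed)
  n <- length(distances)
  if (is.null(resids)) resids <- rep_len(.toy_residues, n)
  resids <- rep_len(resids, n)
  rows <- lapply(seq_len(n), function(i) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    d <- distances[i] + 0.8 * (seq_len(atoms_per_residue) - 1L)
    data.frame(serial = NA_integer_, atom = c("CA", "CB", "CG", "CD",
                                              "CE")[seq_len(atoms_per_residue)],
               resid = resids[i], chain = "A", resno = i,
               x = d * u[1], y = d * u[2], z = d * u[3],
               element = "C", stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec$serial <- seq_len(nrow(rec))
  pose <- data.frame(serial = 1L, atom = "C1", resid = "LIG", chain = "B",
                     resno = 1L, x = 0, y = 0, z = 0, element = "C",
                     stringsAsFactors = FALSE)
  list(receptor = structure_model(rec, role = "receptor"),
       pose = structure_model(pose, role = "ligand_pose"),
       truth = data.frame(resid = resids, resno = seq_len(n), chain = "A",
                          min_distance = distances, stringsAsFactors = FALSE))
}

#' Generate a random toy complex (no planted truth)
#'
#' Uniform random receptor atoms in a cube around a small random ligand;
#' used for oracle-equivalence checks where the expected contact set is
#' computed by brute force.
#'
#' @param n_residues Number of receptor residues.
#' @param atoms_per_residue Atoms per residue.
#' @param n_ligand_atoms Ligand atoms.
#' @param box Half-width of the coordinate cube (Angstrom).
#' @param seed Integer seed.
#' @return List with `receptor` and `pose` `structure_model`s.
#' @export
generate_random_complex <- function(n_residues = 50L, atoms_per_residue = 3L,
                                    n_ligand_atoms = 10L, box = 10, seed) {
  if (missing(seed)) abort_config("a seed is required")
  withr::local_preserve_seed()
  set.seed(seed)
  n_rec <- n_residues * atoms_per_residue
  rec <- data.frame(
    serial = seq_len(n_rec), atom = "CA",
    resid = rep(rep_len(.toy_residues, n_residues), each = atoms_per_residue),
    chain = "A", resno = rep(seq_len(n_residues), each = atoms_per_residue),
    x = stats::runif(n_rec, -box, box), y = stats::runif(n_rec, -box, box),
    z = stats::runif(n_rec, -box, box), element = "C",
    stringsAsFactors = FALSE)
  lig <- data.frame(
    serial = seq_len(n_ligand_atoms), atom = "C1", resid = "LIG", chain = "B",
    resno = 1L, x = stats::runif(n_ligand_atoms, -2, 2),
    y = stats::runif(n_ligand_atoms, -2, 2), z = stats::runif(n_ligand_atoms, -2, 2),
    element = "C", stringsAsFactors = FALSE)
  list(receptor = structure_model(rec, role = "receptor"),
       pose = structure_model(lig, role = "ligand_pose"))
}
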