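#' Parse a SMILES string into a molecular graph
#'
#' Converts a SMILES string into a sanitized molecular graph using the
#' OpenBabel backend of \pkg{ChemmineOB}/\pkg{ChemmineR} (aromaticity is
#' perceived by the toolkit; hydrogens stay implicit and are counted per
#' atom). The returned object keeps the heavy-atom graph alongside the
#' toolkit's SDF representation, which downstream descriptor and
#' substructure operations reuse.
#'
#' Compound sources list chemicals as CAS number + SMILES; entries without
#' valid SMILES are expected to be discarded by callers catching the parse
#' error raised here.
#'
#' @param smiles Single non-empty SMILES string.
#' @return An object of class `molecule`: a list with `atoms` (data.frame
#'   with columns `element`, `charge`, `n_h`), `bonds` (data.frame with
#'   columns `i`, `j`, `order`), `smiles`, and the backing `sdf`
#'   ([ChemmineR::SDFset-class] of length 1).
#' @details Syntactically invalid SMILES (e.g. an unclosed branch `"C("`)
#'   raise a parse error. The OpenBabel backend is lenient about some
#'   chemically impossible valences, which therefore may pass through
#'   unflagged.
#' @examples
#' mol <- parse_smiles("CCO")
#' nrow(mol$atoms)  # 3 heavy atoms
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    abort_parse("`smiles` must be a single non-empty string")
  }
  sdf <- smiles_to_sdfset(smiles)
  if (!ChemmineR::validSDF(sdf)) {
    abort_parse(sprintf("invalid SMILES: '%s'", smiles))
  }
  molecule_from_sdf(sdf[1], smiles)
}

#' Construct a molecule directly from an atom and bond table
#'
#' Used by tests and generators to build molecular graphs without going
#' through SMILES. No SDF backing is attached, so descriptor and
#' substructure operations that need the chemistry toolkit are unavailable
#' on such objects; the pure graph operations (e.g.
#' [longest_fluorinated_chain()]) work.
#'
#' @param elements Character vector of element symbols.
#' @param bonds Two- or three-column matrix/data.frame of 1-based atom
#'   indices (and optional bond order, default 1).
#' @return A `molecule` object (without `$sdf`).
#' @export
make_molecule <- function(elements, bonds = NULL) {
  stopifnot(is.character(elements), length(elements) >= 1L)
  if (is.null(bonds) || NROW(bonds) == 0L) {
    b <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) == 2L) bonds <- cbind(bonds, 1L)
    b <- data.frame(i = as.integer(bonds[, 1]), j = as.integer(bonds[, 2]),
                    order = as.integer(bonds[, 3]))
    if (any(b$i < 1L | b$i > length(elements) | b$j < 1L | b$j > length(elements))) {
      abort_parse("bond indices out of range")
    }
  }
  structure(
    list(atoms = data.frame(element = elements, charge = 0L, n_h = NA_integer_),
         bonds = b, smiles = NA_character_, sdf = NULL),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d heavy atoms, %d bonds", nrow(x$atoms), nrow(x$bonds)))
  if (!is.na(x$smiles)) cat("  (", x$smiles, ")", sep = "")
  cat("\n")
  invisible(x)
}

# Batch SMILES -> SDFset conversion. Invalid entries come back as 0-atom
# SDF records; callers inspect ChemmineR::validSDF.
smiles_to_sdfset <- function(smiles) {
  names(smiles) <- sprintf("mol%06d", seq_along(smiles))
  suppressWarnings(ChemmineR::smiles2sdf(smiles))
}

# Default valences of the SMILES organic subset, used to count implicit
# hydrogens from the kekulized heavy-atom graph.
.default_valence <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
                      F = 1L, Cl = 1L, Br = 1L, I = 1L)

molecule_from_sdf <- function(sdf1, smiles = NA_character_) {
  ab <- ChemmineR::atomblock(sdf1[[1]])
  bb <- ChemmineR::bondblock(sdf1[[1]])
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  if (n == 0L) abort_parse("molecule has no atoms")
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  charge <- integer(n)
  # formal charges live in "M  CHG" property lines of the SDF text
  txt <- ChemmineR::sdf2str(sdf1[[1]])
  chg_lines <- grep("^M  CHG", txt, value = TRUE)
  for (ln in chg_lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    for (z in seq_len(k)) charge[f[2 * z]] <- f[2 * z + 1]
  }
  # implicit hydrogens from default valence, adjusted by formal charge
  bsum <- integer(n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      bsum[bonds$i[r]] <- bsum[bonds$i[r]] + bonds$order[r]
      bsum[bonds$j[r]] <- bsum[bonds$j[r]] + bonds$order[r]
    }
  }
  dv <- .default_valence[elements]
  n_h <- ifelse(is.na(dv), 0L, pmax(0L, dv + ifelse(elements %in% c("N", "P"),
                                                    charge, -charge) - bsum))
  structure(
    list(atoms = data.frame(element = elements, charge = charge,
                            n_h = as.integer(n_h)),
         bonds = bonds, smiles = smiles, sdf = sdf1),
    class = "molecule"
  )
}

# adjacency list of a molecule (heavy atoms only; indices into $atoms)
molecule_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  adj
}
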