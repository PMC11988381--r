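# three- to one-letter amino acid code map for FASTA export
.aa321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Receptor residues contacting a docked ligand
#'
#' Returns every receptor residue with at least one atom within `cutoff`
#' (inclusive) of at least one ligand atom, with the minimum atom-atom
#' Euclidean distance per residue. Both structures must already share the
#' docking coordinate frame; no superposition is performed. By default
#' every atom present in the files counts (including hydrogens, matching
#' the zone-selection behavior of structure viewers); set
#' `heavy_only = TRUE` to ignore hydrogens.
#'
#' @param receptor,pose `structure_model` objects.
#' @param cutoff Contact cutoff in Angstrom (default 5.0; the boundary is
#'   a contact).
#' @param heavy_only Drop hydrogen atoms before measuring.
#' @return Data.frame with columns `resid`, `resno`, `chain`,
#'   `min_distance`, sorted by residue number.
#' @export
contacts_within_cutoff <- function(receptor, pose, cutoff = 5.0,
                                   heavy_only = FALSE) {
  stopifnot(inherits(receptor, "structure_model"),
            inherits(pose, "structure_model"))
  rec <- as.data.frame(receptor)
  lig <- as.data.frame(pose)
  if (heavy_only) {
    rec <- rec[toupper(rec$element) != "H", , drop = FALSE]
    lig <- lig[toupper(lig$element) != "H", , drop = FALSE]
  }
  if (nrow(rec) == 0L || nrow(lig) == 0L) {
    abort_empty_structure("receptor and pose must both contain atoms")
  }
  rxyz <- as.matrix(rec[, c("x", "y", "z")])
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  # squared cross-distances receptor-atoms x ligand-atoms
  d2 <- outer(rowSums(rxyz^2), rowSums(lxyz^2), "+") - 2 * rxyz %*% t(lxyz)
  min_d <- sqrt(pmax(0, apply(d2, 1, min)))
  key <- paste(rec$chain, rec$resno, rec$resid, sep = "|")
  per_res <- tapply(min_d, key, min)
  parts <- do.call(rbind, strsplit(names(per_res), "|", fixed = TRUE))
  out <- data.frame(resid = parts[, 3], resno = as.integer(parts[, 2]),
                    chain = parts[, 1], min_distance = as.numeric(per_res),
                    stringsAsFactors = FALSE)
  out <- out[out$min_distance <= cutoff, , drop = FALSE]
  out <- out[order(out$resno, out$chain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate residue-contact frequencies over top binders
#'
#' Counts each contacted residue once per compound pose (a residue
#' touching one pose contributes one count regardless of how many of its
#' atoms touch), sums the counts per amino-acid type, and converts to
#' percentages over all counted contacts — the per-receptor interaction
#' profile reported for the top-N binders of each chemical class.
#'
#' @param contact_lists Named list (one element per compound pose) of
#'   contact data.frames as returned by [contacts_within_cutoff()].
#' @param receptor Receptor name carried into the profile.
#' @param per_pose_type If `TRUE`, a residue type is counted at most once
#'   per pose regardless of how many residues of that type are contacted
#'   (alternative weighting; default counts each residue).
#' @return An `interaction_profile`: data.frame with columns `resid`
#'   (3-letter type), `count`, `pct`, plus attributes `receptor` and `n`
#'   (number of poses).
#' @export
aggregate_residue_frequencies <- function(contact_lists, receptor = NA_character_,
                                          per_pose_type = FALSE) {
  stopifnot(is.list(contact_lists), length(contact_lists) >= 1L)
  types <- unlist(lapply(contact_lists, function(cl) {
    if (NROW(cl) == 0L) return(character())
    # one count per distinct residue per pose
    u <- unique(cl[, c("resid", "resno", "chain"), drop = FALSE])
    if (per_pose_type) unique(u$resid) else u$resid
  }), use.names = FALSE)
  counts <- table(factor(types, levels = sort(unique(types))))
  out <- data.frame(resid = names(counts), count = as.integer(counts),
                    pct = 100 * as.integer(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  structure(out, class = c("interaction_profile", "data.frame"),
            receptor = receptor, n = length(contact_lists))
}

#' Export contacted residues as FASTA
#'
#' One FASTA record per pose; the header combines receptor and compound
#' ids and the sequence is the 1-letter codes of the contacted residues
#' in residue-number order. Non-standard residue names signal an
#' unprepared receptor (structure preparation removes them) and raise an
#' error.
#'
#' @param contact_lists Named list of contact data.frames (names =
#'   compound ids).
#' @param receptor Receptor name for the headers.
#' @param path Optional output file; when `NULL` the FASTA text is
#'   returned invisibly only.
#' @return Character vector of FASTA lines (invisibly when written).
#' @export
export_contacts_fasta <- function(contact_lists, receptor, path = NULL) {
  stopifnot(is.list(contact_lists), length(contact_lists) >= 1L)
  if (is.null(names(contact_lists)) || any(!nzchar(names(contact_lists)))) {
    names(contact_lists) <- sprintf("pose%03d", seq_along(contact_lists))
  }
  lines <- unlist(lapply(names(contact_lists), function(id) {
    cl <- contact_lists[[id]]
    if (NROW(cl) == 0L) {
      abort_empty_structure(sprintf("no contacts for pose '%s'", id))
    }
    cl <- cl[order(cl$resno), , drop = FALSE]
    codes <- .aa321[toupper(cl$resid)]
    if (any(is.na(codes))) {
      abort_unknown_residue(sprintf(
        "non-standard residue(s) %s in pose '%s'; prepare the receptor first",
        paste(unique(cl$resid[is.na(codes)]), collapse = ", "), id))
    }
    c(sprintf(">%s|%s", receptor, id), paste(codes, collapse = ""))
  }), use.names = FALSE)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
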