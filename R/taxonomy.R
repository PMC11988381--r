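#' Functional-group taxonomy
#'
#' The taxonomy is an ordered table of (group name, SMARTS pattern,
#' precedence rank, optional suppression list) covering the functional
#' groups profiled in fluorinated and plastic-associated chemicals:
#' alcohol, aldehyde, ketone, carboxylic acid, amine, ether, ester, amide,
#' alkene, alkyne, thiol, sulfide, disulfide, sulfoxide, sulfone, sulfonic
#' acid, sulfonamide, sulfonate ester, sulfinate ester, thioketone,
#' nitrile, nitro, phenyl, halide, anhydride, isocyanate, urea and
#' carbamate.
#'
#' Precedence is encoded primarily in the patterns themselves: each SMARTS
#' is written context-exclusively, so a higher-precedence group's atoms do
#' not additionally match lower-precedence patterns (a carboxylic acid is
#' not also an alcohol/ketone/ether; urea and carbamate are not amides; an
#' anhydride is not two esters; a sulfonic acid is not a sulfone). A group
#' occurring independently elsewhere in the same molecule is still
#' reported. The `suppresses` column (semicolon-separated group names) is
#' applied on top of the pattern matches and is meant for user-supplied
#' taxonomies whose patterns overlap; it is empty in the shipped table.
#'
#' "Halide" means any carbon-halogen bond (F, Cl, Br, I), so essentially
#' every per-/polyfluorinated compound reports it.
#'
#' @return A data.frame with columns `name`, `pattern`, `precedence`,
#'   `suppresses`, ordered by precedence (1 = highest).
#' @export
default_group_taxonomy <- function() {
  path <- system.file("extdata", "functional_group_taxonomy.csv",
                      package = "edcscreen", mustWork = TRUE)
  read_group_taxonomy(path)
}

#' Read a functional-group taxonomy from CSV
#'
#' @param path CSV with columns `name`, `pattern` (SMARTS), `precedence`
#'   (integer rank, 1 = highest), and optional `suppresses`
#'   (semicolon-separated group names removed from the result whenever
#'   this group matches).
#' @return Validated taxonomy data.frame ordered by precedence.
#' @export
read_group_taxonomy <- function(path) {
  tx <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "pattern", "precedence")
  if (!all(required %in% names(tx))) {
    abort_format(sprintf("taxonomy must have columns %s",
                         paste(required, collapse = ", ")))
  }
  if (anyDuplicated(tx$name)) abort_format("taxonomy group names must be unique")
  if (is.null(tx$suppresses)) tx$suppresses <- ""
  tx$suppresses[is.na(tx$suppresses)] <- ""
  tx <- tx[order(tx$precedence), , drop = FALSE]
  rownames(tx) <- NULL
  tx
}
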