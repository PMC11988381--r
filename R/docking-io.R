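#' Score tables
#'
#' A score table is a compound x receptor matrix of docking scores in
#' kcal/mol (more negative = stronger binding), with missing entries
#' allowed (a compound not docked or not scored against a receptor).
#'
#' @param scores Numeric matrix with compound ids as rownames and
#'   receptor names as colnames; `NA` marks missing cells.
#' @return An object of class `score_table` (a validated numeric matrix).
#' @export
score_table <- function(scores) {
  stopifnot(is.matrix(scores), is.numeric(scores))
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    abort_format("score matrix needs compound rownames and receptor colnames")
  }
  if (any(!is.finite(scores) & !is.na(scores))) {
    abort_format("scores must be finite or missing")
  }
  structure(scores, class = c("score_table", class(scores)))
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d compounds x %d receptors, %d missing cells\n",
              nrow(x), ncol(x), sum(is.na(x))))
  print(utils::head(unclass(x)))
  invisible(x)
}

# markers accepted as missing in CSV score tables ("#N/A" is the marker
# used in published per-class heat-map tables)
.missing_markers <- c("", "NA", "#N/A", "N/A", "#NA")

#' Read a docking score table from CSV
#'
#' Expects a header row of receptor names with the first column holding
#' compound ids (`cas_id` or any dataset key); cells are numeric scores in
#' kcal/mol or one of the missing markers `""`, `"NA"`, `"#N/A"`. Any
#' additional leading non-numeric columns (e.g. a compound-name column
#' before the CAS column) are folded into the row identifier.
#'
#' @param path CSV file path.
#' @param id_cols Number of leading identifier columns (default 1). When
#'   more than one, the last of them is used as the compound id.
#' @return A [score_table()].
#' @export
read_score_table <- function(path, id_cols = 1L) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  nf <- utils::count.fields(path, sep = ",", quote = "\"", comment.char = "")
  if (length(unique(nf)) != 1L) {
    abort_format(sprintf("ragged CSV (%s): rows have %s fields", path,
                         paste(sort(unique(nf)), collapse = "/")))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) <= id_cols) abort_format("score table has no receptor columns")
  ids <- df[[id_cols]]
  cells <- as.matrix(df[, -seq_len(id_cols), drop = FALSE])
  cells[cells %in% .missing_markers | is.na(cells)] <- NA_character_
  # tolerate unicode minus signs from transcribed tables
  cells[] <- gsub("−|–", "-", cells)
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- !is.na(cells) & is.na(num)
  if (any(bad)) {
    abort_format(sprintf("non-numeric score cell(s): %s",
                         paste(utils::head(cells[bad]), collapse = ", ")))
  }
  dimnames(num) <- list(ids, colnames(cells))
  score_table(num)
}

#' Write a score table to CSV
#'
#' @param table A [score_table()].
#' @param path Output CSV path.
#' @param digits Optional rounding (use 1 for the printed one-decimal
#'   kcal/mol dialect); `NULL` writes full precision so a write/read
#'   round trip is exact.
#' @param na Missing-cell marker (default `"#N/A"`).
#' @export
write_score_table <- function(table, path, digits = NULL, na = "#N/A") {
  stopifnot(inherits(table, "score_table"))
  m <- unclass(table)
  if (!is.null(digits)) m <- round(m, digits)
  df <- data.frame(cas_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = na)
  invisible(path)
}

#' Read a receptor or docked-ligand structure (PDB/PDBQT)
#'
#' Parses ATOM/HETATM records via [bio3d::read.pdb()]; AutoDock PDBQT
#' files are tolerated (ROOT/BRANCH/TORSDOF lines are ignored and partial
#' charge/atom-type extras are dropped). Residue numbering and chain ids
#' are preserved as in the source file.
#'
#' @param path PDB or PDBQT file.
#' @param role `"receptor"` or `"ligand_pose"` (metadata only).
#' @return An object of class `structure_model`: data.frame with columns
#'   `serial`, `atom`, `resid`, `chain`, `resno`, `x`, `y`, `z`,
#'   `element`, plus a `role` attribute.
#' @export
read_structure <- function(path, role = c("receptor", "ligand_pose")) {
  role <- match.arg(role)
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) abort_format(sprintf("cannot parse %s: %s", path,
                                             conditionMessage(e)))
  )
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) abort_format(sprintf("no atoms in %s", path))
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))) {
    abort_format(sprintf("non-finite coordinates in %s", path))
  }
  structure_model(data.frame(
    serial = a$eleno, atom = a$elety, resid = a$resid, chain = a$chain,
    resno = a$resno, x = a$x, y = a$y, z = a$z,
    element = a$elesy, stringsAsFactors = FALSE
  ), role = role)
}

#' @rdname read_structure
#' @param atoms Data.frame with the columns listed above.
#' @export
structure_model <- function(atoms, role = c("receptor", "ligand_pose")) {
  role <- match.arg(role)
  needed <- c("resid", "resno", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(needed %in% names(atoms)))
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$atom)) atoms$atom <- rep("X", n)
  if (is.null(atoms$chain)) atoms$chain <- rep("A", n)
  if (is.null(atoms$element)) atoms$element <- substr(trimws(atoms$atom), 1, 1)
  atoms$chain[is.na(atoms$chain)] <- "A"
  structure(atoms, class = c("structure_model", "data.frame"), role = role)
}

#' Write a structure model as PDB
#'
#' @param model A `structure_model`.
#' @param path Output PDB path (coordinates at the standard 3-decimal
#'   PDB precision).
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
                   type = "ATOM", resno = model$resno, resid = model$resid,
                   eleno = model$serial, elety = model$atom,
                   chain = model$chain, elesy = model$element)
  invisible(path)
}

#' Receptor docking specification
#'
#' @param name Receptor name (e.g. PXR, CAR, PPARa, PPARg, PPARd, AR,
#'   RORgt).
#' @param pdb_id 4-character PDB code of the prepared structure.
#' @param grid_center Numeric xyz center of the docking grid box
#'   (Angstrom).
#' @param grid_dims Strictly positive box dimensions (Angstrom).
#' @return `receptor_spec` object.
#' @export
receptor_spec <- function(name, pdb_id, grid_center, grid_dims) {
  stopifnot(length(grid_center) == 3, length(grid_dims) == 3)
  if (any(grid_dims <= 0)) abort_config("grid_dims must be strictly positive")
  structure(list(name = name, pdb_id = pdb_id,
                 grid_center = as.numeric(grid_center),
                 grid_dims = as.numeric(grid_dims)),
            class = "receptor_spec")
}

#' Run an external docking engine (adapter)
#'
#' Thin adapter around an AutoDock-Vina-compatible command-line engine: no
#' docking math is implemented here. The engine is invoked with the
#' receptor's grid box, the top-ranked pose and its score are captured,
#' and engine/version/seed provenance is appended to a JSON-lines log.
#' The adapter is exercised in tests only against a stub executable.
#'
#' @param receptor A [receptor_spec()].
#' @param receptor_file Prepared receptor PDBQT path.
#' @param ligand_file Prepared ligand PDBQT path.
#' @param engine_config List with `engine` (executable path), and
#'   optionally `exhaustiveness`, `seed`, `extra_args`,
#'   `provenance_log` (JSON-lines path).
#' @return List with `score` (kcal/mol, top ranked), `pose`
#'   (`structure_model`), and `log` (captured engine output).
#' @export
run_docking_adapter <- function(receptor, receptor_file, ligand_file,
                                engine_config) {
  stopifnot(inherits(receptor, "receptor_spec"), is.list(engine_config))
  engine <- engine_config$engine
  if (is.null(engine) || Sys.which(engine) == "" && !file.exists(engine)) {
    abort_adapter(sprintf(
      "docking engine '%s' not found; set engine_config$engine to an installed AutoDock-Vina-compatible executable",
      if (is.null(engine)) "<unset>" else engine))
  }
  out_file <- tempfile(fileext = ".pdbqt")
  args <- c("--receptor", receptor_file, "--ligand", ligand_file,
            "--center_x", receptor$grid_center[1],
            "--center_y", receptor$grid_center[2],
            "--center_z", receptor$grid_center[3],
            "--size_x", receptor$grid_dims[1],
            "--size_y", receptor$grid_dims[2],
            "--size_z", receptor$grid_dims[3],
            "--out", out_file)
  if (!is.null(engine_config$exhaustiveness)) {
    args <- c(args, "--exhaustiveness", engine_config$exhaustiveness)
  }
  if (!is.null(engine_config$seed)) args <- c(args, "--seed", engine_config$seed)
  args <- c(args, engine_config$extra_args)
  res <- suppressWarnings(system2(engine, args, stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    abort_adapter(sprintf("engine exited with status %d: %s", status,
                          paste(utils::tail(res, 3), collapse = " | ")))
  }
  score <- parse_vina_stdout(res)
  if (is.na(score)) abort_adapter("could not parse a top-ranked score from engine output")
  if (!file.exists(out_file)) abort_adapter("engine produced no output pose file")
  pose <- read_structure(out_file, role = "ligand_pose")
  if (!is.null(engine_config$provenance_log)) {
    version <- tryCatch(
      paste(suppressWarnings(system2(engine, "--version", stdout = TRUE, stderr = TRUE)),
            collapse = " "),
      error = function(e) NA_character_)
    rec <- jsonlite::toJSON(list(
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), engine = engine,
      version = version, receptor = receptor$name, ligand = ligand_file,
      seed = engine_config$seed, score = score), auto_unbox = TRUE)
    cat(rec, "\n", file = engine_config$provenance_log, append = TRUE, sep = "")
  }
  list(score = score, pose = pose, log = res)
}

# first row of the Vina result table: "   1   -7.0   0.000   0.000"
parse_vina_stdout <- function(lines) {
  hit <- grep("^\\s*1\\s+-?[0-9.]+", lines, value = TRUE)
  if (length(hit) == 0L) return(NA_real_)
  as.numeric(strsplit(trimws(hit[1]), "\\s+")[[1]][2])
}
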