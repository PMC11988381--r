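#' Rank binders for one receptor
#'
#' Sorts the receptor's non-missing scores ascending (most negative =
#' strongest = rank 1) and truncates to the top N. Ties are broken by
#' `cas_id` lexicographic order so rankings are deterministic; missing
#' cells are never ranked.
#'
#' @param table A [score_table()].
#' @param receptor Receptor (column) name; unknown names raise a key
#'   error.
#' @param n Number of top binders to keep (default 25).
#' @return A `ranked_list`: data.frame `rank`, `cas_id`, `score` with a
#'   `receptor` attribute.
#' @export
rank_binders <- function(table, receptor, n = 25L) {
  stopifnot(inherits(table, "score_table"))
  if (!receptor %in% colnames(table)) {
    abort_key(sprintf("unknown receptor '%s'", receptor))
  }
  s <- table[, receptor]
  ids <- rownames(table)
  keep <- !is.na(s)
  s <- s[keep]; ids <- ids[keep]
  ord <- order(s, ids)
  k <- min(n, length(ord))
  out <- data.frame(rank = seq_len(k), cas_id = ids[ord][seq_len(k)],
                    score = s[ord][seq_len(k)], stringsAsFactors = FALSE)
  structure(out, class = c("ranked_list", "data.frame"), receptor = receptor)
}

#' Strongest or weakest binder in a receptor column
#'
#' @param table A [score_table()].
#' @param receptor Receptor name.
#' @param which `"strongest"` (minimum score) or `"weakest"` (maximum);
#'   ties broken by `cas_id`.
#' @return List with `cas_id` and `score`; an all-missing column raises
#'   an empty-column error.
#' @export
column_extreme <- function(table, receptor, which = c("strongest", "weakest")) {
  which <- match.arg(which)
  rl <- rank_binders(table, receptor, n = nrow(table))
  if (nrow(rl) == 0L) {
    abort_edc("empty_column_error", sprintf("no scores for receptor '%s'", receptor))
  }
  row <- if (which == "strongest") {
    rl[1L, ]
  } else {
    # weakest: maximum score, cas_id tie-break among the tied maxima
    tied <- rl[rl$score == max(rl$score), , drop = FALSE]
    tied[order(tied$cas_id)[1L], ]
  }
  list(cas_id = row$cas_id, score = row$score)
}

#' Cross-receptor prevalence of top binders
#'
#' Counts, per compound, how many receptors' top-N lists contain it
#' (membership is set-based: the rank within a list does not change the
#' count), and reports the membership map of which receptor listed the
#' compound at which rank.
#'
#' @param ranked Named list of `ranked_list` objects (or plain character
#'   vectors of compound ids, taken as already-ranked lists). Names
#'   default to each list's `receptor` attribute.
#' @return A list with `counts` (data.frame `cas_id`, `count`, sorted by
#'   decreasing count) and `membership` (data.frame `cas_id`, `receptor`,
#'   `rank`).
#' @export
cross_receptor_prevalence <- function(ranked) {
  stopifnot(is.list(ranked), length(ranked) >= 1L)
  if (is.null(names(ranked))) {
    names(ranked) <- vapply(ranked, function(x) {
      r <- attr(x, "receptor")
      if (is.null(r)) NA_character_ else r
    }, character(1))
  }
  membership <- do.call(rbind, lapply(names(ranked), function(nm) {
    x <- ranked[[nm]]
    if (is.character(x)) {
      data.frame(cas_id = unique(x), receptor = nm,
                 rank = seq_along(unique(x)), stringsAsFactors = FALSE)
    } else {
      data.frame(cas_id = x$cas_id, receptor = nm, rank = x$rank,
                 stringsAsFactors = FALSE)
    }
  }))
  counts <- as.data.frame(table(membership$cas_id), stringsAsFactors = FALSE)
  names(counts) <- c("cas_id", "count")
  counts <- counts[order(-counts$count, counts$cas_id), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, membership = membership)
}

#' Read a printed top-N binder table
#'
#' Parses a CSV whose first column is the rank and whose remaining
#' columns hold, per receptor, the compound id at that rank (the layout
#' of published per-class top-25 heat-map tables).
#'
#' @param path CSV path.
#' @return Named list of character vectors (rank order) per receptor.
#' @export
read_top_binder_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  lapply(df[, -1, drop = FALSE], function(col) trimws(col))
}

#' Heat matrix of docking scores
#'
#' Extracts the requested compound x receptor submatrix and assigns each
#' cell a color on a green-to-red ramp running from the weakest (least
#' negative) to the strongest (most negative) score, the convention of
#' the published per-class heat maps. Optionally writes the numeric
#' matrix as CSV and a rendering as PNG.
#'
#' @param table A [score_table()].
#' @param compounds,receptors Row/column selections (default: all).
#' @param csv,png Optional output paths.
#' @param n_colors Ramp resolution (default 100).
#' @return List with `matrix` (numeric) and `colors` (character matrix
#'   of hex colors, `NA` cells uncolored).
#' @export
heatmap_matrix <- function(table, compounds = NULL, receptors = NULL,
                           csv = NULL, png = NULL, n_colors = 100L) {
  stopifnot(inherits(table, "score_table"))
  m <- unclass(table)
  if (!is.null(compounds)) {
    if (!all(compounds %in% rownames(m))) abort_key("unknown compound selection")
    m <- m[compounds, , drop = FALSE]
  }
  if (!is.null(receptors)) {
    if (!all(receptors %in% colnames(m))) abort_key("unknown receptor selection")
    m <- m[, receptors, drop = FALSE]
  }
  ramp <- grDevices::colorRampPalette(c("green", "yellow", "red"))(n_colors)
  rng <- range(m, na.rm = TRUE)
  # weakest (max score) -> green end, strongest (min score) -> red end
  frac <- if (diff(rng) == 0) {
    array(0.5, dim = dim(m))
  } else {
    (rng[2] - m) / diff(rng)
  }
  cols <- array(NA_character_, dim = dim(m), dimnames = dimnames(m))
  cols[!is.na(m)] <- ramp[pmin(n_colors, 1L + floor(frac[!is.na(m)] * (n_colors - 1L)))]
  if (!is.null(csv)) {
    utils::write.csv(data.frame(cas_id = rownames(m), m, check.names = FALSE),
                     csv, row.names = FALSE, na = "#N/A")
  }
  if (!is.null(png)) {
    grDevices::png(png, width = 160 + 60 * ncol(m), height = 120 + 18 * nrow(m))
    op <- graphics::par(mar = c(1, 8, 4, 1))
    on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
    z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), z, col = rev(ramp),
                    axes = FALSE, xlab = "", ylab = "",
                    main = "docking scores (kcal/mol)")
    graphics::axis(3, at = seq_len(ncol(m)), labels = colnames(m), tick = FALSE)
    graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                   las = 2, tick = FALSE, cex.axis = 0.7)
  }
  list(matrix = m, colors = cols)
}
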