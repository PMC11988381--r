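#' Chain-length vs affinity trend curve
#'
#' Groups compounds by fluorinated chain length, averages their
#' non-missing docking scores for one receptor, and fits ordinary least
#' squares of the per-length mean score on chain length (the trend is
#' fitted over per-length averages, as the affinity/chain-length analyses
#' plot average binding affinity; `over = "raw"` instead regresses on the
#' individual compound scores).
#'
#' @param records Annotated compound data.frame with
#'   `fluorinated_chain_length` and `cas_id`.
#' @param table A [score_table()] whose rownames match `records$cas_id`.
#' @param receptor Receptor (column) name.
#' @param over `"means"` (default) or `"raw"`.
#' @param min_length Chain lengths below this are excluded (default 1;
#'   length-0 compounds carry no fluorinated chain).
#' @return A `trend_curve`: list with `points` (data.frame `length`,
#'   `mean_score`, `n`), `slope`, `intercept`, `r_squared`, `receptor`.
#'   Fewer than 2 distinct lengths raise an insufficient-data error.
#' @export
chain_length_affinity_curve <- function(records, table, receptor,
                                        over = c("means", "raw"),
                                        min_length = 1L) {
  stopifnot(inherits(table, "score_table"),
            "fluorinated_chain_length" %in% names(records))
  over <- match.arg(over)
  if (!receptor %in% colnames(table)) {
    abort_key(sprintf("receptor '%s' not in score table", receptor))
  }
  idx <- match(records$cas_id, rownames(table))
  score <- ifelse(is.na(idx), NA_real_, table[idx, receptor])
  keep <- !is.na(score) & records$fluorinated_chain_length >= min_length
  L <- records$fluorinated_chain_length[keep]
  s <- score[keep]
  if (length(unique(L)) < 2L) {
    abort_insufficient_data("need scores at >= 2 distinct chain lengths")
  }
  mean_by_len <- tapply(s, L, mean)
  pts <- data.frame(length = as.integer(names(mean_by_len)),
                    mean_score = as.numeric(mean_by_len),
                    n = as.integer(table(L)))
  fit <- if (over == "means") {
    stats::lm(mean_score ~ length, data = pts)
  } else {
    stats::lm(s ~ L)
  }
  sm <- suppressWarnings(summary(fit))  # noiseless input fits exactly
  structure(list(points = pts,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 receptor = receptor, over = over),
            class = "trend_curve")
}

#' @export
print.trend_curve <- function(x, ...) {
  cat(sprintf("<trend_curve> %s: score = %.3f %+.3f * L, R^2 = %.3f (%d lengths)\n",
              x$receptor, x$intercept, x$slope, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Categorize chain lengths into short and long
#'
#' Short chains have 1 to 6 fluorinated carbons, long chains 7 and above;
#' compounds without a fluorinated chain (length 0) belong to neither and
#' are reported separately as `uncategorized`.
#'
#' @param records Data.frame with `fluorinated_chain_length`.
#' @param short_max Largest chain length still counted as short
#'   (default 6).
#' @return Factor (`short`, `long`, `uncategorized`) aligned to
#'   `records`.
#' @export
categorize_chain_lengths <- function(records, short_max = 6L) {
  L <- records$fluorinated_chain_length
  out <- ifelse(L >= 1L & L <= short_max, "short",
                ifelse(L >= short_max + 1L, "long", "uncategorized"))
  factor(out, levels = c("short", "long", "uncategorized"))
}

#' Average docking score per functional group and receptor
#'
#' For each (group, receptor) pair, the mean of non-missing scores over
#' compounds whose functional-group set contains the group; a compound
#' with k groups contributes to k rows.
#'
#' @param records Annotated compound data.frame with `functional_groups`
#'   (semicolon-joined) and `cas_id`.
#' @param table A [score_table()].
#' @return Data.frame with columns `group`, `receptor`, `mean_score`,
#'   `n`; groups with zero scored members are absent.
#' @export
functional_group_affinity_table <- function(records, table) {
  stopifnot(inherits(table, "score_table"),
            "functional_groups" %in% names(records))
  groups <- strsplit(records$functional_groups, ";", fixed = TRUE)
  idx <- match(records$cas_id, rownames(table))
  rows <- list()
  all_groups <- sort(unique(unlist(groups)))
  all_groups <- all_groups[nzchar(all_groups)]
  for (g in all_groups) {
    members <- which(vapply(groups, function(x) g %in% x, logical(1)))
    for (rc in colnames(table)) {
      s <- table[idx[members], rc]
      s <- s[!is.na(s)]
      if (length(s)) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, receptor = rc, mean_score = mean(s), n = length(s),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(), receptor = character(),
                      mean_score = numeric(), n = integer())
  }
  rownames(out) <- NULL
  out
}

#' Hydrophobicity summary of top binders
#'
#' Takes the N strongest (most negative) binders for a receptor and
#' reports their predicted logP range and how many exceed the
#' bioaccumulation threshold (logP > 5). Ties in the top-N selection are
#' broken by `cas_id` so reports are deterministic.
#'
#' @param records Annotated compound data.frame with `logp` and `cas_id`.
#' @param table A [score_table()].
#' @param receptor Receptor name.
#' @param n_top Number of top binders (default 15).
#' @param logp_threshold Bioaccumulation flag threshold (default 5).
#' @return List with `receptor`, `n_top`, `logp_min`, `logp_max`,
#'   `n_bioaccumulative`, and the selected `compounds` data.frame.
#' @export
hydrophobicity_summary <- function(records, table, receptor, n_top = 15L,
                                   logp_threshold = 5) {
  stopifnot(inherits(table, "score_table"), "logp" %in% names(records))
  ranked <- rank_binders(table, receptor, n = nrow(table))
  ranked <- ranked[ranked$cas_id %in% records$cas_id, , drop = FALSE]
  if (nrow(ranked) < n_top) {
    abort_insufficient_data(sprintf(
      "need >= %d scored compounds with descriptors for %s (have %d)",
      n_top, receptor, nrow(ranked)))
  }
  top <- ranked[seq_len(n_top), , drop = FALSE]
  top$logp <- records$logp[match(top$cas_id, records$cas_id)]
  list(receptor = receptor, n_top = n_top,
       logp_min = min(top$logp), logp_max = max(top$logp),
       n_bioaccumulative = sum(top$logp > logp_threshold),
       compounds = top)
}
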