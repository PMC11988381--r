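#' Reference-ligand score sets
#'
#' Per-receptor docking scores of reference ligands (endogenous and
#' synthetic) whose mean anchors the strong/moderate/weak thresholds.
#'
#' @param scores Data.frame with columns `receptor`, `ligand_id`, `score`
#'   (kcal/mol).
#' @return `reference_set` object; per-receptor means are available via
#'   [reference_means()].
#' @export
reference_set <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("receptor", "score") %in% names(scores)))
  if (is.null(scores$ligand_id)) scores$ligand_id <- paste0("ref", seq_len(nrow(scores)))
  if (any(!is.finite(scores$score))) abort_format("reference scores must be finite")
  if (nrow(scores) == 0L) abort_format("reference set is empty")
  structure(scores, class = c("reference_set", "data.frame"))
}

#' @rdname reference_set
#' @param path CSV with columns `receptor`, `ligand_id`, `score`.
#' @export
read_reference_sets <- function(path) {
  reference_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname reference_set
#' @param refs A `reference_set`.
#' @return Named numeric vector of per-receptor mean scores.
#' @export
reference_means <- function(refs) {
  stopifnot(inherits(refs, "reference_set"))
  tapply(refs$score, refs$receptor, mean)
}

#' Classify docking scores into binding-strength classes
#'
#' Stratifies scores against the mean docking score `m` of the receptor's
#' reference ligands: scores exceeding the mean (strictly more negative
#' than `m`) are strong binders; scores within a margin of 10% below the
#' mean (`m <= score <= 0.9 * m`, boundaries inclusive) are moderate; and
#' scores more than 10% below the mean (`score > 0.9 * m`) are weak. The
#' 10% margin is multiplicative on the (negative) mean; with `m = -8.0`
#' the moderate band is `[-8.0, -7.2]`.
#'
#' @param score Numeric vector of docking scores (kcal/mol).
#' @param m Reference mean (kcal/mol); must be negative, otherwise the
#'   thresholds are undefined and a domain error is raised.
#' @param margin Fraction of `|m|` defining the moderate band (default
#'   0.10).
#' @return Ordered factor with levels `weak < moderate < strong`; `NA`
#'   scores stay `NA`.
#' @examples
#' classify_binding(c(-9.1, -8.0, -7.5, -7.0), m = -8.0)
#' @export
classify_binding <- function(score, m, margin = 0.10) {
  if (!is.finite(m) || m >= 0) {
    abort_domain("reference mean must be finite and negative")
  }
  if (any(!is.finite(score) & !is.na(score))) {
    abort_domain("scores must be finite or NA")
  }
  lo <- (1 - margin) * m   # weak threshold, e.g. 0.9 * m
  cls <- ifelse(is.na(score), NA_character_,
                ifelse(score < m, "strong",
                       ifelse(score <= lo, "moderate", "weak")))
  factor(cls, levels = c("weak", "moderate", "strong"), ordered = TRUE)
}

#' Per-receptor binding-class fractions
#'
#' Classifies every non-missing cell of a score table against its
#' receptor's reference mean and summarizes the percentage of strong,
#' moderate and weak binders per receptor (percentages over classified
#' compounds sum to 100).
#'
#' @param table A [score_table()].
#' @param refs A [reference_set()] (or named numeric vector of reference
#'   means) covering every receptor in the table; a missing receptor
#'   raises a key error.
#' @param margin Moderate-band margin passed to [classify_binding()].
#' @param denominator `"scored"` (default) computes percentages over
#'   non-missing cells; `"all"` divides by the full compound count so
#'   that undocked compounds dilute all three classes.
#' @return Data.frame with columns `receptor`, `strong_pct`,
#'   `moderate_pct`, `weak_pct`, `n` (classified count).
#' @export
summarize_class_fractions <- function(table, refs, margin = 0.10,
                                      denominator = c("scored", "all")) {
  stopifnot(inherits(table, "score_table"))
  denominator <- match.arg(denominator)
  means <- if (inherits(refs, "reference_set")) reference_means(refs) else refs
  missing_refs <- setdiff(colnames(table), names(means))
  if (length(missing_refs)) {
    abort_key(sprintf("no reference scores for receptor(s): %s",
                      paste(missing_refs, collapse = ", ")))
  }
  rows <- lapply(colnames(table), function(rc) {
    cls <- classify_binding(table[, rc], means[[rc]], margin = margin)
    n_scored <- sum(!is.na(cls))
    denom <- if (denominator == "scored") n_scored else nrow(table)
    counts <- table(cls)
    pct <- if (denom > 0) 100 * counts / denom else counts * NA_real_
    data.frame(receptor = rc,
               strong_pct = as.numeric(pct[["strong"]]),
               moderate_pct = as.numeric(pct[["moderate"]]),
               weak_pct = as.numeric(pct[["weak"]]),
               n = n_scored, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
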