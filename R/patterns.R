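## Editing-pattern summaries across conditions and the Meet/Min
## (Simpson) overlap index.

#' Meet/Min (Simpson) overlap index of two sets
#'
#' `|A ∩ B| / min(|A|, |B|)`: 1 when one set contains the other, 0 when
#' disjoint. Symmetric and invariant to element relabeling; duplicated
#' elements count once.
#'
#' @param a,b nonempty vectors treated as sets.
#' @return overlap index in \[0,1\].
#' @examples
#' meet_min(c("a", "b", "c", "d"), c("c", "d", "e"))  # 2/3
#' @export
meet_min <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (!length(a) || !length(b)) stop("meet_min is undefined for empty sets")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pairwise Meet/Min matrix over a list of sets
#'
#' Used to compare conditions by their DES sets, DES-bearing gene sets,
#' or enriched-term sets.
#'
#' @param sets named list of nonempty vectors.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
meet_min_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  n <- length(sets)
  m <- matrix(1, n, n, dimnames = list(names(sets), names(sets)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- meet_min(sets[[i]], sets[[j]])
      }
    }
  }
  m
}

#' Summarize over-/under-editing patterns across conditions
#'
#' Per condition: the number and proportion of over-editing DESs (higher
#' editing in resistant samples) and the log2 fold change of ADAR-like
#' expression between resistant and sensitive samples. Across conditions,
#' the proportion of over-editing sites is regressed on the ADAR log2FC
#' (ordinary least squares) to ask how much of the pattern ADAR levels
#' explain. Conditions without any DES stay in the summary with an
#' undefined proportion and are excluded from the regression.
#'
#' @param des_tables named list (one entry per condition) of DES record
#'   data.frames as returned in `call_des()$des`.
#' @param adar named numeric vector of per-sample ADAR-like expression.
#' @param conds named list of [condition()]s, names matching `des_tables`.
#' @return list with `summary` (data.frame `condition`, `n_over`,
#'   `n_under`, `prop_over`, `adar_log2fc`) and `regression` (an
#'   `editing_regression` of prop_over on log2FC, or `NULL` with fewer
#'   than 3 usable conditions).
#' @export
summarize_patterns <- function(des_tables, adar, conds) {
  stopifnot(identical(sort(names(des_tables)), sort(names(conds))))
  rows <- lapply(names(des_tables), function(k) {
    des <- des_tables[[k]]
    cond <- conds[[k]]
    n_over <- sum(des$direction == "over")
    n_under <- sum(des$direction == "under")
    m_r <- mean(adar[intersect(cond$resistant, names(adar))])
    m_s <- mean(adar[intersect(cond$sensitive, names(adar))])
    if (!is.finite(m_r) || !is.finite(m_s) || m_s == 0) {
      stop("cannot compute ADAR log2FC for condition ", k)
    }
    data.frame(condition = k, n_over = n_over, n_under = n_under,
               prop_over = if (n_over + n_under > 0L)
                 n_over / (n_over + n_under) else NA_real_,
               adar_log2fc = log2(m_r / m_s), stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  usable <- !is.na(summary$prop_over)
  regression <- NULL
  if (sum(usable) >= 3L &&
      stats::var(summary$adar_log2fc[usable]) > 0) {
    regression <- regress_oel_on_expression(
      stats::setNames(summary$prop_over[usable], summary$condition[usable]),
      stats::setNames(summary$adar_log2fc[usable], summary$condition[usable]))
  }
  list(summary = summary, regression = regression)
}
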