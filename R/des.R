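## Differential editing-site (DES) calling.

## Two-sided Wilcoxon rank-sum p-value. Exact distribution when both
## groups are <= exact_limit and the pooled data are tie-free, normal
## approximation with continuity and tie correction otherwise (the
## default of the statistical environment the analysis convention comes
## from). p-values near 0.05 can flip between modes, so the mode is
## overridable.
wilcox_rank_p <- function(x, y, exact = NULL, exact_limit = 25L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  if (is.null(exact)) {
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- length(x) <= exact_limit && length(y) <= exact_limit && !ties
  }
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
}

#' Select informative sites for a condition
#'
#' An informative site has no missing values in at least `min_per_group`
#' resistant and `min_per_group` sensitive samples, so a two-group test
#' is meaningful.
#'
#' @param profile editing matrix (sites x samples, `NA` = missing).
#' @param cond a [condition()]; its samples must be profile columns.
#' @param min_per_group minimum non-missing values per group (default 3).
#' @return character vector of informative site ids.
#' @export
find_informative_sites <- function(profile, cond, min_per_group = 3L) {
  res <- cond$resistant
  sen <- cond$sensitive
  missing_cols <- setdiff(c(res, sen), colnames(profile))
  if (length(missing_cols)) {
    stop("condition samples absent from profile: ",
         paste(missing_cols, collapse = ", "))
  }
  n_res <- rowSums(!is.na(profile[, res, drop = FALSE]))
  n_sen <- rowSums(!is.na(profile[, sen, drop = FALSE]))
  rownames(profile)[n_res >= min_per_group & n_sen >= min_per_group]
}

#' Call differential editing sites between resistant and sensitive samples
#'
#' For every informative site, a two-sided Wilcoxon rank-sum test of the
#' editing levels of resistant vs sensitive samples, plus the difference
#' of group means `diff = mean(resistant) - mean(sensitive)`. A DES is a
#' site with `p < alpha` and `|diff| >= min_diff`; its direction is
#' *over* (higher editing in resistant) when `diff > 0` and *under*
#' otherwise. Raw p-values gate the calls; a Benjamini–Hochberg column is
#' included for transparency but not used for filtering.
#'
#' @param profile editing matrix.
#' @param cond a [condition()].
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param min_diff minimum absolute mean difference (default 0.05, i.e.
#'   5 percentage points of editing).
#' @param min_per_group informative-site threshold (default 3).
#' @param exact Wilcoxon mode override (see [compare_oel_groups()]).
#' @return list with `des` (DES records: `site_id`, `p`, `diff`,
#'   `direction`, `n_res`, `n_sen`, `bh_q`) and `tests` (the full
#'   per-site table over all informative sites, e.g. for volcano plots).
#' @export
call_des <- function(profile, cond, alpha = 0.05, min_diff = 0.05,
                     min_per_group = 3L, exact = NULL) {
  sites <- find_informative_sites(profile, cond, min_per_group)
  res <- profile[sites, cond$resistant, drop = FALSE]
  sen <- profile[sites, cond$sensitive, drop = FALSE]
  n <- length(sites)
  p <- numeric(n)
  dif <- numeric(n)
  for (i in seq_len(n)) {
    x <- res[i, ][!is.na(res[i, ])]
    y <- sen[i, ][!is.na(sen[i, ])]
    p[i] <- wilcox_rank_p(x, y, exact = exact)
    dif[i] <- mean(x) - mean(y)
  }
  tests <- data.frame(site_id = sites, p = p, diff = dif,
                      direction = ifelse(dif > 0, "over", "under"),
                      n_res = rowSums(!is.na(res)),
                      n_sen = rowSums(!is.na(sen)),
                      bh_q = stats::p.adjust(p, method = "BH"),
                      stringsAsFactors = FALSE, row.names = NULL)
  keep <- !is.na(tests$p) & tests$p < alpha & abs(tests$diff) >= min_diff
  list(des = tests[keep, , drop = FALSE], tests = tests)
}

#' Rank-based differential expression between condition groups
#'
#' Per feature: two-sided Wilcoxon rank-sum p-value and the log2 fold
#' change of group means (resistant over sensitive). Used for ADAR and
#' miRNA differential expression inside the pipeline's filters. A
#' feature constant across both groups gets p = 1 by convention. With
#' `pseudocount = 0` (default) a zero denominator mean is an error,
#' because a silently added pseudocount can change the sign of the fold
#' change near zero.
#'
#' @param expr numeric matrix, features x samples.
#' @param cond a [condition()] whose samples are columns of `expr`.
#' @param pseudocount added to both group means before the ratio.
#' @param exact Wilcoxon mode override.
#' @return data.frame `feature_id`, `p`, `log2fc`, `mean_res`, `mean_sen`.
#' @export
rank_de <- function(expr, cond, pseudocount = 0, exact = NULL) {
  res <- expr[, intersect(cond$resistant, colnames(expr)), drop = FALSE]
  sen <- expr[, intersect(cond$sensitive, colnames(expr)), drop = FALSE]
  if (ncol(res) < 3L || ncol(sen) < 3L) {
    stop("need at least 3 samples per group for differential expression")
  }
  n <- nrow(expr)
  p <- numeric(n)
  fc <- numeric(n)
  m_r <- rowMeans(res)
  m_s <- rowMeans(sen)
  for (i in seq_len(n)) {
    x <- res[i, ]
    y <- sen[i, ]
    if (length(unique(c(x, y))) == 1L) {
      p[i] <- 1
    } else {
      p[i] <- wilcox_rank_p(x, y, exact = exact)
    }
  }
  denom <- m_s + pseudocount
  if (any(denom == 0)) {
    stop("zero mean sensitive expression for feature ",
         rownames(expr)[which(denom == 0)[1L]],
         "; set a pseudocount explicitly")
  }
  fc <- log2((m_r + pseudocount) / denom)
  data.frame(feature_id = rownames(expr), p = p, log2fc = unname(fc),
             mean_res = unname(m_r), mean_sen = unname(m_s),
             stringsAsFactors = FALSE, row.names = NULL)
}
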