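## Overall editing level (OEL) summaries and their regression on
## ADAR-like expression.

#' Compute per-sample overall editing levels
#'
#' The OEL of a sample is the mean editing level over all informative
#' sites with a non-missing value in that sample. Samples without a
#' single non-missing value are omitted (with a warning), not reported as
#' zero. With an annotation, per-region OELs (mean over that region's
#' sites) are computed as well.
#'
#' @param profile numeric matrix, sites x samples, `NA` = missing.
#' @param annotation optional annotation data.frame covering the sites
#'   (columns `site_id`, `region`).
#' @return list with `oel` (named numeric vector) and, when annotation is
#'   given, `by_region` (data.frame `sample`, `region`, `oel`).
#' @export
compute_oel <- function(profile, annotation = NULL) {
  stopifnot(is.matrix(profile), nrow(profile) > 0L, ncol(profile) > 0L)
  n_obs <- colSums(!is.na(profile))
  if (any(n_obs == 0L)) {
    warning("sample(s) with no non-missing editing values omitted: ",
            paste(colnames(profile)[n_obs == 0L], collapse = ", "))
  }
  keep <- n_obs > 0L
  oel <- colMeans(profile[, keep, drop = FALSE], na.rm = TRUE)
  out <- list(oel = oel)
  if (!is.null(annotation)) {
    ann <- annotation[match(rownames(profile), annotation$site_id), ]
    if (anyNA(ann$region)) stop("annotation does not cover all profile sites")
    rows <- list()
    for (rg in unique(ann$region)) {
      sub <- profile[ann$region == rg, keep, drop = FALSE]
      m <- colMeans(sub, na.rm = TRUE)
      rows[[rg]] <- data.frame(sample = names(m), region = rg,
                               oel = unname(m), stringsAsFactors = FALSE)
    }
    out$by_region <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  out
}

#' Regress overall editing levels on expression of an editing enzyme
#'
#' Ordinary least squares of OEL on an ADAR-like expression vector,
#' reporting the coefficient of determination R^2 and the F-test p-value
#' — the statistic used to quantify how much OEL variation an ADAR
#' enzyme's expression explains.
#'
#' @param oel named numeric vector of per-sample OELs (or the list from
#'   [compute_oel()]).
#' @param expression named numeric vector of per-sample expression.
#' @param log_transform log2(x+1)-transform the expression first
#'   (default FALSE; FPKM-scale values are used as provided).
#' @return list of class `editing_regression` with `slope`, `intercept`,
#'   `r2`, `p`, `n`.
#' @export
regress_oel_on_expression <- function(oel, expression, log_transform = FALSE) {
  if (is.list(oel)) oel <- oel$oel
  common <- intersect(names(oel), names(expression))
  if (length(common) < 3L) stop("need at least 3 paired samples")
  y <- oel[common]
  x <- expression[common]
  if (log_transform) x <- log2(x + 1)
  if (stats::var(x) == 0) stop("constant regressor: expression has no variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fs <- sm$fstatistic
  p <- unname(stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = unname(sm$r.squared), p = p, n = length(common)),
            class = "editing_regression")
}

#' @export
print.editing_regression <- function(x, ...) {
  cat(sprintf("<linear fit> n = %d, R^2 = %.4f, p = %.3g\n", x$n, x$r2, x$p))
  invisible(x)
}

#' Compare overall editing levels between the groups of a condition
#'
#' Two-sided Wilcoxon rank-sum test of the OELs of resistant vs sensitive
#' samples.
#'
#' @param oel named numeric OEL vector (or [compute_oel()] output).
#' @param cond a [condition()].
#' @param exact passed to the Wilcoxon p helper; `NULL` (default) selects
#'   the exact distribution when both groups are small and tie-free.
#' @return two-sided p-value.
#' @export
compare_oel_groups <- function(oel, cond, exact = NULL) {
  if (is.list(oel)) oel <- oel$oel
  x <- oel[intersect(cond$resistant, names(oel))]
  y <- oel[intersect(cond$sensitive, names(oel))]
  if (!length(x) || !length(y)) stop("a group has no samples with an OEL")
  wilcox_rank_p(x, y, exact = exact)
}
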