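## Survival association of editing sites: median binarization,
## univariate Cox regression, log-rank gating, and consistency of the
## prognostic direction with the resistance editing direction.

#' Binarize editing levels at the cohort median
#'
#' Each site's editing levels are split into an over-editing group
#' (value strictly above the median of all non-missing samples) and an
#' under-editing group (value at or below the median — ties at the
#' median go to the under-editing group, so the over-editing group
#' strictly exceeds it). Missing values are excluded. A constant vector
#' admits no split and is an error.
#'
#' @param levels named numeric vector of per-sample editing levels.
#' @return named factor with levels `under`, `over`.
#' @export
binarize_by_median <- function(levels) {
  x <- levels[!is.na(levels)]
  if (length(x) < 2L) stop("need at least 2 non-missing values")
  if (length(unique(x)) == 1L) stop("all editing values identical; no median split")
  med <- stats::median(x)
  g <- factor(ifelse(x > med, "over", "under"), levels = c("under", "over"))
  names(g) <- names(x)
  if (!all(table(g) > 0L)) stop("median split left a group empty")
  g
}

#' Univariate Cox regression of survival on an editing group
#'
#' Fits a univariate Cox proportional hazards model of overall survival
#' on the over- vs under-editing indicator (Efron tie handling) and
#' computes the log-rank test between the two groups. The hazard ratio
#' is for the over-editing group relative to the under-editing group; a
#' site is prognosis-related when the log-rank p-value is below 0.05.
#'
#' @param groups named factor from [binarize_by_median()] (levels
#'   `under`, `over`).
#' @param surv survival data.frame with columns `sample`, `time`,
#'   `event`.
#' @return list with `hr`, `cox_p` (Wald), `logrank_p`, `n_over`,
#'   `n_under`, `n_events`, `separation` (flag: monotone likelihood /
#'   complete separation warning from the fitter).
#' @export
cox_univariate <- function(groups, surv) {
  common <- intersect(names(groups), surv$sample)
  if (length(common) < 2L) stop("fewer than 2 samples with both group and survival")
  g <- droplevels(factor(groups[common], levels = c("under", "over")))
  if (nlevels(g) < 2L) stop("a group is empty after matching to survival data")
  d <- surv[match(common, surv$sample), ]
  if (sum(d$event) < 1L) stop("no events in the survival data")
  over <- as.integer(g == "over")
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(d$time, d$event) ~ over, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)
  hr <- unname(sm$coefficients[1L, "exp(coef)"])
  cox_p <- unname(sm$coefficients[1L, "Pr(>|z|)"])
  sd_ <- survival::survdiff(survival::Surv(d$time, d$event) ~ over)
  logrank_p <- stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  if (separation) {
    warning("possible complete separation; hazard ratio reported as fitted")
  }
  list(hr = hr, cox_p = cox_p, logrank_p = logrank_p,
       n_over = sum(over == 1L), n_under = sum(over == 0L),
       n_events = sum(d$event), separation = separation)
}

#' Survival screen over differential editing sites
#'
#' Applies [binarize_by_median()] + [cox_univariate()] to every site of
#' an editing matrix (typically restricted to DESs). Sites whose levels
#' cannot be split (constant) are skipped with a message.
#'
#' @param profile editing matrix, sites x samples.
#' @param surv survival data.frame.
#' @param sites site ids to test (default: all rows).
#' @return data.frame `site_id`, `hr`, `cox_p`, `logrank_p`, `n_over`,
#'   `n_under`, `prognosis_related` (log-rank p < 0.05).
#' @export
survival_screen <- function(profile, surv, sites = rownames(profile)) {
  rows <- list()
  for (s in sites) {
    lv <- profile[s, ]
    res <- tryCatch({
      g <- binarize_by_median(lv)
      cox_univariate(g, surv)
    }, error = function(e) {
      message("site ", s, " skipped in survival screen: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = s, hr = res$hr, cox_p = res$cox_p,
      logrank_p = res$logrank_p, n_over = res$n_over,
      n_under = res$n_under, prognosis_related = res$logrank_p < 0.05,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(site_id = character(), hr = numeric(),
                      cox_p = numeric(), logrank_p = numeric(),
                      n_over = integer(), n_under = integer(),
                      prognosis_related = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Consistency of prognostic direction with resistance editing direction
#'
#' A site is *consistent* when its risk direction matches its resistance
#' direction: over-edited in resistant samples and a risk factor
#' (HR > 1), or under-edited in resistant samples and protective when
#' over-edited (HR < 1) — i.e. the editing pattern of poor-prognosis
#' patients matches that of therapy-resistant patients. Sites with HR
#' exactly 1 are indeterminate and excluded from the proportion, which
#' is computed over prognosis-related sites (log-rank p < 0.05).
#'
#' @param surv_results data.frame from [survival_screen()].
#' @param des_records DES data.frame with `site_id` and `direction`.
#' @return list with `per_site` (joined data.frame plus a `consistent`
#'   flag) and `proportion` (consistent fraction among prognosis-related
#'   sites; `NA` when none).
#' @export
consistency_with_resistance <- function(surv_results, des_records) {
  common <- intersect(surv_results$site_id, des_records$site_id)
  sr <- surv_results[match(common, surv_results$site_id), , drop = FALSE]
  dir <- des_records$direction[match(common, des_records$site_id)]
  consistent <- ifelse(sr$hr == 1, NA,
                       (dir == "over" & sr$hr > 1) |
                       (dir == "under" & sr$hr < 1))
  per_site <- cbind(sr, direction = dir, consistent = consistent,
                    stringsAsFactors = FALSE)
  rownames(per_site) <- NULL
  rel <- per_site$prognosis_related & !is.na(per_site$consistent)
  proportion <- if (any(rel)) mean(per_site$consistent[rel]) else NA_real_
  list(per_site = per_site, proportion = proportion)
}
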