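## Expression-level screening of seed-site rewiring events into
## (DES, miRNA, gene) triplets.

pearson_cor <- function(x, y) {
  if (length(x) < 3L || stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Screen rewiring events into editing-dependent regulation triplets
#'
#' Applies the three expression-level criteria to each seed-site
#' gain/loss event, for the condition's resistant and sensitive samples.
#' For a DES over-edited in resistant samples:
#'
#' 1. **correlation** — a gain requires a significantly negative
#'    miRNA–gene Pearson correlation (r < 0, two-sided p < `alpha`) in
#'    resistant samples and not in sensitive samples; a loss requires the
#'    reverse group pattern;
#' 2. **fold-change direction** — the gene's mean expression is lower in
#'    resistant samples for a gain (log2FC < 0) and higher for a loss
#'    (log2FC > 0); no magnitude threshold is applied;
#' 3. **miRNA not differentially expressed** — the miRNA's rank-test
#'    p-value is at or above `alpha`, so the correlation is not driven by
#'    a miRNA abundance shift.
#'
#' For a DES under-edited in resistant samples the edited form is the
#' *sensitive*-group form, so the resistant/sensitive roles in criteria
#' 1–2 are swapped. This extension of the over-edited rule is controlled
#' by `under_edited_rule` (default on) and such triplets are labeled
#' `extended_rule = TRUE`.
#'
#' @param events rewiring events ([classify_rewiring()] output, columns
#'   `site_id`, `gene_id`, `mirna_id`, `class`).
#' @param des_records DES data.frame with `site_id` and `direction`.
#' @param gene_expr,mirna_expr expression matrices (features x samples).
#' @param cond a [condition()].
#' @param alpha significance threshold (default 0.05).
#' @param under_edited_rule apply the swapped rule to under-edited DESs
#'   (default TRUE; otherwise they are dropped from the screen).
#' @param pseudocount for the gene fold change (see [rank_de()]).
#' @return list with `triplets` (events passing all three criteria, with
#'   `r_res`, `p_res`, `r_sen`, `p_sen`, `gene_log2fc`, `mirna_de_p`,
#'   criterion flags and `extended_rule`) and `candidates` (all screened
#'   events with the same columns).
#' @export
screen_triplets <- function(events, des_records, gene_expr, mirna_expr,
                            cond, alpha = 0.05, under_edited_rule = TRUE,
                            pseudocount = 0) {
  empty <- data.frame(site_id = character(), gene_id = character(),
                      mirna_id = character(), class = character(),
                      direction = character(), r_res = numeric(),
                      p_res = numeric(), r_sen = numeric(),
                      p_sen = numeric(), gene_log2fc = numeric(),
                      mirna_de_p = numeric(), pass_correlation = logical(),
                      pass_fc = logical(), pass_mirna_not_de = logical(),
                      extended_rule = logical(), stringsAsFactors = FALSE)
  if (!nrow(events)) return(list(triplets = empty, candidates = empty))
  res_s <- intersect(cond$resistant, intersect(colnames(gene_expr),
                                               colnames(mirna_expr)))
  sen_s <- intersect(cond$sensitive, intersect(colnames(gene_expr),
                                               colnames(mirna_expr)))
  mirna_de <- rank_de(mirna_expr, cond, pseudocount = pseudocount)
  rows <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    dir <- des_records$direction[match(ev$site_id, des_records$site_id)]
    if (is.na(dir)) {
      stop("rewiring event site ", ev$site_id, " absent from DES records")
    }
    if (dir == "under" && !under_edited_rule) next
    if (!(ev$gene_id %in% rownames(gene_expr)) ||
        !(ev$mirna_id %in% rownames(mirna_expr))) {
      warning("expression missing for event ", ev$site_id, "/", ev$mirna_id,
              "/", ev$gene_id, "; skipped")
      next
    }
    if (length(res_s) < 3L || length(sen_s) < 3L) {
      warning("fewer than 3 expression pairs in a group; event ",
              ev$site_id, " skipped")
      next
    }
    c_res <- pearson_cor(mirna_expr[ev$mirna_id, res_s],
                         gene_expr[ev$gene_id, res_s])
    c_sen <- pearson_cor(mirna_expr[ev$mirna_id, sen_s],
                         gene_expr[ev$gene_id, sen_s])
    m_r <- mean(gene_expr[ev$gene_id, res_s]) + pseudocount
    m_s <- mean(gene_expr[ev$gene_id, sen_s]) + pseudocount
    if (m_s == 0) stop("zero mean sensitive expression for gene ", ev$gene_id)
    log2fc <- log2(m_r / m_s)
    de_p <- mirna_de$p[match(ev$mirna_id, mirna_de$feature_id)]

    sig_neg_res <- isTRUE(c_res$r < 0 && c_res$p < alpha)
    sig_neg_sen <- isTRUE(c_sen$r < 0 && c_sen$p < alpha)
    ## designate the group in which the *edited* form (hence the rewired
    ## interaction state) dominates: resistant for over-edited DESs,
    ## sensitive for under-edited ones.
    if (dir == "over") {
      if (ev$class == "gain") {
        pass_cor <- sig_neg_res && !sig_neg_sen
        pass_fc <- log2fc < 0
      } else {
        pass_cor <- sig_neg_sen && !sig_neg_res
        pass_fc <- log2fc > 0
      }
    } else {
      if (ev$class == "gain") {
        pass_cor <- sig_neg_sen && !sig_neg_res
        pass_fc <- log2fc > 0
      } else {
        pass_cor <- sig_neg_res && !sig_neg_sen
        pass_fc <- log2fc < 0
      }
    }
    pass_de <- isTRUE(de_p >= alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = ev$site_id, gene_id = ev$gene_id, mirna_id = ev$mirna_id,
      class = ev$class, direction = dir, r_res = c_res$r, p_res = c_res$p,
      r_sen = c_sen$r, p_sen = c_sen$p, gene_log2fc = log2fc,
      mirna_de_p = de_p, pass_correlation = pass_cor, pass_fc = pass_fc,
      pass_mirna_not_de = pass_de, extended_rule = dir == "under",
      stringsAsFactors = FALSE)
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else empty
  keep <- candidates$pass_correlation & candidates$pass_fc &
    candidates$pass_mirna_not_de
  list(triplets = candidates[keep, , drop = FALSE], candidates = candidates)
}
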