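## Hypergeometric over-representation of DESs in transcribed regions and
## within genes (gene-specific changing background).

## upper-tail hypergeometric P(X >= k) drawing n from N with K successes
hyper_upper <- function(k, K, n, N) {
  stopifnot(k >= 0L, K <= N, n <= N, k <= min(K, n))
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Region enrichment of differential editing sites
#'
#' For each transcribed region, tests whether the DESs over-represent the
#' region relative to the informative-site background: with N informative
#' sites of which K lie in the region, and n DESs of which k lie in the
#' region, the p-value is the upper hypergeometric tail P(X >= k).
#' Enrichment only is tested (one-sided); P(X >= 0) = 1 by convention.
#'
#' @param des_sites character vector of DES site ids (subset of
#'   `informative_sites`).
#' @param informative_sites character vector of informative site ids.
#' @param annotation annotation data.frame covering all sites.
#' @return data.frame `region`, `k`, `K`, `n`, `N`, `p`, `significant`
#'   (p < 0.05), one row per region present among the informative sites.
#' @export
region_enrichment <- function(des_sites, informative_sites, annotation) {
  des_sites <- unique(des_sites)
  informative_sites <- unique(informative_sites)
  if (!all(des_sites %in% informative_sites)) {
    stop("DES sites must be a subset of the informative sites")
  }
  reg <- annotation$region[match(informative_sites, annotation$site_id)]
  if (anyNA(reg)) {
    stop("unannotated site: ",
         informative_sites[which(is.na(reg))[1L]])
  }
  reg_des <- annotation$region[match(des_sites, annotation$site_id)]
  N <- length(informative_sites)
  n <- length(des_sites)
  rows <- lapply(sort(unique(reg)), function(rg) {
    K <- sum(reg == rg)
    k <- sum(reg_des == rg)
    p <- hyper_upper(k, K, n, N)
    data.frame(region = rg, k = k, K = K, n = n, N = N, p = p,
               significant = p < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Integrative region enrichment across conditions
#'
#' Pools DESs and informative sites across conditions as unique sites,
#' then runs [region_enrichment()] on the pooled sets.
#'
#' @param des_list,informative_list lists of per-condition site-id
#'   vectors.
#' @param annotation annotation data.frame.
#' @export
region_enrichment_integrative <- function(des_list, informative_list,
                                          annotation) {
  region_enrichment(unique(unlist(des_list)),
                    unique(unlist(informative_list)), annotation)
}

#' Gene enrichment of differential editing sites (changing background)
#'
#' For each gene, tests whether it carries more DESs than expected given
#' the total number of informative editing sites it harbors: per gene g,
#' N = all informative sites in the condition, K = informative sites on
#' g, n = all DESs in the condition, k = DESs on g, and
#' p = P(X >= k) under hypergeometric(N, K, n). The background thus
#' changes with each gene's informative-site load, so long,
#' editing-dense genes are not called enriched merely for being long.
#' Genes with no informative site are skipped. A Benjamini–Hochberg
#' column is included for transparency; filtering uses the raw p < 0.05
#' rule.
#'
#' @inheritParams region_enrichment
#' @return data.frame `gene_id`, `k`, `K`, `n`, `N`, `p`, `bh_q`,
#'   `significant`.
#' @export
gene_enrichment <- function(des_sites, informative_sites, annotation) {
  des_sites <- unique(des_sites)
  informative_sites <- unique(informative_sites)
  if (!all(des_sites %in% informative_sites)) {
    stop("DES sites must be a subset of the informative sites")
  }
  idx <- match(informative_sites, annotation$site_id)
  if (anyNA(idx)) {
    stop("unannotated site: ", informative_sites[which(is.na(idx))[1L]])
  }
  gene <- annotation$gene_id[idx]
  gene_des <- annotation$gene_id[match(des_sites, annotation$site_id)]
  N <- length(informative_sites)
  n <- length(des_sites)
  genes <- sort(unique(gene[!is.na(gene)]))
  rows <- lapply(genes, function(g) {
    K <- sum(gene == g, na.rm = TRUE)
    k <- sum(gene_des == g, na.rm = TRUE)
    data.frame(gene_id = g, k = k, K = K, n = n, N = N,
               p = hyper_upper(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < 0.05
  out
}

#' Per-gene DES summary
#'
#' Per gene and condition: DES count, fraction of over-editing DESs and
#' fraction of DESs in the 3'-UTR, plus a cross-condition roll-up (in
#' how many conditions each gene carries DESs). Genes without DESs are
#' absent.
#'
#' @param des_tables named list of DES record data.frames (per
#'   condition), or a single data.frame for one condition.
#' @param annotation annotation data.frame.
#' @return list with `per_condition` (data.frame `gene_id`, `condition`,
#'   `n_des`, `prop_over`, `frac_utr3`) and `rollup` (data.frame
#'   `gene_id`, `n_conditions`, `total_des`).
#' @export
per_gene_summary <- function(des_tables, annotation) {
  if (is.data.frame(des_tables)) des_tables <- list(condition1 = des_tables)
  rows <- list()
  for (k in names(des_tables)) {
    des <- des_tables[[k]]
    if (!nrow(des)) next
    idx <- match(des$site_id, annotation$site_id)
    if (anyNA(idx)) stop("unannotated DES: ", des$site_id[which(is.na(idx))[1L]])
    g <- annotation$gene_id[idx]
    rg <- annotation$region[idx]
    for (gene in sort(unique(g[!is.na(g)]))) {
      sel <- !is.na(g) & g == gene
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene, condition = k, n_des = sum(sel),
        prop_over = mean(des$direction[sel] == "over"),
        frac_utr3 = mean(rg[sel] == "3'-UTR"), stringsAsFactors = FALSE)
    }
  }
  per_condition <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), condition = character(),
               n_des = integer(), prop_over = numeric(),
               frac_utr3 = numeric(), stringsAsFactors = FALSE)
  agg <- if (nrow(per_condition)) {
    sp <- split(per_condition, per_condition$gene_id)
    do.call(rbind, lapply(sp, function(d) data.frame(
      gene_id = d$gene_id[1L], n_conditions = length(unique(d$condition)),
      total_des = sum(d$n_des), stringsAsFactors = FALSE)))
  } else {
    data.frame(gene_id = character(), n_conditions = integer(),
               total_des = integer(), stringsAsFactors = FALSE)
  }
  rownames(agg) <- NULL
  list(per_condition = per_condition, rollup = agg)
}
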