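## Synthetic-data generator: every pipeline input with known ground
## truth (planted DESs, ADAR-OEL coupling, survival effects, seed-site
## gain/loss triplets), emulating the statistical structure of bulk
## editing profiles with missingness.

#' Simulation configuration
#'
#' Validated parameter set for [simulate_editing_profile()]. Editing
#' levels follow a per-site beta law parameterized by mean and
#' concentration (respecting the \[0,1\] support); planted DESs shift the
#' beta mean by ±`effect_size`/2 per group so the planted Diff is exact
#' in expectation, with construction-time validation keeping both group
#' means inside (0,1).
#'
#' @param n_sites number of editing sites.
#' @param n_resistant,n_sensitive samples per response group.
#' @param missing_rate probability an entry is missing (completely at
#'   random).
#' @param des_fraction fraction of sites planted as DESs.
#' @param effect_size planted |Diff| (difference of group mean editing
#'   levels) for DES sites.
#' @param over_editing_proportion fraction of planted DESs with higher
#'   editing in resistant samples.
#' @param beta_mean,beta_concentration baseline beta law of per-site
#'   mean editing levels and of per-sample values around them.
#' @param region_proportions named probabilities over the transcribed
#'   regions (must sum to 1).
#' @param adar_r2_target population R^2 of the ADAR-expression/OEL
#'   coupling (see [simulate_adar_expression()]).
#' @param survival_hr hazard ratio planted between editing groups.
#' @param censoring_rate probability a survival record is censored.
#' @param n_genes number of genes site annotations draw from.
#' @param cancer,drug labels used in the response table.
#' @param seed integer seed; identical configs give byte-identical
#'   outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 2000L, n_resistant = 20L,
                       n_sensitive = 20L, missing_rate = 0.1,
                       des_fraction = 0.05, effect_size = 0.15,
                       over_editing_proportion = 0.5, beta_mean = 0.25,
                       beta_concentration = 20,
                       region_proportions = c("3'-UTR" = 0.35,
                                              "intronic" = 0.35,
                                              "5'-UTR" = 0.05,
                                              "exonic" = 0.05,
                                              "intergenic" = 0.12,
                                              "ncRNA" = 0.08),
                       adar_r2_target = 0.11, survival_hr = 2,
                       censoring_rate = 0.3, n_genes = 100L,
                       cancer = "SIMCAN", drug = "SimDrug", seed = 1L) {
  probs <- c(missing_rate, des_fraction, over_editing_proportion,
             censoring_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  counts <- c(n_sites, n_resistant, n_sensitive, n_genes)
  if (any(counts < 1L)) stop("counts must be positive")
  if (beta_mean <= 0 || beta_mean >= 1) stop("beta_mean must lie in (0,1)")
  if (beta_concentration <= 0) stop("beta_concentration must be positive")
  if (effect_size < 0 || effect_size > 1) stop("effect_size must lie in [0,1]")
  if (beta_mean - effect_size <= 0 || beta_mean + effect_size >= 1) {
    stop("effect size incompatible with beta support: beta_mean ± ",
         "effect_size must stay inside (0,1)")
  }
  if (is.null(names(region_proportions)) ||
      !all(names(region_proportions) %in% REGION_LEVELS)) {
    stop("region_proportions must be named with regions from: ",
         paste(REGION_LEVELS, collapse = ", "))
  }
  if (abs(sum(region_proportions) - 1) > 1e-9) {
    stop("region_proportions must sum to 1")
  }
  if (adar_r2_target < 0 || adar_r2_target >= 1) {
    stop("adar_r2_target must lie in [0,1)")
  }
  if (survival_hr <= 0) stop("survival_hr must be positive")
  structure(list(n_sites = as.integer(n_sites),
                 n_resistant = as.integer(n_resistant),
                 n_sensitive = as.integer(n_sensitive),
                 missing_rate = missing_rate, des_fraction = des_fraction,
                 effect_size = effect_size,
                 over_editing_proportion = over_editing_proportion,
                 beta_mean = beta_mean,
                 beta_concentration = beta_concentration,
                 region_proportions = region_proportions,
                 adar_r2_target = adar_r2_target,
                 survival_hr = survival_hr,
                 censoring_rate = censoring_rate,
                 n_genes = as.integer(n_genes), cancer = cancer,
                 drug = drug, seed = as.integer(seed)),
            class = "sim_config")
}

rbeta_mean <- function(n, mean, concentration) {
  stats::rbeta(n, shape1 = mean * concentration,
               shape2 = (1 - mean) * concentration)
}

#' Simulate an editing profile with planted differential editing sites
#'
#' Draws per-site baseline mean editing levels from a beta law, plants
#' `des_fraction` of sites as DESs whose resistant and sensitive group
#' means differ by exactly `effect_size` (sign per
#' `over_editing_proportion`; baselines for planted sites are re-drawn
#' until both group means stay inside (0.01, 0.99), so no post-hoc
#' clipping distorts the planted Diff), samples per-sample values from a
#' beta law around each group mean, and masks entries missing completely
#' at random. Resistant samples are labeled "Progressive Disease" and
#' sensitive samples "Complete Response" in the response table.
#'
#' @param config a [sim_config()].
#' @return list with `profile` (sites x samples matrix, `NA` missing),
#'   `response` (sample, cancer, drug, response_label), `annotation`
#'   (site_id, chrom, pos, strand, gene_id, region) and `truth`
#'   (data.frame `site_id`, `is_des`, `planted_diff`, `region`,
#'   `gene_id`).
#' @export
simulate_editing_profile <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_sites
  site_ids <- sprintf("site%05d", seq_len(ns))
  samples <- c(sprintf("R%03d", seq_len(config$n_resistant)),
               sprintf("S%03d", seq_len(config$n_sensitive)))
  is_res <- c(rep(TRUE, config$n_resistant), rep(FALSE, config$n_sensitive))

  region <- sample(names(config$region_proportions), ns, replace = TRUE,
                   prob = config$region_proportions)
  gene_pool <- sprintf("gene%04d", seq_len(config$n_genes))
  gene <- ifelse(region == "intergenic", NA_character_,
                 sample(gene_pool, ns, replace = TRUE))

  n_des <- round(config$des_fraction * ns)
  des_idx <- if (n_des > 0L) sort(sample.int(ns, n_des)) else integer()
  n_over <- round(config$over_editing_proportion * n_des)
  sign_vec <- numeric(ns)
  if (n_des > 0L) {
    signs <- c(rep(1, n_over), rep(-1, n_des - n_over))
    sign_vec[des_idx] <- sample(signs)
  }

  mu <- rbeta_mean(ns, config$beta_mean, config$beta_concentration)
  half <- config$effect_size / 2
  for (i in des_idx) {
    tries <- 0L
    while (mu[i] - half <= 0.01 || mu[i] + half >= 0.99) {
      mu[i] <- rbeta_mean(1L, config$beta_mean, config$beta_concentration)
      tries <- tries + 1L
      if (tries > 10000L) stop("cannot place planted effect inside (0,1)")
    }
  }

  profile <- matrix(NA_real_, ns, length(samples),
                    dimnames = list(site_ids, samples))
  for (j in seq_along(samples)) {
    m_j <- mu + ifelse(is_res[j], half, -half) * sign_vec
    profile[, j] <- stats::rbeta(ns, m_j * config$beta_concentration,
                                 (1 - m_j) * config$beta_concentration)
  }
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(ns * length(samples)) < config$missing_rate,
                   ns, length(samples))
    profile[mask] <- NA_real_
  }

  response <- data.frame(
    sample = samples, cancer = config$cancer, drug = config$drug,
    response_label = ifelse(is_res, "Progressive Disease",
                            "Complete Response"),
    stringsAsFactors = FALSE)
  annotation <- data.frame(
    site_id = site_ids, chrom = "chr1",
    pos = seq_len(ns) * 100L, strand = "+", gene_id = gene,
    region = region, stringsAsFactors = FALSE)
  truth <- data.frame(
    site_id = site_ids, is_des = seq_len(ns) %in% des_idx,
    planted_diff = sign_vec * config$effect_size, region = region,
    gene_id = gene, stringsAsFactors = FALSE)
  list(profile = profile, response = response, annotation = annotation,
       truth = truth)
}

#' Simulate ADAR-like expression coupled to overall editing levels
#'
#' Generates `expression = a + b*oel + noise`, with the noise variance
#' chosen analytically from the variance of the supplied OELs so that
#' the population R^2 of a linear fit of expression on OEL equals
#' `r2_target` (sigma^2 = b^2 Var(oel) (1-R^2)/R^2). With
#' `r2_target = 0` the expression is independent of the OELs. Values are
#' shifted to be nonnegative if needed (FPKM-like scale).
#'
#' @param oel named numeric vector of per-sample OELs in \[0,1\].
#' @param r2_target target coefficient of determination in \[0,1).
#' @param seed integer seed.
#' @return named numeric vector of per-sample expression.
#' @export
simulate_adar_expression <- function(oel, r2_target, seed) {
  if (any(oel < 0 | oel > 1, na.rm = TRUE)) stop("OELs must lie in [0,1]")
  if (r2_target < 0 || r2_target >= 1) {
    stop("r2_target must lie in [0,1); a target of 1 is incompatible ",
         "with nonzero noise")
  }
  v <- stats::var(oel)
  if (r2_target > 0 && (!is.finite(v) || v == 0)) {
    stop("constant OEL vector: R^2 is undefined for a degenerate regressor")
  }
  set.seed(seed)
  a <- 10
  b <- if (r2_target > 0) 50 else 0
  sigma <- if (r2_target > 0) {
    sqrt(b^2 * v * (1 - r2_target) / r2_target)
  } else 1
  expr <- a + b * oel + stats::rnorm(length(oel), 0, sigma)
  if (min(expr) < 0) expr <- expr - min(expr)
  stats::setNames(expr, names(oel))
}

#' Simulate survival times with a planted group hazard ratio
#'
#' Event times are exponential; the `over` group's hazard is `hr` times
#' the `under` group's. Censoring is independent exponential with the
#' per-group rate chosen so the marginal censoring probability equals
#' `censoring_rate` (`censoring_rate = 0` gives fully observed events).
#'
#' @param editing_groups named factor/character vector with two
#'   nonempty groups; the level `over` (or the second level) is the
#'   exposed group.
#' @param hr positive hazard ratio.
#' @param censoring_rate probability in \[0,1).
#' @param seed integer seed.
#' @return data.frame `sample`, `time` (> 0), `event` (0/1).
#' @export
simulate_survival <- function(editing_groups, hr, censoring_rate, seed) {
  if (hr <= 0) stop("hr must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must lie in [0,1)")
  }
  g <- factor(editing_groups)
  if (nlevels(g) != 2L || any(table(g) == 0L)) {
    stop("editing_groups must contain exactly two nonempty groups")
  }
  if ("over" %in% levels(g)) g <- stats::relevel(g, ref = setdiff(levels(g), "over"))
  exposed <- as.integer(g) == 2L
  set.seed(seed)
  base_rate <- 0.1
  rate <- base_rate * ifelse(exposed, hr, 1)
  t_event <- stats::rexp(length(g), rate)
  if (censoring_rate > 0) {
    c_rate <- rate * censoring_rate / (1 - censoring_rate)
    t_cens <- stats::rexp(length(g), c_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, length(g))
  }
  data.frame(sample = names(editing_groups), time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Built-in mature miRNA set for simulations
#'
#' Four mature miRNA sequences whose seeds (positions 2–7) jointly cover
#' both plantable event classes: a seed containing C allows a gain
#' construction (the target-site core then carries a G that can start
#' life as an A), a seed containing U allows a loss construction (the
#' core carries an editable A).
#'
#' @return named character vector of RNA sequences.
#' @export
default_mirnas <- function() {
  c(simR_484like = "UCAGGCUCAGUCCCCUCCCGAU",
    simR_let7like = "UGAGGUAGUAGGUUGUAUAGUU",
    simR_10like = "ACCCGUAGAUCCGAACUUGUG",
    simR_16like = "UAGCAGCACGUAAAUAUUGGCG")
}

#' Simulate 3'-UTRs with plantable miRNA seed-site gains and losses
#'
#' For each planted *gain*, the unedited UTR lacks any canonical seed
#' site for the chosen miRNA at the planted locus and the A-to-G-edited
#' UTR contains one (the editable A sits in the seed-match core, so the
#' edit completes an 8mer site); for each planted *loss* the reverse.
#' Random background sequence is re-drawn until no accidental site for
#' any miRNA of the set confounds the planted locus, so the fixtures are
#' collision-free; if no collision-free placement is found after bounded
#' retries an error is raised.
#'
#' @param n_genes number of UTRs to emit (events occupy the first
#'   `n_gain + n_loss` genes; the rest are event-free decoys).
#' @param mirnas named character vector of mature miRNA sequences
#'   (>= 8 nt each).
#' @param n_gain,n_loss number of planted gains and losses.
#' @param utr_length UTR length in nt (>= 50).
#' @param seed integer seed.
#' @param gene_ids optional character vector of gene ids (length
#'   `n_genes`).
#' @return list with `utrs` (named character vector, RNA letters),
#'   `site_positions` (data.frame `site_id`, `gene_id`, `utr_pos`) and
#'   `truth_triplets` (data.frame `site_id`, `mirna_id`, `gene_id`,
#'   `class`).
#' @export
simulate_utr_rewiring <- function(n_genes, mirnas, n_gain, n_loss,
                                  utr_length = 200L, seed = 1L,
                                  gene_ids = sprintf("geneU%03d",
                                                     seq_len(n_genes))) {
  stopifnot(n_genes >= n_gain + n_loss, length(gene_ids) == n_genes)
  if (utr_length < 50L) stop("utr_length must be at least 50")
  mirnas <- vapply(mirnas, normalize_rna, character(1L))
  if (any(nchar(mirnas) < 8L)) stop("each miRNA must be at least 8 nt")
  set.seed(seed)
  alphabet <- c("A", "C", "G", "U")

  ## target-site 8mer for a miRNA and the core offsets that can host the
  ## editable base for each event class
  site8 <- function(m) paste0(rc_rna(substr(m, 2L, 8L)), "A")
  core_offsets <- function(s8, letter) {
    ch <- strsplit(s8, "", fixed = TRUE)[[1L]]
    which(ch[2:7] == letter) + 1L
  }
  eligible <- function(class) {
    letter <- if (class == "gain") "G" else "A"
    names(mirnas)[vapply(mirnas, function(m)
      length(core_offsets(site8(m), letter)) > 0L, logical(1L))]
  }

  classes <- c(rep("gain", n_gain), rep("loss", n_loss))
  utrs <- character(n_genes)
  names(utrs) <- gene_ids
  pos_rows <- list()
  truth_rows <- list()

  for (g in seq_len(n_genes)) {
    cls <- if (g <= length(classes)) classes[g] else NA_character_
    if (is.na(cls)) {
      utrs[g] <- paste(sample(alphabet, utr_length, replace = TRUE),
                       collapse = "")
      next
    }
    elig <- eligible(cls)
    if (!length(elig)) {
      stop("no miRNA in the set admits a planted ", cls, " construction")
    }
    mir_id <- elig[((g - 1L) %% length(elig)) + 1L]
    s8 <- site8(mirnas[[mir_id]])
    letter <- if (cls == "gain") "G" else "A"
    offs <- core_offsets(s8, letter)
    placed <- FALSE
    ## keep a ±30 nt clearance around the locus when the UTR allows it
    lo <- if (utr_length >= 80L) 31L else 9L
    hi <- if (utr_length >= 80L) utr_length - 38L else utr_length - 16L
    for (try in seq_len(100L)) {
      start <- if (lo == hi) lo else sample(lo:hi, 1L)
      off <- offs[sample.int(length(offs), 1L)]
      bg <- sample(alphabet, utr_length, replace = TRUE)
      locus <- strsplit(s8, "", fixed = TRUE)[[1L]]
      if (cls == "gain") locus[off] <- "A"  # unedited form lacks the site
      bg[start:(start + 7L)] <- locus
      utr <- paste(bg, collapse = "")
      pos <- start + off - 1L
      ev <- classify_rewiring(utr, stats::setNames(pos, "chk"), mirnas)
      if (nrow(ev) == 1L && ev$class == cls && ev$mirna_id == mir_id) {
        site_id <- sprintf("udes_%s", gene_ids[g])
        utrs[g] <- utr
        pos_rows[[length(pos_rows) + 1L]] <- data.frame(
          site_id = site_id, gene_id = gene_ids[g], utr_pos = pos,
          stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          site_id = site_id, mirna_id = mir_id, gene_id = gene_ids[g],
          class = cls, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("cannot place a collision-free ", cls, " site for gene ",
           gene_ids[g], " after bounded retries")
    }
  }
  empty_pos <- data.frame(site_id = character(), gene_id = character(),
                          utr_pos = integer(), stringsAsFactors = FALSE)
  empty_tri <- data.frame(site_id = character(), mirna_id = character(),
                          gene_id = character(), class = character(),
                          stringsAsFactors = FALSE)
  list(utrs = utrs,
       site_positions = if (length(pos_rows)) do.call(rbind, pos_rows)
                        else empty_pos,
       truth_triplets = if (length(truth_rows)) do.call(rbind, truth_rows)
                        else empty_tri)
}

#' Simulate miRNA and gene expression realizing planted triplets
#'
#' For each truth *gain* triplet (seed site gained through over-editing
#' in resistant samples), the miRNA and gene expression are negatively
#' correlated in resistant samples, uncorrelated in sensitive samples,
#' and the gene's mean is lower in resistant samples; for each *loss*
#' triplet, the correlation holds in sensitive samples only and the gene
#' mean is higher in resistant samples. miRNA group means are equal
#' (non-DE). Genes/miRNAs passed as decoys get independent expression in
#' both groups. Correlations are induced on a latent Gaussian scale and
#' exponentiated to an FPKM-like scale.
#'
#' @param truth_triplets data.frame `site_id`, `mirna_id`, `gene_id`,
#'   `class` (from [simulate_utr_rewiring()]).
#' @param cond a [condition()] with >= 3 samples per group.
#' @param correlation_strength latent correlation magnitude in (0,1].
#' @param seed integer seed.
#' @param decoy_genes,decoy_mirnas extra feature ids with independent
#'   expression.
#' @return list with `gene_expr` and `mirna_expr` (features x samples
#'   matrices over the condition's samples).
#' @export
simulate_expression_for_triplets <- function(truth_triplets, cond,
                                             correlation_strength = 0.9,
                                             seed = 1L,
                                             decoy_genes = character(),
                                             decoy_mirnas = character()) {
  if (length(cond$resistant) < 3L || length(cond$sensitive) < 3L) {
    stop("need at least 3 samples per group")
  }
  if (correlation_strength <= 0 || correlation_strength > 1) {
    stop("correlation_strength must lie in (0,1]")
  }
  set.seed(seed)
  samples <- c(cond$resistant, cond$sensitive)
  is_res <- samples %in% cond$resistant
  genes <- unique(c(truth_triplets$gene_id, decoy_genes))
  mirs <- unique(c(truth_triplets$mirna_id, decoy_mirnas))
  n <- length(samples)
  sdlog <- 0.5

  mirna_expr <- matrix(NA_real_, length(mirs), n,
                       dimnames = list(mirs, samples))
  z_mir <- matrix(stats::rnorm(length(mirs) * n), length(mirs), n)
  for (i in seq_along(mirs)) {
    mirna_expr[i, ] <- exp(2 + sdlog * z_mir[i, ])  # same mean both groups
  }
  gene_expr <- matrix(NA_real_, length(genes), n,
                      dimnames = list(genes, samples))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    hit <- truth_triplets[truth_triplets$gene_id == g, , drop = FALSE]
    z <- stats::rnorm(n)
    mu <- rep(2, n)
    if (nrow(hit)) {
      tri <- hit[1L, ]
      mi <- match(tri$mirna_id, mirs)
      corr_group <- if (tri$class == "gain") is_res else !is_res
      rho <- correlation_strength
      z[corr_group] <- -rho * z_mir[mi, corr_group] +
        sqrt(1 - rho^2) * stats::rnorm(sum(corr_group))
      if (tri$class == "gain") {
        mu[is_res] <- 1.5; mu[!is_res] <- 2.5   # lower in resistant
      } else {
        mu[is_res] <- 2.5; mu[!is_res] <- 1.5   # higher in resistant
      }
    }
    gene_expr[gi, ] <- exp(mu + sdlog * z)
  }
  list(gene_expr = gene_expr, mirna_expr = mirna_expr)
}
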