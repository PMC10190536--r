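## End-to-end pipeline over bundled synthetic data: simulate -> ingest
## -> DES -> patterns -> enrichment -> prognosis -> triplets -> motif
## windows, with a manifest. Deterministic: all randomness flows from
## the config seed; re-running with the same config reproduces every
## output file byte-identically.

#' Default pipeline configuration
#'
#' All tunables of [run_pipeline()]: the simulation parameters (see
#' [sim_config()]), the analysis thresholds (alpha = 0.05,
#' min_diff = 0.05, min_per_group = 3, flank = 20) and mode switches
#' (Wilcoxon `exact` mode override, the under-edited triplet rule).
#'
#' @param ... overrides for any default.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_sites = 2000L, n_resistant = 20L, n_sensitive = 20L,
    missing_rate = 0.1, des_fraction = 0.05, effect_size = 0.15,
    over_editing_proportion = 0.5, beta_mean = 0.25,
    beta_concentration = 20, adar_r2_target = 0.11, survival_hr = 2,
    censoring_rate = 0.3, n_genes = 100L,
    cancer = "SIMCAN", drug = "SimDrug",
    n_gain = 3L, n_loss = 3L, n_utr_decoys = 4L, utr_length = 200L,
    correlation_strength = 0.9,
    alpha = 0.05, min_diff = 0.05, min_per_group = 3L, flank = 20L,
    exact = NULL, under_edited_rule = TRUE)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over, keep.null = TRUE)
}

#' Run the full pipeline on simulated data
#'
#' Executes every stage on freshly simulated inputs and writes all
#' result tables, FASTA files and a manifest to `outdir`. The manifest
#' (YAML) records the package version, seed, thresholds and the MD5
#' checksum of every output, and contains no volatile fields, so two
#' runs with the same config produce byte-identical output trees.
#'
#' @param config list from [pipeline_config()], or a path to a YAML file
#'   of overrides.
#' @param outdir output directory (created if absent).
#' @return (invisibly) list of in-memory stage results: `sim`, `cond`,
#'   `informative`, `des`, `oel`, `adar_fit`, `patterns`,
#'   `region_enrichment`, `gene_enrichment`, `survival`, `consistency`,
#'   `rewiring`, `screen`, `windows`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (is.character(config)) config <- pipeline_config(yaml::read_yaml(config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)

  ## -- simulate ------------------------------------------------------
  sc <- sim_config(
    n_sites = config$n_sites, n_resistant = config$n_resistant,
    n_sensitive = config$n_sensitive, missing_rate = config$missing_rate,
    des_fraction = config$des_fraction, effect_size = config$effect_size,
    over_editing_proportion = config$over_editing_proportion,
    beta_mean = config$beta_mean,
    beta_concentration = config$beta_concentration,
    adar_r2_target = config$adar_r2_target,
    survival_hr = config$survival_hr,
    censoring_rate = config$censoring_rate, n_genes = config$n_genes,
    cancer = config$cancer, drug = config$drug, seed = config$seed)
  sim <- simulate_editing_profile(sc)
  write_editing_matrix(sim$profile, p("editing_matrix.tsv"))
  write_response(sim$response, p("response.tsv"))
  write_annotation(sim$annotation, p("annotation.tsv"))
  write_tsv(sim$truth, p("truth_sites.tsv"))
  write_bed(sim$annotation, p("sites.bed"))

  ## -- ingest (round-trip through the written files) -----------------
  profile <- read_editing_matrix(p("editing_matrix.tsv"))
  response <- read_response(p("response.tsv"))
  annotation <- read_annotation(p("annotation.tsv"))

  ## -- conditions ----------------------------------------------------
  labels <- label_tumor_samples(response)
  conds <- build_conditions(labels, min_per_group = config$min_per_group)
  if (!length(conds)) stop("stage conditions: no condition met the minimum group sizes")
  cond <- conds[[1L]]
  cond_name <- names(conds)[1L]

  ## -- DES calling ---------------------------------------------------
  informative <- find_informative_sites(profile, cond,
                                        config$min_per_group)
  des_out <- call_des(profile, cond, alpha = config$alpha,
                      min_diff = config$min_diff,
                      min_per_group = config$min_per_group,
                      exact = config$exact)
  write_tsv(des_out$tests, p("site_tests.tsv"))
  write_tsv(des_out$des, p("des.tsv"))

  ## -- OEL and ADAR regression --------------------------------------
  oel <- compute_oel(profile, annotation)
  adar <- simulate_adar_expression(oel$oel, config$adar_r2_target,
                                   seed = config$seed + 1L)
  adar_fit <- regress_oel_on_expression(oel, adar)
  oel_df <- data.frame(sample = names(oel$oel), oel = unname(oel$oel),
                       adar = unname(adar[names(oel$oel)]),
                       stringsAsFactors = FALSE)
  write_tsv(oel_df, p("oel.tsv"))

  ## -- patterns ------------------------------------------------------
  pat <- summarize_patterns(stats::setNames(list(des_out$des), cond_name),
                            adar, stats::setNames(list(cond), cond_name))
  write_tsv(pat$summary, p("patterns.tsv"))

  ## -- enrichment ----------------------------------------------------
  reg_enr <- region_enrichment(des_out$des$site_id, informative, annotation)
  gene_enr <- gene_enrichment(des_out$des$site_id, informative, annotation)
  write_tsv(reg_enr, p("region_enrichment.tsv"))
  write_tsv(gene_enr, p("gene_enrichment.tsv"))
  gene_sum <- per_gene_summary(stats::setNames(list(des_out$des), cond_name),
                               annotation)
  write_tsv(gene_sum$per_condition, p("gene_summary.tsv"))

  ## -- prognosis -----------------------------------------------------
  anchor <- sim$truth$site_id[sim$truth$is_des & sim$truth$planted_diff > 0]
  anchor <- if (length(anchor)) anchor[1L] else rownames(profile)[1L]
  groups <- binarize_by_median(profile[anchor, ])
  surv <- simulate_survival(groups, config$survival_hr,
                            config$censoring_rate,
                            seed = config$seed + 2L)
  write_survival(surv, p("survival.tsv"))
  surv_sites <- unique(c(anchor, des_out$des$site_id))
  surv_res <- survival_screen(profile, surv, surv_sites)
  des_for_consistency <- des_out$tests[des_out$tests$site_id %in% surv_sites, ]
  consistency <- consistency_with_resistance(surv_res, des_for_consistency)
  write_tsv(consistency$per_site, p("survival_results.tsv"))

  ## -- miRNA rewiring and triplets ----------------------------------
  mirnas <- default_mirnas()
  n_utr_genes <- config$n_gain + config$n_loss + config$n_utr_decoys
  rw <- simulate_utr_rewiring(n_utr_genes, mirnas, config$n_gain,
                              config$n_loss,
                              utr_length = config$utr_length,
                              seed = config$seed + 3L)
  write_fasta(rw$utrs, p("utrs.fasta"))
  write_fasta(mirnas, p("mirnas.fasta"))
  write_tsv(rw$site_positions, p("utr_sites.tsv"))
  write_tsv(rw$truth_triplets, p("truth_triplets.tsv"))
  expr <- simulate_expression_for_triplets(
    rw$truth_triplets, cond,
    correlation_strength = config$correlation_strength,
    seed = config$seed + 4L,
    decoy_genes = setdiff(names(rw$utrs), rw$truth_triplets$gene_id),
    decoy_mirnas = setdiff(names(mirnas), rw$truth_triplets$mirna_id))
  write_expression(expr$gene_expr, p("gene_expression.tsv"))
  write_expression(expr$mirna_expr, p("mirna_expression.tsv"))
  events <- do.call(rbind, lapply(seq_len(nrow(rw$site_positions)),
    function(i) {
      sp <- rw$site_positions[i, ]
      classify_rewiring(rw$utrs[[sp$gene_id]],
                        stats::setNames(sp$utr_pos, sp$site_id), mirnas,
                        gene_id = sp$gene_id)
    }))
  if (is.null(events)) events <- classify_rewiring(paste(rep("C", 60),
                                                   collapse = ""),
                                                   integer(), mirnas)
  ## the planted UTR DESs are over-edited in resistant samples by
  ## construction of the generator
  utr_des <- data.frame(site_id = rw$site_positions$site_id,
                        direction = "over", stringsAsFactors = FALSE)
  screen <- screen_triplets(events, utr_des, expr$gene_expr,
                            expr$mirna_expr, cond, alpha = config$alpha,
                            under_edited_rule = config$under_edited_rule)
  write_tsv(events, p("rewiring_events.tsv"))
  write_tsv(screen$candidates, p("triplet_candidates.tsv"))
  write_tsv(screen$triplets, p("triplets.tsv"))

  ## -- motif windows (±flank around each UTR DES) --------------------
  windows <- extract_windows(
    data.frame(site_id = rw$site_positions$site_id,
               contig = rw$site_positions$gene_id,
               pos = rw$site_positions$utr_pos, stringsAsFactors = FALSE),
    rw$utrs, flank = config$flank)
  if (length(windows)) write_fasta(windows, p("motif_windows.fasta"))

  ## -- manifest ------------------------------------------------------
  outputs <- sort(setdiff(list.files(outdir), "manifest.yaml"))
  checksums <- as.list(tools::md5sum(file.path(outdir, outputs)))
  names(checksums) <- outputs
  manifest <- list(
    package = "editscape",
    version = as.character(utils::packageVersion("editscape")),
    seed = as.integer(config$seed),
    thresholds = list(alpha = config$alpha, min_diff = config$min_diff,
                      min_per_group = config$min_per_group,
                      flank = config$flank),
    condition = cond_name,
    checksums = checksums)
  yaml::write_yaml(manifest, p("manifest.yaml"))

  invisible(list(sim = sim, cond = cond, informative = informative,
                 des = des_out, oel = oel, adar = adar,
                 adar_fit = adar_fit, patterns = pat,
                 region_enrichment = reg_enr, gene_enrichment = gene_enr,
                 survival = surv, survival_results = surv_res,
                 consistency = consistency, rewiring = rw,
                 expression = expr, events = events, screen = screen,
                 windows = windows, manifest = manifest))
}
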