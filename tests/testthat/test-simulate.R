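test_that("generator output is byte-identical under a fixed seed", {
  cfg <- sim_config(n_sites = 2000, effect_size = 0.15,
                    des_fraction = 0.05, seed = 7)
  a <- simulate_editing_profile(cfg)
  b <- simulate_editing_profile(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("degenerate rates behave as configured", {
  none <- simulate_editing_profile(sim_config(n_sites = 100,
                                              des_fraction = 0, seed = 2))
  expect_identical(sum(none$truth$is_des), 0L)
  full <- simulate_editing_profile(sim_config(n_sites = 100,
                                              missing_rate = 0, seed = 2))
  expect_false(anyNA(full$profile))
})

test_that("editing values stay in [0,1] and missingness matches its rate", {
  sim <- simulate_editing_profile(sim_config(n_sites = 1000,
                                             missing_rate = 0.15, seed = 9))
  expect_true(all(sim$profile >= 0 & sim$profile <= 1, na.rm = TRUE))
  n <- length(sim$profile)
  obs <- sum(is.na(sim$profile))
  band <- qbinom(c(0.005, 0.995), n, 0.15)
  expect_gte(obs, band[1])
  expect_lte(obs, band[2])
})

test_that("planted DESs carry the planted group-mean difference", {
  cfg <- sim_config(n_sites = 400, effect_size = 0.2, missing_rate = 0,
                    n_resistant = 200, n_sensitive = 200, seed = 31)
  sim <- simulate_editing_profile(cfg)
  res <- grepl("^R", colnames(sim$profile))
  d <- rowMeans(sim$profile[, res]) - rowMeans(sim$profile[, !res])
  planted <- sim$truth$is_des
  ## beta sampling error at n = 200/group is ~0.01
  expect_equal(unname(d[planted]), sim$truth$planted_diff[planted],
               tolerance = 0.05)
  expect_lt(max(abs(d[!planted])), 0.06)
})

test_that("effect sizes incompatible with the beta support are rejected", {
  expect_error(sim_config(beta_mean = 0.1, effect_size = 0.15),
               "incompatible")
  expect_error(sim_config(missing_rate = 1.2), "probabilities")
  expect_error(sim_config(region_proportions = c("3'-UTR" = 0.5)),
               "sum to 1")
})

test_that("response labels use the clinical vocabulary", {
  sim <- simulate_editing_profile(sim_config(n_sites = 10, n_resistant = 3,
                                             n_sensitive = 4, seed = 1))
  expect_setequal(unique(sim$response$response_label),
                  c("Progressive Disease", "Complete Response"))
  lab <- label_tumor_samples(sim$response)
  expect_identical(sum(lab$label == "resistant"), 3L)
  expect_identical(sum(lab$label == "sensitive"), 4L)
})

test_that("ADAR generator honors the coupling target and degenerate cases", {
  oel <- setNames(runif(200, 0.1, 0.4), paste0("p", 1:200))
  ## independence case
  e0 <- simulate_adar_expression(oel, 0, seed = 4)
  expect_lt(summary(lm(e0 ~ oel))$r.squared, 0.05)
  expect_true(all(e0 >= 0))
  ## coupled case reproduces at large n (single-fit sanity; calibration
  ## over replicates is exercised in the acceptance suite)
  oel2 <- setNames(runif(5000, 0.1, 0.4), paste0("q", 1:5000))
  e1 <- simulate_adar_expression(oel2, 0.3, seed = 5)
  expect_equal(summary(lm(e1 ~ oel2))$r.squared, 0.3, tolerance = 0.05)
  expect_error(simulate_adar_expression(oel, 1, seed = 1), "r2_target")
  expect_error(simulate_adar_expression(setNames(rep(0.2, 10),
                                                 paste0("p", 1:10)),
                                        0.1, seed = 1), "constant")
})

test_that("survival generator respects censoring and group structure", {
  groups <- setNames(factor(rep(c("under", "over"), each = 50),
                            levels = c("under", "over")),
                     paste0("p", 1:100))
  s0 <- simulate_survival(groups, hr = 2, censoring_rate = 0, seed = 8)
  expect_true(all(s0$event == 1L))
  expect_true(all(s0$time > 0))
  s3 <- simulate_survival(groups, hr = 2, censoring_rate = 0.3, seed = 8)
  expect_equal(mean(s3$event == 0L), 0.3, tolerance = 0.15)
  expect_error(simulate_survival(groups, hr = -1, censoring_rate = 0,
                                 seed = 1), "positive")
  expect_error(simulate_survival(setNames(rep("over", 5), paste0("p", 1:5)),
                                 2, 0, 1), "two nonempty")
})

test_that("planted UTR events are confirmed by brute-force seed scanning", {
  rw <- simulate_utr_rewiring(8, default_mirnas(), n_gain = 3, n_loss = 3,
                              utr_length = 150, seed = 17)
  expect_identical(nrow(rw$truth_triplets), 6L)
  expect_identical(as.integer(table(rw$truth_triplets$class)[c("gain", "loss")]),
                   c(3L, 3L))
  mirnas <- default_mirnas()
  for (i in seq_len(nrow(rw$truth_triplets))) {
    tr <- rw$truth_triplets[i, ]
    pos <- rw$site_positions$utr_pos[rw$site_positions$site_id == tr$site_id]
    utr <- rw$utrs[[tr$gene_id]]
    edited <- edit_sequence(utr, pos)
    hit <- function(sites) any(sites$utr_start <= pos & sites$utr_end >= pos)
    un <- hit(oracle_seed_sites(mirnas[[tr$mirna_id]], utr))
    ed <- hit(oracle_seed_sites(mirnas[[tr$mirna_id]], edited))
    if (tr$class == "gain") {
      expect_false(un); expect_true(ed)
    } else {
      expect_true(un); expect_false(ed)
    }
  }
  ## decoy UTRs carry no events at any planted position
  expect_identical(length(rw$utrs), 8L)
  ## no gains/losses requested -> no truths, and the screen stays empty
  rw0 <- simulate_utr_rewiring(3, default_mirnas(), 0, 0,
                               utr_length = 120, seed = 1)
  expect_identical(nrow(rw0$truth_triplets), 0L)
  expect_identical(nrow(rw0$site_positions), 0L)
})

test_that("triplet expression generator realizes the planted structure", {
  cond <- condition("C", "D", paste0("r", 1:30), paste0("s", 1:30))
  truth <- data.frame(site_id = c("d1", "d2"), mirna_id = c("mA", "mB"),
                      gene_id = c("g1", "g2"), class = c("gain", "loss"),
                      stringsAsFactors = FALSE)
  ex <- simulate_expression_for_triplets(truth, cond,
                                         correlation_strength = 1,
                                         seed = 12,
                                         decoy_genes = "gZ",
                                         decoy_mirnas = "mZ")
  res <- cond$resistant
  sen <- cond$sensitive
  ## gain: negative correlation in resistant samples only, gene lower in
  ## resistant
  expect_lt(cor(ex$mirna_expr["mA", res], ex$gene_expr["g1", res]), -0.7)
  expect_gt(cor(ex$mirna_expr["mA", sen], ex$gene_expr["g1", sen]), -0.5)
  expect_lt(mean(ex$gene_expr["g1", res]), mean(ex$gene_expr["g1", sen]))
  ## loss: the reverse
  expect_lt(cor(ex$mirna_expr["mB", sen], ex$gene_expr["g2", sen]), -0.7)
  expect_gt(mean(ex$gene_expr["g2", res]), mean(ex$gene_expr["g2", sen]))
  ## miRNAs are non-DE by construction
  de <- rank_de(ex$mirna_expr, cond)
  expect_true(all(de$p > 0.05 | abs(de$log2fc) < 0.5))
  expect_error(simulate_expression_for_triplets(
    truth, condition("C", "D", c("r1", "r2"), paste0("s", 1:3)),
    0.9, 1), "3 samples")
})

test_that("decoy genes stay uncorrelated in both groups", {
  cond <- condition("C", "D", paste0("r", 1:30), paste0("s", 1:30))
  truth <- data.frame(site_id = "d1", mirna_id = "mA", gene_id = "g1",
                      class = "gain", stringsAsFactors = FALSE)
  set.seed(202)
  sig <- replicate(40, {
    seed <- sample.int(1e6, 1)
    ex <- simulate_expression_for_triplets(truth, cond, 0.9, seed,
                                           decoy_genes = "gZ")
    c(cor.test(ex$mirna_expr["mA", cond$resistant],
               ex$gene_expr["gZ", cond$resistant])$p.value,
      cor.test(ex$mirna_expr["mA", cond$sensitive],
               ex$gene_expr["gZ", cond$sensitive])$p.value)
  })
  expect_gt(mean(sig > 0.05), 0.85)
})
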