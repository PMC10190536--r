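## shared fixture: planted gain + loss triplets with decoys
tri_fixture <- function(seed = 23) {
  cond <- condition("C", "D", paste0("r", 1:30), paste0("s", 1:30))
  rw <- simulate_utr_rewiring(6, default_mirnas(), n_gain = 2, n_loss = 2,
                              utr_length = 150, seed = seed)
  ex <- simulate_expression_for_triplets(
    rw$truth_triplets, cond, correlation_strength = 0.95, seed = seed + 1,
    decoy_genes = setdiff(names(rw$utrs), rw$truth_triplets$gene_id),
    decoy_mirnas = setdiff(names(default_mirnas()),
                           rw$truth_triplets$mirna_id))
  events <- do.call(rbind, lapply(seq_len(nrow(rw$site_positions)),
    function(i) {
      sp <- rw$site_positions[i, ]
      classify_rewiring(rw$utrs[[sp$gene_id]],
                        setNames(sp$utr_pos, sp$site_id),
                        default_mirnas(), gene_id = sp$gene_id)
    }))
  des <- data.frame(site_id = rw$site_positions$site_id,
                    direction = "over", stringsAsFactors = FALSE)
  list(cond = cond, rw = rw, ex = ex, events = events, des = des)
}

test_that("every truth triplet passes the three-criterion screen", {
  f <- tri_fixture()
  out <- screen_triplets(f$events, f$des, f$ex$gene_expr, f$ex$mirna_expr,
                         f$cond)
  got <- out$triplets[order(out$triplets$site_id), ]
  want <- f$rw$truth_triplets[order(f$rw$truth_triplets$site_id), ]
  expect_identical(got$site_id, want$site_id)
  expect_identical(got$mirna_id, want$mirna_id)
  expect_identical(got$class, want$class)
  expect_true(all(got$pass_correlation & got$pass_fc &
                    got$pass_mirna_not_de))
})

test_that("emitted flags re-derive from raw expression", {
  f <- tri_fixture()
  out <- screen_triplets(f$events, f$des, f$ex$gene_expr, f$ex$mirna_expr,
                         f$cond)
  for (i in seq_len(nrow(out$triplets))) {
    tr <- out$triplets[i, ]
    cr <- cor.test(f$ex$mirna_expr[tr$mirna_id, f$cond$resistant],
                   f$ex$gene_expr[tr$gene_id, f$cond$resistant])
    cs <- cor.test(f$ex$mirna_expr[tr$mirna_id, f$cond$sensitive],
                   f$ex$gene_expr[tr$gene_id, f$cond$sensitive])
    expect_equal(unname(cr$estimate), tr$r_res, tolerance = 1e-12)
    expect_equal(cs$p.value, tr$p_sen, tolerance = 1e-12)
    fc <- log2(mean(f$ex$gene_expr[tr$gene_id, f$cond$resistant]) /
                 mean(f$ex$gene_expr[tr$gene_id, f$cond$sensitive]))
    expect_equal(fc, tr$gene_log2fc, tolerance = 1e-12)
    sig_res <- cr$estimate < 0 && cr$p.value < 0.05
    sig_sen <- cs$estimate < 0 && cs$p.value < 0.05
    if (tr$class == "gain") {
      expect_true(sig_res && !sig_sen && fc < 0)
    } else {
      expect_true(sig_sen && !sig_res && fc > 0)
    }
  }
})

test_that("single-criterion decoys are each rejected", {
  f <- tri_fixture()
  gain <- f$rw$truth_triplets[f$rw$truth_triplets$class == "gain", ][1, ]
  ev <- f$events[f$events$site_id == gain$site_id &
                   f$events$mirna_id == gain$mirna_id, ]

  ## decoy 1: same event, but the miRNA is strongly DE
  ex_de <- f$ex
  ex_de$mirna_expr[gain$mirna_id, f$cond$resistant] <-
    ex_de$mirna_expr[gain$mirna_id, f$cond$resistant] * 20
  out1 <- screen_triplets(ev, f$des, ex_de$gene_expr, ex_de$mirna_expr,
                          f$cond)
  expect_identical(nrow(out1$triplets), 0L)
  expect_false(out1$candidates$pass_mirna_not_de)

  ## decoy 2: gene fold change of the wrong sign (gene up in resistant)
  ex_fc <- f$ex
  ex_fc$gene_expr[gain$gene_id, f$cond$resistant] <-
    ex_fc$gene_expr[gain$gene_id, f$cond$resistant] + 100
  out2 <- screen_triplets(ev, f$des, ex_fc$gene_expr, ex_fc$mirna_expr,
                          f$cond)
  expect_identical(nrow(out2$triplets), 0L)
  expect_false(out2$candidates$pass_fc)

  ## decoy 3: correlation in the wrong group (loss-like pattern fed to a
  ## gain event): swap the two groups' expression columns
  swap <- c(f$cond$sensitive, f$cond$resistant)
  ex_sw <- list(gene_expr = f$ex$gene_expr[, swap, drop = FALSE],
                mirna_expr = f$ex$mirna_expr[, swap, drop = FALSE])
  colnames(ex_sw$gene_expr) <- c(f$cond$resistant, f$cond$sensitive)
  colnames(ex_sw$mirna_expr) <- c(f$cond$resistant, f$cond$sensitive)
  out3 <- screen_triplets(ev, f$des, ex_sw$gene_expr, ex_sw$mirna_expr,
                          f$cond)
  expect_identical(nrow(out3$triplets), 0L)
  expect_false(out3$candidates$pass_correlation)
})

test_that("removing any criterion strictly enlarges the decoy output", {
  f <- tri_fixture()
  gain <- f$rw$truth_triplets[f$rw$truth_triplets$class == "gain", ][1, ]
  ev <- f$events[f$events$site_id == gain$site_id &
                   f$events$mirna_id == gain$mirna_id, ]
  ex_de <- f$ex
  ex_de$mirna_expr[gain$mirna_id, f$cond$resistant] <-
    ex_de$mirna_expr[gain$mirna_id, f$cond$resistant] * 20
  out <- screen_triplets(ev, f$des, ex_de$gene_expr, ex_de$mirna_expr,
                         f$cond)
  with_two <- with(out$candidates, pass_correlation & pass_fc)
  expect_true(any(with_two))              # passes the other two criteria
  expect_identical(nrow(out$triplets), 0L)  # but not all three
})

test_that("under-edited DESs use the swapped rule behind the flag", {
  f <- tri_fixture()
  loss <- f$rw$truth_triplets[f$rw$truth_triplets$class == "loss", ][1, ]
  ev <- f$events[f$events$site_id == loss$site_id &
                   f$events$mirna_id == loss$mirna_id, ]
  des_under <- data.frame(site_id = loss$site_id, direction = "under",
                          stringsAsFactors = FALSE)
  ## with the rule off the event is dropped entirely
  out_off <- screen_triplets(ev, des_under, f$ex$gene_expr,
                             f$ex$mirna_expr, f$cond,
                             under_edited_rule = FALSE)
  expect_identical(nrow(out_off$candidates), 0L)
  ## with the rule on it is screened with resistant/sensitive roles
  ## swapped and labeled as extended
  out_on <- screen_triplets(ev, des_under, f$ex$gene_expr,
                            f$ex$mirna_expr, f$cond)
  expect_identical(nrow(out_on$candidates), 1L)
  expect_true(out_on$candidates$extended_rule)
  ## the loss fixture has its correlation in the sensitive group and a
  ## positive fold change, which under the swapped rule reads as a
  ## resistant-group requirement, so it must fail the correlation gate
  expect_false(out_on$candidates$pass_correlation)
})

test_that("events whose DES is missing from the DES table are an error", {
  f <- tri_fixture()
  expect_error(screen_triplets(f$events,
                               data.frame(site_id = "nope",
                                          direction = "over"),
                               f$ex$gene_expr, f$ex$mirna_expr, f$cond),
               "absent from DES records")
})
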