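let7 <- "UGAGGUAGUAGGUUGUAUAGUU"  # seed 2-8 = GAGGUAG

test_that("canonical site types are detected by their definitions", {
  ## 8mer: rc(seed 2-8) + A = CUACCUCA
  s8 <- find_seed_sites(let7, "GGGCUACCUCAGGG")
  expect_identical(s8$site_type, "8mer")
  expect_identical(s8$utr_start, 4L)
  expect_identical(s8$utr_end, 11L)
  ## 7mer-m8: positions 2-8 matched, trailing base not A
  s7 <- find_seed_sites(let7, "GGGCUACCUCGGGG")
  expect_identical(s7$site_type, "7mer-m8")
  expect_identical(s7$utr_start, 4L)
  ## 7mer-A1: positions 2-7 matched plus A, no m8 match
  sa <- find_seed_sites(let7, "GGGGUACCUCAGGG")
  expect_identical(sa$site_type, "7mer-A1")
  expect_identical(sa$utr_start, 5L)
  ## no complementary hexamer at all
  expect_identical(nrow(find_seed_sites(let7, "GGGGGGGGGGGG")), 0L)
  ## DNA letters are accepted
  expect_identical(find_seed_sites(chartr("U", "T", let7),
                                   "GGGCTACCTCAGGG")$site_type, "8mer")
})

test_that("seed scanning rejects short miRNAs and bad alphabets", {
  expect_error(find_seed_sites("ACGUACG", "ACGUACGU"), "8 nt")
  expect_error(find_seed_sites(let7, "ACGUNNN"), "alphabet")
})

test_that("seed scan equals brute-force window checking on random sequences", {
  set.seed(314)
  mirnas <- c(let7, default_mirnas())
  for (i in 1:150) {
    mir <- mirnas[[sample.int(length(mirnas), 1)]]
    utr <- paste(sample(c("A", "C", "G", "U"), sample(8:30, 1),
                        replace = TRUE), collapse = "")
    got <- find_seed_sites(mir, utr)
    want <- oracle_seed_sites(mir, utr)
    got <- got[order(got$utr_start, got$site_type), , drop = FALSE]
    rownames(got) <- NULL
    expect_identical(got, want)
  }
  ## seed-rich sequences (biased toward the let-7 site alphabet)
  for (i in 1:150) {
    utr <- paste(sample(c("C", "U", "A", "C", "C", "U", "C", "A", "G"),
                        sample(10:30, 1), replace = TRUE), collapse = "")
    got <- find_seed_sites(let7, utr)
    want <- oracle_seed_sites(let7, utr)
    got <- got[order(got$utr_start, got$site_type), , drop = FALSE]
    rownames(got) <- NULL
    expect_identical(got, want)
  }
})

test_that("edit_sequence performs exact A-to-G substitution", {
  expect_identical(edit_sequence("AAGCCUGA", 1), "GAGCCUGA")
  expect_identical(edit_sequence("CUACCUCA", 3), "CUGCCUCA")
  expect_identical(edit_sequence("ACGU", integer()), "ACGU")
  expect_error(edit_sequence("ACGU", 2), "not A")
  expect_error(edit_sequence("ACGU", 9), "bounds")
  ## differs from the original at exactly the edited positions
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "U"), 40, replace = TRUE),
               collapse = "")
    pos <- which(strsplit(s, "")[[1]] == "A")
    if (length(pos) < 2) next
    pick <- sample(pos, 2)
    e <- edit_sequence(s, pick)
    diff <- which(strsplit(s, "")[[1]] != strsplit(e, "")[[1]])
    expect_setequal(diff, pick)
  }
})

test_that("rewiring classification recovers constructed gain and loss events", {
  mirnas <- c(m1 = let7)
  ## loss: editing the third A of the 8mer target destroys the site
  utr_loss <- "GGGGGGCUACCUCAGGGGGG"
  ev <- classify_rewiring(utr_loss, c(d1 = 9L), mirnas, gene_id = "gX")
  expect_identical(ev$class, "loss")
  expect_identical(ev$mirna_id, "m1")
  expect_identical(ev$gene_id, "gX")
  ## gain: unedited core carries an A where the seed match needs a G.
  ## miRNA seed 2-8 = CAGGCUC, target 8mer GAGCCUGA; the unedited UTR
  ## holds GAACCUGA and editing the broken core position restores it.
  mir484 <- c(m2 = "UCAGGCUCAGUCCCCUCCCGAU")
  utr_gain <- paste0("GGGGGG", "GAACCUGA", "GGGGGG")
  expect_identical(nrow(find_seed_sites(mir484[[1]], utr_gain)), 0L)
  ev2 <- classify_rewiring(utr_gain, c(d2 = 9L), mir484)
  expect_identical(ev2$class, "gain")
  expect_identical(ev2$mirna_id, "m2")
  ## editing outside any potential seed window produces no event
  ev3 <- classify_rewiring("AGGGGGGGGGCUACCUCAGGGG", c(d3 = 1L), mirnas)
  expect_identical(nrow(ev3), 0L)
})

test_that("window extraction honors flanks and truncation", {
  contigs <- c(c1 = paste(rep("ACGU", 25), collapse = ""))  # 100 nt
  w <- extract_windows(data.frame(site_id = "s1", contig = "c1", pos = 21),
                       contigs, flank = 20)
  expect_identical(nchar(w[["s1"]]), 41L)
  expect_identical(w[["s1"]], substr(contigs[["c1"]], 1, 41))
  expect_warning(
    w2 <- extract_windows(data.frame(site_id = "s2", contig = "c1", pos = 5),
                          contigs, flank = 20),
    "truncated")
  expect_identical(nchar(w2[["s2"]]), 25L)
  w3 <- extract_windows(data.frame(site_id = "s3", contig = "c1", pos = 10),
                        contigs, flank = 0)
  expect_identical(nchar(w3[["s3"]]), 1L)
  expect_error(extract_windows(data.frame(site_id = "s4", contig = "c1",
                                          pos = 101), contigs), "bounds")
})
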