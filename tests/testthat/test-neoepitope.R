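test_that("tiling agrees with exhaustive window enumeration on random fixtures", {
  set.seed(55)
  for (i in 1:300) {
    L <- sample(12:60, 1)
    p <- sample.int(L, 1)
    prot <- random_protein(L)
    ref <- substr(prot, p, p)
    alt <- sample(setdiff(serotarget:::AMINO_ACIDS, ref), 1)
    tiles <- tile_peptides(prot, ref, p, alt)
    oracle <- tiling_oracle(L, p)
    expect_equal(nrow(tiles), if (is.null(oracle)) 0L else nrow(oracle))
    if (!is.null(oracle)) {
      expect_equal(paste(tiles$protein_start, tiles$length),
                   paste(oracle[order(oracle[, "length"],
                                      oracle[, "start"]), "start"],
                         oracle[order(oracle[, "length"],
                                      oracle[, "start"]), "length"]))
    }
    # closed-form window count
    ks <- c(8L, 9L, 10L)
    counts <- pmax(0L, pmin(p, L - ks + 1L) - pmax(1L, p - ks + 1L) + 1L)
    expect_equal(nrow(tiles), sum(counts))
  }
})

test_that("interior mutations give 27 pairs; terminal mutations one per length", {
  prot <- random_protein(40)
  p <- 20L
  ref <- substr(prot, p, p)
  alt <- setdiff(serotarget:::AMINO_ACIDS, ref)[1]
  expect_equal(nrow(tile_peptides(prot, ref, p, alt)), 27L)
  ref1 <- substr(prot, 1, 1)
  alt1 <- setdiff(serotarget:::AMINO_ACIDS, ref1)[1]
  t1 <- tile_peptides(prot, ref1, 1L, alt1)
  expect_equal(nrow(t1), 3L)
  expect_true(all(t1$protein_start == 1L))
})

test_that("mutant and wildtype peptides differ at exactly the mutated index", {
  set.seed(66)
  for (i in 1:40) {
    L <- sample(15:50, 1)
    p <- sample.int(L, 1)
    prot <- random_protein(L)
    ref <- substr(prot, p, p)
    alt <- sample(setdiff(serotarget:::AMINO_ACIDS, ref), 1)
    tiles <- tile_peptides(prot, ref, p, alt)
    for (j in seq_len(nrow(tiles))) {
      mu <- strsplit(tiles$mutant_peptide[j], "")[[1]]
      wt <- strsplit(tiles$wildtype_peptide[j], "")[[1]]
      diff_at <- which(mu != wt)
      expect_identical(diff_at, as.integer(tiles$mut_position_in_peptide[j]))
      expect_identical(mu[diff_at], alt)
      expect_identical(wt[diff_at], ref)
    }
  }
})

test_that("tiling rejects annotation/sequence disagreement and bad positions", {
  prot <- "ACDEFGHIKLMNPQRSTVWY"
  wrong_ref <- setdiff(serotarget:::AMINO_ACIDS, substr(prot, 5, 5))[1]
  expect_error(tile_peptides(prot, wrong_ref, 5L, "A"), "mismatch")
  expect_error(tile_peptides(prot, "A", 0L, "V"), "outside")
  expect_error(tile_peptides(prot, "A", 99L, "V"), "outside")
  expect_error(tile_peptides(prot, "A", 1L, "A"), "synonymous")
})

test_that("the toy predictor is deterministic and respects the contract", {
  pred <- toy_predictor()
  peps <- vapply(rep(c(8, 9, 10), each = 4), random_protein, character(1))
  a1 <- pred$affinity(peps)
  a2 <- pred$affinity(peps)
  expect_identical(a1, a2)
  expect_true(all(a1 > 0))
  s <- pred$processing_score(peps)
  expect_true(all(s >= 0 & s <= 1))
  # allele-dependent but deterministic per allele
  expect_identical(pred$affinity(peps, "HLA-A*01:01"),
                   pred$affinity(peps, "HLA-A*01:01"))
})

test_that("scoring is repeatable and flags unscorable candidates", {
  prot <- random_protein(30)
  ref <- substr(prot, 15, 15)
  alt <- setdiff(serotarget:::AMINO_ACIDS, ref)[1]
  tiles <- tile_peptides(prot, ref, 15L, alt, gene_id = "G1")
  s1 <- score_candidates(tiles, toy_predictor())
  s2 <- score_candidates(tiles, toy_predictor())
  expect_identical(s1, s2)
  expect_false(any(s1$unscored))
  # tabular predictor missing some peptides -> flagged, not dropped
  tab <- data.frame(
    peptide = c(s1$mutant_peptide[1:3], s1$wildtype_peptide[1:3]),
    allele = "HLA-A*02:01",
    affinity_nM = c(100, 200, 300, 400, 500, 600), combined_score = 0.7)
  expect_warning(s3 <- score_candidates(tiles, tabular_predictor(tab)),
                 "unscored")
  expect_equal(nrow(s3), nrow(tiles))
  expect_equal(sum(s3$unscored), nrow(tiles) - 3L)
})

test_that("filter verdicts follow the three rules and relax monotonically", {
  base <- tile_peptides(paste(rep("ARNDCQEGHILKMFPSTWYV", 3), collapse = ""),
                        "C", 5L, "W", gene_id = "G")
  sc <- score_candidates(base, toy_predictor())
  # hand-set scores to probe each rule
  sc$mut_affinity_nM <- c(100, 100, 700, rep(50, nrow(sc) - 3))
  sc$wt_affinity_nM <- c(300, 50, 900, rep(400, nrow(sc) - 3))
  sc$combined_score <- c(0.7, 0.9, 0.7, rep(0.5, nrow(sc) - 3))
  kept <- filter_candidates(sc, keep_failing = TRUE)
  expect_true(kept$pass_all[1])          # 100 nM < wt 300, score 0.7
  expect_false(kept$pass_wt[2])          # wildtype binds more strongly
  expect_false(kept$pass_affinity[3])    # above 500 nM
  expect_false(any(kept$pass_score[-(1:3)]))  # score 0.5 below 0.6
  # each verdict recomputable from the stored scores
  expect_equal(kept$pass_all,
               kept$pass_affinity & kept$pass_score & kept$pass_wt)

  scored <- score_candidates(base, toy_predictor())
  tight <- filter_candidates(scored, max_affinity_nM = 500)
  loose <- filter_candidates(scored, max_affinity_nM = 1000)
  expect_true(all(tight$mutant_peptide %in% loose$mutant_peptide))
})

test_that("panel selection matches a brute-force sort oracle and caps size", {
  set.seed(77)
  prot <- random_protein(60)
  cands <- do.call(rbind, lapply(c(15L, 30L, 45L), function(p) {
    ref <- substr(prot, p, p)
    alt <- sample(setdiff(serotarget:::AMINO_ACIDS, ref), 1)
    tile_peptides(prot, ref, p, alt, gene_id = paste0("G", p))
  }))
  class(cands) <- c("epitope_candidates", "data.frame")
  scored <- score_candidates(cands, toy_predictor())
  passing <- filter_candidates(scored, max_affinity_nM = 1e9,
                               min_combined_score = 0, require_mut_stronger = FALSE)
  panel <- select_panel(passing, n_min = 2, n_max = 9, hydropathy_limit = NULL)
  expect_lte(nrow(panel), 9L)
  # oracle: drop dominated duplicates per (gene, mutation, length), sort
  key <- paste(passing$gene_id, passing$aa_ref, passing$aa_pos,
               passing$aa_alt, passing$length, sep = "|")
  ord <- order(passing$mut_affinity_nM, -passing$combined_score,
               passing$mutant_peptide)
  oracle <- passing[ord, ][!duplicated(key[ord]), ]
  oracle <- head(oracle, 9L)
  expect_identical(panel$mutant_peptide, oracle$mutant_peptide)
  expect_identical(panel$rank, seq_len(nrow(panel)))

  one <- passing[1, ]
  class(one) <- c("epitope_candidates", "data.frame")
  expect_warning(p1 <- select_panel(one), "below the requested minimum")
  expect_equal(nrow(p1), 1L)
})

test_that("GRAVY matches hand-computed Kyte-Doolittle means and screens panels", {
  expect_equal(gravy("AIV"), mean(c(1.8, 4.5, 4.2)))
  expect_equal(gravy("RKDE"), mean(c(-4.5, -3.9, -3.5, -3.5)))
  expect_error(gravy("AXB"), "non-standard")
  prot <- paste(rep("I", 30), collapse = "")  # maximally hydrophobic
  tiles <- tile_peptides(prot, "I", 15L, "V", gene_id = "G")
  scored <- score_candidates(tiles, toy_predictor())
  all_pass <- filter_candidates(scored, max_affinity_nM = 1e9,
                                min_combined_score = 0,
                                require_mut_stronger = FALSE)
  expect_warning(panel <- select_panel(all_pass, hydropathy_limit = 2.0),
                 "below")
  expect_equal(nrow(panel), 0L)
})
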