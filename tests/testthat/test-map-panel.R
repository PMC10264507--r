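test_that("proteome matching equals the naive substring-scan oracle", {
  set.seed(88)
  proteome <- setNames(vapply(sample(60:150, 25, replace = TRUE),
                              random_protein, character(1)),
                       sprintf("PG%02d", 1:25))
  true_peps <- vapply(1:30, function(i) {
    g <- sample(names(proteome), 1)
    k <- sample(8:11, 1)
    s <- sample.int(nchar(proteome[[g]]) - k + 1L, 1)
    substr(proteome[[g]], s, s + k - 1L)
  }, character(1))
  decoys <- vapply(1:10, function(i) {
    repeat {
      pep <- random_protein(9)
      if (!any(grepl(pep, proteome, fixed = TRUE))) return(pep)
    }
  }, character(1))
  peps <- sample(c(true_peps, decoys))
  res <- match_to_proteome(peps, proteome)
  expect_equal(res$matched_genes, naive_match(res$sequence, proteome))
  expect_true(all(res$n_matches[res$sequence %in% decoys] == 0L))
  expect_true(all(res$n_matches[res$sequence %in% true_peps] >= 1L))
})

test_that("shared subsequences report every containing paralog", {
  core <- "WYHKDEFRQ"
  proteome <- c(PARA1 = paste0(random_protein(20), core, random_protein(20)),
                PARA2 = paste0(random_protein(5), core),
                OTHER = random_protein(40))
  res <- match_to_proteome(core, proteome)
  expect_identical(res$matched_genes, "PARA1,PARA2")
})

test_that("peptides with bad lengths or residues are skipped with warnings", {
  proteome <- c(G1 = random_protein(50))
  expect_warning(r <- match_to_proteome(c("SHORT", "ACDEFGHIK"), proteome),
                 "length 8-11")
  expect_equal(nrow(r), 1L)
  expect_warning(r2 <- match_to_proteome(c("ACDEFGHIX", "ACDEFGHIK"), proteome),
                 "non-standard")
  expect_equal(nrow(r2), 1L)
})

test_that("I/L equivalence is off by default and togglable", {
  proteome <- c(G1 = "AAAAILKWYHAAAA")
  pep_l <- "AALLKWYH"  # I replaced by L
  expect_equal(match_to_proteome(pep_l, proteome)$n_matches, 0L)
  expect_equal(match_to_proteome(pep_l, proteome,
                                 il_equivalent = TRUE)$n_matches, 1L)
})

test_that("annotations flag geneset membership and exact known epitopes", {
  proteome <- c(CTA1 = random_protein(40), PLAIN = random_protein(40))
  pep_cta <- substr(proteome[["CTA1"]], 5, 13)
  pep_plain <- substr(proteome[["PLAIN"]], 5, 13)
  maps <- match_to_proteome(c(pep_cta, pep_plain), proteome)
  ann <- annotate_maps(
    maps,
    genesets = list(CTA = gene_set("CTA", "CTA1")),
    repertoire = gene_set("rep", "PLAIN"),
    known_epitopes = data.frame(sequence = pep_cta, gene_id = "CTA1")
  )
  expect_equal(ann$CTA, c(TRUE, FALSE))
  expect_equal(ann$autoAb_target, c(FALSE, TRUE))
  expect_equal(ann$known_A2_epitope, c(TRUE, FALSE))
  # annotation is monotone: growing a geneset never clears a flag
  ann2 <- annotate_maps(maps,
                        genesets = list(CTA = gene_set("CTA",
                                                       c("CTA1", "PLAIN"))),
                        repertoire = gene_set("rep", "PLAIN"),
                        known_epitopes = data.frame(sequence = pep_cta,
                                                    gene_id = "CTA1"))
  expect_true(all(ann2$CTA >= ann$CTA))
})

test_that("MAP panels cap categories, deduplicate, and ignore input order", {
  set.seed(99)
  proteome <- setNames(vapply(rep(60, 20), random_protein, character(1)),
                       sprintf("MG%02d", 1:20))
  peps <- vapply(1:40, function(i) {
    g <- sample(names(proteome), 1)
    s <- sample.int(60 - 9 + 1L, 1)
    substr(proteome[[g]], s, s + 8L)
  }, character(1))
  maps <- match_to_proteome(unique(peps), proteome)
  known <- data.frame(sequence = maps$sequence[1:15],
                      gene_id = sub(",.*", "", maps$matched_genes[1:15]))
  auto_genes <- unique(sub(",.*", "", maps$matched_genes[16:25]))
  ann <- annotate_maps(maps, repertoire = gene_set("rep", auto_genes),
                       known_epitopes = known)
  panel <- select_map_panel(ann)
  expect_lte(sum(panel$category == "known_epitope"), 10L)
  expect_lte(sum(panel$category == "autoAb_target"), 2L)
  expect_false(any(duplicated(panel$sequence)))
  shuffled <- ann[sample(nrow(ann)), ]
  class(shuffled) <- class(ann)
  expect_equal(select_map_panel(shuffled), panel)
  empty <- ann[0, ]
  class(empty) <- class(ann)
  expect_warning(p0 <- select_map_panel(empty), "no peptides")
  expect_equal(nrow(p0), 0L)
})

test_that("a full 10 known + 2 auto-antibody pool yields a 12-peptide panel", {
  sc <- small_cohort()
  proteome <- read_proteome(sc$bundle$proteome)
  ledger <- sc$bundle$ledger
  pid <- names(ledger$maps)[1]
  peps <- read_peptide_list(sc$bundle$maps[[pid]])
  maps <- match_to_proteome(peps, proteome, patient_id = pid)
  known <- utils::read.delim(sc$bundle$known_epitopes,
                             stringsAsFactors = FALSE)
  ann <- annotate_maps(maps,
                       repertoire = gene_set("autoAb",
                                             unlist(ledger$enriched_genes)),
                       known_epitopes = known)
  panel <- select_map_panel(ann, max_known = 10, max_autoab = 2)
  expect_equal(nrow(panel), 12L)
  expect_equal(sum(panel$category == "known_epitope"), 10L)
  expect_equal(sum(panel$category == "autoAb_target"), 2L)
})
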