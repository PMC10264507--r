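test_that("intersect_calls keeps exactly the shared keys with merged evidence", {
  wes <- somatic_variants("P1", c("1", "1", "2"), c(100L, 200L, 300L),
                          c("A", "C", "G"), c("T", "T", "A"),
                          c("GA", "GB", "GC"), vaf = 0.3)
  rna <- somatic_variants("P1", c("1", "2", "3"), c(100L, 300L, 400L),
                          c("A", "G", "C"), c("T", "A", "G"),
                          c("GA", "GC", "GD"), vaf = 0.25)
  both <- intersect_calls(wes, rna)
  expect_setequal(both$gene_id, c("GA", "GC"))
  expect_true(all(both$evidence == "WES,RNA"))
  # symmetric in which keys survive
  expect_setequal(serotarget:::variant_key(both),
                  serotarget:::variant_key(intersect_calls(rna, wes)))
  rna_other <- rna
  rna_other$patient_id <- "P2"
  expect_error(intersect_calls(wes, rna_other), "single patient")
})

test_that("intersect_calls agrees with a brute-force pairwise oracle", {
  wes <- random_variant_table(1000, seed = 101)
  rna <- random_variant_table(1000, seed = 202)
  res <- intersect_calls(wes, rna)
  rna_keys <- paste(rna$chrom, rna$pos, rna$ref_allele, rna$alt_allele)
  in_both <- vapply(seq_len(nrow(wes)), function(i) {
    any(rna_keys == paste(wes$chrom[i], wes$pos[i], wes$ref_allele[i],
                          wes$alt_allele[i]))
  }, logical(1))
  expect_equal(sort(serotarget:::variant_key(res)),
               sort(serotarget:::variant_key(wes)[in_both]))
  expect_lte(nrow(res), min(nrow(wes), nrow(rna)))
})

test_that("germline and VAF filters use the printed boundary conventions", {
  v <- somatic_variants("P1", "1", c(1L, 2L, 3L, 4L, 5L),
                        rep("A", 5), rep("T", 5), sprintf("G%d", 1:5),
                        vaf = c(0.10, 0.05, 0.50, 0.10, 0.30),
                        population_af = c(0.001, 0.001, 0.01, 0.005, NA))
  # population AF strictly greater than 0.005 is removed; 0.005 retained
  expect_warning(g <- filter_germline(v), "lack a population")
  expect_setequal(g$gene_id, c("G1", "G2", "G4", "G5"))
  # VAF >= 0.10 inclusive: 0.10 retained, 0.05 removed
  f <- filter_vaf(v)
  expect_setequal(f$gene_id, c("G1", "G3", "G4", "G5"))
  expect_true(all(filter_vaf(v, 0.2)$gene_id %in% f$gene_id))
})

test_that("the cascade commutes, is idempotent, and every output obeys all rules", {
  wes <- random_variant_table(400, seed = 7)
  rna <- random_variant_table(400, seed = 8)
  ab <- suppressWarnings(
    filter_vaf(filter_germline(intersect_calls(wes, rna))))
  ba <- suppressWarnings(
    filter_germline(filter_vaf(intersect_calls(wes, rna))))
  expect_identical(ab, ba)
  again <- suppressWarnings(filter_vaf(filter_germline(ab)))
  expect_identical(again, ab)
  expect_true(all(ab$vaf >= 0.10))
  expect_true(all(is.na(ab$population_af) | ab$population_af <= 0.005))
  rna_keys <- serotarget:::variant_key(rna)
  expect_true(all(serotarget:::variant_key(ab) %in% rna_keys))
})

test_that("the cascade retains exactly the ledgered true variants", {
  sc <- small_cohort()
  ledger <- sc$bundle$ledger
  for (pid in names(ledger$variants)) {
    wes <- read_variants_tsv(file.path(sc$dir, "variants",
                                       paste0(pid, "_wes.tsv")))
    rna <- read_variants_tsv(file.path(sc$dir, "variants",
                                       paste0(pid, "_rna.tsv")))
    kept <- expressed_snv(wes, rna)
    expect_setequal(serotarget:::variant_key(kept),
                    unlist(ledger$variants[[pid]]$true_keys))
  }
})

test_that("summaries count per patient and ignore input order", {
  v <- random_variant_table(60, seed = 3)
  v$patient_id <- rep(c("PA", "PB", "PC"), each = 20)
  class(v) <- c("somatic_variants", "data.frame")
  s <- summarize_expressed_snv(v)
  expect_equal(s$n_snv, c(20L, 20L, 20L))
  shuffled <- v[sample(nrow(v)), ]
  class(shuffled) <- c("somatic_variants", "data.frame")
  expect_equal(summarize_expressed_snv(shuffled), s)
  empty <- v[0, ]
  class(empty) <- c("somatic_variants", "data.frame")
  expect_equal(nrow(summarize_expressed_snv(empty)), 0L)
})

test_that("VCF ingestion matches the TSV dialect on generated data", {
  sc <- small_cohort()
  pid <- names(sc$bundle$ledger$variants)[1]
  tsv <- read_variants_tsv(file.path(sc$dir, "variants",
                                     paste0(pid, "_wes.tsv")))
  vcf <- read_variants_vcf(file.path(sc$dir, "variants",
                                     paste0(pid, "_wes.vcf")),
                           patient_id = pid, evidence = "WES")
  expect_equal(nrow(vcf), nrow(tsv))
  expect_setequal(serotarget:::variant_key(vcf),
                  serotarget:::variant_key(tsv))
  m <- match(serotarget:::variant_key(tsv), serotarget:::variant_key(vcf))
  expect_equal(vcf$vaf[m], tsv$vaf)
  expect_equal(vcf$population_af[m], tsv$population_af)
  expect_equal(vcf$gene_id[m], tsv$gene_id)
  expect_equal(vcf$aa_pos[m], tsv$aa_pos)
})

test_that("tileable flag requires a complete non-synonymous protein change", {
  v <- somatic_variants("P1", "1", 1:3, rep("A", 3), rep("G", 3),
                        c("G1", "G2", "G3"),
                        aa_ref = c("A", NA, "L"), aa_pos = c(10L, NA, 5L),
                        aa_alt = c("V", NA, "L"))
  expect_equal(flag_tileable(v)$tileable, c(TRUE, FALSE, FALSE))
})
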