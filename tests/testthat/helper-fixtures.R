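# two replicates with exact mean m and exact sample sd s
signals_with <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))

# array patient whose features have exact means/sds against flat controls
patient_with_features <- function(id, means, sds = rep(0, length(means)),
                                  genes = sprintf("G%03d", seq_along(means)),
                                  controls = signals_with(500, 0),
                                  group = "HGSC") {
  sig <- do.call(rbind, lapply(seq_along(means), function(i) {
    data.frame(gene_id = genes[i], signal = signals_with(means[i], sds[i]),
               stringsAsFactors = FALSE)
  }))
  array_patient(id, sig, controls, group_label = group)
}

repertoire_of <- function(id, genes, group = "HGSC") {
  structure(list(patient_id = id, group_label = group,
                 hits = data.frame(gene_id = genes,
                                   mean_signal = rep(2000, length(genes)),
                                   z_factor = rep(0.9, length(genes)),
                                   stringsAsFactors = FALSE)),
            class = "hit_repertoire")
}

random_variant_table <- function(n, pid = "P1", seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  somatic_variants(
    patient_id = pid,
    chrom = sample(c("1", "2", "X"), n, replace = TRUE),
    pos = sample.int(5e5, n, replace = TRUE),
    ref_allele = ref, alt_allele = alt,
    gene_id = sprintf("G%04d", sample.int(500, n, replace = TRUE)),
    vaf = runif(n), population_af = runif(n, 0, 0.05)
  )
}

random_protein <- function(len) {
  paste(sample(serotarget:::AMINO_ACIDS, len, replace = TRUE), collapse = "")
}

# exhaustive window-enumeration oracle for mutation-centered tiling
tiling_oracle <- function(L, p, lengths = c(8L, 9L, 10L)) {
  out <- list()
  for (k in lengths) {
    for (s in seq_len(max(0L, L - k + 1L))) {
      if (s <= p && p <= s + k - 1L) {
        out[[length(out) + 1L]] <- c(start = s, length = k)
      }
    }
  }
  do.call(rbind, out)
}

# naive all-against-all substring scan oracle for MAP matching,
# comma-joined to the reporting convention
naive_match <- function(peptides, proteome) {
  vapply(peptides, function(p) {
    paste(sort(names(proteome)[vapply(proteome, function(s)
      grepl(p, s, fixed = TRUE), logical(1))]), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
}

# hit-count bounds implied by the generator guarantees: sensitivity >= 0.95
# bounds the misses, FDP <= 0.05 bounds the extras
expect_count_in_recovery_band <- function(count, truth) {
  expect_gte(count, floor(0.95 * truth))
  expect_lte(count, ceiling(truth / 0.95))
}

# small cached synthetic cohort shared across test files
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "serotarget-small-cohort")
      cfg <- cohort_config(n_hgsc = 6L, n_other = 4L, n_features = 200L,
                           responder_pool_size = 60L, n_enriched = 10L,
                           n_proteins = 40L, maps_per_patient = 30L,
                           n_true_snv = 12L, n_decoy_wes_only = 4L,
                           n_decoy_rna_only = 4L, n_decoy_popaf = 3L,
                           n_decoy_lowvaf = 3L, seed = 421L)
      bundle <- generate_cohort(cfg, dir)
      cache <<- list(dir = dir, config = cfg, bundle = bundle)
    }
    cache
  }
})

file_checksums <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  sums <- tools::md5sum(files)
  names(sums) <- sub(paste0("^", dir, "/?"), "", names(sums))
  sums
}
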