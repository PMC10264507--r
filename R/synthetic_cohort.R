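#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the pipeline targets: 9 HGSC and 9
#' non-HGSC patients profiled on protein arrays with duplicate spots, per
#' patient tens of expressed somatic SNVs, a shared reference proteome and
#' per-patient eluted MAP lists. Every stochastic choice flows from `seed`;
#' the same config yields byte-identical bundles.
#'
#' @param n_hgsc,n_other patients per group (defaults 9 and 9).
#' @param n_features array protein features per patient (default 800).
#' @param n_controls pooled negative-control features per array (default 30).
#' @param replicates replicate spots per feature (default 2, duplicate spots).
#' @param background_meanlog,background_sdlog log-normal background signal
#'   distribution (defaults log(300) and 0.4 fluorescence-unit scale).
#' @param spike_fraction fraction of features spiked as true responders per
#'   patient (default 0.1).
#' @param spike_fold fold-change of spiked features over the control mean
#'   (default 8).
#' @param replicate_cv coefficient of variation of replicate noise
#'   (default 0.05).
#' @param n_enriched genes spiked in every HGSC patient only, driving the
#'   group-differential signal (default 20).
#' @param responder_pool_size size of the shared gene pool per group from
#'   which each patient's remaining spikes are drawn, so that targets recur
#'   across patients (default 150).
#' @param n_true_snv true expressed SNVs per patient (default 30; the study
#'   reports 10-67 per patient).
#' @param n_decoy_wes_only,n_decoy_rna_only,n_decoy_popaf,n_decoy_lowvaf
#'   decoy variants per patient, each violating exactly one filter rule
#'   (defaults 10, 10, 5, 5).
#' @param n_proteins proteome size (default 120).
#' @param protein_length_range protein lengths, uniform (default 80-300).
#' @param maps_per_patient eluted MAPs per HGSC patient (default 50).
#' @param map_decoy_fraction fraction of MAP decoys absent from the proteome
#'   (default 0.1).
#' @param n_cta,n_tantigen sizes of the synthetic CTA and TANTIGEN genesets
#'   (defaults 40 and 40).
#' @param n_known_epitopes entries in the synthetic known-epitope list,
#'   drawn from the first HGSC patient's true MAPs (default 12).
#' @param tumor_high_tpm TPM value above which the generator treats a gene as
#'   highly expressed in tumor (default 10).
#' @param expr_high_fraction fraction of genes assigned high tumor/mTEC
#'   expression (default 0.3).
#' @param seed integer random seed (default 1).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_hgsc = 9L, n_other = 9L, n_features = 800L,
                          n_controls = 30L, replicates = 2L,
                          background_meanlog = log(300),
                          background_sdlog = 0.4,
                          spike_fraction = 0.1, spike_fold = 8,
                          replicate_cv = 0.05, n_enriched = 20L,
                          responder_pool_size = 150L,
                          n_true_snv = 30L, n_decoy_wes_only = 10L,
                          n_decoy_rna_only = 10L, n_decoy_popaf = 5L,
                          n_decoy_lowvaf = 5L, n_proteins = 120L,
                          protein_length_range = c(80L, 300L),
                          maps_per_patient = 50L, map_decoy_fraction = 0.1,
                          n_cta = 40L, n_tantigen = 40L,
                          n_known_epitopes = 12L,
                          tumor_high_tpm = 10, expr_high_fraction = 0.3,
                          seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_hgsc", "n_other", "n_features", "n_controls", "replicates",
              "n_enriched", "responder_pool_size", "n_true_snv",
              "n_decoy_wes_only", "n_decoy_rna_only", "n_decoy_popaf",
              "n_decoy_lowvaf", "n_proteins", "maps_per_patient",
              "n_cta", "n_tantigen", "n_known_epitopes")
  for (nm in counts) {
    if (cfg[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  }
  for (nm in c("spike_fraction", "replicate_cv", "map_decoy_fraction",
               "expr_high_fraction")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$replicates < 2L) stop("replicates must be >= 2", call. = FALSE)
  if (cfg$n_controls < 2L) stop("n_controls must be >= 2", call. = FALSE)
  spike_count <- round(cfg$spike_fraction * cfg$n_features)
  if (cfg$n_enriched > spike_count) {
    stop("n_enriched cannot exceed the per-patient spike count (",
         spike_count, ")", call. = FALSE)
  }
  if (cfg$n_proteins > cfg$n_features) {
    stop("n_proteins cannot exceed n_features (gene universe)", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic multi-patient cohort bundle
#'
#' Writes a complete on-disk cohort: a long-format array signal table,
#' gene-level expression tables (tumor TPM, mTEC, OV_HiSeq, OV_PANCAN), per
#' patient WES/RNA variant tables (TSV and minimal VCF), a shared FASTA
#' proteome consistent with every variant's wildtype residue, per-patient MAP
#' lists (true proteome substrings plus scrambled decoys), CTA/TANTIGEN
#' genesets (GMT), a known-epitope list, and a ground-truth ledger (JSON)
#' enumerating every spiked responder, true variant and MAP source so that
#' pipeline outputs are classifiable as TP/FP/FN without ambiguity.
#'
#' @param config a [cohort_config()].
#' @param out_dir directory to write the bundle into (created if needed).
#' @return Invisibly, a list of the file paths written plus the parsed ledger.
#' @export
generate_cohort <- function(config = cohort_config(), out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "expression"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "variants"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  set.seed(config$seed)

  genes <- sprintf("GENE%04d", seq_len(config$n_features))
  hgsc_ids <- sprintf("HGSC%02d", seq_len(config$n_hgsc))
  other_ids <- sprintf("OTH%02d", seq_len(config$n_other))

  # -- responder structure -------------------------------------------------
  enriched_genes <- sample(genes, config$n_enriched)
  rest <- setdiff(genes, enriched_genes)
  pool_a <- sample(rest, config$responder_pool_size)
  pool_b <- sample(setdiff(rest, pool_a), config$responder_pool_size)
  spike_count <- round(config$spike_fraction * config$n_features)
  n_extra <- spike_count - config$n_enriched

  spikes <- list()
  for (pid in hgsc_ids) {
    spikes[[pid]] <- sort(c(enriched_genes, sample(pool_a, n_extra)))
  }
  for (pid in other_ids) {
    spikes[[pid]] <- sort(sample(pool_b, min(n_extra, length(pool_b))))
  }

  # -- array signals -------------------------------------------------------
  control_mean <- exp(config$background_meanlog + config$background_sdlog^2 / 2)
  cv_sdlog <- sqrt(log(1 + config$replicate_cv^2))
  rep_noise <- function(n) {
    stats::rlnorm(n, meanlog = -cv_sdlog^2 / 2, sdlog = cv_sdlog)
  }
  array_rows <- list()
  for (pid in c(hgsc_ids, other_ids)) {
    grp <- if (pid %in% hgsc_ids) "HGSC" else "non-HGSC"
    level <- stats::rlnorm(config$n_features, config$background_meanlog,
                           config$background_sdlog)
    names(level) <- genes
    level[spikes[[pid]]] <- config$spike_fold * control_mean
    feat <- data.frame(
      patient_id = pid, group_label = grp,
      gene_id = rep(genes, each = config$replicates),
      replicate_index = rep(seq_len(config$replicates), config$n_features),
      signal = rep(level, each = config$replicates) *
        rep_noise(config$n_features * config$replicates),
      is_control = FALSE, stringsAsFactors = FALSE
    )
    ctrl_level <- stats::rlnorm(config$n_controls, config$background_meanlog,
                                config$background_sdlog)
    ctrl <- data.frame(
      patient_id = pid, group_label = grp,
      gene_id = rep(sprintf("CTRL%03d", seq_len(config$n_controls)),
                    each = config$replicates),
      replicate_index = rep(seq_len(config$replicates), config$n_controls),
      signal = rep(ctrl_level, each = config$replicates) *
        rep_noise(config$n_controls * config$replicates),
      is_control = TRUE, stringsAsFactors = FALSE
    )
    array_rows[[pid]] <- rbind(feat, ctrl)
  }
  arrays <- do.call(rbind, array_rows)
  arrays$signal <- round(arrays$signal, 3)
  arrays_path <- file.path(out_dir, "arrays.tsv")
  utils::write.table(arrays, arrays_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # -- expression tables ---------------------------------------------------
  n_high <- round(config$expr_high_fraction * config$n_features)
  tumor_high <- sample(genes, n_high)
  tumor <- stats::rlnorm(config$n_features, log(1), 0.5)
  names(tumor) <- genes
  tumor[tumor_high] <- stats::rlnorm(n_high, log(50), 0.5)
  mtec_high <- sample(genes, n_high)
  mtec <- stats::rlnorm(config$n_features, log(1), 0.5)
  names(mtec) <- genes
  mtec[mtec_high] <- stats::rlnorm(n_high, log(50), 0.5)
  hiseq <- stats::setNames(stats::rnorm(config$n_features, 8, 2), genes)
  pancan <- stats::setNames(stats::rnorm(config$n_features, 0, 1), genes)
  expr_paths <- list()
  for (src in c("tumor_TPM", "mTEC", "OV_HiSeq", "OV_PANCAN")) {
    vals <- switch(src, tumor_TPM = tumor, mTEC = mtec,
                   OV_HiSeq = hiseq, OV_PANCAN = pancan)
    p <- file.path(out_dir, "expression", paste0(src, ".tsv"))
    utils::write.table(
      data.frame(gene_id = genes, value = round(unname(vals[genes]), 4)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    expr_paths[[src]] <- p
  }

  # -- proteome ------------------------------------------------------------
  proteome_genes <- unique(c(
    enriched_genes[enriched_genes %in% genes],
    sample(genes, config$n_proteins)
  ))[seq_len(max(config$n_proteins, length(enriched_genes)))]
  prot_len <- sample(seq(config$protein_length_range[1],
                         config$protein_length_range[2]),
                     length(proteome_genes), replace = TRUE)
  proteome <- vapply(prot_len, function(L) {
    paste(sample(AMINO_ACIDS, L, replace = TRUE), collapse = "")
  }, character(1))
  names(proteome) <- proteome_genes
  proteome_path <- file.path(out_dir, "proteome.fasta")
  aa <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(aa, proteome_path)

  # -- variants ------------------------------------------------------------
  ledger_variants <- list()
  variant_paths <- list()
  for (pid in hgsc_ids) {
    vt <- make_patient_variants(pid, config, proteome)
    ledger_variants[[pid]] <- vt$ledger
    base <- file.path(out_dir, "variants", pid)
    write_variants_tsv(vt$wes, paste0(base, "_wes.tsv"))
    write_variants_tsv(vt$rna, paste0(base, "_rna.tsv"))
    write_minimal_vcf(vt$wes, paste0(base, "_wes.vcf"))
    write_minimal_vcf(vt$rna, paste0(base, "_rna.vcf"))
    variant_paths[[pid]] <- base
  }

  # -- MAP lists -----------------------------------------------------------
  ledger_maps <- list()
  map_paths <- list()
  n_decoy_maps <- round(config$map_decoy_fraction * config$maps_per_patient)
  n_true_maps <- config$maps_per_patient - n_decoy_maps
  enriched_in_proteome <- intersect(enriched_genes, proteome_genes)
  n_from_enriched <- if (length(enriched_in_proteome) == 0L) 0L
                     else min(5L, n_true_maps)
  for (pid in hgsc_ids) {
    src_genes <- c(
      sample(enriched_in_proteome, n_from_enriched, replace = TRUE),
      sample(proteome_genes, n_true_maps - n_from_enriched, replace = TRUE)
    )
    true_maps <- vapply(src_genes, function(g) {
      L <- nchar(proteome[[g]])
      k <- sample(8:11, 1)
      s <- sample.int(L - k + 1L, 1)
      substr(proteome[[g]], s, s + k - 1L)
    }, character(1), USE.NAMES = FALSE)
    decoys <- vapply(seq_len(n_decoy_maps),
                     function(i) random_decoy_peptide(proteome), character(1))
    ledger_maps[[pid]] <- list(
      true = data.frame(sequence = true_maps, gene_id = src_genes,
                        stringsAsFactors = FALSE),
      decoys = as.character(decoys)
    )
    p <- file.path(out_dir, "maps", paste0(pid, ".txt"))
    writeLines(c(true_maps, decoys), p)
    map_paths[[pid]] <- p
  }

  # -- genesets and known epitopes ----------------------------------------
  cta <- gene_set("CTA_synthetic", sample(genes, config$n_cta))
  tant <- gene_set("TANTIGEN_synthetic", sample(genes, config$n_tantigen))
  gmt_path <- file.path(out_dir, "genesets.gmt")
  write_gmt(list(cta, tant), gmt_path)
  # known epitopes and auto-antibody-target MAPs are distinct screening
  # categories: prefer peptides from genes outside the enriched repertoire
  ref_maps <- ledger_maps[[hgsc_ids[1]]]$true
  ref_maps <- ref_maps[!duplicated(ref_maps$sequence), ]
  pref <- ref_maps[!(ref_maps$gene_id %in% enriched_genes), ]
  rest <- ref_maps[ref_maps$gene_id %in% enriched_genes, ]
  known <- utils::head(rbind(pref, rest), config$n_known_epitopes)
  known_path <- file.path(out_dir, "known_epitopes.tsv")
  utils::write.table(known, known_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # -- ground-truth ledger -------------------------------------------------
  ledger <- list(
    config = unclass(config),
    genes = genes,
    enriched_genes = sort(enriched_genes),
    spiked_responders = spikes,
    tumor_high_genes = sort(names(tumor)[tumor > config$tumor_high_tpm]),
    variants = ledger_variants,
    maps = ledger_maps,
    cta_genes = cta$genes,
    tantigen_genes = tant$genes,
    known_epitopes = known
  )
  ledger_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(ledger, ledger_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(
    arrays = arrays_path, expression = expr_paths, proteome = proteome_path,
    variants = variant_paths, maps = map_paths, genesets = gmt_path,
    known_epitopes = known_path, ledger_path = ledger_path, ledger = ledger
  ))
}

# one patient's WES/RNA variant tables: true calls satisfy the full cascade,
# each decoy class violates exactly its designated rule
make_patient_variants <- function(pid, config, proteome) {
  n_total <- config$n_true_snv + config$n_decoy_wes_only +
    config$n_decoy_rna_only + config$n_decoy_popaf + config$n_decoy_lowvaf
  gene <- sample(names(proteome), n_total, replace = TRUE)
  aa_pos <- vapply(gene, function(g) sample.int(nchar(proteome[[g]]), 1),
                   integer(1), USE.NAMES = FALSE)
  aa_ref <- substr(proteome[gene], aa_pos, aa_pos)
  aa_alt <- vapply(aa_ref, function(r) sample(setdiff(AMINO_ACIDS, r), 1),
                   character(1), USE.NAMES = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                character(1), USE.NAMES = FALSE)
  cls <- rep(c("true", "wes_only", "rna_only", "popaf", "lowvaf"),
             c(config$n_true_snv, config$n_decoy_wes_only,
               config$n_decoy_rna_only, config$n_decoy_popaf,
               config$n_decoy_lowvaf))
  vaf <- stats::runif(n_total, 0.10, 0.60)
  vaf[cls == "lowvaf"] <- stats::runif(sum(cls == "lowvaf"), 0.01, 0.099)
  popaf <- stats::runif(n_total, 0, 0.005)
  popaf[cls == "popaf"] <- stats::runif(sum(cls == "popaf"), 0.006, 0.5)
  v <- somatic_variants(
    patient_id = pid, chrom = "1", pos = 1000L + 10L * seq_len(n_total),
    ref_allele = ref, alt_allele = alt, gene_id = gene,
    aa_ref = aa_ref, aa_pos = aa_pos, aa_alt = aa_alt,
    vaf = round(vaf, 4), population_af = round(popaf, 6), evidence = ""
  )
  in_wes <- cls != "rna_only"
  in_rna <- cls != "wes_only"
  wes <- v[in_wes, , drop = FALSE]; wes$evidence <- "WES"
  rna <- v[in_rna, , drop = FALSE]; rna$evidence <- "RNA"
  class(wes) <- class(rna) <- c("somatic_variants", "data.frame")
  list(
    wes = wes, rna = rna,
    ledger = list(
      true_keys = variant_key(v)[cls == "true"],
      true_genes = sort(unique(gene[cls == "true"])),
      decoys = split(variant_key(v)[cls != "true"], cls[cls != "true"])
    )
  )
}

# scrambled peptide guaranteed absent from every proteome entry
random_decoy_peptide <- function(proteome, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    k <- sample(8:11, 1)
    pep <- paste(sample(AMINO_ACIDS, k, replace = TRUE), collapse = "")
    if (!any(vapply(proteome, function(p) grepl(pep, p, fixed = TRUE),
                    logical(1)))) {
      return(pep)
    }
  }
  stop("could not generate a decoy peptide absent from the proteome",
       call. = FALSE)
}

# minimal single-sample VCF 4.2 sitelist with AF/POPAF/GENE/PCHANGE INFO keys
write_minimal_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- sprintf("AF=%s;GENE=%s;PCHANGE=%s%d%s%s",
                  variants$vaf, variants$gene_id, variants$aa_ref,
                  variants$aa_pos, variants$aa_alt,
                  ifelse(is.na(variants$population_af), "",
                         paste0(";POPAF=", variants$population_af)))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  variants$chrom, variants$pos, variants$ref_allele,
                  variants$alt_allele, info)
  writeLines(c(header, body), path)
  invisible(path)
}
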