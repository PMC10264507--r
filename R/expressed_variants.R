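#' Construct a somatic variant table
#'
#' Canonical long-format container for protein-coding SNV calls. One row per
#' variant; the protein change is given as wildtype residue, 1-based protein
#' position and mutant residue.
#'
#' @param patient_id,chrom,pos,ref_allele,alt_allele,gene_id vectors of equal
#'   length describing each call (`pos` 1-based genomic).
#' @param aa_ref,aa_pos,aa_alt protein change: wildtype residue, protein
#'   position (1-based), mutant residue. `NA` for non-coding/indel rows.
#' @param vaf variant allele frequency in \[0, 1\].
#' @param population_af gnomAD-style population allele frequency in \[0, 1\];
#'   `NA` when the variant is absent from the population database.
#' @param evidence character vector like "WES", "RNA" or "WES,RNA".
#' @return data.frame of class `somatic_variants`.
#' @export
somatic_variants <- function(patient_id, chrom, pos, ref_allele, alt_allele,
                             gene_id, aa_ref = NA_character_, aa_pos = NA_integer_,
                             aa_alt = NA_character_, vaf = NA_real_,
                             population_af = NA_real_, evidence = "") {
  df <- data.frame(
    patient_id = as.character(patient_id), chrom = as.character(chrom),
    pos = as.integer(pos), ref_allele = as.character(ref_allele),
    alt_allele = as.character(alt_allele), gene_id = as.character(gene_id),
    aa_ref = as.character(aa_ref), aa_pos = as.integer(aa_pos),
    aa_alt = as.character(aa_alt), vaf = as.numeric(vaf),
    population_af = as.numeric(population_af),
    evidence = as.character(evidence),
    stringsAsFactors = FALSE
  )
  if (any(df$ref_allele == df$alt_allele)) {
    stop("ref_allele must differ from alt_allele", call. = FALSE)
  }
  bad_frac <- function(x) !is.na(x) & (x < 0 | x > 1)
  if (any(bad_frac(df$vaf)) || any(bad_frac(df$population_af))) {
    stop("vaf and population_af must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.na(df$aa_pos) & df$aa_pos < 1L)) {
    stop("protein position must be >= 1", call. = FALSE)
  }
  class(df) <- c("somatic_variants", "data.frame")
  df
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref_allele, v$alt_allele, sep = ":")

#' Intersect WES and RNA-seq variant calls
#'
#' Retains the calls present in both the tumor WES and tumor RNA-seq call
#' sets of the same patient, keyed by (chrom, pos, ref, alt). The surviving
#' records carry evidence "WES,RNA" and the WES row's annotations (VAF is
#' taken from the WES call). Symmetric in which keys survive.
#'
#' @param wes,rna `somatic_variants` tables for one patient each.
#' @return `somatic_variants` with the common calls.
#' @export
intersect_calls <- function(wes, rna) {
  stopifnot(inherits(wes, "somatic_variants"), inherits(rna, "somatic_variants"))
  pats <- unique(c(wes$patient_id, rna$patient_id))
  if (length(pats) > 1L) {
    stop("intersect_calls expects a single patient; got: ",
         paste(pats, collapse = ", "), call. = FALSE)
  }
  common <- wes[variant_key(wes) %in% variant_key(rna), , drop = FALSE]
  common$evidence <- rep("WES,RNA", nrow(common))
  rownames(common) <- NULL
  common
}

#' Remove suspected germline variants by population allele frequency
#'
#' Drops variants whose population allele frequency exceeds `af_threshold`
#' (strict inequality: a variant at exactly the threshold is retained).
#' Variants with no population frequency record are retained with a warning.
#'
#' @param variants `somatic_variants` table.
#' @param af_threshold population AF above which a call is treated as a
#'   germline SNP (default 0.005).
#' @return Filtered `somatic_variants`.
#' @export
filter_germline <- function(variants, af_threshold = 0.005) {
  stopifnot(inherits(variants, "somatic_variants"), af_threshold >= 0)
  n_missing <- sum(is.na(variants$population_af))
  if (n_missing > 0) {
    warning(n_missing, " variant(s) lack a population allele frequency; ",
            "retained", call. = FALSE)
  }
  keep <- is.na(variants$population_af) | variants$population_af <= af_threshold
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain variants with sufficient variant allele frequency
#'
#' Keeps variants with VAF greater than or equal to `min_vaf` (inclusive).
#'
#' @param variants `somatic_variants` table.
#' @param min_vaf minimum VAF (default 0.10).
#' @return Filtered `somatic_variants`.
#' @export
filter_vaf <- function(variants, min_vaf = 0.10) {
  stopifnot(inherits(variants, "somatic_variants"),
            min_vaf >= 0, min_vaf <= 1)
  out <- variants[!is.na(variants$vaf) & variants$vaf >= min_vaf, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full expressed-SNV filter cascade
#'
#' Selects the "expressed somatic SNVs" of one tumor: calls common to both
#' WES and RNA-seq, not suspected germline (population AF <= `af_threshold`),
#' with VAF >= `min_vaf`. The two post-intersection filters commute and the
#' cascade is idempotent.
#'
#' @param wes,rna `somatic_variants` for one patient.
#' @param af_threshold,min_vaf see [filter_germline()] and [filter_vaf()].
#' @return `somatic_variants` of expressed SNVs.
#' @export
expressed_snv <- function(wes, rna, af_threshold = 0.005, min_vaf = 0.10) {
  filter_vaf(filter_germline(intersect_calls(wes, rna), af_threshold), min_vaf)
}

#' Per-patient expressed-SNV summary
#'
#' @param variants `somatic_variants` (already filtered).
#' @return data.frame with one row per patient: `patient_id`, `n_snv`, and
#'   `genes` (comma-separated sorted unique mutated genes).
#' @export
summarize_expressed_snv <- function(variants) {
  stopifnot(inherits(variants, "somatic_variants"))
  if (nrow(variants) == 0L) {
    return(data.frame(patient_id = character(), n_snv = integer(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  sp <- split(variants, variants$patient_id)
  out <- data.frame(
    patient_id = names(sp),
    n_snv = vapply(sp, nrow, integer(1)),
    genes = vapply(sp, function(v) paste(sort(unique(v$gene_id)), collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Flag variants tileable into neo-epitopes
#'
#' Only SNVs producing a single amino-acid substitution are carried to peptide
#' tiling; rows lacking a complete protein change, or whose wildtype and
#' mutant residues agree (synonymous), are flagged non-tileable.
#'
#' @param variants `somatic_variants`.
#' @return The table with a logical `tileable` column appended.
#' @export
flag_tileable <- function(variants) {
  stopifnot(inherits(variants, "somatic_variants"))
  variants$tileable <- !is.na(variants$aa_ref) & !is.na(variants$aa_pos) &
    !is.na(variants$aa_alt) & variants$aa_ref != variants$aa_alt
  variants
}

#' Read somatic variants from the TSV dialect
#'
#' Columns: `patient_id`, `chrom`, `pos`, `ref_allele`, `alt_allele`,
#' `gene_id`, `aa_ref`, `aa_pos`, `aa_alt`, `vaf`, `population_af`,
#' `evidence`. Empty `population_af` cells become `NA`.
#'
#' @param path TSV path.
#' @return `somatic_variants` table.
#' @export
read_variants_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  do.call(somatic_variants, tab[intersect(names(tab), c(
    "patient_id", "chrom", "pos", "ref_allele", "alt_allele", "gene_id",
    "aa_ref", "aa_pos", "aa_alt", "vaf", "population_af", "evidence"))])
}

#' Write somatic variants in the TSV dialect
#' @param variants `somatic_variants`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(as.data.frame(variants), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read somatic variants from a VCF file
#'
#' Minimal single-sample VCF ingestion via `vcfR`. VAF is taken from the
#' `AF` INFO field when present, otherwise computed from `AD` (alt depth over
#' total depth) — AF takes precedence. Population allele frequency is read
#' from the `POPAF` INFO field (gnomAD-style), gene and protein change from
#' `GENE` and `PCHANGE` (formatted like `A123T`). Multi-allelic rows are not
#' supported.
#'
#' @param path VCF path.
#' @param patient_id patient the file belongs to.
#' @param evidence evidence label for all rows (e.g. "WES").
#' @return `somatic_variants` table.
#' @export
read_variants_vcf <- function(path, patient_id, evidence = "") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  info_field <- function(key) {
    vals <- vcfR::extract.info(vcf, element = key)
    if (is.null(vals)) rep(NA_character_, nrow(fix)) else vals
  }
  af <- suppressWarnings(as.numeric(info_field("AF")))
  ad <- info_field("AD")
  if (any(is.na(af)) && !all(is.na(ad))) {
    parts <- strsplit(ad, ",", fixed = TRUE)
    ad_vaf <- vapply(parts, function(p) {
      d <- suppressWarnings(as.numeric(p))
      if (length(d) != 2L || anyNA(d) || sum(d) == 0) NA_real_ else d[2] / sum(d)
    }, numeric(1))
    af[is.na(af)] <- ad_vaf[is.na(af)]
  }
  pchange <- info_field("PCHANGE")
  m <- regmatches(pchange, regexec("^([A-Z])([0-9]+)([A-Z])$", pchange))
  aa <- t(vapply(m, function(g) {
    if (length(g) == 4L) g[2:4] else rep(NA_character_, 3L)
  }, character(3)))
  somatic_variants(
    patient_id = patient_id, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref_allele = fix$REF, alt_allele = fix$ALT,
    gene_id = info_field("GENE"),
    aa_ref = aa[, 1], aa_pos = suppressWarnings(as.integer(aa[, 2])),
    aa_alt = aa[, 3], vaf = af,
    population_af = suppressWarnings(as.numeric(info_field("POPAF"))),
    evidence = evidence
  )
}
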