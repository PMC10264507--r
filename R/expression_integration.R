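#' Read a two-column expression table
#'
#' @param path TSV with columns `gene_id` and `value` (TPM for RNA-seq
#'   sources, log/normalized units for TCGA-style sources).
#' @param source label recorded on the table (e.g. "tumor_TPM", "mTEC",
#'   "OV_HiSeq", "OV_PANCAN").
#' @return Named numeric vector of class `expression_table` with attribute
#'   `source`.
#' @export
read_expression_table <- function(path, source) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "value") %in% names(tab)))
  expression_table(stats::setNames(tab$value, tab$gene_id), source)
}

#' Construct an expression table from a named vector
#'
#' @param values named numeric vector (names are gene ids; no duplicates).
#' @param source source label.
#' @return `expression_table`.
#' @export
expression_table <- function(values, source) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (anyDuplicated(names(values))) {
    stop("duplicate gene ids in expression table '", source, "'", call. = FALSE)
  }
  structure(values, source = source, class = "expression_table")
}

#' Apply a gene-alias map to an expression table or gene set
#'
#' Exact symbol matching across datasets is assumed; a user-supplied
#' two-column alias map (columns `alias`, `gene_id`) renames aliased entries
#' before joining. No fuzzy matching is ever performed.
#'
#' @param x `expression_table` or [gene_set()].
#' @param alias_map data.frame with columns `alias`, `gene_id`.
#' @return Object of the same class with aliases renamed.
#' @export
apply_alias_map <- function(x, alias_map) {
  stopifnot(all(c("alias", "gene_id") %in% names(alias_map)))
  rename <- function(ids) {
    hit <- match(ids, alias_map$alias)
    ifelse(is.na(hit), ids, alias_map$gene_id[hit])
  }
  if (inherits(x, "expression_table")) {
    out <- stats::setNames(as.numeric(x), rename(names(x)))
    expression_table(out, attr(x, "source"))
  } else if (inherits(x, "gene_set")) {
    gene_set(x$name, rename(x$genes))
  } else {
    stop("apply_alias_map handles expression_table or gene_set", call. = FALSE)
  }
}

#' Join target genes with expression tables, repertoire scores and genesets
#'
#' One record per target gene. Genes absent from a table are recorded as `NA`
#' (explicit missingness), never as zero; each expression column is named
#' after its table's source label so provenance is retained. Optional geneset
#' membership flags (e.g. CTA, TANTIGEN, shared, enriched) are appended as
#' logical columns.
#'
#' @param targets [gene_set()] of genes to annotate.
#' @param tables list of `expression_table` objects.
#' @param repertoire optional `hit_repertoire`; contributes `z_factor` and
#'   `mean_signal` columns (NA for genes not hit in that patient).
#' @param genesets optional named list of [gene_set()] objects; each becomes a
#'   logical flag column.
#' @return data.frame of annotated targets, one row per gene.
#' @export
join_expression <- function(targets, tables, repertoire = NULL,
                            genesets = list()) {
  stopifnot(inherits(targets, "gene_set"),
            all(vapply(tables, inherits, logical(1), "expression_table")))
  out <- data.frame(gene_id = targets$genes, stringsAsFactors = FALSE)
  if (!is.null(repertoire)) {
    stopifnot(inherits(repertoire, "hit_repertoire"))
    idx <- match(out$gene_id, repertoire$hits$gene_id)
    out$z_factor <- repertoire$hits$z_factor[idx]
    out$mean_signal <- repertoire$hits$mean_signal[idx]
  }
  for (tab in tables) {
    out[[attr(tab, "source")]] <- as.numeric(tab)[match(out$gene_id, names(tab))]
  }
  for (nm in names(genesets)) {
    out[[nm]] <- out$gene_id %in% genesets[[nm]]$genes
  }
  out
}

#' Classify targets into expression quadrants
#'
#' Labels each gene by tumor and thymic (mTEC) expression relative to the
#' supplied cutoffs: "high" requires a value strictly greater than the cutoff,
#' so a gene exactly at a cutoff is "low" on that axis. Genes missing either
#' value are labeled "missing". The labeling is invariant under any strictly
#' increasing transform applied consistently to an axis and its cutoff.
#'
#' @param annotated output of [join_expression()].
#' @param tumor_col,mtec_col column names of the two axes.
#' @param tumor_cut,mtec_cut cutoffs in the units of their columns (no
#'   defaults: the choice of line is the caller's).
#' @return The input with a `quadrant` column (one of "high/high", "high/low",
#'   "low/high", "low/low", "missing"; tumor axis first) and attribute
#'   `quadrant_counts`.
#' @export
classify_quadrants <- function(annotated, tumor_cut, mtec_cut,
                               tumor_col = "tumor_TPM", mtec_col = "mTEC") {
  stopifnot(is.data.frame(annotated),
            all(c(tumor_col, mtec_col) %in% names(annotated)))
  tu <- annotated[[tumor_col]]
  mt <- annotated[[mtec_col]]
  lab <- ifelse(is.na(tu) | is.na(mt), "missing",
         paste(ifelse(tu > tumor_cut, "high", "low"),
               ifelse(mt > mtec_cut, "high", "low"), sep = "/"))
  annotated$quadrant <- lab
  counts <- table(factor(lab, levels = c("high/high", "high/low",
                                         "low/high", "low/low", "missing")))
  attr(annotated, "quadrant_counts") <- counts
  annotated
}

#' Mutated genes within an auto-antibody repertoire
#'
#' Intersects a patient's mutated genes with their auto-antibody hit
#' repertoire and reports the fraction of mutated genes that are hits. With no
#' variants the fraction is undefined and reported as `NA`.
#'
#' @param repertoire `hit_repertoire`.
#' @param variants `somatic_variants` (typically the expressed-SNV set).
#' @return List with `genes` (a [gene_set()] of mutated hit genes) and
#'   `fraction` (mutated genes that are hits / mutated genes, or `NA`).
#' @export
flag_mutated_targets <- function(repertoire, variants) {
  stopifnot(inherits(repertoire, "hit_repertoire"),
            inherits(variants, "somatic_variants"))
  mutated <- unique(variants$gene_id)
  overlap <- intersect(mutated, hit_genes(repertoire))
  list(
    genes = gene_set(paste0(repertoire$patient_id, "_mutated_hits"), overlap),
    fraction = if (length(mutated) == 0L) NA_real_
               else length(overlap) / length(mutated)
  )
}

#' Write annotated targets and a quadrant summary
#'
#' @param annotated output of [classify_quadrants()] (or [join_expression()]).
#' @param tsv_path TSV output for the per-gene table; `NULL` to skip.
#' @param json_path JSON output for the quadrant counts; `NULL` to skip
#'   (requires a `quadrant` column).
#' @return Invisibly, the paths written.
#' @export
write_annotated_targets <- function(annotated, tsv_path = NULL,
                                    json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(annotated, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    counts <- attr(annotated, "quadrant_counts")
    if (is.null(counts)) stop("no quadrant counts; run classify_quadrants first",
                              call. = FALSE)
    jsonlite::write_json(as.list(counts), json_path, auto_unbox = TRUE)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}
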