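#' Match eluted MHC-associated peptides to a proteome
#'
#' Assigns each eluted ligand (MAP) the set of genes whose protein contains
#' the peptide as an exact substring. Matching runs through Biostrings
#' dictionary search; isoleucine/leucine are distinct unless `il_equivalent`
#' collapses them (mass spectrometry cannot distinguish the two, but
#' collapsing is off by default). Peptides with non-standard residues are
#' skipped with a warning; unmatched peptides are retained with an empty match
#' set.
#'
#' @param peptides character vector of peptide sequences (8-11 residues).
#' @param proteome named character vector or `AAStringSet` of protein
#'   sequences; names are gene ids.
#' @param patient_id optional label carried through.
#' @param il_equivalent treat I and L as identical (default FALSE).
#' @return data.frame of class `map_peptides`: `patient_id`, `sequence`,
#'   `matched_genes` (comma-separated, "" if none), `n_matches`.
#' @export
match_to_proteome <- function(peptides, proteome, patient_id = NA_character_,
                              il_equivalent = FALSE) {
  if (inherits(proteome, "AAStringSet")) proteome <- as.character(proteome)
  stopifnot(length(proteome) > 0, !is.null(names(proteome)))
  peptides <- toupper(peptides)
  ok_len <- nchar(peptides) >= 8 & nchar(peptides) <= 11
  if (any(!ok_len)) {
    warning(sum(!ok_len), " peptide(s) outside length 8-11 skipped",
            call. = FALSE)
  }
  standard <- grepl(paste0("^[", paste(AMINO_ACIDS, collapse = ""), "]+$"),
                    peptides)
  if (any(!standard & ok_len)) {
    warning(sum(!standard & ok_len),
            " peptide(s) with non-standard residues skipped", call. = FALSE)
  }
  keep <- ok_len & standard
  pep <- peptides[keep]
  subject <- toupper(proteome)
  if (il_equivalent) {
    pep <- gsub("I", "L", pep, fixed = TRUE)
    subject <- vapply(subject, gsub, character(1), pattern = "I",
                      replacement = "L", fixed = TRUE)
  }
  matches <- rep(list(character()), length(pep))
  if (length(pep) > 0) {
    subj <- Biostrings::AAStringSet(subject)
    for (i in seq_along(pep)) {
      hit <- Biostrings::vcountPattern(pep[i], subj, fixed = TRUE) > 0
      matches[[i]] <- names(proteome)[hit]
    }
  }
  out <- data.frame(
    patient_id = patient_id,
    sequence = pep,
    matched_genes = vapply(matches, function(g)
      paste(sort(unique(g)), collapse = ","), character(1)),
    n_matches = vapply(matches, function(g) length(unique(g)), integer(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("map_peptides", "data.frame")
  out
}

#' Annotate MAPs with geneset membership and known epitopes
#'
#' Sets one logical flag per supplied geneset (via the peptide's matched
#' genes), an `autoAb_target` flag from the auto-antibody repertoire geneset,
#' and `known_A2_epitope` on exact sequence identity with the supplied
#' known-epitope list. Adding genes to a geneset can only add flags, never
#' remove one.
#'
#' @param map_peptides output of [match_to_proteome()].
#' @param genesets named list of [gene_set()] objects (e.g. CTA, TANTIGEN).
#' @param repertoire [gene_set()] of auto-antibody target genes, or `NULL`.
#' @param known_epitopes data.frame with columns `sequence`, `gene_id`, or
#'   `NULL`.
#' @return The table with one logical column per annotation.
#' @export
annotate_maps <- function(map_peptides, genesets = list(), repertoire = NULL,
                          known_epitopes = NULL) {
  stopifnot(inherits(map_peptides, "map_peptides"))
  gene_lists <- strsplit(map_peptides$matched_genes, ",", fixed = TRUE)
  in_set <- function(set) vapply(gene_lists, function(g)
    any(g %in% set$genes), logical(1))
  for (nm in names(genesets)) map_peptides[[nm]] <- in_set(genesets[[nm]])
  if (!is.null(repertoire)) {
    stopifnot(inherits(repertoire, "gene_set"))
    map_peptides$autoAb_target <- in_set(repertoire)
  }
  if (!is.null(known_epitopes)) {
    stopifnot(all(c("sequence", "gene_id") %in% names(known_epitopes)))
    map_peptides$known_A2_epitope <- map_peptides$sequence %in%
      toupper(known_epitopes$sequence)
  }
  map_peptides
}

#' Assemble a MAP screening panel
#'
#' Mirrors the selection of a 12-peptide re-stimulation pool: up to
#' `max_known` MAPs flagged as known MHC class I epitopes, plus up to
#' `max_autoab` MAPs from auto-antibody target proteins that are not already
#' in the known-epitope slice. Peptides are deduplicated by sequence;
#' selection order is deterministic — known epitopes first, within each
#' category by first matched gene name then sequence — so reruns and input
#' reorderings give identical panels.
#'
#' @param annotated output of [annotate_maps()] with `known_A2_epitope` and
#'   `autoAb_target` columns.
#' @param max_known,max_autoab category caps (defaults 10 and 2).
#' @return `map_peptides` panel with a `category` column.
#' @export
select_map_panel <- function(annotated, max_known = 10L, max_autoab = 2L) {
  stopifnot(inherits(annotated, "map_peptides"),
            all(c("known_A2_epitope", "autoAb_target") %in% names(annotated)))
  dedup_sort <- function(df) {
    if (nrow(df) == 0L) return(df)
    first_gene <- vapply(strsplit(df$matched_genes, ",", fixed = TRUE),
                         function(g) if (length(g)) g[1] else "", character(1))
    df <- df[order(first_gene, df$sequence), , drop = FALSE]
    df[!duplicated(df$sequence), , drop = FALSE]
  }
  known <- dedup_sort(annotated[annotated$known_A2_epitope, , drop = FALSE])
  known <- utils::head(known, max_known)
  auto <- annotated[annotated$autoAb_target &
                      !(annotated$sequence %in% known$sequence), , drop = FALSE]
  auto <- utils::head(dedup_sort(auto), max_autoab)
  panel <- rbind(known, auto)
  panel$category <- rep(c("known_epitope", "autoAb_target"),
                        c(nrow(known), nrow(auto)))
  if (nrow(panel) == 0L) {
    warning("no peptides available for the MAP panel", call. = FALSE)
  }
  rownames(panel) <- NULL
  class(panel) <- c("map_peptides", "data.frame")
  panel
}

#' Read a plain-text peptide list
#'
#' One peptide sequence per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path file path.
#' @return Character vector of uppercase sequences.
#' @export
read_peptide_list <- function(path) {
  lines <- trimws(readLines(path))
  toupper(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Read a proteome FASTA as a named character vector
#'
#' Sequence names are the first whitespace-delimited token of each header
#' (expected to be the gene id or mappable through an alias map).
#'
#' @param path FASTA path.
#' @return Named character vector of protein sequences.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Write a MAP panel as TSV and FASTA
#' @param panel output of [select_map_panel()].
#' @param tsv_path,fasta_path output paths; either may be `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_map_panel <- function(panel, tsv_path = NULL, fasta_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(panel), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::AAStringSet(panel$sequence)
    names(seqs) <- sprintf("%s|%s", panel$category,
                           sub(",.*", "", panel$matched_genes))
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  invisible(list(tsv = tsv_path, fasta = fasta_path))
}
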