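AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Kyte-Doolittle hydropathy index
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Grand average of hydropathy (GRAVY) of a peptide
#'
#' Mean Kyte-Doolittle hydropathy index over the residues. Used as the
#' synthesizability screen in panel selection: very hydrophobic peptides are
#' difficult to synthesize and load onto MHC reagents.
#'
#' @param peptide character vector of uppercase peptide sequences.
#' @return Numeric GRAVY value per peptide.
#' @export
gravy <- function(peptide) {
  vapply(strsplit(toupper(peptide), ""), function(aa) {
    h <- KYTE_DOOLITTLE[aa]
    if (anyNA(h)) stop("non-standard residue in peptide", call. = FALSE)
    mean(h)
  }, numeric(1))
}

#' Tile mutation-centered candidate peptides
#'
#' Enumerates, for each requested length k, every k-mer window of the protein
#' that contains the mutated position and lies fully within the sequence
#' (windows at the termini are truncated away, not padded). Each window is
#' emitted as a mutant/wildtype peptide pair differing at exactly the mutated
#' residue. An interior mutation with at least 9 residues on both flanks
#' yields 8 + 9 + 10 = 27 pairs for the default lengths.
#'
#' @param protein_sequence wildtype protein sequence (uppercase string).
#' @param aa_ref,aa_pos,aa_alt the substitution: wildtype residue, 1-based
#'   protein position, mutant residue. `aa_ref` must match the sequence at
#'   `aa_pos`, otherwise the annotation and sequence disagree and an error is
#'   raised.
#' @param lengths peptide lengths to tile (default `c(8, 9, 10)`).
#' @param gene_id,patient_id carried through to the output.
#' @return data.frame of class `epitope_candidates`: one row per window with
#'   `mutant_peptide`, `wildtype_peptide`, `protein_start`, `length`,
#'   `mut_position_in_peptide`.
#' @export
tile_peptides <- function(protein_sequence, aa_ref, aa_pos, aa_alt,
                          lengths = c(8L, 9L, 10L),
                          gene_id = NA_character_, patient_id = NA_character_) {
  seq <- toupper(protein_sequence)
  L <- nchar(seq)
  aa_pos <- as.integer(aa_pos)
  if (aa_pos < 1L || aa_pos > L) {
    stop("mutation position ", aa_pos, " outside protein of length ", L,
         call. = FALSE)
  }
  found <- substr(seq, aa_pos, aa_pos)
  if (found != toupper(aa_ref)) {
    stop("annotation/sequence mismatch: expected wildtype '", aa_ref,
         "' at position ", aa_pos, " but sequence has '", found, "'",
         call. = FALSE)
  }
  if (toupper(aa_ref) == toupper(aa_alt)) {
    stop("synonymous change (", aa_ref, " -> ", aa_alt, ") cannot be tiled",
         call. = FALSE)
  }
  mut_seq <- seq
  substr(mut_seq, aa_pos, aa_pos) <- toupper(aa_alt)
  rows <- lapply(sort(as.integer(lengths)), function(k) {
    starts <- seq.int(max(1L, aa_pos - k + 1L), min(aa_pos, L - k + 1L))
    starts <- starts[starts >= 1L & starts + k - 1L <= L]
    if (length(starts) == 0L) return(NULL)
    data.frame(
      patient_id = patient_id, gene_id = gene_id,
      aa_ref = toupper(aa_ref), aa_pos = aa_pos, aa_alt = toupper(aa_alt),
      mutant_peptide = substring(mut_seq, starts, starts + k - 1L),
      wildtype_peptide = substring(seq, starts, starts + k - 1L),
      protein_start = starts, length = k,
      mut_position_in_peptide = aa_pos - starts + 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), gene_id = character(),
                      aa_ref = character(), aa_pos = integer(),
                      aa_alt = character(), mutant_peptide = character(),
                      wildtype_peptide = character(), protein_start = integer(),
                      length = integer(), mut_position_in_peptide = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("epitope_candidates", "data.frame")
  out
}

#' Deterministic toy MHC predictor
#'
#' A self-contained predictor satisfying the predictor contract: an `affinity`
#' function returning a predicted IC50 in nM (> 0) and a `processing_score`
#' function returning a combined processing/binding score in \[0, 1\], both
#' deterministic for fixed inputs and defined for peptide lengths 8-10. The
#' scores come from fixed per-position residue weight matrices (one per
#' length, derived from a closed-form trigonometric hash of residue index,
#' position, length and allele), with affinity the exponential transform of
#' the summed weights. It stands in for external neural-network predictors in
#' tests and synthetic runs; real predictions can be supplied through
#' [tabular_predictor()] or any list with the same two functions.
#'
#' @return List of class `mhc_predictor` with elements `name`,
#'   `affinity(peptide, allele)` and `processing_score(peptide, allele)`.
#' @export
toy_predictor <- function() {
  weight <- function(peptide, allele, phase) {
    aa_idx <- match(strsplit(toupper(peptide), "")[[1]], AMINO_ACIDS)
    if (anyNA(aa_idx)) stop("non-standard residue in peptide", call. = FALSE)
    k <- length(aa_idx)
    allele_off <- sum(utf8ToInt(allele)) %% 97
    pos <- seq_len(k)
    sum(sin(aa_idx * 2.399963 + pos * 0.711 + k * 1.618 + allele_off + phase))
  }
  structure(list(
    name = "toy",
    affinity = function(peptide, allele = "HLA-A*02:01") {
      vapply(peptide, function(p) {
        # map summed weights to a plausible IC50 range (~1 nM - ~50 uM)
        exp(5.5 + 1.3 * weight(p, allele, phase = 0))
      }, numeric(1), USE.NAMES = FALSE)
    },
    processing_score = function(peptide, allele = "HLA-A*02:01") {
      vapply(peptide, function(p) {
        stats::plogis(0.9 * weight(p, allele, phase = 2.07))
      }, numeric(1), USE.NAMES = FALSE)
    }
  ), class = "mhc_predictor")
}

#' Predictor backed by a precomputed score table
#'
#' Adapter for externally computed predictions (e.g. parsed from the tabular
#' output of standalone NetMHCpan/NetCTLpan runs). Peptides absent from the
#' table score `NA` and are flagged unscored downstream.
#'
#' @param table data.frame with columns `peptide`, `allele`, `affinity_nM`,
#'   `combined_score`.
#' @return An `mhc_predictor`.
#' @export
tabular_predictor <- function(table) {
  stopifnot(all(c("peptide", "allele", "affinity_nM", "combined_score") %in%
                  names(table)))
  key <- paste(toupper(table$peptide), table$allele)
  lookup <- function(peptide, allele, col) {
    vals <- table[[col]][match(paste(toupper(peptide), allele), key)]
    as.numeric(vals)
  }
  structure(list(
    name = "tabular",
    affinity = function(peptide, allele = "HLA-A*02:01")
      lookup(peptide, allele, "affinity_nM"),
    processing_score = function(peptide, allele = "HLA-A*02:01")
      lookup(peptide, allele, "combined_score")
  ), class = "mhc_predictor")
}

#' Score candidate peptide pairs through a predictor
#'
#' Populates mutant and wildtype predicted affinities (IC50, nM) and the
#' mutant combined processing score. Candidates the predictor cannot score
#' (e.g. missing from a tabular predictor) are flagged `unscored` and kept.
#'
#' @param candidates `epitope_candidates` from [tile_peptides()].
#' @param predictor an `mhc_predictor` (see [toy_predictor()]).
#' @param allele MHC allele name passed to the predictor.
#' @return The candidates with `allele`, `mut_affinity_nM`, `wt_affinity_nM`,
#'   `combined_score`, `unscored` columns appended.
#' @export
score_candidates <- function(candidates, predictor, allele = "HLA-A*02:01") {
  stopifnot(inherits(candidates, "epitope_candidates"),
            inherits(predictor, "mhc_predictor"))
  n <- nrow(candidates)
  candidates$allele <- rep(allele, n)
  if (n == 0L) {
    candidates$mut_affinity_nM <- numeric()
    candidates$wt_affinity_nM <- numeric()
    candidates$combined_score <- numeric()
    candidates$unscored <- logical()
    return(candidates)
  }
  candidates$mut_affinity_nM <- predictor$affinity(candidates$mutant_peptide, allele)
  candidates$wt_affinity_nM <- predictor$affinity(candidates$wildtype_peptide, allele)
  candidates$combined_score <- predictor$processing_score(candidates$mutant_peptide,
                                                          allele)
  candidates$unscored <- is.na(candidates$mut_affinity_nM) |
    is.na(candidates$wt_affinity_nM) | is.na(candidates$combined_score)
  if (any(candidates$unscored)) {
    warning(sum(candidates$unscored),
            " candidate(s) could not be scored; flagged unscored", call. = FALSE)
  }
  candidates
}

#' Apply the neo-epitope filter cascade
#'
#' Three independent filters mirror the selection of predicted neo-epitopes:
#' predicted mutant affinity below `max_affinity_nM` (IC50 < 500 nM by
#' default), combined processing score above `min_combined_score` (> 0.6 by
#' default), and — when `require_mut_stronger` — a mutant that binds more
#' strongly than its wildtype counterpart (numerically lower IC50). Per-filter
#' verdict columns are retained so each verdict can be recomputed from the
#' stored scores.
#'
#' @param scored output of [score_candidates()].
#' @param max_affinity_nM strict upper bound on mutant IC50 (default 500).
#' @param min_combined_score strict lower bound on combined score (default 0.6).
#' @param require_mut_stronger require mutant IC50 < wildtype IC50
#'   (default TRUE).
#' @param keep_failing keep failing rows (with verdicts) instead of dropping
#'   them (default FALSE).
#' @return The candidates with `pass_affinity`, `pass_score`, `pass_wt`,
#'   `pass_all` columns; rows restricted to `pass_all` unless `keep_failing`.
#' @export
filter_candidates <- function(scored, max_affinity_nM = 500,
                              min_combined_score = 0.6,
                              require_mut_stronger = TRUE,
                              keep_failing = FALSE) {
  stopifnot(inherits(scored, "epitope_candidates"),
            !is.null(scored$mut_affinity_nM))
  scored$pass_affinity <- !is.na(scored$mut_affinity_nM) &
    scored$mut_affinity_nM < max_affinity_nM
  scored$pass_score <- !is.na(scored$combined_score) &
    scored$combined_score > min_combined_score
  scored$pass_wt <- if (require_mut_stronger) {
    !is.na(scored$mut_affinity_nM) & !is.na(scored$wt_affinity_nM) &
      scored$mut_affinity_nM < scored$wt_affinity_nM
  } else rep(TRUE, nrow(scored))
  scored$pass_all <- scored$pass_affinity & scored$pass_score & scored$pass_wt
  out <- if (keep_failing) scored else scored[scored$pass_all, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select a ranked per-patient epitope panel
#'
#' From the passing candidates, removes peptides whose Kyte-Doolittle GRAVY
#' exceeds `hydropathy_limit` (unset = no hydropathy screen), keeps the best
#' candidate per (gene, mutation, length), ranks by mutant affinity ascending
#' (ties: higher combined score, then lexicographic mutant peptide), and
#' returns at most `n_max` peptides. A warning is raised when fewer than
#' `n_min` survive, matching the practice of synthesizing 2-9 top-scoring
#' peptides per patient.
#'
#' @param passing filtered `epitope_candidates`.
#' @param n_min,n_max panel size bounds (defaults 2 and 9).
#' @param hydropathy_limit maximum GRAVY (default 2.0); `NULL` disables the
#'   screen.
#' @return The ranked panel (`epitope_candidates` with a `rank` column).
#' @export
select_panel <- function(passing, n_min = 2L, n_max = 9L,
                         hydropathy_limit = 2.0) {
  stopifnot(inherits(passing, "epitope_candidates"), n_min <= n_max)
  out <- passing
  if (!is.null(hydropathy_limit) && nrow(out) > 0L) {
    out <- out[gravy(out$mutant_peptide) <= hydropathy_limit, , drop = FALSE]
  }
  if (nrow(out) > 0L) {
    ord <- order(out$mut_affinity_nM, -out$combined_score, out$mutant_peptide)
    out <- out[ord, , drop = FALSE]
    # one candidate per (gene, mutation, length): first (= best-ranked) wins
    mut_key <- paste(out$gene_id, out$aa_ref, out$aa_pos, out$aa_alt,
                     out$length, sep = "|")
    out <- out[!duplicated(mut_key), , drop = FALSE]
    out <- utils::head(out, n_max)
  }
  if (nrow(out) < n_min) {
    warning("panel has ", nrow(out), " peptide(s), below the requested minimum ",
            n_min, call. = FALSE)
  }
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write an epitope panel as TSV and FASTA
#'
#' @param panel output of [select_panel()].
#' @param tsv_path,fasta_path output paths; either may be `NULL` to skip.
#' @return Invisibly, a list of the paths written.
#' @export
write_panel <- function(panel, tsv_path = NULL, fasta_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(panel), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::AAStringSet(panel$mutant_peptide)
    names(seqs) <- sprintf("%s|%s%d%s|len%d",
                           panel$gene_id, panel$aa_ref, panel$aa_pos,
                           panel$aa_alt, panel$length)
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  invisible(list(tsv = tsv_path, fasta = fasta_path))
}
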