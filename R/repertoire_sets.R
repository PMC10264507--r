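#' Construct a named gene set
#'
#' @param name non-empty set name.
#' @param genes character vector of gene ids; duplicates are collapsed.
#' @return A `gene_set` object (list with `name` and sorted unique `genes`).
#' @export
gene_set <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  genes <- genes[!is.na(genes) & nzchar(genes)]
  structure(list(name = name, genes = sort(unique(genes))), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set>", x$name, "-", length(x$genes), "genes\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Targets shared by at least `min_patients` repertoires
#'
#' The cross-patient "shared repertoire": genes called as hits in at least
#' `min_patients` of the supplied repertoires. `min_patients = 1` gives the
#' union, `min_patients = length(repertoires)` the intersection; the result is
#' monotone non-increasing in `min_patients`.
#'
#' @param repertoires list of `hit_repertoire` objects.
#' @param min_patients minimum number of repertoires a gene must appear in.
#' @param name name for the returned set.
#' @return A [gene_set()].
#' @export
shared_targets <- function(repertoires, min_patients,
                           name = sprintf("shared_ge%d", min_patients)) {
  stopifnot(length(repertoires) >= 1L,
            all(vapply(repertoires, inherits, logical(1), "hit_repertoire")))
  min_patients <- as.integer(min_patients)
  if (min_patients < 1L || min_patients > length(repertoires)) {
    stop("min_patients must be between 1 and the number of repertoires (",
         length(repertoires), ")", call. = FALSE)
  }
  counts <- table(unlist(lapply(repertoires, hit_genes), use.names = FALSE))
  gene_set(name, names(counts)[counts >= min_patients])
}

#' Union of the enriched and shared repertoires
#'
#' The combined target repertoire: genes either enriched in the case group or
#' shared across case patients. Plain set union; |A ∪ B| = |A| + |B| − |A ∩ B|.
#'
#' @param enriched,shared [gene_set()] objects.
#' @param name name for the combined set.
#' @return A [gene_set()].
#' @export
combine_repertoire <- function(enriched, shared, name = "combined") {
  stopifnot(inherits(enriched, "gene_set"), inherits(shared, "gene_set"))
  gene_set(name, union(enriched$genes, shared$genes))
}

#' Overlap between two gene sets
#'
#' Intersection count together with the percentage of set A that overlaps,
#' reported to one decimal place (round-half-even).
#'
#' @param a,b [gene_set()] objects.
#' @return data.frame with `set_a_name`, `set_b_name`, `n_a`, `n_b`,
#'   `n_overlap`, `percent_of_a`.
#' @export
overlap_stats <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  n_overlap <- length(intersect(a$genes, b$genes))
  if (length(a$genes) == 0L) {
    warning("set A ('", a$name, "') is empty; percent_of_a reported as 0",
            call. = FALSE)
    pct <- 0
  } else {
    pct <- round(100 * n_overlap / length(a$genes), 1)
  }
  data.frame(
    set_a_name = a$name, set_b_name = b$name,
    n_a = length(a$genes), n_b = length(b$genes),
    n_overlap = n_overlap, percent_of_a = pct,
    stringsAsFactors = FALSE
  )
}

#' Group-differential auto-antibody targets
#'
#' Per-gene two-sided Welch t-test on per-array median-normalized
#' log(signal + 1), with Benjamini-Hochberg adjustment across genes. Replicate
#' spots are first averaged per gene within each array; each array's log
#' signals are then shifted so its median matches the cohort grand median.
#' A gene is "enriched" in group A when `q_value <= alpha` and its group-A
#' mean exceeds its group-B mean.
#'
#' @param group_a,group_b lists of [array_patient()] objects (>= 2 each).
#' @param alpha FDR level used for the `enriched` flag (default 0.05).
#' @return data.frame (`gene_id`, `effect`, `p_value`, `q_value`, `enriched`);
#'   `effect` is mean(normalized log signal in A) - mean(in B). Genes with
#'   fewer than 2 values in either group are dropped.
#' @export
differential_targets <- function(group_a, group_b, alpha = 0.05) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L,
            all(vapply(c(group_a, group_b), inherits, logical(1), "array_patient")),
            alpha > 0, alpha <= 1)
  mat_a <- gene_by_patient_log(group_a)
  mat_b <- gene_by_patient_log(group_b)
  grand_median <- stats::median(c(unlist(mat_a), unlist(mat_b)), na.rm = TRUE)
  mat_a <- median_shift(mat_a, grand_median)
  mat_b <- median_shift(mat_b, grand_median)
  genes <- sort(union(rownames(mat_a), rownames(mat_b)))
  res <- lapply(genes, function(g) {
    xa <- if (g %in% rownames(mat_a)) mat_a[g, ] else numeric()
    xb <- if (g %in% rownames(mat_b)) mat_b[g, ] else numeric()
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L) return(NULL)
    eff <- mean(xa) - mean(xb)
    p <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      # constant within both groups: identical -> no evidence; different -> sure
      if (mean(xa) == mean(xb)) 1 else 0
    } else {
      stats::t.test(xa, xb)$p.value
    }
    data.frame(gene_id = g, effect = eff, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(gene_id = character(), effect = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      enriched = logical()))
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$q_value <= alpha & out$effect > 0
  rownames(out) <- NULL
  out
}

# gene x patient matrix of log(mean replicate signal + 1)
gene_by_patient_log <- function(patients) {
  per_pat <- lapply(patients, function(p) {
    m <- vapply(split(p$signals$signal, p$signals$gene_id), mean, numeric(1))
    log(m + 1)
  })
  genes <- sort(unique(unlist(lapply(per_pat, names))))
  mat <- vapply(per_pat, function(v) v[genes], numeric(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, vapply(patients, `[[`, character(1),
                                              "patient_id")))
  mat
}

# shift each array (column) so its median equals the cohort grand median
median_shift <- function(mat, grand_median) {
  meds <- apply(mat, 2, stats::median, na.rm = TRUE)
  sweep(mat, 2, meds - grand_median, "-")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  out <- lapply(names(sets), function(nm) gene_set(nm, sets[[nm]]))
  names(out) <- names(sets)
  out
}

#' Write gene sets to a GMT file
#'
#' Standard three-plus-column GMT: set name, description ("na"), then one gene
#' per column.
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(all(vapply(sets, inherits, logical(1), "gene_set")))
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
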