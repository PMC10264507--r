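#' Z-Factor of an array feature against the negative controls
#'
#' The Z-Factor is a signal-to-noise statistic used to call significant
#' auto-antibody reactivity on high-density protein arrays:
#' \deqn{Z = 1 - \frac{3\sigma_s + 3\sigma_{c-}}{|\mu_s - \mu_{c-}|}}
#' where \eqn{\mu_s, \sigma_s} are the mean and sample standard deviation of
#' the replicate signals of the target protein feature and
#' \eqn{\mu_{c-}, \sigma_{c-}} those of the pooled negative-control features.
#' Z is at most 1 (exactly 1 only when both standard deviations vanish) and
#' decreases as either source of noise grows relative to the separation of
#' feature and control means.
#'
#' @param feature_signals numeric vector of replicate fluorescence intensities
#'   for one array feature (length >= 2, all >= 0).
#' @param control_signals numeric vector of pooled negative-control replicate
#'   intensities (length >= 2, all >= 0).
#' @return A single numeric Z-Factor (unitless, <= 1).
#' @examples
#' compute_z_factor(c(2000, 2000), c(500, 500))  # both sd 0 -> Z = 1
#' @export
compute_z_factor <- function(feature_signals, control_signals) {
  check_signals(feature_signals, "feature_signals")
  check_signals(control_signals, "control_signals")
  mu_s <- mean(feature_signals)
  mu_c <- mean(control_signals)
  if (mu_s == mu_c) {
    stop("degenerate Z-Factor: feature mean equals control mean (",
         mu_s, "); signal indistinguishable from controls", call. = FALSE)
  }
  1 - (3 * stats::sd(feature_signals) + 3 * stats::sd(control_signals)) /
    abs(mu_s - mu_c)
}

check_signals <- function(x, what) {
  if (!is.numeric(x) || length(x) < 2) {
    stop(what, " must contain at least 2 replicate signals", call. = FALSE)
  }
  if (anyNA(x) || any(x < 0)) {
    stop(what, " must be non-negative and free of NA", call. = FALSE)
  }
  invisible(x)
}

#' Construct an array patient
#'
#' Bundles one patient's protein-array measurement: a long table of
#' per-feature replicate signals and the pooled negative-control replicates.
#'
#' @param patient_id scalar character identifier.
#' @param signals data.frame with columns `gene_id`, `signal` (one row per
#'   replicate spot; features must have >= 2 replicates).
#' @param control_signals numeric vector of pooled negative-control replicate
#'   signals (length >= 2).
#' @param group_label cohort group, e.g. "HGSC", "non-HGSC".
#' @return An object of class `array_patient`.
#' @export
array_patient <- function(patient_id, signals, control_signals,
                          group_label = NA_character_) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L, nzchar(patient_id))
  stopifnot(is.data.frame(signals), all(c("gene_id", "signal") %in% names(signals)))
  check_signals(control_signals, "control_signals")
  if (nrow(signals) > 0 && (anyNA(signals$signal) || any(signals$signal < 0))) {
    stop("feature signals must be non-negative and free of NA", call. = FALSE)
  }
  structure(
    list(patient_id = patient_id,
         group_label = group_label,
         signals = signals[c("gene_id", "signal")],
         control_signals = as.numeric(control_signals)),
    class = "array_patient"
  )
}

#' @export
print.array_patient <- function(x, ...) {
  cat("<array_patient>", x$patient_id,
      if (!is.na(x$group_label)) paste0("[", x$group_label, "]"), "\n")
  cat("  features:", length(unique(x$signals$gene_id)),
      " control replicates:", length(x$control_signals), "\n")
  invisible(x)
}

#' Call the per-patient auto-antibody hit repertoire
#'
#' A feature is a significant "hit" when its mean replicate signal exceeds
#' `signal_threshold` fluorescence units and its Z-Factor against the pooled
#' negative controls exceeds `z_threshold` (both strict inequalities).
#' Features whose mean equals the control mean have an undefined Z-Factor;
#' they are excluded from the repertoire with a warning rather than aborting
#' the patient.
#'
#' @param patient an [array_patient()].
#' @param signal_threshold minimum mean fluorescence (default 1000 units).
#' @param z_threshold minimum Z-Factor (default 0.4, unitless).
#' @return A `hit_repertoire`: list with `patient_id`, `group_label` and a
#'   data.frame `hits` (columns `gene_id`, `mean_signal`, `z_factor`).
#' @export
call_hits <- function(patient, signal_threshold = 1000, z_threshold = 0.4) {
  stopifnot(inherits(patient, "array_patient"),
            is.finite(signal_threshold), is.finite(z_threshold))
  sig <- patient$signals
  if (nrow(sig) == 0L) {
    warning("patient ", patient$patient_id, " has no array features; ",
            "empty repertoire", call. = FALSE)
    return(new_hit_repertoire(patient, empty_hits()))
  }
  by_gene <- split(sig$signal, sig$gene_id)
  n_rep <- lengths(by_gene)
  if (any(n_rep < 2L)) {
    stop("features with fewer than 2 replicates: ",
         paste(utils::head(names(by_gene)[n_rep < 2L], 5L), collapse = ", "),
         call. = FALSE)
  }
  mu_c <- mean(patient$control_signals)
  sd_c <- stats::sd(patient$control_signals)
  mean_signal <- vapply(by_gene, mean, numeric(1))
  sd_signal <- vapply(by_gene, stats::sd, numeric(1))
  degenerate <- mean_signal == mu_c
  if (any(degenerate)) {
    warning(sum(degenerate), " feature(s) with mean equal to the control mean ",
            "excluded (undefined Z-Factor): ",
            paste(utils::head(names(by_gene)[degenerate], 5L), collapse = ", "),
            call. = FALSE)
  }
  z <- ifelse(degenerate, NA_real_,
              1 - (3 * sd_signal + 3 * sd_c) / abs(mean_signal - mu_c))
  keep <- !degenerate & mean_signal > signal_threshold & z > z_threshold
  hits <- data.frame(
    gene_id = names(by_gene)[keep],
    mean_signal = unname(mean_signal[keep]),
    z_factor = unname(z[keep]),
    stringsAsFactors = FALSE
  )
  hits <- hits[order(hits$gene_id), , drop = FALSE]
  rownames(hits) <- NULL
  new_hit_repertoire(patient, hits)
}

empty_hits <- function() {
  data.frame(gene_id = character(), mean_signal = numeric(),
             z_factor = numeric(), stringsAsFactors = FALSE)
}

new_hit_repertoire <- function(patient, hits) {
  structure(
    list(patient_id = patient$patient_id,
         group_label = patient$group_label,
         hits = hits),
    class = "hit_repertoire"
  )
}

#' @export
print.hit_repertoire <- function(x, ...) {
  cat("<hit_repertoire>", x$patient_id, "-", nrow(x$hits), "hits\n")
  invisible(x)
}

#' Genes in a hit repertoire
#' @param repertoire a `hit_repertoire`.
#' @return Character vector of hit gene ids.
#' @export
hit_genes <- function(repertoire) {
  stopifnot(inherits(repertoire, "hit_repertoire"))
  repertoire$hits$gene_id
}

#' Summarize hit counts across a cohort
#'
#' One row per patient with its hit count and group label, plus the per-group
#' mean hit count as an attribute and in the printout.
#'
#' @param repertoires list of `hit_repertoire` objects.
#' @return data.frame (`patient_id`, `group_label`, `n_hits`) with attribute
#'   `group_means` (named numeric).
#' @export
summarize_cohort <- function(repertoires) {
  stopifnot(length(repertoires) >= 1L,
            all(vapply(repertoires, inherits, logical(1), "hit_repertoire")))
  tab <- data.frame(
    patient_id = vapply(repertoires, `[[`, character(1), "patient_id"),
    group_label = vapply(repertoires, `[[`, character(1), "group_label"),
    n_hits = vapply(repertoires, function(r) nrow(r$hits), integer(1)),
    stringsAsFactors = FALSE
  )
  attr(tab, "group_means") <- tapply(tab$n_hits, tab$group_label, mean)
  tab
}

#' Read a long-format protein-array signal table
#'
#' Expected columns: `patient_id`, `gene_id`, `replicate_index`, `signal`,
#' `is_control` (logical or 0/1). Control rows are pooled per patient into the
#' negative-control set; their `gene_id` is ignored for hit calling.
#'
#' @param path TSV file path.
#' @return Named list of [array_patient()] objects (one per patient).
#' @export
read_array_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "gene_id", "replicate_index", "signal", "is_control")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("array table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tab$is_control <- as.logical(tab$is_control)
  split_tab <- split(tab, tab$patient_id)
  pats <- lapply(split_tab, function(pt) {
    grp <- if ("group_label" %in% names(pt)) pt$group_label[1] else NA_character_
    array_patient(
      patient_id = pt$patient_id[1],
      signals = pt[!pt$is_control, c("gene_id", "signal")],
      control_signals = pt$signal[pt$is_control],
      group_label = grp
    )
  })
  pats
}

#' Write hit repertoires as a TSV table
#'
#' @param repertoires list of `hit_repertoire` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(repertoires, path) {
  rows <- lapply(repertoires, function(r) {
    if (nrow(r$hits) == 0L) return(NULL)
    cbind(patient_id = r$patient_id, r$hits)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), gene_id = character(),
                      mean_signal = numeric(), z_factor = numeric())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
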