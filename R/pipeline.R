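PIPELINE_STAGES <- c("seromics", "repertoire", "variants", "neoepitope",
                     "integrate", "maps")

RUN_CONFIG_KEYS <- c(
  "version", "seed", "out_dir",
  "arrays", "expression", "variants_dir", "proteome", "genesets",
  "maps_dir", "known_epitopes",
  "case_group",
  "signal_threshold", "z_threshold", "min_patients", "fdr_alpha",
  "af_threshold", "min_vaf",
  "max_affinity_nM", "min_combined_score", "require_mut_stronger",
  "panel_n_min", "panel_n_max", "hydropathy_limit", "allele",
  "tumor_cut", "mtec_cut",
  "map_max_known", "map_max_autoab"
)

#' Default pipeline run configuration
#'
#' Builds a run configuration pointing at a cohort bundle laid out as written
#' by [generate_cohort()]. All stage thresholds carry the pipeline defaults
#' (hit rule signal > 1000 and Z > 0.4; shared rule >= 4 patients; FDR 0.05;
#' germline population AF cutoff 0.005; VAF >= 0.10; epitope filters
#' < 500 nM, combined score > 0.6, mutant stronger than wildtype; panel 2-9;
#' MAP panel 10 known + 2 auto-antibody peptides).
#'
#' @param cohort_dir directory holding the cohort bundle.
#' @param out_dir run output directory.
#' @param seed integer seed recorded in the manifest.
#' @return A `run_config` list.
#' @export
default_run_config <- function(cohort_dir, out_dir, seed = 1L) {
  cfg <- list(
    version = 1L, seed = as.integer(seed), out_dir = out_dir,
    arrays = file.path(cohort_dir, "arrays.tsv"),
    expression = list(
      tumor_TPM = file.path(cohort_dir, "expression", "tumor_TPM.tsv"),
      mTEC = file.path(cohort_dir, "expression", "mTEC.tsv"),
      OV_HiSeq = file.path(cohort_dir, "expression", "OV_HiSeq.tsv"),
      OV_PANCAN = file.path(cohort_dir, "expression", "OV_PANCAN.tsv")
    ),
    variants_dir = file.path(cohort_dir, "variants"),
    proteome = file.path(cohort_dir, "proteome.fasta"),
    genesets = file.path(cohort_dir, "genesets.gmt"),
    maps_dir = file.path(cohort_dir, "maps"),
    known_epitopes = file.path(cohort_dir, "known_epitopes.tsv"),
    case_group = "HGSC",
    signal_threshold = 1000, z_threshold = 0.4, min_patients = 4L,
    fdr_alpha = 0.05, af_threshold = 0.005, min_vaf = 0.10,
    max_affinity_nM = 500, min_combined_score = 0.6,
    require_mut_stronger = TRUE,
    panel_n_min = 2L, panel_n_max = 9L, hydropathy_limit = 2.0,
    allele = "HLA-A*02:01",
    tumor_cut = 10, mtec_cut = 10,
    map_max_known = 10L, map_max_autoab = 2L
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline run configuration from YAML
#'
#' Unknown keys are errors (fail fast); the configuration round-trips
#' losslessly through [write_run_config()].
#'
#' @param path YAML file.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- unclass(default_run_config(".", cfg$out_dir %||% "."))
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  validate_run_config(base)
  class(base) <- "run_config"
  base
}

#' Write a pipeline run configuration as YAML
#' @param config `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_run_config <- function(cfg) {
  stopifnot(cfg$signal_threshold >= 0, is.finite(cfg$z_threshold),
            cfg$min_patients >= 1, cfg$fdr_alpha > 0, cfg$fdr_alpha <= 1,
            cfg$af_threshold >= 0, cfg$min_vaf >= 0, cfg$min_vaf <= 1,
            cfg$max_affinity_nM > 0, cfg$panel_n_min <= cfg$panel_n_max)
  invisible(cfg)
}

#' Run the tumor-antigen discovery pipeline
#'
#' Executes the requested stages in canonical order — seromics hit calling,
#' repertoire set algebra, expressed-variant filtering, neo-epitope candidate
#' selection, expression integration, MAP panel assembly — on the inputs named
#' in `config`, writing per-stage TSV/JSON outputs plus a run manifest and a
#' summary report under `config$out_dir`. Missing optional inputs (the MAP
#' lists) skip their stage with an explicit notice; any stage failure aborts
#' with a stage-identified error. Reruns with the same config and seed write
#' byte-identical stage outputs.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param stages character subset of
#'   `c("seromics","repertoire","variants","neoepitope","integrate","maps")`.
#' @param predictor `mhc_predictor` used by the neo-epitope stage (default
#'   [toy_predictor()]).
#' @param quiet suppress progress messages.
#' @return Invisibly, the summary report list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES,
                         predictor = toy_predictor(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  state <- new.env(parent = emptyenv())
  state$config <- config
  state$predictor <- predictor
  state$summary <- list(stages_run = stages, seed = config$seed)
  say <- function(...) if (!quiet) message("[serotarget] ", ...)

  for (stage in stages) {
    say("stage: ", stage)
    fn <- switch(stage,
      seromics = stage_seromics, repertoire = stage_repertoire,
      variants = stage_variants, neoepitope = stage_neoepitope,
      integrate = stage_integrate, maps = stage_maps)
    tryCatch(fn(state), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # manifest: config echo + hash, versions, seed
  cfg_path <- file.path(config$out_dir, "run_config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(
    package = "serotarget",
    package_version = as.character(utils::packageVersion("serotarget")),
    r_version = R.version.string,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages_run = stages
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(state$summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(state$summary)
}

# ---- lazy shared computations ------------------------------------------

need_patients <- function(state) {
  if (is.null(state$patients)) {
    state$patients <- read_array_table(state$config$arrays)
  }
  state$patients
}

need_repertoires <- function(state) {
  if (is.null(state$repertoires)) {
    cfg <- state$config
    pats <- need_patients(state)
    state$repertoires <- lapply(pats, call_hits,
                                signal_threshold = cfg$signal_threshold,
                                z_threshold = cfg$z_threshold)
  }
  state$repertoires
}

case_split <- function(state) {
  reps <- need_repertoires(state)
  grp <- vapply(reps, `[[`, character(1), "group_label")
  list(case = reps[grp == state$config$case_group],
       other = reps[grp != state$config$case_group])
}

need_combined_set <- function(state) {
  if (is.null(state$combined_set)) stage_repertoire(state, write = FALSE)
  state$combined_set
}

need_expressed <- function(state) {
  if (is.null(state$expressed)) stage_variants(state, write = FALSE)
  state$expressed
}

# ---- stages -------------------------------------------------------------

stage_seromics <- function(state, write = TRUE) {
  reps <- need_repertoires(state)
  summ <- summarize_cohort(reps)
  state$summary$hit_counts <- summ
  state$summary$group_mean_hits <- as.list(attr(summ, "group_means"))
  if (write) {
    write_hits(reps, file.path(state$config$out_dir, "hits.tsv"))
    utils::write.table(summ, file.path(state$config$out_dir,
                                       "hit_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(state)
}

stage_repertoire <- function(state, write = TRUE) {
  cfg <- state$config
  groups <- case_split(state)
  if (length(groups$case) == 0L) stop("no patients in case group '",
                                      cfg$case_group, "'")
  shared <- shared_targets(groups$case, cfg$min_patients, name = "shared")
  pats <- need_patients(state)
  grp <- vapply(pats, `[[`, character(1), "group_label")
  diff_tab <- differential_targets(pats[grp == cfg$case_group],
                                   pats[grp != cfg$case_group],
                                   alpha = cfg$fdr_alpha)
  enriched <- gene_set("enriched", diff_tab$gene_id[diff_tab$enriched])
  combined <- combine_repertoire(enriched, shared, name = "combined")
  state$shared_set <- shared
  state$enriched_set <- enriched
  state$combined_set <- combined
  state$differential <- diff_tab
  state$summary$n_shared <- length(shared)
  state$summary$n_enriched <- length(enriched)
  state$summary$n_combined <- length(combined)
  overlaps <- NULL
  if (!is.null(cfg$genesets) && file.exists(cfg$genesets)) {
    sets <- read_gmt(cfg$genesets)
    state$genesets <- sets
    overlaps <- do.call(rbind, lapply(sets, function(s)
      overlap_stats(combined, s)))
    state$summary$geneset_overlaps <- overlaps
  }
  if (write) {
    write_gmt(list(shared, enriched, combined),
              file.path(cfg$out_dir, "repertoires.gmt"))
    utils::write.table(diff_tab, file.path(cfg$out_dir, "differential.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(overlaps)) {
      utils::write.table(overlaps, file.path(cfg$out_dir, "overlaps.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(state)
}

stage_variants <- function(state, write = TRUE) {
  cfg <- state$config
  wes_files <- sort(list.files(cfg$variants_dir, pattern = "_wes\\.tsv$",
                               full.names = TRUE))
  if (length(wes_files) == 0L) stop("no *_wes.tsv files in ", cfg$variants_dir)
  expressed <- list()
  for (wf in wes_files) {
    rf <- sub("_wes\\.tsv$", "_rna.tsv", wf)
    if (!file.exists(rf)) stop("missing RNA companion for ", basename(wf))
    wes <- read_variants_tsv(wf)
    rna <- read_variants_tsv(rf)
    keep <- suppressWarnings(
      expressed_snv(wes, rna, af_threshold = cfg$af_threshold,
                    min_vaf = cfg$min_vaf))
    expressed[[keep$patient_id[1] %||% basename(wf)]] <- keep
  }
  state$expressed <- expressed
  all_expressed <- do.call(rbind, expressed)
  class(all_expressed) <- c("somatic_variants", "data.frame")
  snv_summary <- summarize_expressed_snv(all_expressed)
  state$summary$snv_counts <- snv_summary[c("patient_id", "n_snv")]
  if (write) {
    write_variants_tsv(all_expressed,
                       file.path(cfg$out_dir, "expressed_snv.tsv"))
    jsonlite::write_json(snv_summary, file.path(cfg$out_dir,
                                                "expressed_snv_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(state)
}

stage_neoepitope <- function(state, write = TRUE) {
  cfg <- state$config
  expressed <- need_expressed(state)
  proteome <- read_proteome(cfg$proteome)
  panels <- list()
  for (pid in names(expressed)) {
    v <- flag_tileable(expressed[[pid]])
    v <- v[v$tileable & v$gene_id %in% names(proteome), , drop = FALSE]
    cands <- lapply(seq_len(nrow(v)), function(i) {
      tile_peptides(proteome[[v$gene_id[i]]], v$aa_ref[i], v$aa_pos[i],
                    v$aa_alt[i], gene_id = v$gene_id[i], patient_id = pid)
    })
    cands <- do.call(rbind, cands)
    if (is.null(cands) || nrow(cands) == 0L) next
    class(cands) <- c("epitope_candidates", "data.frame")
    scored <- score_candidates(cands, state$predictor, allele = cfg$allele)
    passing <- filter_candidates(scored,
                                 max_affinity_nM = cfg$max_affinity_nM,
                                 min_combined_score = cfg$min_combined_score,
                                 require_mut_stronger = cfg$require_mut_stronger)
    panel <- withCallingHandlers(
      select_panel(passing, n_min = cfg$panel_n_min, n_max = cfg$panel_n_max,
                   hydropathy_limit = cfg$hydropathy_limit),
      warning = function(w) invokeRestart("muffleWarning"))
    panels[[pid]] <- panel
    if (write && nrow(panel) > 0L) {
      write_panel(panel,
                  tsv_path = file.path(cfg$out_dir,
                                       paste0("panel_", pid, ".tsv")),
                  fasta_path = file.path(cfg$out_dir,
                                         paste0("panel_", pid, ".fasta")))
    }
  }
  state$panels <- panels
  state$summary$panel_sizes <- lapply(panels, nrow)
  invisible(state)
}

stage_integrate <- function(state, write = TRUE) {
  cfg <- state$config
  combined <- need_combined_set(state)
  tables <- lapply(names(cfg$expression), function(src)
    read_expression_table(cfg$expression[[src]], src))
  pooled <- pooled_repertoire(case_split(state)$case)
  genesets <- c(
    if (!is.null(state$genesets)) {
      stats::setNames(state$genesets,
                      vapply(state$genesets, `[[`, character(1), "name"))
    },
    list(shared = state$shared_set, enriched = state$enriched_set)
  )
  ann <- join_expression(combined, tables, repertoire = pooled,
                         genesets = genesets)
  ann <- classify_quadrants(ann, tumor_cut = cfg$tumor_cut,
                            mtec_cut = cfg$mtec_cut)
  state$annotated <- ann
  state$summary$quadrant_counts <- as.list(attr(ann, "quadrant_counts"))
  expressed <- tryCatch(need_expressed(state), error = function(e) NULL)
  if (!is.null(expressed)) {
    reps <- need_repertoires(state)
    frac <- lapply(names(expressed), function(pid) {
      r <- reps[[pid]]
      if (is.null(r)) return(NULL)
      flag_mutated_targets(r, expressed[[pid]])$fraction
    })
    names(frac) <- names(expressed)
    state$summary$mutated_hit_fraction <- frac[!vapply(frac, is.null,
                                                       logical(1))]
  }
  if (write) {
    write_annotated_targets(ann,
      tsv_path = file.path(cfg$out_dir, "annotated_targets.tsv"),
      json_path = file.path(cfg$out_dir, "quadrant_summary.json"))
  }
  invisible(state)
}

stage_maps <- function(state, write = TRUE) {
  cfg <- state$config
  if (is.null(cfg$maps_dir) || !dir.exists(cfg$maps_dir) ||
      length(list.files(cfg$maps_dir, pattern = "\\.txt$")) == 0L) {
    message("[serotarget] MAP inputs not found; MAP stage skipped")
    state$summary$maps_skipped <- TRUE
    return(invisible(state))
  }
  proteome <- read_proteome(cfg$proteome)
  combined <- need_combined_set(state)
  known <- if (!is.null(cfg$known_epitopes) && file.exists(cfg$known_epitopes)) {
    utils::read.delim(cfg$known_epitopes, stringsAsFactors = FALSE)
  } else NULL
  genesets <- if (!is.null(cfg$genesets) && file.exists(cfg$genesets)) {
    sets <- read_gmt(cfg$genesets)
    stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
  } else list()
  map_files <- sort(list.files(cfg$maps_dir, pattern = "\\.txt$",
                               full.names = TRUE))
  map_summary <- list()
  panels <- list()
  for (mf in map_files) {
    pid <- sub("\\.txt$", "", basename(mf))
    peps <- read_peptide_list(mf)
    matched <- match_to_proteome(peps, proteome, patient_id = pid)
    ann <- annotate_maps(matched, genesets = genesets, repertoire = combined,
                         known_epitopes = known)
    panel <- withCallingHandlers(
      select_map_panel(ann, max_known = cfg$map_max_known,
                       max_autoab = cfg$map_max_autoab),
      warning = function(w) invokeRestart("muffleWarning"))
    panels[[pid]] <- panel
    map_summary[[pid]] <- list(n_maps = nrow(ann),
                               n_matched = sum(ann$n_matches > 0),
                               panel_size = nrow(panel))
    if (write) {
      utils::write.table(ann, file.path(cfg$out_dir,
                                        paste0("maps_", pid, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(panel) > 0L) {
        write_map_panel(panel,
          tsv_path = file.path(cfg$out_dir, paste0("map_panel_", pid, ".tsv")),
          fasta_path = file.path(cfg$out_dir,
                                 paste0("map_panel_", pid, ".fasta")))
      }
    }
  }
  state$map_panels <- panels
  state$summary$map_summary <- map_summary
  invisible(state)
}

# per-gene best hit (max Z) across a group of repertoires, as one pooled
# repertoire for plotting/joining all significant hits of the cohort
pooled_repertoire <- function(repertoires) {
  all_hits <- do.call(rbind, lapply(repertoires, `[[`, "hits"))
  if (is.null(all_hits) || nrow(all_hits) == 0L) {
    hits <- empty_hits()
  } else {
    ord <- order(all_hits$gene_id, -all_hits$z_factor)
    all_hits <- all_hits[ord, , drop = FALSE]
    hits <- all_hits[!duplicated(all_hits$gene_id), , drop = FALSE]
    rownames(hits) <- NULL
  }
  structure(list(patient_id = "pooled", group_label = "pooled", hits = hits),
            class = "hit_repertoire")
}
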