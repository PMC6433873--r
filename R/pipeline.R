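#' Run the full analysis pipeline from one configuration
#'
#' Executes the enabled stages in dependency order — `simulate` (or load an
#' expression matrix from disk), `deg` (per-timepoint regularized t-test
#' calls), `timecourse` (nested polynomial ANOVA), `dynamics` (subset
#' distance curve + sample PCA), `compare` (cross-study overlap against
#' synthetic external lists), `enrich` (GO-style term enrichment) — writing
#' each stage's table under `out_dir` and returning a manifest with file
#' digests and row counts. A single global seed is expanded into per-stage
#' substreams (`seed * 101 + stage_index * 7919 mod 2^31 - 1`), so any stage
#' can be re-run in isolation reproducibly; re-running an identical
#' configuration reproduces all outputs bit-identically.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized entries: `out_dir` (required), `seed` (default 1), `stages`
#'   (subset of simulate/deg/timecourse/dynamics/compare/enrich; default
#'   all), `matrix_path`/`samplesheet_path` (inputs when `simulate` is
#'   disabled), `sim` (arguments for [sim_config()]), `deg`
#'   (`q_cutoff`, `window_size`, `nu0`), `timecourse` (`q_cutoff`, `degree`,
#'   `fdr_method`), `dynamics` (`sizes`), `compare` (`dropout`,
#'   `contamination` per synthetic external study), `enrich`
#'   (`annotations_path` or omitted to build a term map from simulation
#'   truth).
#' @return the manifest (list), invisibly also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages_all <- c("simulate", "deg", "timecourse", "dynamics", "compare",
                  "enrich")
  stages <- config$stages %||% stages_all
  unknown <- setdiff(stages, stages_all)
  if (length(unknown))
    abort(paste0("unknown stage name(s): ", paste(unknown, collapse = ", ")),
          "abatime_config_error")
  out_dir <- config$out_dir
  if (is.null(out_dir)) abort("config needs an out_dir", "abatime_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(package_version = as.character(utils::packageVersion("abatime")),
                   seed = seed, stages = list(),
                   config = config)
  truth <- NULL

  if ("simulate" %in% stages) {
    sim_args <- config$sim %||% list()
    sim_args$seed <- derive_seed(seed, 1L)
    cfg <- do.call(sim_config, sim_args)
    sim <- generate_timecourse(cfg)
    em <- sim$matrix
    truth <- sim$truth
    mp <- file.path(out_dir, "matrix.tsv")
    sp <- file.path(out_dir, "samples.tsv")
    write_expression(em, mp, sp)
    tp <- file.path(out_dir, "truth.tsv")
    utils::write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$simulate <- stage_record(c(mp, sp, tp), nrow(truth))
  } else {
    if (is.null(config$matrix_path) || is.null(config$samplesheet_path))
      abort("stage 'simulate' disabled but no matrix_path/samplesheet_path given",
            "abatime_config_error")
    em <- read_expression(config$matrix_path, config$samplesheet_path)
  }

  degs <- NULL
  if ("deg" %in% stages) {
    dc <- config$deg %||% list()
    params <- reg_params(dc$window_size %||% 101, dc$nu0 %||% 10)
    degs <- call_degs(em, q_cutoff = dc$q_cutoff %||% 0.05, params = params)
    p <- file.path(out_dir, "deg.tsv")
    utils::write.table(degs, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$deg <- stage_record(p, nrow(degs))
  }

  if ("timecourse" %in% stages) {
    tc_cfg <- config$timecourse %||% list()
    tc <- call_timecourse(em, q_cutoff = tc_cfg$q_cutoff %||% 0.001,
                          degree = tc_cfg$degree %||% 3,
                          fdr_method = tc_cfg$fdr_method %||% "storey")
    p <- file.path(out_dir, "timecourse.tsv")
    utils::write.table(tc, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$timecourse <- stage_record(p, nrow(tc))
  }

  if ("dynamics" %in% stages) {
    dyn_cfg <- config$dynamics %||% list()
    sizes <- dyn_cfg$sizes %||% c(50, 100, 200, 300, 400, 500)
    sizes <- sizes[sizes <= nrow(em$values)]
    curve <- subset_distance_curve(em, sizes = sizes)
    p <- file.path(out_dir, "distance_curve.tsv")
    utils::write.table(as.data.frame(curve), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pca <- sample_pca(em)
    pp <- file.path(out_dir, "pca.tsv")
    utils::write.table(data.frame(sample_id = rownames(pca$scores),
                                  pca$scores[, 1:min(4, ncol(pca$scores))]),
                       pp, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$dynamics <- stage_record(c(p, pp), nrow(curve))
  }

  if ("compare" %in% stages) {
    if (is.null(degs))
      abort("stage 'compare' requires stage 'deg' output", "abatime_config_error")
    if (is.null(truth))
      abort("stage 'compare' requires simulation truth", "abatime_config_error")
    cmp_cfg <- config$compare %||% list(study_a = list(dropout = 0.2,
                                                       contamination = 0.02),
                                        study_b = list(dropout = 0.4,
                                                       contamination = 0.05))
    ours <- degs$gene_id[degs$temporal_class != "none"]
    studies <- lapply(seq_along(cmp_cfg), function(i)
      make_study_lists(truth, cmp_cfg[[i]]$dropout %||% 0,
                       cmp_cfg[[i]]$contamination %||% 0,
                       seed = derive_seed(seed, 10L + i)))
    names(studies) <- names(cmp_cfg)
    ov <- cross_study_overlap(ours, studies)
    p <- file.path(out_dir, "overlap.tsv")
    utils::write.table(ov$pairwise, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$stages$compare <- stage_record(p, nrow(ov$pairwise))
  }

  if ("enrich" %in% stages) {
    if (is.null(degs))
      abort("stage 'enrich' requires stage 'deg' output", "abatime_config_error")
    if (!is.null(config$enrich$annotations_path)) {
      ann <- read_annotations(config$enrich$annotations_path,
                              background = em$gene_ids)
    } else {
      if (is.null(truth))
        abort("stage 'enrich' needs annotations_path or simulation truth",
              "abatime_config_error")
      ann <- truth_annotation_map(truth, seed = derive_seed(seed, 20L))
    }
    study <- intersect(degs$gene_id[degs$temporal_class != "none"],
                       ann$background)
    enr <- run_enrichment(study, ann)
    p <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(enr, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$enrich <- stage_record(p, nrow(enr))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}

stage_record <- function(paths, rows) {
  list(paths = paths, rows = rows,
       md5 = unname(tools::md5sum(paths)))
}

# Synthetic term map from simulation truth: one term per archetype plus
# random decoy terms, so planted enrichment is recoverable by construction.
truth_annotation_map <- function(truth, seed, n_decoys = 10,
                                 decoy_size = 50) {
  with_seed(seed, {
    terms <- split(truth$gene_id, truth$archetype)
    names(terms) <- paste0("ARCH:", names(terms))
    for (i in seq_len(n_decoys)) {
      terms[[sprintf("DECOY:%02d", i)]] <-
        sample(truth$gene_id, min(decoy_size, nrow(truth)))
    }
    gene_id <- unlist(terms, use.names = FALSE)
    term_id <- rep(names(terms), lengths(terms))
    annotation_map(gene_id, term_id, background = truth$gene_id)
  })
}

#' Human-readable summary report of a pipeline run
#'
#' Re-reads the stage outputs named in a manifest and writes a plain-text
#' summary: DEG counts per timepoint, temporal-class counts, time-course
#' called count, the distance-curve minimum, and the top enrichment rows.
#' Regenerating the report from the same manifest is byte-identical.
#'
#' @param manifest the list returned by [run_pipeline()] (or parsed from
#'   `manifest.json`).
#' @param path output file (default `report.txt` next to the manifest
#'   outputs).
#' @return invisibly, the lines written.
#' @export
report <- function(manifest, path = NULL) {
  st <- manifest$stages
  if (!length(st)) abort("manifest has no completed stages", "abatime_input_error")
  lines <- c("abatime pipeline report",
             sprintf("package version %s, seed %d",
                     manifest$package_version, manifest$seed), "")
  if (!is.null(st$deg)) {
    degs <- utils::read.delim(st$deg$paths[1], stringsAsFactors = FALSE)
    tps <- sub("^dir_", "", grep("^dir_", names(degs), value = TRUE))
    for (tp in tps)
      lines <- c(lines, sprintf("DEGs at %s min: %d (up %d, down %d)",
                                tp, sum(degs[[paste0("dir_", tp)]] != "none"),
                                sum(degs[[paste0("dir_", tp)]] == "up"),
                                sum(degs[[paste0("dir_", tp)]] == "down")))
    cls <- table(degs$temporal_class[degs$temporal_class != "none"])
    lines <- c(lines, "temporal classes:",
               sprintf("  %s: %d", names(cls), as.integer(cls)))
  }
  if (!is.null(st$timecourse)) {
    tc <- utils::read.delim(st$timecourse$paths[1], stringsAsFactors = FALSE)
    lines <- c(lines, sprintf("time-course called genes: %d", sum(tc$called)))
  }
  if (!is.null(st$dynamics)) {
    curve <- utils::read.delim(st$dynamics$paths[1], stringsAsFactors = FALSE)
    i <- which.min(curve$distance)
    lines <- c(lines, sprintf(
      "distance curve minimum %.4f at start rank %d (window %d)",
      curve$distance[i], curve$start_rank[i], curve$size[i]))
  }
  if (!is.null(st$enrich)) {
    enr <- utils::read.delim(st$enrich$paths[1], stringsAsFactors = FALSE)
    top <- utils::head(enr, 3)
    lines <- c(lines, "top enrichment terms:",
               sprintf("  %s: fold %.2f, q %.3g", top$term_id,
                       top$fold_enrichment, top$q_value))
  }
  if (is.null(path))
    path <- file.path(dirname(manifest$stages[[1]]$paths[1]), "report.txt")
  writeLines(lines, path)
  invisible(lines)
}
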