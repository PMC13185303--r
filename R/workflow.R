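# End-to-end orchestration: build the four comparison pipelines (proteomic,
# unfiltered fingerprint, filtered fingerprint, score-product fusion) from a
# synthetic or file-based study, benchmark them, emit per-indication
# prediction tables and gold-standard overlap reports, and record a
# manifest sufficient to reproduce the run.

.known_pipelines <- c("proteomic", "tanimoto", "tanimoto_filtered",
                      "fusion_score_product", "fusion_rank_min",
                      "fusion_rank_max", "fusion_rank_mean",
                      "fusion_rank_sum", "fusion_rank_product",
                      "fusion_distance_product")

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_full_study()]; a `synthetic`
#' block holds [synthetic_config()] arguments, an `inputs` block holds file
#' paths (`matrix`, `fingerprints`, `mapping`, optional `gold` file list).
#'
#' @param path YAML file path.
#' @return config list suitable for [run_full_study()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$synthetic)) {
    cfg$synthetic <- do.call(synthetic_config, cfg$synthetic)
  }
  cfg
}

.load_study_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    if (!inherits(sc, "synthetic_config")) {
      sc <- do.call(synthetic_config, sc)
    }
    return(generate_study(sc))
  }
  inp <- config$inputs
  if (is.null(inp$matrix) && is.null(inp$fingerprints)) {
    stop("config must provide a synthetic block or input paths", call. = FALSE)
  }
  gold <- NULL
  if (!is.null(inp$gold)) {
    gold <- lapply(inp$gold, read_gold_standard)
    names(gold) <- vapply(gold, `[[`, character(1), "name")
  }
  list(
    config = config,
    matrix = if (!is.null(inp$matrix)) read_interaction_matrix(inp$matrix),
    fingerprints = if (!is.null(inp$fingerprints))
      read_fingerprints(inp$fingerprints),
    mapping = if (!is.null(inp$mapping)) read_indication_mapping(inp$mapping),
    compounds = if (!is.null(inp$compounds))
      utils::read.delim(inp$compounds, colClasses = "character"),
    gold_standards = gold
  )
}

.build_pipelines <- function(study, wanted, filter_fraction) {
  built <- list()
  need_prot <- any(wanted %in% c("proteomic", grep("^fusion", wanted,
                                                   value = TRUE)))
  need_tan <- any(wanted %in% c("tanimoto", "tanimoto_filtered",
                                grep("^fusion", wanted, value = TRUE)))
  prot <- if (need_prot) build_proteomic_lists(study$matrix)
  tan <- if (need_tan) build_tanimoto_lists(study$fingerprints)
  for (w in wanted) {
    built[[w]] <- switch(w,
      proteomic = prot,
      tanimoto = tan,
      tanimoto_filtered = apply_uniqueness_filter(tan, filter_fraction),
      fusion_score_product = fuse_score_product(prot, tan),
      fusion_distance_product = fuse_ranks(prot, tan, "distance_product"),
      fuse_ranks(prot, tan, sub("^fusion_rank_", "", w))
    )
  }
  built
}

#' Run a full multi-pipeline study
#'
#' Orchestrates the complete analysis: study inputs (synthetic or from
#' files), pipeline construction, benchmarking with controls,
#' per-indication candidate prediction, and gold-standard overlap
#' comparison of top / random / bottom candidate groups. Every stage is
#' deterministic given the config and seed; the returned manifest records
#' everything needed to reproduce the run.
#'
#' @param config list (or path to a YAML file, see [read_run_config()])
#'   with elements: `synthetic` ([synthetic_config()]) or `inputs` (file
#'   paths); `pipelines` (subset of proteomic, tanimoto, tanimoto_filtered,
#'   fusion_score_product, fusion_rank_min/max/mean/sum/product,
#'   fusion_distance_product; default the four-pipeline comparison);
#'   `cutoffs`; `voting_cutoff`;
#'   `filter_fraction` (default 0.02); `control`; `mc_reps`; `seed`;
#'   `prediction_pipeline` (default `"proteomic"`); `per_list_cutoff`
#'   (default 100); `top_k` (default 100); `group_size` (default 24);
#'   `out_dir` (optional: write reports there).
#' @return list of class `study_report` with `manifest`, `pipelines`,
#'   `benchmarks`, `predictions`, `overlap`.
#' @export
run_full_study <- function(config) {
  if (is.character(config)) {
    config <- read_run_config(config)
  }
  pipelines <- unlist(config$pipelines) %||%
    c("proteomic", "tanimoto", "tanimoto_filtered", "fusion_score_product")
  unknown <- setdiff(pipelines, .known_pipelines)
  if (length(unknown) > 0) {
    stop("unknown pipeline(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cutoffs <- unlist(config$cutoffs) %||% c(10, 25, 50, 100)
  filter_fraction <- config$filter_fraction %||% 0.02
  control <- config$control %||% "closed_form"
  seed <- config$seed %||% 1L
  per_list_cutoff <- config$per_list_cutoff %||% 100
  top_k <- config$top_k %||% 100
  group_size <- config$group_size %||% 24
  prediction_pipeline <- config$prediction_pipeline %||% "proteomic"

  study <- .load_study_inputs(config)
  built <- .build_pipelines(study, pipelines, filter_fraction)

  bench_mapping <- restrict_to_benchmarkable(study$mapping, 2)
  benchmarks <- lapply(built, run_benchmark, mapping = bench_mapping,
                       cutoffs = cutoffs, control = control,
                       voting_cutoff = config$voting_cutoff,
                       mc_reps = config$mc_reps %||% 100, seed = seed)

  pred_pipe <- built[[prediction_pipeline]]
  if (is.null(pred_pipe)) {
    stop("prediction pipeline '", prediction_pipeline,
         "' is not among the built pipelines", call. = FALSE)
  }
  pred_ranks <- rank_matrix(pred_pipe)
  predictions <- lapply(study$mapping, function(approved) {
    predict_candidates(pred_pipe, approved,
                       per_list_cutoff = per_list_cutoff, top_k = top_k,
                       ranks = pred_ranks)
  })

  overlap <- NULL
  if (!is.null(study$gold_standards) && !is.null(study$matrix)) {
    overlap <- lapply(names(study$mapping), function(ind) {
      gold <- study$gold_standards[[ind]]
      if (is.null(gold)) {
        return(NULL)
      }
      preds <- predictions[[ind]]
      novel <- preds$compound_id[!preds$approved]
      top_ids <- utils::head(novel, group_size)
      bottom_pool <- data.frame(id = rev(novel), stringsAsFactors = FALSE)
      if (!is.null(study$compounds) &&
          "heavy_atoms" %in% names(study$compounds)) {
        bottom_pool$heavy_atoms <- study$compounds$heavy_atoms[
          match(bottom_pool$id, study$compounds$id)]
        bottom_pool <- heavy_atom_filter(bottom_pool, 5)
      }
      bottom_ids <- utils::head(bottom_pool$id, group_size)
      compare_candidate_groups(study$matrix, top_ids, bottom_ids,
                               list(gold = gold), seed = seed)
    })
    names(overlap) <- names(study$mapping)
    overlap <- overlap[!vapply(overlap, is.null, logical(1))]
  }

  manifest <- list(
    package = "drugsig",
    version = as.character(utils::packageVersion("drugsig")),
    seed = seed,
    pipelines = pipelines,
    cutoffs = cutoffs,
    voting_cutoff = config$voting_cutoff,
    filter_fraction = filter_fraction,
    control = control,
    per_list_cutoff = per_list_cutoff,
    top_k = top_k,
    group_size = group_size,
    prediction_pipeline = prediction_pipeline,
    synthetic = if (!is.null(config$synthetic)) unclass(config$synthetic),
    inputs = config$inputs
  )

  report <- structure(list(manifest = manifest,
                           pipelines = built,
                           benchmarks = benchmarks,
                           predictions = predictions,
                           overlap = overlap),
                      class = "study_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    for (nm in names(benchmarks)) {
      write_benchmark_json(benchmarks[[nm]],
                           file.path(config$out_dir,
                                     paste0("benchmark_", nm, ".json")))
      write_benchmark_tsv(benchmarks[[nm]],
                          file.path(config$out_dir,
                                    paste0("benchmark_", nm, ".tsv")))
    }
    for (ind in names(predictions)) {
      export_prediction_table(predictions[[ind]],
                              file.path(config$out_dir,
                                        paste0("predictions_", ind, ".tsv")))
    }
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> pipelines: ",
      paste(names(x$pipelines), collapse = ", "), "\n", sep = "")
  for (b in x$benchmarks) print(b)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
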