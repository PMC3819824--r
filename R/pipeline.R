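#' Pipeline configuration for the end-to-end analysis
#'
#' Inputs are either a synthetic-world config (everything simulated) or
#' file paths: a DHS BED, a DNase signal track, and a feature manifest
#' (`data.frame` with columns `name`, `class`, `track`, `peaks` -- one
#' signal track and one peak BED per chromatin feature). Defaults
#' follow the analysis design: 5000 sampled DHSs, 10-fold CV, top set
#' at >90% of the full model's power, enrichment at raw p < 0.01.
#'
#' @param synthetic a [synthetic_config()], or `NULL` to read files.
#' @param dhs_bed,dnase_track paths (used when `synthetic` is `NULL`).
#' @param dnase_dialect `"bedgraph"` or `"wiggle"`.
#' @param manifest feature manifest `data.frame` (see above).
#' @param sample_n DHS regions to sample for modeling (default 5000).
#' @param folds CV folds (default 10).
#' @param seed master seed; all stages draw named substreams from it.
#' @param model a [model_config()] for the four-way model comparison.
#' @param combo_model a [model_config()] for exhaustive subset search
#'   (linear by default: the exhaustive search over thousands of
#'   subsets is run with the cheap model unless configured otherwise).
#' @param combo_k subset sizes to enumerate (default 1:3).
#' @param top_threshold fraction of full-model R (default 0.90).
#' @param enrichment_alpha raw p threshold (default 0.01).
#' @param sample_sizes optional sizes for the sample-size curve.
#' @param sample_reps replicates per size (default 500).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(synthetic = NULL, dhs_bed = NULL,
                            dnase_track = NULL,
                            dnase_dialect = "bedgraph", manifest = NULL,
                            sample_n = 5000L, folds = 10L, seed = 1L,
                            model = model_config("svr"),
                            combo_model = model_config("lm"),
                            combo_k = 1:3, top_threshold = 0.90,
                            enrichment_alpha = 0.01,
                            sample_sizes = NULL, sample_reps = 500L) {
  if (is.null(synthetic)) {
    stopifnot(!is.null(dhs_bed), !is.null(dnase_track),
              !is.null(manifest),
              all(c("name", "class", "track", "peaks") %in%
                    colnames(manifest)))
    if (anyDuplicated(manifest$name)) stop("duplicate feature names")
    for (p in c(dhs_bed, dnase_track, manifest$track, manifest$peaks))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(synthetic = synthetic, dhs_bed = dhs_bed,
                 dnase_track = dnase_track,
                 dnase_dialect = dnase_dialect, manifest = manifest,
                 sample_n = as.integer(sample_n),
                 folds = as.integer(folds), seed = as.integer(seed),
                 model = model, combo_model = combo_model,
                 combo_k = combo_k, top_threshold = top_threshold,
                 enrichment_alpha = enrichment_alpha,
                 sample_sizes = sample_sizes,
                 sample_reps = as.integer(sample_reps)),
            class = "PipelineConfig")
}

.load_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    ds <- simulate_dataset(config$synthetic)
    list(dhs = ds$dhs, dnase_track = ds$dnase_track,
         feature_tracks = ds$feature_tracks, peaksets = ds$peaksets,
         classes = ds$classes)
  } else {
    mf <- config$manifest
    tracks <- lapply(seq_len(nrow(mf)), function(i)
      read_signal_track(mf$track[i], config$dnase_dialect, mf$name[i]))
    names(tracks) <- mf$name
    peaks <- lapply(seq_len(nrow(mf)), function(i)
      read_bed(mf$peaks[i], mf$name[i]))
    names(peaks) <- mf$name
    list(dhs = read_bed(config$dhs_bed, "DHS"),
         dnase_track = read_signal_track(config$dnase_track,
                                         config$dnase_dialect, "DNase"),
         feature_tracks = tracks, peaksets = peaks,
         classes = setNames(mf$class, mf$name))
  }
}

#' Run the full analysis end to end
#'
#' Stages, in order: (1) peak localization table; (2) feature-matrix
#' construction under both max and avg aggregation; (3) region
#' sampling; (4) four-way model comparison (SVR/linear x max/avg for
#' HM, TF, HM+TF); (5) exhaustive k-feature combination evaluation,
#' top-combination selection and hypergeometric feature enrichment;
#' (6) optional sample-size curve. Deterministic given the master
#' seed: each stage draws a named substream. If `out_dir` is given,
#' every table is written as TSV together with a JSON manifest of the
#' parameters used.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress progress messages.
#' @return List: `localization`, `matrix_max`, `matrix_avg` (sampled),
#'   `comparison`, `combinations` (per k: `combos`, `top`,
#'   `enrichment`), `sample_size` (or `NULL`).
#' @export
run_full_analysis <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(obj, file, writer = write_tsv_table) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
  }

  inputs <- stage("load", .load_pipeline_inputs(config))
  say("[load] %d DHS regions, %d features", length(inputs$dhs),
      length(inputs$feature_tracks))

  loc <- stage("localize",
               localization_table(inputs$peaksets,
                                  inputs$classes[names(inputs$peaksets)],
                                  inputs$dhs))
  emit(loc, "localization.tsv", write_localization_table)

  fm_max <- stage("matrix_max",
                  build_feature_matrix(inputs$dhs, inputs$dnase_track,
                                       inputs$feature_tracks, "max"))
  fm_avg <- stage("matrix_avg",
                  build_feature_matrix(inputs$dhs, inputs$dnase_track,
                                       inputs$feature_tracks, "avg"))
  samp_seed <- derive_seed(config$seed, "sampling")
  fm_max <- sample_regions(fm_max, config$sample_n, samp_seed)
  fm_avg <- sample_regions(fm_avg, config$sample_n, samp_seed)
  say("[sample] %d regions retained", nrow(fm_max$X))
  emit(fm_max, "matrix_max.tsv", write_feature_matrix)
  emit(fm_avg, "matrix_avg.tsv", write_feature_matrix)

  fold_seed <- derive_seed(config$seed, "folds")
  comparison <- stage("model_comparison",
                      model_comparison(fm_max, fm_avg, inputs$classes,
                                       config$model, config$folds,
                                       fold_seed))
  if (!is.null(out_dir)) {
    df <- cbind(model = rownames(comparison), comparison)
    write_tsv_table(df, file.path(out_dir, "model_comparison.tsv"))
  }

  combinations <- list()
  for (k in config$combo_k) {
    combos <- stage(sprintf("combos_k%d", k),
                    evaluate_combinations(fm_max, k, config$combo_model,
                                          config$folds, fold_seed))
    top <- top_combinations(combos, config$top_threshold)
    # an empty top set (no subset clears the threshold) is a valid
    # outcome at small k; there is then nothing to test for enrichment
    enr <- if (nrow(top$results) > 0)
      feature_enrichment(top, fm_max$feature_names, k,
                         config$enrichment_alpha)
    else NULL
    combinations[[as.character(k)]] <-
      list(combos = combos, top = top, enrichment = enr)
    if (!is.null(out_dir)) {
      write_combos_table(combos, file.path(out_dir,
                                           sprintf("combinations_k%d.tsv", k)))
      write_combos_table(top, file.path(out_dir,
                                        sprintf("top_combinations_k%d.tsv", k)))
      if (!is.null(enr))
        write_tsv_table(enr, file.path(out_dir,
                                       sprintf("enrichment_k%d.tsv", k)))
    }
  }

  curve <- NULL
  if (!is.null(config$sample_sizes)) {
    curve <- stage("sample_size_curve",
                   sample_size_curve(fm_max, config$sample_sizes,
                                     config$sample_reps,
                                     config$combo_model, config$folds,
                                     derive_seed(config$seed, "curve")))
    emit(curve, "sample_size_curve.tsv")
  }

  if (!is.null(out_dir)) {
    params <- list(sample_n = config$sample_n, folds = config$folds,
                   seed = config$seed, combo_k = config$combo_k,
                   top_threshold = config$top_threshold,
                   enrichment_alpha = config$enrichment_alpha,
                   model = unclass(config$model),
                   combo_model = unclass(config$combo_model),
                   n_regions_used = nrow(fm_max$X),
                   n_features = length(fm_max$feature_names))
    jsonlite::write_json(params, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(localization = loc, matrix_max = fm_max, matrix_avg = fm_avg,
       comparison = comparison, combinations = combinations,
       sample_size = curve)
}

write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Combination tables carry R_full as a comment header so the top-set /
# enrichment steps can be re-run from the file alone.
write_combos_table <- function(combos, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# R_full=%.10g\n", combos$R_full), file = con)
  write.table(combos$results, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a combination table written by the pipeline
#'
#' @param path TSV produced by the `combos` stage.
#' @return List with `results`, `subsets`, `R_full`.
#' @export
read_combos_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# R_full="))
    stop("missing '# R_full=' header in ", path)
  res <- read.table(path, sep = "\t", header = TRUE, skip = 1L,
                    comment.char = "", stringsAsFactors = FALSE)
  list(results = res, subsets = strsplit(res$features, "/", fixed = TRUE),
       R_full = as.numeric(sub("# R_full=", "", first)))
}
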