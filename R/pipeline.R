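#' Pipeline run configuration
#'
#' Assembles the per-stage parameter blocks for [run_pipeline()]. Any block
#' can also be supplied from a YAML file (pass its path to
#' [run_pipeline()]); entries given here override the YAML defaults.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master integer seed; all stage randomness derives from it.
#' @param stages Stages to run, in order, from
#'   `c("simulate", "segment", "matrix", "train", "crossval", "accel")`.
#' @param genome_spec Arguments for [synthetic_genome_spec()].
#' @param design Cohort design tibble (default
#'   [default_cohort_design()]).
#' @param segmentation Arguments for [segmentation_config()].
#' @param filter Arguments for [filter_config()] (SNP positions are filled
#'   from the simulated truth automatically).
#' @param clock List with `alpha`, `k_folds`, `normalize` for the clock
#'   stages.
#' @param accel List with `design` (design tibble for the acceleration
#'   cohort) and `reference_group`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "segment", "matrix",
                                       "train", "crossval", "accel"),
                            genome_spec = list(), design = NULL,
                            segmentation = list(), filter = list(),
                            clock = list(alpha = 0.9, k_folds = 6),
                            accel = list()) {
  known <- c("simulate", "segment", "matrix", "train", "crossval", "accel")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 genome_spec = genome_spec, design = design,
                 segmentation = segmentation, filter = filter,
                 clock = clock, accel = accel),
            class = "pipeline_config")
}

checksum_files <- function(paths) {
  as.list(tools::md5sum(paths))
}

#' Run the end-to-end clock pipeline
#'
#' Executes the enabled stages in order — simulate a cohort, call and pool
#' LMRs, build/filter/normalize the feature matrix, train the clock,
#' cross-validate it, and test age acceleration — writing each stage's
#' outputs plus a JSON manifest recording inputs, parameters, seeds and
#' output checksums. Re-running with an identical config reproduces
#' identical outputs. A stage failure halts the run; the manifest then
#' records the stages completed.
#'
#' @param config A [pipeline_config()], or the path to a YAML file whose
#'   top-level keys mirror its arguments.
#' @return The run manifest (a list), invisibly written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    raw <- yaml::read_yaml(config)
    if (!is.null(raw$design)) raw$design <- tibble::as_tibble(raw$design)
    config <- do.call(pipeline_config, raw)
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  manifest <- list(seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())

  record <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      stage = stage, parameters = params, seed = config$seed,
      outputs = checksum_files(files))
  }

  runners <- list(
    simulate = function() {
      gs <- config$genome_spec
      if (!is.null(gs$chromosomes)) gs$chromosomes <- unlist(gs$chromosomes)
      if (!is.null(gs$region_length)) gs$region_length <- unlist(gs$region_length)
      spec <- do.call(synthetic_genome_spec,
                      utils::modifyList(list(seed = config$seed), gs))
      genome <- simulate_genome(spec)
      design <- config$design %||% default_cohort_design()
      cohort <- simulate_cohort(design, genome, seed = config$seed)
      state$cohort <- cohort
      files <- character()
      for (sid in names(cohort$tracks)) {
        f <- out(paste0(sid, ".methratio.tsv"))
        write_methratio(cohort$tracks[[sid]], f)
        files <- c(files, f)
      }
      sheet <- out("sample_sheet.csv")
      readr::write_csv(cohort$metadata, sheet, progress = FALSE)
      truth_bed <- out("truth_regions.bed")
      write_intervals_bed(
        dplyr::mutate(genome$regions, segment_class = .data$class,
                      n_cpgs = 0L), truth_bed)
      record("simulate", list(n_samples = nrow(cohort$metadata),
                              n_regions = nrow(genome$regions)),
             c(files, sheet, truth_bed))
    },
    segment = function() {
      cohort <- state$cohort %||% abort("segment stage needs the simulate stage")
      meta <- cohort$metadata
      reps <- meta[!duplicated(meta$tissue), ]
      seg_cfg <- do.call(segmentation_config,
                         utils::modifyList(list(seed = config$seed),
                                           config$segmentation))
      sets <- purrr::map(reps$sample_id, function(sid) {
        call_lmrs(aggregate_strands(cohort$tracks[[sid]]), seg_cfg)$segments
      })
      pooled <- pool_interval_sets(sets)
      state$lmrs <- pooled
      f <- out("lmrs_pooled.bed")
      write_intervals_bed(pooled, f)
      record("segment", list(n_samples_segmented = nrow(reps),
                             n_pooled = nrow(pooled),
                             m_cutoff = seg_cfg$m_cutoff), f)
    },
    matrix = function() {
      cohort <- state$cohort %||% abort("matrix stage needs the simulate stage")
      lmrs <- state$lmrs %||% abort("matrix stage needs the segment stage")
      fc <- do.call(filter_config, utils::modifyList(
        list(snp_positions = cohort$genome$snp_positions), config$filter))
      mat <- build_feature_matrix(cohort$tracks, cohort$metadata, lmrs, fc)
      state$mat <- mat
      f <- out("lmr_matrix.csv")
      readr::write_csv(mat, f, progress = FALSE)
      record("matrix", list(n_features = ncol(mat) - 1L), f)
    },
    train = function() {
      mat <- state$mat %||% abort("train stage needs the matrix stage")
      meta <- state$cohort$metadata
      norm <- tissue_normalize(mat, meta)
      model <- train_clock(norm, meta, alpha = config$clock$alpha %||% 0.9,
                           k_folds = config$clock$k_folds %||% 6,
                           seed = config$seed)
      state$model <- model
      f <- out("clock.json")
      write_clock(model, f)
      record("train", list(alpha = model$alpha, lambda = model$lambda,
                           n_features = length(model$weights)), f)
    },
    crossval = function() {
      mat <- state$mat %||% abort("crossval stage needs the matrix stage")
      meta <- state$cohort$metadata
      cv <- cross_validate_clock(mat, meta,
                                 alpha = config$clock$alpha %||% 0.9,
                                 k_folds = config$clock$k_folds %||% 6,
                                 seed = config$seed,
                                 normalize = config$clock$normalize %||% "fold")
      state$cv <- cv
      f <- out("crossval_predictions.csv")
      readr::write_csv(cv$predictions, f, progress = FALSE)
      record("crossval", list(rmse_days = cv$rmse, k_folds = cv$k_folds), f)
    },
    accel = function() {
      model <- state$model %||% abort("accel stage needs the train stage")
      cohort <- state$cohort
      acc_design <- config$accel$design %||% tibble::tibble(
        tissue = "jejunum", age_days = c(14, 35), n = 5,
        group = c("treated", "reference"), acceleration = c(3, 0))
      acc_cohort <- simulate_cohort(acc_design, cohort$genome,
                                    seed = config$seed + 101L)
      fc <- do.call(filter_config, utils::modifyList(
        list(snp_positions = cohort$genome$snp_positions), config$filter))
      lmrs <- state$lmrs
      amat <- build_feature_matrix(acc_cohort$tracks, acc_cohort$metadata,
                                   lmrs, fc)
      acc <- age_acceleration(model, amat, acc_cohort$metadata)
      tests <- test_group_acceleration(
        acc, reference_group = config$accel$reference_group %||% "reference")
      f1 <- out("acceleration.csv"); f2 <- out("acceleration_tests.csv")
      readr::write_csv(acc, f1, progress = FALSE)
      readr::write_csv(tests, f2, progress = FALSE)
      record("accel", list(reference_group = config$accel$reference_group %||%
                             "reference"), c(f1, f2))
    }
  )

  for (stage in config$stages) {
    ok <- tryCatch({ runners[[stage]](); TRUE },
                   error = function(e) {
                     manifest$error <<- list(stage = stage,
                                             message = conditionMessage(e))
                     FALSE
                   })
    if (!ok) break
  }
  manifest$completed <- names(manifest$stages)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (!is.null(manifest$error)) {
    abort(sprintf("pipeline halted at stage '%s': %s (manifest written)",
                  manifest$error$stage, manifest$error$message))
  }
  invisible(manifest)
}
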