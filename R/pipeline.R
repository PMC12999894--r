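#' @include synth.R dataset.R validation.R
NULL

#' Run configuration
#'
#' Composite configuration for [runPipeline()]: sub-configs for every
#' stage plus paths and the master seed. Any element can be overridden via
#' the `overrides` list (e.g. from CLI flags).
#'
#' @param preprocess a [preprocessConfig()].
#' @param vmd a [vmdConfig()].
#' @param entropy an [entropyParams()].
#' @param optimization an [optimizationConfig()].
#' @param synth a [synthConfig()].
#' @param classifier list with `family`, `variant`, optional `optimize`
#'   flag and `params`.
#' @param lobe lobe restriction for train/evaluate/loocv
#'   (`"all"` or a lobe name).
#' @param cv_folds folds for the evaluate stage.
#' @param seed master seed, recorded in every manifest.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(preprocess = preprocessConfig(), vmd = vmdConfig(),
                      entropy = entropyParams(),
                      optimization = optimizationConfig(),
                      synth = synthConfig(),
                      classifier = list(family = "knn", variant = "fine",
                                        optimize = FALSE),
                      lobe = "all", cv_folds = 10L, seed = 1L) {
  structure(list(preprocess = preprocess, vmd = vmd, entropy = entropy,
                 optimization = optimization, synth = synth,
                 classifier = classifier, lobe = lobe,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Top-level keys `preprocess`, `vmd`, `entropy`, `optimization`, `synth`,
#' `classifier`, `lobe`, `cv_folds`, `seed`; each sub-key overrides the
#' corresponding constructor default.
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  runConfig(
    preprocess = build(preprocessConfig, y$preprocess),
    vmd = build(vmdConfig, y$vmd),
    entropy = build(entropyParams, y$entropy),
    optimization = build(optimizationConfig, y$optimization),
    synth = build(synthConfig, y$synth),
    classifier = y$classifier %||% list(family = "knn", variant = "fine",
                                        optimize = FALSE),
    lobe = y$lobe %||% "all",
    cv_folds = y$cv_folds %||% 10L,
    seed = y$seed %||% 1L)
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(config), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

writeManifest <- function(dir, config, stage, inputs = character()) {
  jsonlite::write_json(
    list(stage = stage, seed = config$seed,
         config_hash = configHash(config),
         package_version = as.character(utils::packageVersion("vmdEEG")),
         inputs = as.list(inputs)),
    file.path(dir, "stage_manifest.json"), auto_unbox = TRUE)
}

requireArtifact <- function(path, stage, hint) {
  if (!file.exists(path))
    stop("stage '", stage, "' requires missing artifact: ", path,
         " (", hint, ")")
  path
}

#' Run the pipeline
#'
#' Executes the requested stages in topological order under `out`:
#' \describe{
#'   \item{synth}{generate recordings -> `out/recordings/`}
#'   \item{preprocess}{filter + re-reference -> `out/preprocessed/`}
#'   \item{decompose}{per-segment VMD modes -> `out/modes/` (CSV per
#'     channel + JSON center frequencies)}
#'   \item{features}{feature table -> `out/features.csv` (+ schema)}
#'   \item{train}{(optionally Bayesian-optimized) model parameters ->
#'     `out/model.json`}
#'   \item{evaluate}{stratified k-fold CV metrics -> `out/metrics.json` +
#'     `out/roc.csv`}
#'   \item{lobewise}{lobe-wise sweep -> `out/lobewise.csv`}
#'   \item{loocv}{subject-wise LOOCV -> `out/loocv.json`}
#'   \item{compare}{paired comparison of the first two specs across lobes
#'     -> `out/compare.json`}
#' }
#' Every stage writes a provenance manifest (config hash, seed, package
#' version). Missing stage inputs raise an error naming the absent
#' artifact.
#'
#' @param config a [runConfig()].
#' @param stages character vector of stage names.
#' @param out output directory.
#' @param recordingsDir optional existing recordings directory (skips the
#'   synth stage as input provider).
#' @return invisibly, a named list of per-stage outputs.
#' @export
runPipeline <- function(config, stages, out,
                        recordingsDir = NULL) {
  allStages <- c("synth", "preprocess", "decompose", "features", "train",
                 "evaluate", "lobewise", "loocv", "compare")
  bad <- setdiff(stages, allStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- allStages[allStages %in% stages]
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  recDir <- recordingsDir %||% file.path(out, "recordings")

  loadRecordings <- function(stage) {
    requireArtifact(file.path(recDir, "manifest.json"), stage,
                    "run the synth stage or pass recordingsDir")
    readFixture(recDir)
  }
  loadTable <- function(stage) {
    requireArtifact(file.path(out, "features.csv"), stage,
                    "run the features stage first")
    readFeatureTable(file.path(out, "features.csv"))
  }
  specFromConfig <- function() {
    cl <- config$classifier
    classifierSpec(cl$family, cl$variant %||% NULL,
                   params = cl$params %||% list())
  }
  maybeLobe <- function(tab) {
    if (identical(config$lobe, "all")) tab
    else subsetLobe(tab, config$lobe)
  }

  for (stage in stages) {
    if (stage == "synth") {
      recs <- generateRecordings(config$synth)
      writeFixture(recs, recDir, format = "csv")
      writeManifest(recDir, config, "synth")
      results$synth <- recs
    } else if (stage == "preprocess") {
      recs <- loadRecordings("preprocess")
      pre <- lapply(recs, function(r) {
        r |> bandpassFilter(config$preprocess) |>
          notchFilter(config$preprocess) |>
          commonAverageReference()
      })
      d <- file.path(out, "preprocessed")
      writeFixture(pre, d, format = "csv")
      writeManifest(d, config, "preprocess", inputs = recDir)
      results$preprocess <- pre
    } else if (stage == "decompose") {
      src <- if (file.exists(file.path(out, "preprocessed",
                                       "manifest.json")))
        readFixture(file.path(out, "preprocessed"))
      else loadRecordings("decompose")
      d <- file.path(out, "modes")
      dir.create(d, showWarnings = FALSE)
      for (rec in src) {
        seg <- segmentRecording(rec, config$preprocess)
        for (i in seq_len(nSegments(seg))) {
          dec <- decomposeSegment(segments(seg)[[i]], samplingRate(seg),
                                  config$vmd, channelLabels(seg))
          for (ch in names(dec)) {
            base <- sprintf("%s_seg%03d_%s", subjectId(rec), i, ch)
            write.csv(t(modes(dec[[ch]])),
                      file.path(d, paste0(base, ".csv")),
                      row.names = FALSE)
            jsonlite::write_json(
              list(center_freqs_hz = centerFreqs(dec[[ch]]),
                   converged = converged(dec[[ch]])),
              file.path(d, paste0(base, ".json")), auto_unbox = TRUE)
          }
        }
      }
      writeManifest(d, config, "decompose")
      results$decompose <- d
    } else if (stage == "features") {
      src <- if (file.exists(file.path(out, "preprocessed",
                                       "manifest.json"))) {
        recs <- readFixture(file.path(out, "preprocessed"))
        # already filtered/re-referenced: segment + decompose only
        tabRows <- lapply(recs, function(rec) {
          seg <- segmentRecording(rec, config$preprocess)
          lapply(seq_len(nSegments(seg)), function(i) {
            dec <- decomposeSegment(segments(seg)[[i]], samplingRate(seg),
                                    config$vmd, channelLabels(seg))
            suppressWarnings(extractFeatures(dec, samplingRate(seg),
                                             config$entropy))
          })
        })
        X <- do.call(rbind, unlist(tabRows, recursive = FALSE))
        featureTable(X,
          y = unlist(lapply(seq_along(recs), function(i)
            rep(classLabel(recs[[i]]), length(tabRows[[i]])))),
          subject_ids = unlist(lapply(seq_along(recs), function(i)
            rep(subjectId(recs[[i]]), length(tabRows[[i]])))))
      } else {
        buildFeatureTable(loadRecordings("features"), config$preprocess,
                          config$vmd, config$entropy)
      }
      writeFeatureTable(src, file.path(out, "features.csv"))
      writeManifest(out, config, "features")
      results$features <- src
    } else if (stage == "train") {
      tab <- maybeLobe(loadTable("train"))
      cl <- config$classifier
      if (isTRUE(cl$optimize)) {
        opt <- bayesOptimize(cl$family, featureMatrix(tab),
                             segmentLabels(tab), config$optimization)
        spec <- opt$spec
        jsonlite::write_json(
          list(family = cl$family, params = opt$best_params,
               best_cv_loss = opt$best_cv_loss, seed = config$seed),
          file.path(out, "model.json"), auto_unbox = TRUE, digits = NA)
        utils::write.csv(opt$trace, file.path(out, "bo_trace.csv"),
                         row.names = FALSE)
      } else {
        spec <- specFromConfig()
        jsonlite::write_json(
          list(family = spec@family, variant = spec@variant,
               params = spec@params, seed = config$seed),
          file.path(out, "model.json"), auto_unbox = TRUE, digits = NA)
      }
      results$train <- spec
    } else if (stage == "evaluate") {
      tab <- maybeLobe(loadTable("evaluate"))
      spec <- results$train %||% specFromConfig()
      repEval <- kfoldCV(spec, tab, k = config$cv_folds,
                         seed = config$seed)
      jsonlite::write_json(
        list(metrics = as.list(metrics(repEval)),
             confusion = confusionMatrix(repEval),
             auc = aucValue(repEval), seed = config$seed),
        file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
      utils::write.csv(rocPoints(repEval), file.path(out, "roc.csv"),
                       row.names = FALSE)
      writeManifest(out, config, "evaluate")
      results$evaluate <- repEval
    } else if (stage == "lobewise") {
      tab <- loadTable("lobewise")
      specs <- list(specFromConfig())
      if (!is.null(config$classifier$second_family))
        specs[[2]] <- classifierSpec(config$classifier$second_family,
                                     config$classifier$second_variant %||%
                                       NULL)
      sw <- lobewiseSweep(specs, tab, k = config$cv_folds,
                          seed = config$seed)
      utils::write.csv(sw$results, file.path(out, "lobewise.csv"),
                       row.names = FALSE)
      results$lobewise <- sw
    } else if (stage == "loocv") {
      tab <- maybeLobe(loadTable("loocv"))
      lr <- subjectLOOCV(specFromConfig(), tab, seed = config$seed)
      jsonlite::write_json(
        list(per_subject = as.list(perSubjectAccuracy(lr)),
             mean_accuracy = meanAccuracy(lr),
             sd_accuracy = sdAccuracy(lr), seed = config$seed),
        file.path(out, "loocv.json"), auto_unbox = TRUE, digits = NA)
      results$loocv <- lr
    } else if (stage == "compare") {
      requireArtifact(file.path(out, "lobewise.csv"), "compare",
                      "run the lobewise stage first")
      lw <- utils::read.csv(file.path(out, "lobewise.csv"))
      idx <- sort(unique(lw$spec_index))
      if (length(idx) < 2)
        stop("compare requires a lobewise sweep over >= 2 specs")
      a <- lw$Ac[lw$spec_index == idx[1]]
      b <- lw$Ac[lw$spec_index == idx[2]]
      pc <- pairedComparison(a, b)
      jsonlite::write_json(
        list(n = pc@n, mean_diff = pc@meanDiff, t = pc@tStat,
             p_value = pc@pValue, cohens_d = pc@cohensD),
        file.path(out, "compare.json"), auto_unbox = TRUE, digits = NA)
      results$compare <- pc
    }
  }
  invisible(results)
}
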