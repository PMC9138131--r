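#' @include metrics.R
NULL

.allProjections <- c("pca", "lda", "srelm", "tsne")
.allClassifiers <- c("lda", "nb", "knn", "svml", "svmb", "svmp", "nn")

#' Training-position-reduction schedule
#'
#' The nested best-position subsets evaluated in the study, from one training
#' position up to all nine.
#'
#' @return named list of position-label vectors.
#' @export
positionSchedule <- function() {
  list(
    `1` = "P5",
    `2` = c("P5", "P9"),
    `3` = c("P1", "P5", "P9"),
    `4` = c("P1", "P3", "P5", "P9"),
    `5` = c("P1", "P3", "P5", "P8", "P9"),
    `6` = c("P1", "P3", "P4", "P6", "P7", "P9"),
    `7` = c("P1", "P2", "P3", "P4", "P6", "P7", "P9"),
    `8` = c("P1", "P2", "P3", "P4", "P5", "P6", "P7", "P9"),
    `9` = paste0("P", 1:9)
  )
}

## shared per-fold projected data: project once, reuse for every classifier
.projectFolds <- function(fs, folds, projection, k, projParams) {
  if (projection == "tsne") {
    normAll <- applyNormalizer(fitNormalizer(fs), fs)
    emb <- do.call(tsneEmbed, modifyList(list(data = normAll, k = k), projParams))
    projAll <- setFeatureMatrix(fs, `colnames<-`(emb@Y, paste0("Y", seq_len(k))))
    return(lapply(sort(unique(folds)), function(f) {
      list(train = subsetWindows(projAll, folds != f),
           test = subsetWindows(projAll, folds == f))
    }))
  }
  lapply(sort(unique(folds)), function(f) {
    tr <- subsetWindows(fs, folds != f); ts <- subsetWindows(fs, folds == f)
    norm <- fitNormalizer(tr)
    pr <- projectFeatures(projection, applyNormalizer(norm, tr),
                          applyNormalizer(norm, ts), k = k, params = projParams)
    list(train = pr$train, test = pr$test)
  })
}

#' Projection-by-classifier error grid
#'
#' The study's first experiment: for every subject, every pairing of the four
#' projection techniques with the seven classifiers is scored by five-fold
#' cross-validation (projection and normalizer refitted inside each training
#' fold; t-SNE embedded transductively once per subject). Per (projection,
#' subject), SI and MSA of the projected features (projection fitted on all of
#' that subject's normalized data) are also reported.
#'
#' @param fs a 66-D [GraspFeatureSet-class] (any number of subjects).
#' @param projections subset of `c("pca", "lda", "srelm", "tsne")`.
#' @param classifiers subset of the seven classifier kinds.
#' @param nFolds fold count.
#' @param seed base seed: drives fold assignment and every stochastic stage.
#' @param k projected dimension.
#' @param srelmL,srelmAlpha SRELM operating point.
#' @param tsnePerplexity,tsneIter t-SNE settings.
#' @return an `ExperimentResult` list: `records` (subject, projection,
#'   classifier, fold, error_percent), `metrics` (subject, projection, SI,
#'   MSA) and `aggregates` (mean/SD error per projection x classifier).
#' @export
runProjectionClassifierGrid <- function(fs,
    projections = .allProjections, classifiers = .allClassifiers,
    nFolds = 5L, seed = 1L, k = 4L,
    srelmL = 1000L, srelmAlpha = 1, tsnePerplexity = 30, tsneIter = 1000L) {
  records <- list(); metrics <- list()
  for (subj in unique(subjectLabels(fs))) {
    sub <- subsetWindows(fs, subjectLabels(fs) == subj)
    folds <- makeFolds(ncol(sub), nFolds = nFolds, seed = seed)
    for (proj in projections) {
      projParams <- switch(proj,
        srelm = list(L = srelmL, alpha = srelmAlpha, seed = seed),
        tsne = list(perplexity = tsnePerplexity, maxIter = tsneIter, seed = seed),
        list())
      pf <- .projectFolds(sub, folds, proj, k, projParams)
      for (clf in classifiers) {
        spec <- classifierSpec(clf, seed = seed)
        for (f in seq_along(pf)) {
          err <- tryCatch({
            model <- trainClassifier(spec, pf[[f]]$train)
            classificationError(graspLabels(pf[[f]]$test),
                                predictClassifier(model, pf[[f]]$test))
          }, error = function(e) NA_real_)
          records[[length(records) + 1L]] <- data.frame(
            subject = subj, projection = proj, classifier = clf,
            fold = f, error_percent = err, stringsAsFactors = FALSE)
        }
      }
      # reporting metrics: projection fitted on all of this subject's data
      normAll <- applyNormalizer(fitNormalizer(sub), sub)
      projAll <- if (proj == "tsne") {
        bindWindows(pf[[1]]$train, pf[[1]]$test)
      } else {
        projectFeatures(proj, normAll, normAll, k = k, params = projParams)$train
      }
      metrics[[length(metrics) + 1L]] <- data.frame(
        subject = subj, projection = proj,
        SI = separabilityIndex(projAll),
        MSA = meanSemiPrincipalAxis(projAll), stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, records)
  structure(list(records = records, metrics = do.call(rbind, metrics),
                 aggregates = aggregateResults(records)),
            class = "ExperimentResult")
}

#' Aggregate long-format experiment records
#'
#' Mean and standard deviation of `error_percent` per (projection,
#' classifier), recomputable from the records at any time.
#'
#' @param records long-format data.frame from an experiment run.
#' @return data.frame with columns projection, classifier, mean_error,
#'   sd_error, n.
#' @export
aggregateResults <- function(records) {
  agg <- aggregate(error_percent ~ projection + classifier, data = records,
                   FUN = function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- data.frame(projection = agg$projection, classifier = agg$classifier,
                    mean_error = agg$error_percent[, "mean"],
                    sd_error = agg$error_percent[, "sd"],
                    n = agg$error_percent[, "n"])
  out[order(out$projection, out$classifier), ]
}

#' Training-position-reduction experiment
#'
#' The study's second experiment: along a schedule of training-position
#' subsets (default: the nine best-position subsets, 1 to 9 positions), the
#' projection and classifier are trained on windows from the scheduled
#' positions only and tested on held-out windows from all nine positions.
#' Windows are split 80/20 within every position; the training side of the
#' scheduled positions trains, the held-out 20 percent of all positions tests.
#' Reported per subset: percent error, SI of the projected training data, and
#' RI between projected training and all-position test data.
#'
#' @param fs a 66-D `GraspFeatureSet`.
#' @param schedule list of position-label vectors ([positionSchedule()]).
#' @param projection,classifier the evaluated pair (study focus: SRELM + NN).
#' @param trainFrac within-position training fraction.
#' @param seed base seed.
#' @param k projected dimension.
#' @param projParams projection parameters (seed is added automatically for
#'   SRELM/t-SNE).
#' @return an `ExperimentResult` list with `records` (subject, n_positions,
#'   training_positions, error_percent, SI, RI).
#' @export
runPositionReduction <- function(fs, schedule = positionSchedule(),
    projection = "srelm", classifier = "nn", trainFrac = 0.8, seed = 1L,
    k = 4L, projParams = NULL) {
  if (any(vapply(schedule, length, integer(1)) == 0)) stop("empty position subset")
  if (is.null(projParams)) {
    projParams <- switch(projection,
      srelm = list(L = 1000L, alpha = 1, seed = seed),
      tsne = list(perplexity = 30, seed = seed),
      list())
  }
  records <- list()
  for (subj in unique(subjectLabels(fs))) {
    sub <- subsetWindows(fs, subjectLabels(fs) == subj)
    pos <- as.character(positionLabels(sub))
    # one fixed 80/20 split within every position, shared by all subsets
    set.seed(.subSeed(seed, 20000000L))
    inTrain <- logical(ncol(sub))
    for (p in unique(pos)) {
      idx <- which(pos == p)
      nTr <- floor(trainFrac * length(idx))
      inTrain[sample(idx, nTr)] <- TRUE
    }
    for (s in seq_along(schedule)) {
      pset <- schedule[[s]]
      trIdx <- which(inTrain & pos %in% pset)
      tsIdx <- which(!inTrain)
      tr <- subsetWindows(sub, trIdx); ts <- subsetWindows(sub, tsIdx)
      norm <- fitNormalizer(tr)
      pr <- projectFeatures(projection, applyNormalizer(norm, tr),
                            applyNormalizer(norm, ts), k = k,
                            params = projParams)
      spec <- classifierSpec(classifier, seed = seed)
      model <- trainClassifier(spec, pr$train)
      err <- classificationError(graspLabels(pr$test),
                                 predictClassifier(model, pr$test))
      records[[length(records) + 1L]] <- data.frame(
        subject = subj, n_positions = length(pset),
        training_positions = paste(pset, collapse = "-"),
        error_percent = err,
        SI = separabilityIndex(pr$train),
        RI = repeatabilityIndex(pr$train, pr$test),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(records = do.call(rbind, records)),
            class = "ExperimentResult")
}

#' @export
print.ExperimentResult <- function(x, ...) {
  cat("ExperimentResult with", nrow(x$records), "records\n")
  if (!is.null(x$aggregates)) {
    cat("Aggregate mean error (%) per projection x classifier:\n")
    print(x$aggregates, row.names = FALSE, digits = 3)
  } else {
    print(head(x$records, 12), row.names = FALSE, digits = 3)
  }
  invisible(x)
}
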