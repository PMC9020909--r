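#' Train the linear segment classifier
#'
#' Z-score normalization is fitted on the training rows (constant
#' features dropped with a warning), then a linear hinge-loss SVM with
#' C = 1 is fitted on the standardized segments, every segment carrying
#' its trial's label. The solver is a deterministic dual
#' coordinate-descent routine (the liblinear algorithm, compiled);
#' cross-validation over thousands of folds makes the quadratic
#' kernel-cache solvers impractical here, and the linear primal weight
#' vector is exactly what the channel weight maps need.
#'
#' @param features a [FusedFeatureSet-class] of training segments.
#' @param labels optional per-segment labels (default: the labels in
#'   `segmentInfo(features)`).
#' @param cost SVM regularization constant C (default 1).
#' @return a [ClassifierModel-class].
#' @export
trainClassifier <- function(features, labels = NULL, cost = 1) {
  stopifnot(is(features, "FusedFeatureSet"))
  X <- features@values
  if (is.null(labels)) labels <- features@segmentInfo$label
  y <- factor(as.character(labels), levels = c("fear", "neutral"))
  if (length(unique(y)) < 2)
    ffStop("TrainError", "training data contains a single class")
  fit <- .fitLinearSVM(X, y, cost)
  new("ClassifierModel", weights = fit$w, bias = fit$b,
      center = fit$center, scale = fit$scale, keep = fit$keep,
      featureNames = features@featureNames, blocks = features@blocks,
      levels = levels(y))
}

## core fit on a plain matrix: z-score, then dual coordinate descent on
## the standardized rows with an augmented bias feature; fear -> +1
.fitLinearSVM <- function(X, y, cost = 1, tol = 1e-3,
                          maxEpochs = 2000L) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  keep <- scale > 0
  if (!all(keep))
    ffWarn("TrainWarning", sprintf(
      "%d constant feature(s) dropped before standardization",
      sum(!keep)))
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep]), 2,
              scale[keep], "/")
  yy <- ifelse(y == levels(y)[1], 1, -1)
  fit <- .svmDualCD(t(cbind(Xs, 1)), yy, cost, tol, maxEpochs)
  w <- numeric(ncol(X))
  w[keep] <- fit$w[seq_len(sum(keep))]
  names(w) <- colnames(X)
  list(w = w, b = fit$w[sum(keep) + 1], center = center, scale = scale,
       keep = keep, epochs = fit$epochs)
}

## decision values for new rows (plain matrix on the original scale);
## positive = first class level ("fear")
.decisionSVM <- function(model, X) {
  Xs <- sweep(sweep(X[, model@keep, drop = FALSE], 2,
                    model@center[model@keep]), 2,
              model@scale[model@keep], "/")
  as.vector(Xs %*% model@weights[model@keep] + model@bias)
}

## predicted labels; a decision value of exactly 0 falls to "neutral"
.predictSVM <- function(model, X) {
  ifelse(.decisionSVM(model, X) > 0, model@levels[1], model@levels[2])
}

#' Majority-vote trial prediction
#'
#' Predicts every segment of one trial and returns the most common
#' segment label as the trial label. An even split is broken toward
#' "neutral" and flagged.
#'
#' @param model a [ClassifierModel-class].
#' @param trialFeatures a [FusedFeatureSet-class] (or numeric matrix)
#'   holding the segments of a single trial.
#' @return list with `label`, `votes` (named counts), `tie` (logical).
#' @export
predictTrial <- function(model, trialFeatures) {
  X <- if (is(trialFeatures, "FusedFeatureSet")) trialFeatures@values
       else trialFeatures
  if (nrow(X) == 0) ffStop("PredictError", "no segments to predict")
  pred <- .predictSVM(model, X)
  votes <- c(fear = sum(pred == "fear"), neutral = sum(pred == "neutral"))
  tie <- votes[["fear"]] == votes[["neutral"]]
  label <- if (tie) "neutral" else names(which.max(votes))
  if (tie) ffWarn("TieWarning", "segment votes tied; labeling neutral")
  list(label = label, votes = votes, tie = tie)
}

## fold-wise CSP feature matrix for all segments, fitted on training
## segments only (provenance: trial indices in cache$segmentInfo)
.foldCSP <- function(cache, trainMask, normalizeVariance = FALSE) {
  info <- cache$segmentInfo
  lab <- info$label
  out <- vector("list", length(cache$bands))
  models <- vector("list", length(cache$bands))
  for (bi in seq_along(cache$bands)) {
    A <- cache$covs[[bi]]
    tr <- cache$traces[[bi]]
    i1 <- which(trainMask & lab == "fear")
    i2 <- which(trainMask & lab == "neutral")
    C1 <- .meanNormCov(A, tr, i1)
    C2 <- .meanNormCov(A, tr, i2)
    m <- .fitCSPFromCovs(C1, C2, cache$bands[[bi]])
    models[[bi]] <- m
    Fb <- m@filters[m@selected, , drop = FALSE]
    nSeg <- dim(A)[3]
    v <- matrix(NA_real_, nSeg, 6)
    for (k in seq_len(6)) {
      fk <- Fb[k, ]
      ## f' S f for every segment at once: flatten the cov array
      M <- matrix(A, dim(A)[1], dim(A)[2] * nSeg)
      v[, k] <- colSums(matrix(fk %*% M, dim(A)[2], nSeg) * fk)
    }
    v[v <= 0] <- .POWER_FLOOR
    if (normalizeVariance) v <- v / rowSums(v)
    colnames(v) <- paste("CSP", cache$bands[[bi]]@name,
                         paste0("comp", 1:6), sep = "|")
    out[[bi]] <- log10(v)
  }
  names(models) <- names(cache$bands)
  list(csp = do.call(cbind, out), models = models)
}

.meanNormCov <- function(A, traces, idx) {
  S <- matrix(0, dim(A)[1], dim(A)[2])
  for (i in idx) S <- S + A[, , i] / traces[i]
  S / length(idx)
}

#' Leave-one-out cross-validated trial classification
#'
#' For each trial in turn: per-band CSP models, feature normalization,
#' and the SVM are fitted on the remaining trials only; the held-out
#' trial's segments are then extracted with those training artifacts
#' and majority-vote classified. Accuracy is the percentage of
#' correctly labeled trials. Single blocks and single bands are
#' selectable, so the full feature x band comparison grid can be run.
#'
#' @param session an [EEGSession-class].
#' @param blocks character subset of c("DE", "ENP", "CSP").
#' @param bandSelection "all" (concatenate the five per-band blocks) or
#'   a single band name.
#' @param cache optional precomputed [sessionFeatureCache()] of
#'   `session` (computed if missing); sharing it across calls avoids
#'   re-extracting features when running the comparison grid.
#' @param cost SVM regularization constant.
#' @param shuffleLabels permute trial labels before evaluation (chance
#'   control); uses `shuffleSeed`.
#' @param shuffleSeed seed for the label permutation.
#' @param ... passed to [sessionFeatureCache()].
#' @return a [CVResult-class].
#' @export
loocv <- function(session, blocks = c("DE", "ENP", "CSP"),
                  bandSelection = "all", cache = NULL, cost = 1,
                  shuffleLabels = FALSE, shuffleSeed = 1, ...) {
  if (is.null(cache)) cache <- sessionFeatureCache(session, ...)
  info <- cache$segmentInfo
  trials <- sort(unique(info$trial))
  trialLab <- vapply(trials, function(tr)
    info$label[match(tr, info$trial)], "")
  if (shuffleLabels) {
    trialLab <- .withSeed(shuffleSeed, sample(trialLab))
    info$label <- trialLab[match(info$trial, trials)]
  }
  if (min(table(trialLab)) < 2)
    ffStop("TrainError", "need at least two trials per class")
  useCSP <- "CSP" %in% blocks
  folds <- lapply(trials, function(heldOut) {
    trainMask <- info$trial != heldOut
    cspRes <- if (useCSP) .foldCSP(cache, trainMask)
    fused <- fuseFeatures(
      de = if ("DE" %in% blocks) cache$de,
      enp = if ("ENP" %in% blocks) cache$enp,
      csp = if (useCSP) cspRes$csp,
      segmentInfo = info, blocks = blocks)
    cols <- .bandColumns(fused@featureNames, bandSelection)
    X <- fused@values[, cols, drop = FALSE]
    yTrain <- factor(info$label[trainMask],
                     levels = c("fear", "neutral"))
    fit <- .fitLinearSVM(X[trainMask, , drop = FALSE], yTrain, cost)
    mdl <- new("ClassifierModel", weights = fit$w, bias = fit$b,
               center = fit$center, scale = fit$scale, keep = fit$keep,
               featureNames = fused@featureNames[cols],
               blocks = fused@blocks, levels = levels(yTrain))
    pred <- withCallingHandlers(
      predictTrial(mdl, X[!trainMask, , drop = FALSE]),
      fearfuseWarning = function(w) invokeRestart("muffleWarning"))
    data.frame(trial = heldOut,
               truth = trialLab[match(heldOut, trials)],
               predicted = pred$label,
               votesFear = pred$votes[["fear"]],
               votesNeutral = pred$votes[["neutral"]],
               tie = pred$tie, stringsAsFactors = FALSE)
  })
  folds <- do.call(rbind, folds)
  new("CVResult", folds = folds,
      accuracy = 100 * mean(folds$truth == folds$predicted),
      config = list(blocks = blocks, bandSelection = bandSelection,
                    cost = cost, shuffleLabels = shuffleLabels))
}

#' @rdname loocv
#' @param x a [CVResult-class].
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname loocv
#' @export
setMethod("accuracy", "CVResult", function(x) x@accuracy)

#' @rdname loocv
#' @export
setGeneric("foldPredictions", function(x) standardGeneric("foldPredictions"))

#' @rdname loocv
#' @export
setMethod("foldPredictions", "CVResult", function(x) x@folds)

setMethod("show", "CVResult", function(object) {
  cat(sprintf(paste0("CVResult: %d folds, accuracy %.2f%% ",
                     "(blocks %s, bands %s)\n"),
              nrow(object@folds), object@accuracy,
              paste(object@config$blocks, collapse = "+"),
              object@config$bandSelection))
})

#' Feature-by-band accuracy grid
#'
#' Runs [loocv()] for every requested feature set and band selection
#' (the per-subject comparison table), reusing one feature cache.
#'
#' @param session an [EEGSession-class].
#' @param featureSets named list of block subsets; default the four
#'   canonical sets DE, ENP, CSP, DE_ENP_CSP.
#' @param bands band selections; default the five bands plus "all".
#' @param cache optional precomputed cache.
#' @param ... passed to [loocv()].
#' @return data.frame: feature, band, accuracy.
#' @export
accuracyGrid <- function(session,
                         featureSets = list(DE = "DE", ENP = "ENP",
                                            CSP = "CSP",
                                            DE_ENP_CSP = c("DE", "ENP",
                                                           "CSP")),
                         bands = c(names(defaultBands()), "all"),
                         cache = NULL, ...) {
  if (is.null(cache)) cache <- sessionFeatureCache(session)
  grid <- expand.grid(feature = names(featureSets), band = bands,
                      stringsAsFactors = FALSE)
  grid$accuracy <- mapply(function(f, b)
    accuracy(loocv(session, blocks = featureSets[[f]],
                   bandSelection = b, cache = cache, ...)),
    grid$feature, grid$band)
  grid
}

#' Per-channel classifier weight map
#'
#' For each channel, the mean over bands of the absolute DE-block SVM
#' weights assigned to that channel — the data behind a topographic
#' weight map (export only; no plotting here).
#'
#' @param model a [ClassifierModel-class] trained with the DE block.
#' @return named numeric vector, one weight per channel.
#' @export
channelWeightMap <- function(model) {
  stopifnot(is(model, "ClassifierModel"))
  w <- model@weights
  de <- grep("^DE\\|", names(w), value = TRUE)
  if (length(de) == 0)
    ffStop("WeightMapError", "model has no DE-block features")
  parts <- strsplit(de, "|", fixed = TRUE)
  chan <- vapply(parts, `[`, "", 3)
  out <- tapply(abs(w[de]), chan, mean)
  chans <- unique(chan)
  out <- as.numeric(out[chans])
  names(out) <- chans
  out
}

#' Paired t test between two per-subject accuracy vectors
#'
#' Two-sided paired t test comparing, e.g., fusion accuracies against a
#' single-feature method across subjects. With a zero-variance
#' difference vector the test degenerates: p = 1 if the means are equal
#' and p = 0 otherwise (flagged with a warning).
#'
#' @param accuraciesA,accuraciesB numeric vectors, equal length >= 2.
#' @return the two-sided p value.
#' @export
compareFeaturesTTest <- function(accuraciesA, accuraciesB) {
  stopifnot(length(accuraciesA) == length(accuraciesB),
            length(accuraciesA) >= 2)
  d <- accuraciesA - accuraciesB
  if (stats::sd(d) == 0) {
    ffWarn("StatsWarning", "zero-variance differences; degenerate p")
    return(if (mean(d) == 0) 1 else 0)
  }
  stats::t.test(accuraciesA, accuraciesB, paired = TRUE)$p.value
}
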