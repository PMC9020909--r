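#' Fit a per-band common-spatial-pattern model
#'
#' Standard composite-whitening CSP: the trace-normalized covariance of
#' every band-filtered segment is averaged per class; the composite
#' covariance `C1 + C2` is whitened; the whitened class-1 covariance is
#' eigendecomposed; spatial filters are the eigenvectors transformed
#' back through the whitener, ordered by descending eigenvalue. The
#' first three and last three rows (the ends that maximize the variance
#' ratio for one class or the other) are selected for features.
#'
#' Filter signs are fixed so each row's largest-magnitude coefficient is
#' positive (signs are mathematically arbitrary; fixing them makes
#' outputs reproducible). Exact eigenvalue ties are broken by the
#' ascending channel index of the dominant coefficient. A ridge of
#' `1e-8 * trace / n` is added to a rank-deficient composite covariance.
#'
#' @param segmentsClass1,segmentsClass2 lists of band-filtered
#'   [Segment-class] objects (or channels x samples matrices), one list
#'   per class. Class 1 is conventionally "fear".
#' @param band the [FrequencyBand-class] the segments were filtered in.
#' @param classNames character(2), recorded as `classOrder`.
#' @return a [CSPModel-class].
#' @export
fitCSP <- function(segmentsClass1, segmentsClass2, band,
                   classNames = c("fear", "neutral")) {
  m1 <- .segCovMean(segmentsClass1)
  m2 <- .segCovMean(segmentsClass2)
  n <- nrow(m1)
  if (length(segmentsClass1) < n || length(segmentsClass2) < n)
    ffWarn("CSPWarning",
           "fewer segments than channels in a class; covariance may be poorly conditioned")
  .fitCSPFromCovs(m1, m2, band, classNames)
}

.segCov <- function(s) {
  d <- if (is(s, "Segment")) s@data else s
  tcrossprod(d)
}

.segCovMean <- function(segs) {
  covs <- lapply(segs, .segCov)
  norm <- lapply(covs, function(S) {
    tr <- sum(diag(S))
    if (tr <= 0) ffStop("CSPError", "zero-power segment in CSP fit")
    S / tr
  })
  Reduce(`+`, norm) / length(norm)
}

## C1, C2: trace-normalized mean class covariances
.fitCSPFromCovs <- function(C1, C2, band, classNames = c("fear", "neutral")) {
  n <- nrow(C1)
  comp <- (C1 + C2)
  comp <- (comp + t(comp)) / 2
  e <- eigen(comp, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(e$values)) {
    ffWarn("CSPWarning", "rank-deficient composite covariance; adding ridge")
    comp <- comp + diag(1e-8 * sum(diag(comp)) / n, n)
    e <- eigen(comp, symmetric = TRUE)
    if (min(e$values) <= 0)
      ffStop("CSPError", "composite covariance is singular")
  }
  P <- diag(1 / sqrt(e$values)) %*% t(e$vectors)   # whitener
  S1 <- P %*% C1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  e1 <- eigen(S1, symmetric = TRUE)                # descending values
  F <- t(e1$vectors) %*% P
  lambda <- pmin(pmax(e1$values, 0), 1)
  dom <- apply(abs(F), 1, which.max)
  o <- order(-lambda, dom)                         # tie-break by channel
  F <- F[o, , drop = FALSE]
  lambda <- lambda[o]
  sgn <- ifelse(F[cbind(seq_len(n), apply(abs(F), 1, which.max))] < 0,
                -1, 1)
  F <- F * sgn
  rownames(F) <- NULL
  new("CSPModel", band = band, filters = F,
      selected = as.integer(c(1:3, (n - 2):n)), eigenvalues = lambda,
      classOrder = classNames)
}

#' @rdname fitCSP
#' @param x a [CSPModel-class].
#' @export
setGeneric("spatialFilters", function(x) standardGeneric("spatialFilters"))

#' @rdname fitCSP
#' @export
setMethod("spatialFilters", "CSPModel", function(x) x@filters)

#' @rdname fitCSP
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname fitCSP
#' @export
setMethod("eigenvalues", "CSPModel", function(x) x@eigenvalues)

setMethod("show", "CSPModel", function(object) {
  cat(sprintf(paste0("CSPModel [%s %g-%g Hz]: %d filters, selected ",
                     "rows %s\n  extreme eigenvalues: %.3f / %.3f\n"),
              object@band@name, object@band@low, object@band@high,
              nrow(object@filters),
              paste(object@selected, collapse = ","),
              object@eigenvalues[1],
              object@eigenvalues[length(object@eigenvalues)]))
})

#' CSP log-variance features of one segment
#'
#' Projects a band-filtered segment through the six selected spatial
#' filters and returns `log10` of each projection's energy (the
#' diagonal of `Fbar %*% E %*% t(E) %*% t(Fbar)`). No cross-component
#' variance normalization is applied by default (the literal
#' log-energy form); `normalizeVariance = TRUE` divides each energy by
#' their sum first.
#'
#' @param model a fitted [CSPModel-class].
#' @param segment a band-filtered [Segment-class] or matrix.
#' @param normalizeVariance divide energies by their total before log.
#' @return numeric vector of length 6.
#' @export
cspFeatures <- function(model, segment, normalizeVariance = FALSE) {
  d <- if (is(segment, "Segment")) segment@data else segment
  if (nrow(d) != ncol(model@filters))
    ffStop("CSPError", "segment channel count does not match model")
  Fb <- model@filters[model@selected, , drop = FALSE]
  v <- rowSums((Fb %*% d)^2)
  if (normalizeVariance) v <- v / sum(v)
  if (any(v <= 0)) {
    ffWarn("CSPWarning", "zero projected variance floored")
    v <- pmax(v, .POWER_FLOOR)
  }
  log10(v)
}

#' CSP feature block of a trial
#'
#' Band-filters the preprocessed trial with the filter bank, segments
#' it, and concatenates the per-band 6-component log-variance features
#' band-major: 30 columns for the 5-band bank.
#'
#' @param models named list of fitted [CSPModel-class], one per band,
#'   in band order.
#' @param epoch a preprocessed [TrialEpoch-class].
#' @param windowSec,stepSec segmentation grid (default 1 s, 1 s).
#' @param normalizeVariance see [cspFeatures()].
#' @return numeric matrix, segments x (6 * bands), feature names
#'   "CSP|band|comp".
#' @export
cspFeatureMatrix <- function(models, epoch, windowSec = 1, stepSec = 1,
                             normalizeVariance = FALSE) {
  .requireSteps(epoch, c("baseline", "notch", "bandpass"))
  fs <- epoch@samplingRate
  blocks <- lapply(models, function(m) {
    filt <- bandFilter(epoch@stimulus, m@band, fs = fs)
    nWin <- round(windowSec * fs); nStep <- round(stepSec * fs)
    starts <- seq(0L, ncol(filt) - nWin, by = nStep)
    t(vapply(starts, function(s0)
      cspFeatures(m, filt[, (s0 + 1):(s0 + nWin), drop = FALSE],
                  normalizeVariance),
      numeric(6)))
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(models, function(m)
    paste("CSP", m@band@name, paste0("comp", seq_len(6)), sep = "|")),
    use.names = FALSE)
  out
}

#' Serialize / restore a fitted CSP model
#'
#' Plain-JSON archive of the spatial filters, eigenvalues, selected
#' rows, band, and class order, so models fitted in a training session
#' can be applied later or inspected from other languages. Numeric
#' values are written in full precision.
#'
#' @param model a [CSPModel-class].
#' @param path output path (conventionally `.cspmodel.json`).
#' @return `path` (write) / a [CSPModel-class] (read).
#' @export
writeCSPModel <- function(model, path) {
  stopifnot(is(model, "CSPModel"))
  obj <- list(format = "fearfuse-cspmodel-v1",
              band = list(name = model@band@name, low = model@band@low,
                          high = model@band@high),
              filters = model@filters,
              selected = model@selected,
              eigenvalues = model@eigenvalues,
              classOrder = model@classOrder)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCSPModel
#' @export
readCSPModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "fearfuse-cspmodel-v1"))
    ffStop("FileError", "not a fearfuse CSP model archive")
  new("CSPModel",
      band = frequencyBand(obj$band$name, obj$band$low, obj$band$high),
      filters = obj$filters, selected = as.integer(obj$selected),
      eigenvalues = obj$eigenvalues, classOrder = obj$classOrder)
}
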