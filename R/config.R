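#' Read a pipeline configuration from YAML or JSON
#'
#' A configuration file may override the montage, the frequency-band
#' bank, and the preprocessing filter settings:
#'
#' ```yaml
#' montage:
#'   channels: [Fp1, Fp2, ...]
#'   reference: A2
#'   ground: Fpz
#' bands:
#'   - {name: delta, low: 1, high: 3}
#'   - {name: alpha, low: 8, high: 13}
#' filters:
#'   notchFreq: 50
#'   notchQ: 30
#'   bandpassLow: 0.1
#'   bandpassHigh: 70
#'   bandpassOrder: 10
#' ```
#'
#' Omitted sections fall back to [standardMontage()], [defaultBands()],
#' and [filterSpec()] defaults.
#'
#' @param path a `.yaml`/`.yml` (requires the yaml package) or `.json`
#'   file.
#' @return list with elements `montage`, `bands`, `filters`.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) ffStop("FileError", paste("no such file:", path))
  cfg <- if (grepl("[.]ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      ffStop("ConfigError", "reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  montage <- if (is.null(cfg$montage)) standardMontage()
    else new("Montage",
             channels = as.character(unlist(cfg$montage$channels)),
             reference = cfg$montage$reference %||% "A2",
             ground = cfg$montage$ground %||% "Fpz")
  bands <- if (is.null(cfg$bands)) defaultBands()
    else {
      out <- lapply(cfg$bands, function(b)
        frequencyBand(b$name, b$low, b$high))
      names(out) <- vapply(out, function(b) b@name, "")
      out
    }
  f <- cfg$filters
  filters <- filterSpec(
    notchFreq = f$notchFreq %||% 50, notchQ = f$notchQ %||% 30,
    bandpassLow = f$bandpassLow %||% 0.1,
    bandpassHigh = f$bandpassHigh %||% 70,
    bandpassOrder = f$bandpassOrder %||% 10)
  list(montage = montage, bands = bands, filters = filters)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a cross-validation run log
#'
#' JSON record of a [CVResult-class]: the configuration snapshot, the
#' accuracy, and the per-fold predictions — the audit trail of an
#' evaluation run.
#'
#' @param cv a [CVResult-class].
#' @param path output path.
#' @param seed optional seed to record alongside the config.
#' @return `path`, invisibly.
#' @export
writeRunLog <- function(cv, path, seed = NULL) {
  stopifnot(is(cv, "CVResult"))
  jsonlite::write_json(
    list(config = cv@config, seed = seed, accuracy = cv@accuracy,
         folds = cv@folds),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
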