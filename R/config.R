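#' Load a run configuration file
#'
#' Reads a flat key-value configuration (JSON, or YAML when the `yaml`
#' package is available) and resolves it against the default parameter
#' set: unspecified keys take their defaults, unknown keys are a hard
#' error (no silently ignored typos). Keys are the argument names of
#' [fieldParams()], [trainingConfig()] and [lesionSpec()].
#'
#' @param path path to a `.json`, `.yaml`/`.yml` file, or `NULL` for pure
#'   defaults.
#' @return A list with elements `params` (a `FieldParams`), `training`
#'   (a `TrainingConfig`), `lesion` (a `LesionSpec` or `NULL`), and
#'   `overridden` (character vector of keys set by the file).
#' @export
loadConfig <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    raw <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the 'yaml' package", call. = FALSE)
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    if (is.null(raw)) raw <- list()
  }
  fp_keys <- names(formals(fieldParams))
  tc_keys <- names(formals(trainingConfig))
  ls_keys <- c("lesion_target", "lesion_type", "lesion_fraction",
               "lesion_orientation")
  unknown <- setdiff(names(raw), c(fp_keys, tc_keys, ls_keys))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- do.call(fieldParams, raw[intersect(names(raw), fp_keys)])
  training <- do.call(trainingConfig, raw[intersect(names(raw), tc_keys)])
  lesion <- NULL
  if (any(ls_keys %in% names(raw))) {
    lesion <- lesionSpec(
      target = if (!is.null(raw$lesion_target)) raw$lesion_target else "skin",
      type = if (!is.null(raw$lesion_type)) raw$lesion_type else "II",
      fraction = raw$lesion_fraction,
      orientation = if (!is.null(raw$lesion_orientation))
        raw$lesion_orientation else "vertical",
      grid_shape = c(params$m, params$m))
  }
  list(params = params, training = training, lesion = lesion,
       overridden = names(raw))
}

#' Write a run manifest
#'
#' Records every resolved parameter, the seeds, timestamps, package
#' version and output paths of a run as JSON, so the run is
#' reconstructible from the manifest alone.
#'
#' @param path output file.
#' @param params a `FieldParams`.
#' @param training a `TrainingConfig` (or `NULL`).
#' @param lesion a `LesionSpec` (or `NULL`).
#' @param seed the run seed.
#' @param outputs named list or character vector of output paths.
#' @param overridden keys overridden by the user's config file.
#' @export
writeRunManifest <- function(path, params, training = NULL, lesion = NULL,
                             seed = NA_integer_, outputs = list(),
                             overridden = character(0)) {
  man <- list(
    package = "somatomap",
    version = as.character(utils::packageVersion("somatomap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = unclass(params),
    training = if (!is.null(training)) unclass(training),
    lesion = if (!is.null(lesion)) unclass(lesion),
    overridden = as.list(overridden),
    outputs = as.list(outputs))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
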