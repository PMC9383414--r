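# Portable text containers (JSON, 17-significant-digit numbers so doubles
# round-trip bit-exactly), run configuration handling, and artifact
# provenance (seed + config hash embedded in every file).

CONTAINER_VERSION <- "1.0"

to_json_file <- function(x, path) {
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE, null = "null")
}

#' Write an EEG dataset to the portable trial container
#'
#' Single JSON file holding the format version, dataset metadata (including
#' generator provenance such as seeds, when supplied) and every trial's
#' matrix at full precision: write -> read reproduces the trials
#' bit-exactly.
#'
#' @param dataset An [eeg_dataset()].
#' @param path Output file.
#' @param provenance Optional named list recorded verbatim (e.g. seeds,
#'   config hash).
#' @return `path`, invisibly.
#' @export
write_trial_container <- function(dataset, path, provenance = NULL) {
  obj <- list(
    version = CONTAINER_VERSION,
    kind = "eeg_trials",
    metadata = list(n_channels = dataset$n_channels,
                    n_classes = dataset$n_classes,
                    sampling_rate = dataset$sampling_rate,
                    class_names = dataset$class_names,
                    provenance = provenance),
    trials = lapply(dataset$trials, function(tr) {
      list(label = tr$label, subject = tr$subject,
           data = apply(tr$data, 1, function(r) r, simplify = FALSE))
    })
  )
  to_json_file(obj, path)
  invisible(path)
}

#' Read the portable trial container
#'
#' @param path File written by [write_trial_container()].
#' @return An [eeg_dataset()]; generator provenance, if present, is attached
#'   as attribute `"provenance"`.
#' @export
read_trial_container <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$version, CONTAINER_VERSION)) {
    stopf("unsupported trial container version %s (expected %s)",
          obj$version %||% "<missing>", CONTAINER_VERSION)
  }
  md <- obj$metadata
  trials <- lapply(obj$trials, function(tr) {
    list(data = do.call(rbind, lapply(tr$data, function(r) unlist(r, use.names = FALSE))),
         label = as.integer(tr$label), subject = as.character(tr$subject))
  })
  ds <- eeg_dataset(trials, n_channels = md$n_channels, n_classes = md$n_classes,
                    sampling_rate = md$sampling_rate,
                    class_names = unlist(md$class_names))
  attr(ds, "provenance") <- md$provenance
  ds
}

# ---- model / descriptor serialization --------------------------------------

array_to_json <- function(a) list(dim = dim(a) %||% length(a), values = as.numeric(a))

array_from_json <- function(o) {
  v <- unlist(o$values, use.names = FALSE)
  dm <- unlist(o$dim, use.names = FALSE)
  if (length(dm) > 1) dim(v) <- dm
  v
}

#' Save model parameters as JSON
#'
#' @param params A `model_params` object.
#' @param path Output file.
#' @param provenance Optional named list (seed, config hash, phase tag).
#' @return `path`, invisibly.
#' @export
write_model <- function(params, path, provenance = NULL) {
  obj <- list(
    version = CONTAINER_VERSION, kind = "model_params",
    input_dim = params$input_dim, n_classes = params$n_classes,
    flatten_dim = params$flatten_dim,
    extractor = lapply(params$extractor, function(l) {
      list(W = array_to_json(l$W), b = array_to_json(l$b))
    }),
    classifier = lapply(params$classifier, array_to_json),
    ss = params$ss,
    provenance = provenance
  )
  to_json_file(obj, path)
  invisible(path)
}

#' Load model parameters saved by [write_model()]
#' @param path Input file.
#' @return A `model_params` object (provenance attached as attribute).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$kind, "model_params") || !identical(obj$version, CONTAINER_VERSION)) {
    stopf("%s is not a version-%s model file", path, CONTAINER_VERSION)
  }
  params <- structure(
    list(extractor = lapply(obj$extractor, function(l) {
           list(W = array_from_json(l$W), b = array_from_json(l$b))
         }),
         classifier = lapply(obj$classifier, array_from_json),
         ss = list(scale = unlist(obj$ss$scale), shift = unlist(obj$ss$shift)),
         input_dim = as.integer(obj$input_dim),
         n_classes = as.integer(obj$n_classes),
         flatten_dim = as.integer(obj$flatten_dim)),
    class = "model_params"
  )
  attr(params, "provenance") <- obj$provenance
  params
}

#' Save normalized or raw descriptors (plus optional normalizer stats)
#' @param samples List of [spd_sample()] objects.
#' @param path Output file.
#' @param stats Optional [fit_normalizer()] result to embed.
#' @param provenance Optional named list.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(samples, path, stats = NULL, provenance = NULL) {
  obj <- list(
    version = CONTAINER_VERSION, kind = "spd_descriptors",
    samples = lapply(samples, function(s) {
      list(label = s$label, subject = s$subject, normalized = s$normalized,
           matrix = array_to_json(s$matrix))
    }),
    normalizer = if (!is.null(stats)) {
      list(mean = array_to_json(stats$mean), std = array_to_json(stats$std),
           guarded = array_to_json(stats$guarded * 1),
           n_fitted = stats$n_fitted, epsilon = stats$epsilon)
    },
    provenance = provenance
  )
  to_json_file(obj, path)
  invisible(path)
}

#' Load descriptors saved by [write_descriptors()]
#' @param path Input file.
#' @return List with `samples`, `stats` (or `NULL`) and `provenance`.
#' @export
read_descriptors <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$kind, "spd_descriptors")) stopf("%s is not a descriptor file", path)
  samples <- lapply(obj$samples, function(s) {
    spd_sample(array_from_json(s$matrix), label = as.integer(s$label),
               subject = as.character(s$subject), normalized = isTRUE(s$normalized))
  })
  stats <- NULL
  if (!is.null(obj$normalizer)) {
    stats <- structure(
      list(mean = array_from_json(obj$normalizer$mean),
           std = array_from_json(obj$normalizer$std),
           guarded = array_from_json(obj$normalizer$guarded) > 0,
           n_fitted = obj$normalizer$n_fitted,
           epsilon = obj$normalizer$epsilon),
      class = "normalizer_stats")
  }
  list(samples = samples, stats = stats, provenance = obj$provenance)
}

# ---- configuration ---------------------------------------------------------

#' Load and validate a run configuration
#'
#' YAML file whose keys must be a subset of the [training_config()]
#' arguments; unknown keys are rejected.  The resolved configuration carries
#' a content hash as attribute `"config_hash"`.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied after the file.
#' @return A [training_config()] with a `config_hash` attribute.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(training_config))
    bad <- setdiff(names(vals), known)
    if (length(bad) > 0) {
      stopf("unknown configuration key(s): %s", paste(bad, collapse = ", "))
    }
  }
  vals[names(overrides)] <- overrides
  cfg <- do.call(training_config, vals)
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

#' Content hash of a configuration
#' @param config A [training_config()].
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  flat <- unlist(config[sort(names(config))])
  string_hash(paste(names(flat), sprintf("%.17g", as.numeric(flat)),
                    sep = "=", collapse = ";"))
}

#' Load an EEG dataset from a supported format
#'
#' `"container"` reads the portable JSON trial container.  Raw `"edf"` /
#' `"gdf"` recordings additionally need an event-to-class mapping and an
#' epoch window; no reader for those binary formats ships with this package,
#' so requesting them signals an error directing the user to epoch the
#' recording externally and convert it to the container format.
#'
#' @param path Input file.
#' @param format One of `"container"`, `"edf"`, `"gdf"`.
#' @param event_mapping,epoch_window Epoching options for raw formats.
#' @return An [eeg_dataset()].
#' @export
load_dataset <- function(path, format = c("container", "edf", "gdf"),
                         event_mapping = NULL, epoch_window = NULL) {
  format <- match.arg(format)
  if (format == "container") return(read_trial_container(path))
  if (is.null(event_mapping) || is.null(epoch_window)) {
    stopf("%s input needs an event-to-class mapping and an epoch window", format)
  }
  stopf(paste0("no %s reader is bundled: epoch the recording externally ",
               "(e.g. with MNE) and convert it to the trial container format"), format)
}
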