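# Serialization: array state and experiment logs round-trip through JSON;
# device parameters through flat YAML key/value files.

#' Save a synapse array state to JSON
#'
#' The file records, per pixel and device, the conductance, pulse count,
#' dry-storage age and variability factor, together with the device
#' parameters, read configuration and (if present) the initialization
#' seed, so that [load_array_state()] reconstructs the array exactly.
#'
#' @param array A `synapse_array`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_array_state <- function(array, path) {
  stopifnot(inherits(array, "synapse_array"))
  field <- function(dev, nm) {
    vapply(array$pixels, function(px) px[[dev]][[nm]], numeric(1))
  }
  state <- list(
    n_pixels = array$n_pixels,
    params = unclass(array$params),
    read_config = unclass(array$cfg),
    seed = attr(array, "seed"),
    plus = list(g = field("plus", "g"), n_pulses = field("plus", "n_pulses"),
                age_h = field("plus", "age_h"),
                dev_factor = field("plus", "dev_factor"),
                g_ref = field("plus", "g_ref")),
    minus = list(g = field("minus", "g"), n_pulses = field("minus", "n_pulses"),
                 age_h = field("minus", "age_h"),
                 dev_factor = field("minus", "dev_factor"),
                 g_ref = field("minus", "g_ref"))
  )
  jsonlite::write_json(state, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a synapse array state from JSON
#'
#' @param path File written by [save_array_state()].
#' @return A `synapse_array`.
#' @export
load_array_state <- function(path) {
  st <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(device_params, st$params[
    intersect(names(st$params), names(formals(device_params)))])
  cfg <- do.call(read_config, st$read_config)
  arr <- synapse_array(params, cfg, n_pixels = st$n_pixels)
  for (i in seq_len(arr$n_pixels)) {
    for (dev in c("plus", "minus")) {
      s <- new_eoect(dev_factor = st[[dev]]$dev_factor[i])
      s$g <- st[[dev]]$g[i]
      s$n_pulses <- as.integer(st[[dev]]$n_pulses[i])
      s$age_h <- st[[dev]]$age_h[i]
      s$g_ref <- st[[dev]]$g_ref[i]
      arr$pixels[[i]][[dev]] <- s
    }
  }
  attr(arr, "seed") <- st$seed
  arr
}

#' Read device parameters from a YAML config file
#'
#' Flat key/value YAML; keys are the arguments of [device_params()] and
#' unknown keys are rejected. Missing keys take the package defaults.
#'
#' @param path YAML file.
#' @return An `eoect_params`.
#' @export
read_device_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(device_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(device_params, vals)
}

#' Write device parameters as a YAML config file
#'
#' @param params An `eoect_params`.
#' @param path Destination; `""` prints to stdout.
#' @return `path`, invisibly.
#' @export
write_device_config <- function(params = device_params(), path = "") {
  stopifnot(inherits(params, "eoect_params"))
  txt <- yaml::as.yaml(unclass(params), precision = 15L)
  if (identical(path, "")) cat(txt) else writeLines(txt, path)
  invisible(path)
}

#' Write an experiment log to JSON
#'
#' Serializes the records plus the seed and configuration snapshot so the
#' run can be replayed; [read_experiment_log()] restores them losslessly.
#'
#' @param log An `experiment_log`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_experiment_log <- function(log, path) {
  stopifnot(inherits(log, "experiment_log"))
  obj <- list(seed = attr(log, "seed"), config = attr(log, "config"),
              records = as.data.frame(log))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read an experiment log from JSON
#'
#' @param path File written by [write_experiment_log()].
#' @return An `experiment_log`.
#' @export
read_experiment_log <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec <- as.data.frame(obj$records, stringsAsFactors = FALSE)
  .new_log(rec, obj$seed, obj$config)
}
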