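## Plain-text (YAML) run configuration binding all modules together.
## Unknown keys are rejected so typos cannot silently fall back to
## defaults; every field has a default, and a config round-trips through
## serialization unchanged.

#' Default run configuration
#'
#' Composite of network architecture, training, loss, phantom and path
#' settings. Defaults reproduce the published recipe (lambda = 1,
#' lr = 0.001, 200 epochs, threshold 0.5, channels 16..256).
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 42L,
    network = list(
      channels = c(16L, 32L, 64L, 128L, 256L),
      conv_kernel = 3L, pool_kernel = 2L,
      convs_per_stage = 2L, decoder_convs_per_stage = 1L,
      ffn_expansion = 2, attention_heads = 1L,
      in_channels = 1L, out_channels = 1L
    ),
    train = list(
      initial_lr = 0.001, epochs = 200L, momentum = 0.9, batch_size = 2L,
      lambda_bce = 1, threshold = 0.5, seed = 42L, smooth_eps = 1e-5,
      init_head_prior = TRUE,
      augment = list(prob = 0.5, scale_range = c(0.5, 1.5),
                     angle_range = c(-25, 25), shift_range = c(-10, 10))
    ),
    phantom = list(
      grid_shape = c(64L, 64L, 32L), spacing = c(1.25, 1.25, 2.5),
      body_a = c(8, 14), body_b = c(7, 12), body_c = c(4, 7),
      n_tubes = c(2L, 4L), tube_radius = c(1.0, 1.8),
      tube_length = c(8, 16), appendage = TRUE,
      contrast = 1.5, noise_sd = 1.0, smooth_sigma = 1.0,
      fg_fraction = c(0.005, 0.05), max_retries = 25L
    ),
    paths = list(train_dir = "", val_dir = "", test_dir = "", out_dir = ".")
  ), class = "run_config")
}

merge_strict <- function(default, user, path = "") {
  for (key in names(user)) {
    here <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(default))
      stop("unknown config key: `", here, "`")
    dv <- default[[key]]
    uv <- user[[key]]
    if (is.list(dv) && !is.null(names(dv))) {
      if (!is.list(uv)) stop("config key `", here, "` must be a mapping")
      default[[key]] <- merge_strict(dv, uv, here)
    } else {
      if (is.numeric(dv) && !is.numeric(uv))
        stop("config key `", here, "` must be numeric")
      if (is.logical(dv) && !is.logical(uv))
        stop("config key `", here, "` must be logical")
      if (is.numeric(dv) && length(dv) > 1 && length(uv) != length(dv))
        stop("config key `", here, "` must have length ", length(dv))
      default[[key]] <- if (is.integer(dv) && is.numeric(uv))
        as.integer(uv) else uv
    }
  }
  default
}

#' Parse a YAML run configuration
#'
#' Reads a YAML file, overlays it on [default_run_config()] and validates
#' strictly: unknown keys and type mismatches abort with the offending key
#' name. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config must be a YAML mapping")
  structure(merge_strict(unclass(default_run_config()), user),
            class = "run_config")
}

#' Serialize a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Destination file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## Typed views of a run_config
rc_network <- function(rc) do.call(usformer_config, rc$network)
rc_train <- function(rc) {
  tr <- rc$train
  tr$augment <- do.call(augment_config, tr$augment)
  do.call(train_config, tr)
}
rc_phantom <- function(rc) do.call(phantom_spec, rc$phantom)
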