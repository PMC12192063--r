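# Run configuration.
#
# The reference profile stores the published training hyperparameters
# (SGD lr 2e-4 with poly decay, momentum 0.9, weight decay 1e-4, batch 160,
# 1000 epochs, competitive lambda 0.1, mu 10). The desk profile scales batch,
# epochs, image size and channel widths down to sizes a CPU can train in
# minutes; everything else is inherited.

reference_config <- function() {
  list(
    data = list(image_size = 160L, noise_sigma = 0.03, drop_empty = FALSE,
                split = c(0.8, 0.1, 0.1)),
    model = list(base_channels = 32L,
                 mhmoe = list(num_heads = 4L, num_experts = 4L),
                 assistant = list(num_attention_heads = 2L),
                 unet_depth = 4L),
    optim = list(lr = 2e-4, momentum = 0.9, weight_decay = 1e-4,
                 lr_decay = "poly", poly_power = 0.9,
                 batch_size = 160L, epochs = 1000L),
    distill = list(tau = 1, alpha = 0.5, lambda = 0.1, mu = 10,
                   lambda_student = 1, lambda_comp = 1, lambda_res = 1,
                   ta_weight = 0.7),
    seed = 0L
  )
}

desk_overrides <- function() {
  list(data = list(image_size = 64L),
       model = list(base_channels = 8L),
       optim = list(lr = 0.1, batch_size = 8L, epochs = 40L))
}

merge_config <- function(base, overrides, path = "") {
  for (nm in names(overrides)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", sub("^\\.", "", paste0(path, ".", nm)))
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]],
                                 paste0(path, ".", nm))
    else base[[nm]] <- overrides[[nm]]
  }
  base
}

#' Load a run configuration
#'
#' Starts from the reference profile, optionally applies the desk-scale
#' profile, then a YAML file, then explicit overrides. Unknown keys raise an
#' error naming the offending key.
#'
#' @param path optional YAML file with overrides.
#' @param profile `"reference"` or `"desk"`.
#' @param overrides optional nested list of final overrides.
#' @return the merged configuration list.
#' @export
load_run_config <- function(path = NULL, profile = c("reference", "desk"),
                            overrides = NULL) {
  profile <- match.arg(profile)
  cfg <- reference_config()
  if (profile == "desk") cfg <- merge_config(cfg, desk_overrides())
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

#' Write a configuration snapshot
#'
#' @param config configuration list.
#' @param dir run directory (created if needed).
#' @return the snapshot path, invisibly.
#' @export
save_config_snapshot <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, path)
  invisible(path)
}

distill_config_from <- function(cfg) {
  d <- cfg$distill
  distill_config(tau = d$tau, alpha = d$alpha, lambda = d$lambda, mu = d$mu,
                 lambda_student = d$lambda_student,
                 lambda_comp = d$lambda_comp, lambda_res = d$lambda_res,
                 ta_weight = d$ta_weight)
}

#' Save / load a model checkpoint
#'
#' Serialized parameter tree plus a JSON config sidecar.
#'
#' @param params parameter tree.
#' @param path checkpoint path (`.rds`).
#' @param config optional configuration stored alongside as JSON.
#' @return the path, invisibly.
#' @export
save_checkpoint <- function(params, path, config = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(params, path)
  if (!is.null(config))
    jsonlite::write_json(config, paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
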