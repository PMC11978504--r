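# Checkpointing: named-array archive plus a JSON manifest with the
# configuration and a format version; strict shape validation on load.

.CKPT_VERSION <- "1"

#' Save model weights with a JSON manifest
#'
#' Writes `<path>` (RDS archive of the named parameter arrays) and
#' `<path>.json` (manifest: format version, variant, configs, shapes).
#'
#' @param model a `pocket_model` or `pocket_packer`.
#' @param path output path for the weight archive.
#' @return invisible `path`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model$params, path)
  manifest <- list(
    format_version = .CKPT_VERSION,
    variant = model$variant,
    config = unclass(model$config),
    feat = unclass(model$feat),
    shapes = lapply(model$params, function(p) dim(p) %||% length(p)))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path weight-archive path (manifest expected at `<path>.json`).
#' @return a `pocket_model` or `pocket_packer` with restored weights.
#' @export
load_checkpoint <- function(path) {
  manifest <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(as.character(manifest$format_version), .CKPT_VERSION))
    stop("unsupported checkpoint format version: ", manifest$format_version)
  params <- readRDS(path)
  cfgl <- manifest$config
  config <- model_config(m = cfgl$m, num_enc_layers = cfgl$num_enc_layers,
                         num_ctx_layers = cfgl$num_ctx_layers,
                         num_dec_layers = cfgl$num_dec_layers,
                         dropout_p = cfgl$dropout_p,
                         msg_scale = cfgl$msg_scale,
                         ffn_width = cfgl$ffn_width,
                         alphabet_size = cfgl$alphabet_size)
  fl <- manifest$feat
  feat <- feature_config(K = fl$K, M = fl$M, r = fl$r, m = fl$m,
                         max_offset = fl$max_offset,
                         noise_level = fl$noise_level,
                         rbf_min = fl$rbf_min, rbf_max = fl$rbf_max)
  variant <- manifest$variant
  shapes <- if (variant == "packer") .packer_shapes(config, feat)
            else .param_shapes(config, feat, variant)
  if (!setequal(names(shapes), names(params)))
    stop("checkpoint parameter names do not match the declared config")
  for (nm in names(shapes)) {
    want <- as.integer(shapes[[nm]])
    have <- as.integer(dim(params[[nm]]) %||% length(params[[nm]]))
    if (!identical(want, have))
      stop("shape mismatch for parameter ", nm)
  }
  cls <- if (variant == "packer") "pocket_packer" else "pocket_model"
  structure(list(params = params, config = config, feat = feat,
                 variant = variant, seed = NA_integer_),
            class = cls)
}
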