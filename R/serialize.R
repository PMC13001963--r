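# Plain-text (JSON) model checkpoints: flattened parameter matrices with
# shapes, plus the configuration and layout needed to rebuild the model.

serialize_params <- function(params) {
  flat <- unlist_mats(params)
  lapply(flat, function(m) list(dim = dim(m), data = as.numeric(m)))
}

deserialize_params <- function(ser, skeleton) {
  flat <- lapply(ser, function(e) {
    matrix(as.numeric(e$data), e$dim[1], e$dim[2])
  })
  relist_mats(flat, skeleton)
}

layout_to_list <- function(layout) {
  list(joint_names = layout$joint_names, parents = layout$parents,
       left_right = if (is.null(layout$left_right)) NULL else
         apply(layout$left_right, 2, as.integer))
}

layout_from_list <- function(lst) {
  lr <- if (is.null(lst$left_right)) NULL else
    matrix(as.integer(unlist(lst$left_right)), ncol = 2)
  joint_layout(lst$joint_names, lst$parents, left_right = lr)
}

#' Write a trained model to a JSON checkpoint
#'
#' @param model a `datp_model` or `agtm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  cfg <- unclass(model$config)
  if (inherits(model, "datp_model")) {
    payload <- list(type = "datp", config = cfg,
                    layout = layout_to_list(model$layout),
                    segment_lengths = model$segment_lengths,
                    ablate = model$ablate,
                    params = serialize_params(model$params))
  } else if (inherits(model, "agtm_model")) {
    payload <- list(type = "agtm", config = cfg,
                    layout = layout_to_list(model$layout),
                    input_channels = model$input_channels,
                    lambda = model$lambda, task_name = model$task_name,
                    params = serialize_params(model$params))
  } else {
    stop("unknown model type")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a model checkpoint written by [write_model()]
#'
#' @param path checkpoint path.
#' @return a `datp_model` or `agtm_model`.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgvals <- payload$config[names(payload$config) %in% names(formals(model_config))]
  cfg <- do.call(model_config, cfgvals)
  layout <- layout_from_list(payload$layout)
  if (identical(payload$type, "datp")) {
    skeleton <- datp_init(layout, cfg, seed = cfg$seed)$params
    structure(list(params = deserialize_params(payload$params, skeleton),
                   config = cfg, layout = layout,
                   segment_lengths = as.integer(payload$segment_lengths),
                   history = NULL,
                   ablate = as.character(payload$ablate)),
              class = "datp_model")
  } else if (identical(payload$type, "agtm")) {
    set.seed(cfg$seed)
    skeleton <- agtm_params(as.integer(payload$input_channels), cfg)
    structure(list(params = deserialize_params(payload$params, skeleton),
                   config = cfg, layout = layout,
                   input_channels = as.integer(payload$input_channels),
                   A0 = build_static_adjacency(layout),
                   lambda = payload$lambda, task_name = payload$task_name,
                   history = NULL),
              class = "agtm_model")
  } else {
    stop("unknown checkpoint type")
  }
}
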