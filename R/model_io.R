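#' Save a boosted model as JSON
#'
#' The file stores the stumps (feature, split, class orientation, alpha),
#' subcommittee bounds, feature set, calibrated thresholds, training seed
#' and the energy-table version; [load_model()] restores it losslessly.
#'
#' @param model a `boosted_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "boosted_model"))
  obj <- list(
    format = "mirsite-model-1",
    stumps = model$stumps,
    n_iterations = model$n_iterations,
    subcommittee_bounds = model$subcommittee_bounds,
    feature_set = model$feature_set,
    thresholds = model$thresholds,
    seed = model$seed,
    params_version = model$params_version)
  # 17 significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a boosted model saved by [save_model()]
#'
#' @param path JSON model file.
#' @return a `boosted_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "mirsite-model-1") {
    stop("not a mirsite model file: ", path)
  }
  st <- as.data.frame(obj$stumps, stringsAsFactors = FALSE)
  if (nrow(st)) {
    st$split <- as.numeric(st$split); st$alpha <- as.numeric(st$alpha)
    st$left_class <- as.integer(st$left_class)
  }
  thr <- obj$thresholds
  if (!is.null(thr)) thr <- list(sens = as.numeric(thr$sens), spec = as.numeric(thr$spec))
  structure(list(stumps = st,
                 n_iterations = as.integer(obj$n_iterations),
                 subcommittee_bounds = as.integer(obj$subcommittee_bounds),
                 feature_set = as.character(obj$feature_set),
                 thresholds = thr,
                 seed = as.integer(obj$seed),
                 params_version = obj$params_version),
            class = "boosted_model")
}
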