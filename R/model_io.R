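#' Write a fitted model to JSON
#'
#' Versioned schema storing intercept, axis, coefficients,
#' standardization and training manifest.
#'
#' @param model a [fit_lasso_logistic()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  payload <- list(
    schema = "ramanTreg-model", schema_version = 1,
    intercept = model$intercept, coefficients = model$coefficients,
    center = model$center, scale = model$scale, lambda = model$lambda,
    axis = model$axis, class_orientation = model$class_orientation,
    weights = model$weights, manifest = model$manifest
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path a file written by [write_model_json()].
#' @return a `fitted_model`.
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "ramanTreg-model")) {
    stop("not a ramanTreg model file: ", path)
  }
  structure(
    list(intercept = p$intercept, coefficients = p$coefficients,
         center = p$center, scale = p$scale, lambda = p$lambda,
         axis = p$axis, class_orientation = p$class_orientation,
         weights = p$weights, manifest = p$manifest),
    class = "fitted_model"
  )
}
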