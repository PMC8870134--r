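# Structured-text (JSON) serialisation for models, libraries and ANN
# weights. Model parameters are encoded as %.17g strings (17 significant
# digits round-trip IEEE doubles exactly), so reloading is bit-compatible.

num_out <- function(x) sprintf("%.17g", x)
num_in <- function(x) if (is.null(x)) numeric(0) else as.numeric(unlist(x))

nl_to_list <- function(nl) {
  out <- list(family = nl$family)
  if (nl$family == "piecewise_linear") {
    out$breakpoints <- num_out(nl$breakpoints)
    out$values <- num_out(nl$values)
  } else if (nl$family == "polynomial") {
    out$coefficients <- num_out(nl$coefficients)
  }
  out
}

nl_from_list <- function(x) {
  static_nl(x$family,
            breakpoints = if (is.null(x$breakpoints)) NULL
                          else num_in(x$breakpoints),
            values = if (is.null(x$values)) NULL else num_in(x$values),
            coefficients = if (is.null(x$coefficients)) NULL
                           else num_in(x$coefficients))
}

hw_to_list <- function(model) {
  list(
    input_nl = nl_to_list(model$input_nl),
    linear = list(b = num_out(model$linear$b), f = num_out(model$linear$f),
                  nk = model$linear$nk),
    output_nl = nl_to_list(model$output_nl),
    converged = model$converged,
    fit_info = if (!is.null(model$fit_info))
      list(outer_iters = model$fit_info$outer_iters,
           innovation_rms = model$fit_info$innovation_rms,
           theta_lin_final = model$fit_info$theta_lin_final,
           rls_steps = model$fit_info$rls_steps)
    else NULL
  )
}

hw_from_list <- function(x) {
  m <- hw_model(nl_from_list(x$input_nl),
                linear_block(num_in(x$linear$b), num_in(x$linear$f),
                             x$linear$nk),
                nl_from_list(x$output_nl),
                converged = if (is.null(x$converged)) NA else x$converged)
  if (!is.null(x$fit_info)) m$fit_info <- x$fit_info
  m
}

#' Save a Hammerstein-Wiener model to JSON
#'
#' @param model A `hw_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
hw_save <- function(model, path) {
  jsonlite::write_json(hw_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a Hammerstein-Wiener model from JSON
#'
#' @param path File written by [hw_save()].
#' @return A `hw_model`.
#' @export
hw_load <- function(path) {
  hw_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Save a model library to JSON
#'
#' One structured document aggregating every sub-model together with its
#' provenance and the library's signal conventions.
#'
#' @param library A `model_library`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
library_save <- function(library, path) {
  entries <- lapply(library$entries, function(e)
    list(id = e$id, training_ref = e$training_ref,
         profile_kind = e$profile_kind, model = hw_to_list(e$model)))
  jsonlite::write_json(list(fs = library$fs, entries = entries), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Load a model library from JSON
#'
#' @param path File written by [library_save()].
#' @return A `model_library`.
#' @export
library_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  entries <- lapply(x$entries, function(e)
    list(id = as.integer(e$id), training_ref = e$training_ref,
         profile_kind = e$profile_kind,
         model = hw_from_list(lapply(e$model, function(z) z))))
  model_library(entries, fs = if (is.null(x$fs)) NA_real_ else x$fs)
}

#' Save MLP weights to JSON
#' @param weights An `mlp_weights`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
mlp_save <- function(weights, path) {
  jsonlite::write_json(
    list(config = unclass(weights$config),
         W1 = weights$W1, b1 = weights$b1,
         W2 = weights$W2, b2 = weights$b2),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Load MLP weights from JSON
#' @param path File written by [mlp_save()].
#' @return An `mlp_weights`.
#' @export
mlp_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(mlp_config, x$config[c("n_inputs", "n_hidden", "n_outputs",
                                        "lambda0", "lambda_factor",
                                        "max_iter", "tol", "max_lambda",
                                        "seed")])
  structure(list(W1 = x$W1, b1 = x$b1, W2 = x$W2, b2 = x$b2, config = cfg),
            class = "mlp_weights")
}
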