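# Checkpointing: a fitted model serializes to a single archive whose
# manifest records shapes, seeds and hyperparameters; reloading restores
# bit-identical predictions.

#' Save a fitted model checkpoint
#'
#' Writes a single RDS archive containing a JSON-style manifest (package
#' version, task, dimensions, seed, epsilon, K, provider id) alongside the
#' parameters. The restored model predicts bit-identically.
#'
#' @param model A fitted `molproto`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
molproto_save <- function(model, path) {
  stopifnot(inherits(model, "molproto"))
  manifest <- list(
    package = "molproto",
    version = as.character(utils::packageVersion("molproto")),
    task = model$task,
    L = model$config$L,
    dims = c(g = model$config$d_g, t = model$config$d_t, p = model$config$d_p),
    C = model$config$C, N = model$config$N, K = model$config$K,
    epsilon = model$config$epsilon, seed = model$seed,
    provider = model$provider$id,
    param_shapes = rapply(model$params,
                          function(m) paste(dim(m) %||% length(m),
                                            collapse = "x"),
                          how = "list"))
  saveRDS(list(manifest = manifest, model = model), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [molproto_save()].
#' @return The fitted `molproto` model, with the manifest attached as
#'   attribute `manifest`.
#' @export
molproto_load <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$manifest) || !identical(obj$manifest$package, "molproto"))
    stopf("'%s' is not a molproto checkpoint", path)
  model <- obj$model
  attr(model, "manifest") <- obj$manifest
  model
}
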