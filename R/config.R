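# Model/training configuration with the published defaults.

#' Model and training configuration
#'
#' Defaults follow the published setup: Adam with learning rate 8e-5 and
#' weight decay 1e-4, cosine annealing over 100 epochs, batch size 128,
#' GIN backbone with sum readout, N = 5 prototypes per class with K = 5
#' retained entries, and all three loss weights at 0.9. Desk-scale
#' overrides suitable for laptop-sized experiments ship in
#' `system.file("configs", "desk.yml", package = "molproto")`.
#'
#' @param L Shared layer count of both branches.
#' @param d_g,d_t,d_p Hidden dims of the graph branch, text branch and
#'   prototype space.
#' @param N Prototypes per class; `K` retained top-K entries.
#' @param epsilon Log-ratio constant in (0,1); `eps_kl` KL floor.
#' @param tau Contrastive temperature (> 0).
#' @param lambda_align,lambda_pred,lambda_proto Loss weights (>= 0).
#' @param lr,weight_decay,epochs,batch_size,schedule Optimizer settings.
#' @param fusion "layerwise" (default) or "final" (cross-modal attention
#'   applied only at the last layer — the w/o-CA ablation).
#' @param proto_mode "unified" (default shared prototype space) or
#'   "separate" (independent per-modality spaces — the w/o-UP ablation).
#' @param readout Graph readout, "sum" or "mean".
#' @return A `molproto_config` list.
#' @export
molproto_config <- function(L = 3L, d_g = 64L, d_t = 64L, d_p = 64L,
                            N = 5L, K = 5L, epsilon = 1e-6, eps_kl = 1e-8,
                            tau = 0.5,
                            lambda_align = 0.9, lambda_pred = 0.9,
                            lambda_proto = 0.9,
                            lr = 8e-5, weight_decay = 1e-4,
                            epochs = 100L, batch_size = 128L,
                            schedule = c("cosine", "constant"),
                            fusion = c("layerwise", "final"),
                            proto_mode = c("unified", "separate"),
                            readout = c("sum", "mean")) {
  cfg <- list(L = as.integer(L), d_g = as.integer(d_g),
              d_t = as.integer(d_t), d_p = as.integer(d_p),
              N = as.integer(N), K = as.integer(K),
              epsilon = epsilon, eps_kl = eps_kl, tau = tau,
              lambda_align = lambda_align, lambda_pred = lambda_pred,
              lambda_proto = lambda_proto,
              lr = lr, weight_decay = weight_decay,
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              schedule = match.arg(schedule),
              fusion = match.arg(fusion),
              proto_mode = match.arg(proto_mode),
              readout = match.arg(readout))
  if (cfg$L < 1L || cfg$d_g < 1L || cfg$d_t < 1L || cfg$d_p < 1L)
    stopf("config error: L and all dims must be >= 1")
  if (cfg$tau <= 0) stopf("config error: tau must be > 0")
  if (any(c(cfg$lambda_align, cfg$lambda_pred, cfg$lambda_proto) < 0))
    stopf("config error: negative loss weight")
  if (cfg$epsilon <= 0 || cfg$epsilon >= 1)
    stopf("config error: epsilon must lie in (0,1)")
  structure(cfg, class = c("molproto_config", "list"))
}

#' Read a configuration from a YAML file
#'
#' Keys not present fall back to [molproto_config()] defaults; `overrides`
#' (a named list, e.g. from CLI flags) win over the file.
#'
#' @param path YAML file path.
#' @param overrides Named list of overrides.
#' @return A `molproto_config`.
#' @export
read_config_yaml <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(molproto_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stopf("config error: unknown key(s) in %s: %s", path,
          paste(unknown, collapse = ", "))
  do.call(molproto_config, vals)
}

#' @export
print.molproto_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<molproto_config> L=%d d_g=%d d_t=%d d_p=%d | N=%d K=%d tau=%g\n",
    "  lambdas (align/pred/proto) %.2g/%.2g/%.2g | %s fusion, %s prototypes\n",
    "  Adam lr=%g wd=%g, %d epochs, batch %d, %s schedule\n"),
    x$L, x$d_g, x$d_t, x$d_p, x$N, x$K, x$tau,
    x$lambda_align, x$lambda_pred, x$lambda_proto, x$fusion, x$proto_mode,
    x$lr, x$weight_decay, x$epochs, x$batch_size, x$schedule))
  invisible(x)
}
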