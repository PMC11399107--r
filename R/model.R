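# Model-level API: untrained models, prediction, edge masks, checkpoints.

CHECKPOINT_VERSION <- "specnet-checkpoint-1"

#' Create an untrained model
#'
#' Parameters are initialized from `config$seed`; the 4-way output head is
#' zero-initialized, so an untrained model predicts exactly uniform columns.
#'
#' @param config A [specnet_config()].
#' @return Object of class `specnet_model`.
#' @export
specnet_model <- function(config = specnet_config()) {
  stopifnot(inherits(config, "specnet_config"))
  structure(list(config = config, params = init_params(config),
                 version = CHECKPOINT_VERSION),
            class = "specnet_model")
}

#' @export
print.specnet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("specnet model (mode:", x$config$mode, ") -", np, "parameters\n")
  invisible(x)
}

#' Edge mask for bipartite perturbation
#'
#' Names protein atoms whose bipartite (atom -> helix point) edges are
#' removed during prediction. Protein-graph edges are never masked.
#'
#' @param excluded_atoms Integer atom ids (`atom_id` column of the complex's
#'   `protein_atoms`).
#' @return Integer vector of class `edge_mask`.
#' @export
edge_mask <- function(excluded_atoms = integer()) {
  structure(unique(as.integer(excluded_atoms)), class = "edge_mask")
}

#' Predict a PWM from a protein-DNA complex
#'
#' Runs the full pipeline: protein heavy-atom graph message passing, four
#' grouped bipartite geometric convolutions onto the symmetrized helix,
#' flattening along the pair axis (with shape features and, in seqinfo mode,
#' sequence one-hots), 1D convolutions and a per-column softmax. The output
#' has one row per base pair, flanks included.
#'
#' @param model A `specnet_model` (or the `model` element of a fit).
#' @param complex A `pdna_complex`.
#' @param mask Optional [edge_mask()].
#' @param inputs Optional precomputed tensors (internal reuse).
#' @param diagnostics If `TRUE`, also return per-point embeddings.
#' @return List of class `specnet_prediction`: `pwm` ([pwm()]), `logits`,
#'   and optionally `per_point`.
#' @export
predict_pwm <- function(model, complex, mask = NULL, inputs = NULL,
                        diagnostics = FALSE) {
  stopifnot(inherits(model, "specnet_model"))
  if (is.null(inputs)) {
    stopifnot(inherits(complex, "pdna_complex"))
    inputs <- precompute_inputs(complex, model$config)
  }
  fw <- forward_specnet(model$params, inputs, model$config, mask = mask,
                        keep_cache = diagnostics)
  out <- list(pwm = pwm(fw$probs, name = if (!is.null(complex)) complex$source_id),
              logits = fw$logits)
  if (diagnostics) {
    out$per_point <- lapply(fw$cache$groups, function(gc_) gc_$PV)
  }
  class(out) <- "specnet_prediction"
  out
}

#' @export
print.specnet_prediction <- function(x, ...) {
  cat("specnet prediction:\n")
  print(x$pwm)
  invisible(x)
}

#' Save a model checkpoint
#'
#' Single-file archive holding the format version, configuration and
#' weights. [load_model()] refuses to load other versions.
#'
#' @param model A `specnet_model`.
#' @param path Output file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "specnet_model"))
  saveRDS(list(version = CHECKPOINT_VERSION, config = unclass(model$config),
               params = model$params), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path File written by [save_model()].
#' @return A `specnet_model`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, CHECKPOINT_VERSION)) {
    stop("checkpoint format version mismatch: found ",
         obj$version %||% "<none>", ", expected ", CHECKPOINT_VERSION)
  }
  cfg <- structure(obj$config, class = "specnet_config")
  structure(list(config = cfg, params = obj$params,
                 version = obj$version), class = "specnet_model")
}
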