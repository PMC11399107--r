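# Training: data points (complex + target PWM + frozen alignment),
# cluster-aware cross-validation folds, L1 column loss on covered columns,
# the specnet() fitting function and the cross-validated ensemble.

#' Assemble a training data point
#'
#' Pairs a complex with its target PWM and freezes the ungapped alignment of
#' the target onto the structure's Watson-strand sequence; the alignment
#' defines which predicted columns are covered by the target during loss and
#' metric computation.
#'
#' @param complex A `pdna_complex`.
#' @param target_pwm A [pwm()].
#' @param group_label Cluster token for fold assignment (points sharing a
#'   label are never split across folds).
#' @param min_overlap Passed to [align_pwm()].
#' @param id Optional identifier.
#' @return List of class `specnet_datapoint`.
#' @export
specnet_datapoint <- function(complex, target_pwm, group_label = "all",
                              min_overlap = 4, id = NULL) {
  stopifnot(inherits(complex, "pdna_complex"), is_pwm(target_pwm))
  al <- align_pwm(target_pwm, complex$dna_sequence, min_overlap = min_overlap)
  structure(list(complex = complex, target_pwm = target_pwm,
                 alignment = al, group_label = as.character(group_label),
                 id = id %||% complex$source_id),
            class = "specnet_datapoint")
}

# Map the target PWM onto structure columns via the frozen alignment:
# an n_pairs x 4 matrix with NA rows for uncovered (flank) columns.
aligned_target <- function(dp) {
  n <- dp$complex$n_pairs
  al <- dp$alignment
  m <- if (al$strand == "forward") as_pwm_matrix(dp$target_pwm) else
    as_pwm_matrix(reverse_complement(dp$target_pwm))
  L <- nrow(m)
  out <- matrix(NA_real_, n, 4, dimnames = list(NULL, BASES))
  j0 <- max(0L, al$offset)
  j1 <- min(n, al$offset + L) - 1L
  if (j1 >= j0) {
    jj <- j0:j1
    out[jj + 1L, ] <- m[jj - al$offset + 1L, , drop = FALSE]
  }
  out
}

#' L1 loss over target-covered columns
#'
#' Mean over covered columns (via the data point's frozen alignment) of the
#' per-column base-probability L1 distance; uncovered flank columns are
#' excluded. On full coverage this equals [pwm_mae()].
#'
#' @param pred A [pwm()] of length equal to the duplex.
#' @param dp A [specnet_datapoint()].
#' @return Nonnegative scalar.
#' @export
column_loss <- function(pred, dp) {
  stopifnot(is_pwm(pred), inherits(dp, "specnet_datapoint"))
  if (nrow(pred) != dp$complex$n_pairs) {
    stop("prediction length ", nrow(pred), " does not match duplex length ",
         dp$complex$n_pairs)
  }
  tg <- aligned_target(dp)
  cov <- !is.na(tg[, 1])
  if (!any(cov)) stop("alignment covers no columns")
  sum(abs(as_pwm_matrix(pred)[cov, , drop = FALSE] -
            tg[cov, , drop = FALSE])) / sum(cov)
}

#' Cluster-aware cross-validation folds
#'
#' Partitions data points into k folds such that all points sharing a
#' `group_label` land in the same fold; groups are shuffled (seeded) and
#' dealt round-robin, so fold sizes are balanced to within one group.
#'
#' @param dataset List of [specnet_datapoint()] (or any list whose elements
#'   have a `group_label`).
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return List of k integer index vectors partitioning `seq_along(dataset)`.
#' @export
make_folds <- function(dataset, k = 5, seed = 1) {
  labels <- vapply(dataset, function(d) d$group_label, character(1))
  groups <- unique(labels)
  if (k > length(groups)) {
    stop("k = ", k, " exceeds the number of distinct groups (",
         length(groups), ")")
  }
  perm <- with_seed(seed, sample(groups))
  fold_of_group <- setNames(rep_len(seq_len(k), length(perm)), perm)
  folds <- lapply(seq_len(k), function(f) {
    which(fold_of_group[labels] == f)
  })
  lapply(folds, function(ix) as.integer(sort(unname(ix))))
}

#' Training control parameters
#'
#' @param lr Adam learning rate.
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size (gradients averaged within a batch).
#' @param patience Early-stopping patience on validation loss (epochs).
#' @param loss `"l1"` (matches the MAE metric family) or `"cross_entropy"`.
#' @param verbose Print per-epoch losses.
#' @return List of class `specnet_control`.
#' @export
specnet_control <- function(lr = 0.01, epochs = 40, batch_size = 16,
                            patience = 6, loss = c("l1", "cross_entropy"),
                            verbose = FALSE) {
  loss <- match.arg(loss)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), loss = loss,
                 verbose = verbose),
            class = "specnet_control")
}

# loss value and dL/dlogits for one datapoint given forward probs.
loss_and_grad <- function(probs, tg, loss) {
  cov <- !is.na(tg[, 1])
  ncov <- sum(cov)
  P <- probs[cov, , drop = FALSE]
  T_ <- tg[cov, , drop = FALSE]
  if (loss == "l1") {
    val <- sum(abs(P - T_)) / ncov
    dP <- sign(P - T_) / ncov
  } else {
    val <- -sum(T_ * log(pmax(P, 1e-12))) / ncov
    dP <- -(T_ / pmax(P, 1e-12)) / ncov
  }
  dprobs <- matrix(0, nrow(probs), 4)
  dprobs[cov, ] <- dP
  # softmax jacobian
  dlogits <- probs * (dprobs - rowSums(dprobs * probs))
  list(value = val, dlogits = dlogits)
}

#' Fit a binding-specificity network
#'
#' The main fitting function: gradient training (Adam) of the geometric
#' network minimizing the covered-column L1 loss over a corpus of
#' (complex, target PWM) data points, with early stopping on validation
#' loss. Inputs are tensorized once up front; a fixed seed makes the run
#' reproducible.
#'
#' @param data List of [specnet_datapoint()] used for training.
#' @param config A [specnet_config()].
#' @param control A [specnet_control()].
#' @param val_data Optional validation list; defaults to a (seeded) 20%
#'   holdout split from `data` when `NULL`.
#' @param seed RNG seed for shuffling/splitting (parameter init uses
#'   `config$seed`).
#' @param inputs,val_inputs Optional precomputed tensors (internal reuse
#'   across ensemble members).
#' @return Object of class `specnet`: `model`, `history` (per-epoch train
#'   and validation loss), `best_epoch`, `config`, `control`, `call`.
#' @export
specnet <- function(data, config = specnet_config(),
                    control = specnet_control(), val_data = NULL,
                    seed = 1, inputs = NULL, val_inputs = NULL) {
  cl <- match.call()
  if (!length(data)) stop("empty training set")
  stopifnot(inherits(config, "specnet_config"),
            inherits(control, "specnet_control"))
  if (is.null(val_data)) {
    ix <- with_seed(child_seed(seed, 17L), sample(seq_along(data)))
    nval <- max(1L, floor(0.2 * length(data)))
    if (length(data) < 2) {
      val_data <- data
    } else {
      val_data <- data[ix[seq_len(nval)]]
      data <- data[ix[-seq_len(nval)]]
    }
    inputs <- val_inputs <- NULL
  }
  if (is.null(inputs)) {
    inputs <- lapply(data, function(dp) precompute_inputs(dp$complex, config))
  }
  if (is.null(val_inputs)) {
    val_inputs <- lapply(val_data, function(dp)
      precompute_inputs(dp$complex, config))
  }
  targets <- lapply(data, aligned_target)
  val_targets <- lapply(val_data, aligned_target)

  params <- init_params(config)
  state <- adam_init(params)
  ntr <- length(data)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(val = Inf, params = params, epoch = 0L)
  wait <- 0L

  val_loss_of <- function(params) {
    mean(vapply(seq_along(val_data), function(i) {
      fw <- forward_specnet(params, val_inputs[[i]], config)
      loss_and_grad(fw$probs, val_targets[[i]], control$loss)$value
    }, numeric(1)))
  }

  for (epoch in seq_len(control$epochs)) {
    ord <- with_seed(child_seed(seed, 100L + epoch), sample(ntr))
    tr_losses <- numeric(0)
    b0 <- 1L
    while (b0 <= ntr) {
      b1 <- min(b0 + control$batch_size - 1L, ntr)
      batch <- ord[b0:b1]
      acc <- NULL
      for (i in batch) {
        fw <- forward_specnet(params, inputs[[i]], config, keep_cache = TRUE)
        lg <- loss_and_grad(fw$probs, targets[[i]], control$loss)
        if (!is.finite(lg$value)) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (datapoint ", data[[i]]$id, ")")
        }
        tr_losses <- c(tr_losses, lg$value)
        g <- backward_specnet(params, inputs[[i]], config, fw$cache,
                              lg$dlogits)
        if (is.null(acc)) {
          acc <- g
        } else {
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]]
        }
      }
      nb <- length(batch)
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / nb
      st <- adam_step(params, acc, state, lr = control$lr)
      params <- st$params
      state <- st$state
      b0 <- b1 + 1L
    }
    vl <- val_loss_of(params)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(tr_losses),
                                         val_loss = vl))
    if (control$verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      mean(tr_losses), vl))
    }
    if (vl < best$val - 1e-6) {
      best <- list(val = vl, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }
  model <- structure(list(config = config, params = best$params,
                          version = CHECKPOINT_VERSION),
                     class = "specnet_model")
  structure(list(model = model, history = history,
                 best_epoch = best$epoch, best_val_loss = best$val,
                 config = config, control = control,
                 n_train = ntr, n_val = length(val_data), call = cl),
            class = "specnet")
}

#' @export
print.specnet <- function(x, ...) {
  cat("specnet fit (mode:", x$config$mode, ")\n")
  cat("  trained on", x$n_train, "complexes,", x$n_val, "validation\n")
  cat(sprintf("  best validation loss %.4f at epoch %d (of %d run)\n",
              x$best_val_loss, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' @export
summary.specnet <- function(object, ...) {
  np <- sum(vapply(object$model$params, length, numeric(1)))
  cat("specnet fit\n")
  cat("  mode:", object$config$mode, " embed_dim:", object$config$embed_dim,
      " parameters:", np, "\n")
  cat("  training size:", object$n_train, " validation size:", object$n_val, "\n")
  cat(sprintf("  final train loss %.4f; best val loss %.4f (epoch %d)\n",
              utils::tail(object$history$train_loss, 1),
              object$best_val_loss, object$best_epoch))
  invisible(object)
}

#' @export
coef.specnet <- function(object, ...) object$model$params

#' @export
plot.specnet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "covered-column L1 loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' @export
predict.specnet <- function(object, newdata, mask = NULL, ...) {
  if (inherits(newdata, "pdna_complex")) {
    return(predict_pwm(object$model, newdata, mask = mask)$pwm)
  }
  lapply(newdata, function(dp) {
    cx <- if (inherits(dp, "specnet_datapoint")) dp$complex else dp
    predict_pwm(object$model, cx, mask = mask)$pwm
  })
}

#' @export
residuals.specnet <- function(object, data, ...) {
  vapply(data, function(dp) {
    column_loss(predict_pwm(object$model, dp$complex)$pwm, dp)
  }, numeric(1))
}

#' Fit a cross-validated ensemble
#'
#' Builds k cluster-aware folds and trains one model per fold (training on
#' the other k-1 folds, validating on the held-out fold). The ensemble
#' prediction is the column-wise arithmetic mean of the member PWMs, which
#' stays on the probability simplex.
#'
#' @param data List of [specnet_datapoint()].
#' @param k Number of folds / members.
#' @param config A [specnet_config()].
#' @param control A [specnet_control()].
#' @param seed RNG seed (folds and member training streams derive from it).
#' @return Object of class `specnet_ensemble`: `members` (list of `specnet`
#'   fits), `folds`, `config`.
#' @export
specnet_ensemble <- function(data, k = 5, config = specnet_config(),
                             control = specnet_control(), seed = 1) {
  folds <- make_folds(data, k = k, seed = seed)
  all_inputs <- lapply(data, function(dp) precompute_inputs(dp$complex, config))
  members <- vector("list", k)
  for (f in seq_len(k)) {
    val_ix <- folds[[f]]
    tr_ix <- setdiff(seq_along(data), val_ix)
    cfg <- config
    cfg$seed <- child_seed(config$seed, f)
    members[[f]] <- specnet(
      data[tr_ix], config = cfg, control = control,
      val_data = data[val_ix], seed = child_seed(seed, 1000L + f),
      inputs = all_inputs[tr_ix], val_inputs = all_inputs[val_ix])
  }
  structure(list(members = members, folds = folds, config = config,
                 seed = seed),
            class = "specnet_ensemble")
}

#' @export
print.specnet_ensemble <- function(x, ...) {
  cat("specnet ensemble of", length(x$members), "cross-validation members",
      "(mode:", x$config$mode, ")\n")
  invisible(x)
}

#' Ensemble PWM prediction
#'
#' Column-wise arithmetic mean of the member predictions.
#'
#' @param ensemble A `specnet_ensemble` (or a plain list of `specnet` /
#'   `specnet_model` objects).
#' @param complex A `pdna_complex`.
#' @param mask Optional [edge_mask()].
#' @return A [pwm()].
#' @export
ensemble_predict <- function(ensemble, complex, mask = NULL) {
  members <- if (inherits(ensemble, "specnet_ensemble")) ensemble$members
             else ensemble
  stopifnot(length(members) >= 1)
  mats <- lapply(members, function(m) {
    mod <- if (inherits(m, "specnet")) m$model else m
    as_pwm_matrix(predict_pwm(mod, complex, mask = mask)$pwm)
  })
  pwm(Reduce(`+`, mats) / length(mats), name = complex$source_id)
}

#' @export
predict.specnet_ensemble <- function(object, newdata, mask = NULL, ...) {
  if (inherits(newdata, "pdna_complex")) {
    return(ensemble_predict(object, newdata, mask = mask))
  }
  lapply(newdata, function(dp) {
    cx <- if (inherits(dp, "specnet_datapoint")) dp$complex else dp
    ensemble_predict(object, cx, mask = mask)
  })
}

#' Per-datapoint evaluation table
#'
#' For each data point: covered-column loss, full-length MAE/RMSE against
#' the aligned target (uncovered columns compared to uniform), and the
#' frozen alignment's score, offset and strand.
#'
#' @param object A `specnet` fit, `specnet_ensemble` or `specnet_model`.
#' @param data List of [specnet_datapoint()].
#' @return A data.frame, one row per data point.
#' @export
evaluate_corpus <- function(object, data) {
  predict_one <- function(cx) {
    if (inherits(object, "specnet_ensemble")) ensemble_predict(object, cx)
    else if (inherits(object, "specnet")) predict_pwm(object$model, cx)$pwm
    else predict_pwm(object, cx)$pwm
  }
  rows <- lapply(data, function(dp) {
    pred <- predict_one(dp$complex)
    tg <- aligned_target(dp)
    cov <- !is.na(tg[, 1])
    tg_full <- tg
    tg_full[!cov, ] <- 0.25
    ty <- pwm(tg_full)
    data.frame(id = dp$id,
               covered_loss = column_loss(pred, dp),
               mae = pwm_mae(ty, pred), rmse = pwm_rmse(ty, pred),
               align_score = dp$alignment$score,
               align_offset = dp$alignment$offset,
               align_strand = dp$alignment$strand,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Held-out metrics for a cross-validated ensemble
#'
#' Each data point is predicted by the member that held its fold out, so
#' every metric is computed out-of-sample. Reports the covered-column L1
#' loss, and - when the data points carry planted ground truth (synthetic
#' corpora) - the mean absolute error and argmax-base recovery rate on
#' planted columns plus the mean information content of unplanted flank
#' columns.
#'
#' @param ensemble A [specnet_ensemble()].
#' @param data The full data list the ensemble was fitted on (same order).
#' @return List with `covered_loss`, `planted_mae`, `argmax_recovery`,
#'   `flank_ic`, `n_points`, `n_planted_columns`.
#' @export
crossval_metrics <- function(ensemble, data) {
  stopifnot(inherits(ensemble, "specnet_ensemble"))
  covered <- numeric(0)
  planted_err <- numeric(0)
  hits <- integer(0)
  flank_ic <- numeric(0)
  for (f in seq_along(ensemble$folds)) {
    member <- ensemble$members[[f]]
    for (i in ensemble$folds[[f]]) {
      dp <- data[[i]]
      pred <- predict_pwm(member$model, dp$complex)$pwm
      covered <- c(covered, column_loss(pred, dp))
      if (!is.null(dp$planted) && nrow(dp$planted)) {
        tgt <- aligned_target(dp)
        ic <- information_content(pred)
        planted <- dp$planted$pair_index + 1L
        for (p in planted) {
          if (is.na(tgt[p, 1])) next
          if (max(tgt[p, ]) - min(tgt[p, ]) < 1e-9) next  # uniform rule column
          planted_err <- c(planted_err, sum(abs(pred[p, ] - tgt[p, ])))
          hits <- c(hits, which.max(pred[p, ]) == which.max(tgt[p, ]))
        }
        flank_ic <- c(flank_ic, ic[setdiff(seq_len(nrow(pred)), planted)])
      }
    }
  }
  list(covered_loss = mean(covered),
       planted_mae = if (length(planted_err)) mean(planted_err) else NA_real_,
       argmax_recovery = if (length(hits)) mean(hits) else NA_real_,
       flank_ic = if (length(flank_ic)) mean(flank_ic) else NA_real_,
       n_points = length(covered), n_planted_columns = length(planted_err))
}
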