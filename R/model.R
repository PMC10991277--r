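#' Create a model configuration
#'
#' Defaults are the tuned architecture: kernel size 18 and 256 neurons (the
#' neuron count is applied both as convolution filter count and dense-layer
#' width), dropout 0.3, at most 100 epochs in batches of 32, Adam with
#' AMSGRAD minimising mean squared error in degrees Celsius. Pooling window,
#' learning rate and early-stopping patience are unstated upstream and
#' exposed as knobs with conventional defaults.
#'
#' @param kernel_size convolution kernel width (residues).
#' @param n_neurons convolution filter count and dense width.
#' @param dropout_rate dropout probability after each dense layer.
#' @param max_epochs,batch_size training schedule.
#' @param pool_size max-pooling window (and stride).
#' @param learning_rate Adam step size.
#' @param amsgrad use the AMSGRAD variant of Adam.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (best-validation weights are restored).
#' @param normalize_labels optimise on z-scored labels (predictions are mapped
#'   back to degrees Celsius automatically). Off by default: the loss is then
#'   plain MSE in degrees C squared. Standardisation conditions the
#'   optimisation when labels span a wide absolute range.
#' @param seed seed for weight initialisation, shuffling and dropout.
#' @return a \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(kernel_size = 18L, n_neurons = 256L, dropout_rate = 0.3,
                        max_epochs = 100L, batch_size = 32L, pool_size = 2L,
                        learning_rate = 0.001, amsgrad = TRUE,
                        early_stop_patience = 5L, normalize_labels = FALSE,
                        seed = 1L) {
  methods::new("ModelConfig", kernel_size = as.integer(kernel_size),
               n_neurons = as.integer(n_neurons), dropout_rate = dropout_rate,
               max_epochs = as.integer(max_epochs),
               batch_size = as.integer(batch_size),
               pool_size = as.integer(pool_size),
               learning_rate = learning_rate, amsgrad = amsgrad,
               early_stop_patience = as.integer(early_stop_patience),
               normalize_labels = isTRUE(normalize_labels),
               seed = as.integer(seed))
}

# Feature-map lengths after each layer, or an error if L_max is too short
# for two pooled convolutions.
layerSizes <- function(config, L_max) {
  k <- config@kernel_size; p <- config@pool_size
  P1 <- L_max - k + 1L
  P2 <- P1 %/% p
  P3 <- P2 - k + 1L
  P4 <- P3 %/% p
  if (P1 < 1L || P3 < 1L || P4 < 1L) {
    Lmin <- (2L * k - 1L) * p + k - 1L  # smallest L giving P4 >= 1
    stop("L_max = ", L_max, " too small for two pooled convolutions with ",
         "kernel ", k, " and pool ", p, "; minimum input length is ", Lmin)
  }
  c(P1 = P1, P2 = P2, P3 = P3, P4 = P4)
}

#' Build an untrained convolutional regressor
#'
#' Initialises weights (He-scaled normal draws from the config seed) for the
#' architecture conv-pool-conv-pool-dense-dropout-dense-dropout-linear.
#' Two builds with the same config and \code{L_max} are identical.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param L_max input one-hot length the model is bound to.
#' @return an untrained \linkS4class{OptTempCNN}.
#' @export
buildModel <- function(config, L_max = 1000L) {
  methods::validObject(config)
  L_max <- as.integer(L_max)
  sz <- layerSizes(config, L_max)
  k <- config@kernel_size; F <- config@n_neurons; H <- config@n_neurons
  flat <- sz[["P4"]] * F
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  w <- with_seed(config@seed, list(
    W1 = he(k * 20L, F), b1 = numeric(F),
    W2 = he(k * F, F), b2 = numeric(F),
    W3 = he(flat, H), b3 = numeric(H),
    W4 = he(H, H), b4 = numeric(H),
    w5 = rnorm(H, sd = sqrt(2 / H)), b5 = 0))
  methods::new("OptTempCNN", config = config, L_max = L_max, weights = w,
               trained = FALSE,
               history = data.frame(epoch = integer(), train_loss = numeric(),
                                    val_loss = numeric()),
               stopped_epoch = 0L, label_center = 0, label_scale = 1)
}

#' Number of trainable parameters of a model
#' @param model an \linkS4class{OptTempCNN}.
#' @return integer parameter count.
#' @export
countParams <- function(model) {
  sum(vapply(model@weights, length, 1L))
}

#' @rdname OptTempCNN-class
#' @export
setMethod("modelConfigOf", "OptTempCNN", function(x) x@config)

#' @rdname OptTempCNN-class
#' @export
setMethod("trainingHistory", "OptTempCNN", function(x) x@history)

setMethod("show", "OptTempCNN", function(object) {
  cfg <- object@config
  cat("OptTempCNN (kernel ", cfg@kernel_size, ", ", cfg@n_neurons,
      " neurons, L_max ", object@L_max, "): ",
      if (object@trained) paste0("trained, stopped at epoch ", object@stopped_epoch)
      else "untrained",
      ", ", countParams(object), " parameters\n", sep = "")
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig: kernel ", object@kernel_size, ", neurons ",
      object@n_neurons, ", dropout ", object@dropout_rate, ", epochs <= ",
      object@max_epochs, ", batch ", object@batch_size, ", lr ",
      object@learning_rate, ", amsgrad ", object@amsgrad, "\n", sep = "")
})

# Encode labelled proteins as (L, 20, n) cube ready for the C++ kernels.
encodeForModel <- function(corpus, ids, L_max) {
  arr <- encodeBatch(corpus, L_max = L_max, ids = ids)
  aperm(arr, c(2, 3, 1))
}

labelsOf <- function(corpus, ids) {
  info <- proteinInfo(corpus)
  lab <- info$label_celsius[match(ids, info$protein_id)]
  if (any(is.na(lab)))
    stop("unlabelled or unknown protein(s) in split: ",
         paste(head(ids[is.na(lab)], 5), collapse = ", "))
  stats::setNames(lab, ids)
}

adamInit <- function(w) {
  zero <- lapply(w, function(x) x * 0)
  list(m = zero, v = zero, vhat = zero, t = 0L)
}

adamStep <- function(w, g, state, lr, amsgrad, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(w)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / bc1
    if (amsgrad) {
      state$vhat[[nm]] <- pmax(state$vhat[[nm]], state$v[[nm]])
      vv <- state$vhat[[nm]] / bc2
    } else {
      vv <- state$v[[nm]] / bc2
    }
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vv) + eps)
  }
  list(w = w, state = state)
}

#' Train the convolutional regressor
#'
#' Minimises mean squared error (degrees Celsius squared) with Adam
#' (optionally AMSGRAD) over shuffled minibatches; stops early when the
#' validation loss has not improved for \code{early_stop_patience} epochs and
#' restores the best-validation weights. All randomness (shuffling, dropout)
#' derives from the config seed, so a rerun reproduces the same weights.
#'
#' @param model an \linkS4class{OptTempCNN} from \code{\link{buildModel}}.
#' @param corpus the \linkS4class{ThermoCorpus} holding sequences and labels.
#' @param train_ids,val_ids disjoint labelled protein id vectors.
#' @param verbose print per-epoch losses.
#' @return the trained \linkS4class{OptTempCNN} with per-epoch history.
#' @export
trainModel <- function(model, corpus, train_ids, val_ids, verbose = FALSE) {
  if (length(train_ids) == 0L || length(val_ids) == 0L)
    stop("empty train or validation split")
  if (length(intersect(train_ids, val_ids)))
    stop("train and validation splits overlap")
  cfg <- model@config
  Xtr <- encodeForModel(corpus, train_ids, model@L_max)
  ytr <- labelsOf(corpus, train_ids)
  Xval <- encodeForModel(corpus, val_ids, model@L_max)
  yval <- labelsOf(corpus, val_ids)
  if (cfg@normalize_labels) {
    center <- mean(ytr)
    scale <- sd(ytr)
    if (!is.finite(scale) || scale == 0) scale <- 1
  } else {
    center <- 0; scale <- 1
  }
  ytr <- (ytr - center) / scale
  yval <- (yval - center) / scale
  n <- length(ytr); H <- cfg@n_neurons
  keep_prob <- 1 - cfg@dropout_rate

  w <- model@weights
  state <- adamInit(w)
  best_w <- w
  best_val <- Inf
  best_epoch <- 0L
  wait <- 0L
  hist <- vector("list", cfg@max_epochs)
  stopped <- cfg@max_epochs

  with_seed(cfg@seed + 1L, {
    for (epoch in seq_len(cfg@max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg@batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg@batch_size - 1L, n)]
        b <- length(idx)
        D1 <- matrix(rbinom(b * H, 1L, keep_prob), b, H) / keep_prob
        D2 <- matrix(rbinom(b * H, 1L, keep_prob), b, H) / keep_prob
        res <- cnn_grad_cpp(Xtr[, , idx, drop = FALSE], ytr[idx], w,
                            cfg@kernel_size, cfg@pool_size, D1, D2)
        if (!is.finite(res$loss))
          stop("non-finite training loss at epoch ", epoch,
               "; lower the learning rate or check the labels")
        upd <- adamStep(w, res$grads, state, cfg@learning_rate, cfg@amsgrad)
        w <- upd$w; state <- upd$state
        ep_loss <- ep_loss + res$loss * b
      }
      ep_loss <- ep_loss / n
      val_pred <- cnn_forward_cpp(Xval, w, cfg@kernel_size, cfg@pool_size)
      val_loss <- mean((val_pred - yval)^2)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                  val_loss = val_loss)
      if (verbose)
        log_msg(sprintf("epoch %d: train MSE %.3f, val MSE %.3f",
                        epoch, ep_loss, val_loss))
      if (val_loss < best_val - 1e-10) {
        best_val <- val_loss; best_w <- w; best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg@early_stop_patience) { stopped <- epoch; break }
      }
    }
  })

  model@weights <- best_w
  model@trained <- TRUE
  model@label_center <- center
  model@label_scale <- scale
  model@history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model@stopped_epoch <- as.integer(stopped)
  attr(model@history, "best_epoch") <- best_epoch
  model
}

#' @rdname predictOptTemp
#' @param batch_size prediction chunk size.
#' @export
setMethod("predictOptTemp", "OptTempCNN", function(model, x, batch_size = 256L, ...) {
  if (!model@trained)
    log_msg("predicting with an untrained model (random weights)")
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[2] != model@L_max || dim(x)[3] != 20L)
      stop("encoded batch has L_max = ", dim(x)[2],
           " but the model was built for L_max = ", model@L_max)
    cube <- aperm(x, c(2, 3, 1))
    ids <- dimnames(x)[[1]]
  } else {
    seqs <- asSequenceVector(x)
    cube <- aperm(encodeBatch(seqs, L_max = model@L_max), c(2, 3, 1))
    ids <- names(seqs)
  }
  n <- dim(cube)[3]
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    out[idx] <- cnn_forward_cpp(cube[, , idx, drop = FALSE], model@weights,
                                model@config@kernel_size, model@config@pool_size)
  }
  stats::setNames(out * model@label_scale + model@label_center, ids)
})

#' @rdname predictOptTemp
#' @export
setMethod("predictOptTemp", "function", function(model, x, ...) {
  seqs <- asSequenceVector(x)
  out <- model(seqs)
  if (is.null(names(out))) names(out) <- names(seqs)
  out
})

#' Save / load a model checkpoint
#'
#' Single-file serialised checkpoint embedding the config, \code{L_max} and a
#' schema tag; \code{loadModel} refuses checkpoints written by an
#' incompatible schema version.
#'
#' @param model a \linkS4class{OptTempCNN}.
#' @param path checkpoint file path.
#' @return \code{saveModel}: the path, invisibly; \code{loadModel}: the model.
#' @export
saveModel <- function(model, path) {
  payload <- list(schema = "OptTempCNN/1",
                  config = lapply(methods::slotNames("ModelConfig"),
                                  function(s) methods::slot(model@config, s)),
                  config_names = methods::slotNames("ModelConfig"),
                  L_max = model@L_max, weights = model@weights,
                  trained = model@trained, history = model@history,
                  stopped_epoch = model@stopped_epoch,
                  label_center = model@label_center,
                  label_scale = model@label_scale)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$schema, "OptTempCNN/1"))
    stop("checkpoint schema ", payload$schema %||% "<missing>",
         " does not match this code version (OptTempCNN/1)")
  cfg_args <- stats::setNames(payload$config, payload$config_names)
  cfg <- do.call(modelConfig, cfg_args)
  methods::new("OptTempCNN", config = cfg, L_max = payload$L_max,
               weights = payload$weights, trained = payload$trained,
               history = payload$history,
               stopped_epoch = payload$stopped_epoch,
               label_center = payload$label_center,
               label_scale = payload$label_scale)
}

#' Grid search over kernel size and neuron count
#'
#' Trains one model per (kernel, neurons) pair on the same seeded
#' train/validation split and scores each by validation Pearson correlation
#' between predicted and observed temperatures. The best configuration
#' attains the maximum validation r; ties break towards the smaller kernel,
#' then fewer neurons. A pair whose training fails is recorded and skipped.
#'
#' @param corpus a \linkS4class{ThermoCorpus}.
#' @param train_ids,val_ids the split the candidates share.
#' @param kernel_sizes,n_neurons integer candidate vectors.
#' @param template a \linkS4class{ModelConfig} supplying all other settings.
#' @param L_max input length.
#' @return a \linkS4class{GridSearchResult}.
#' @export
gridSearch <- function(corpus, train_ids, val_ids, kernel_sizes, n_neurons,
                       template = modelConfig(), L_max = 1000L) {
  if (!length(kernel_sizes) || !length(n_neurons))
    stop("empty candidate list")
  grid <- expand.grid(kernel_size = as.integer(kernel_sizes),
                      n_neurons = as.integer(n_neurons))
  yval <- labelsOf(corpus, val_ids)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- template
    cfg@kernel_size <- grid$kernel_size[i]
    cfg@n_neurons <- grid$n_neurons[i]
    r <- tryCatch({
      m <- buildModel(cfg, L_max = L_max)
      m <- trainModel(m, corpus, train_ids, val_ids)
      pred <- predictOptTemp(m, corpus)[val_ids]
      pearsonR(pred, yval)
    }, error = function(e) {
      log_msg("grid pair (", cfg@kernel_size, ", ", cfg@n_neurons,
              ") failed: ", conditionMessage(e))
      NA_real_
    })
    data.frame(kernel_size = grid$kernel_size[i], n_neurons = grid$n_neurons[i],
               validation_r = r,
               status = if (is.na(r)) "failed" else "ok")
  })
  tried <- do.call(rbind, rows)
  ok <- tried[tried$status == "ok" & !is.na(tried$validation_r), ]
  if (nrow(ok) == 0) stop("all grid-search pairs failed")
  ord <- order(-ok$validation_r, ok$kernel_size, ok$n_neurons)
  best_row <- ok[ord[1], ]
  best <- template
  best@kernel_size <- best_row$kernel_size
  best@n_neurons <- best_row$n_neurons
  methods::new("GridSearchResult", tried = tried, best = best)
}

setMethod("show", "GridSearchResult", function(object) {
  cat("GridSearchResult:", nrow(object@tried), "pairs tried; best kernel",
      object@best@kernel_size, "with", object@best@n_neurons, "neurons\n")
})
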