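# Training loop: plain SGD with momentum and weight decay on the compound
# loss, fully seeded. Checkpoints are the parameter values plus the config,
# serialised with saveRDS.

#' Run configuration
#'
#' Optimiser and loop settings. The optimiser defaults (SGD, learning rate
#' 0.01, momentum 0.9, weight decay 1e-4, batch size 24) follow the training
#' recipe the architecture was published with; `epochs` has no published
#' value and defaults to a desk-scale 50.
#'
#' @param model a [model_config()].
#' @param lr learning rate (> 0).
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty coefficient applied inside the update.
#' @param batch_size minibatch size (>= 1).
#' @param epochs number of passes over the training set.
#' @param seed integer seed controlling shuffling (and, through
#'   `model$seed`, initialisation).
#' @return a `run_config` object.
#' @export
run_config <- function(model = model_config(), lr = 0.01, momentum = 0.9,
                       weight_decay = 1e-4, batch_size = 24L, epochs = 50L,
                       seed = 1L) {
  if (!is.numeric(lr) || lr <= 0) stop("lr must be > 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  structure(list(model = model, optimizer = list(type = "sgd", lr = lr,
                                                 momentum = momentum,
                                                 weight_decay = weight_decay),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "run_config")
}

sgd_step <- function(params, lr, momentum, weight_decay) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad + weight_decay * p$value
    if (is.null(p$momentum)) p$momentum <- 0 * p$value
    p$momentum <- momentum * p$momentum - lr * g
    p$value <- p$value + p$momentum
  }
  invisible(params)
}

#' Train a model on a phantom dataset
#'
#' Minimises the compound cross-entropy + soft-Dice loss with SGD. The loop
#' is fully seeded: the same `run` seed and dataset reproduce the loss
#' trajectory exactly.
#'
#' @param model an `mipc_model` (modified in place; also returned).
#' @param dataset a `phantom_dataset` or list of `image`/`mask` pairs.
#' @param run a [run_config()]; its `model` entry is ignored in favour of
#'   the already-built `model`.
#' @param eval_every compute training Dice (argmax prediction vs labels,
#'   macro over foreground classes) every this many epochs; 0 disables.
#' @param stop_dice optional early-stopping target: training ends at the
#'   first Dice evaluation reaching this value.
#' @param log_file optional path receiving one JSON line per epoch.
#' @param verbose print a line per `eval_every` epochs.
#' @return list with `model` and `history` (tibble: epoch, loss, dice).
#' @export
train_model <- function(model, dataset, run = run_config(), eval_every = 10L,
                        stop_dice = NULL, log_file = NULL, verbose = FALSE) {
  td <- dataset_tensors(dataset)
  n <- dim(td$images)[1]
  K <- model$cfg$num_classes
  if (max(td$labels) > max(K - 1L, 1L)) {
    stop("dataset labels exceed the configured number of classes")
  }
  params <- model$params
  if (!is.null(log_file)) {
    dir.create(dirname(log_file), recursive = TRUE, showWarnings = FALSE)
  }
  history <- with_seed(run$seed, function() {
    history <- vector("list", run$epochs)
    for (ep in seq_len(run$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / run$batch_size))
      ep_loss <- 0
      for (b in batches) {
        xb <- tn_const(td$images[b, , , , drop = FALSE])
        yb <- td$labels[b, , , drop = FALSE]
        loss <- tn_compound_loss(model_fwd(model, xb, train = TRUE), yb, K)
        tn_zero_grad(params)
        tn_backward(loss)
        sgd_step(params, run$optimizer$lr, run$optimizer$momentum,
                 run$optimizer$weight_decay)
        ep_loss <- ep_loss + as.numeric(loss$value) * length(b)
      }
      ep_loss <- ep_loss / n
      dice <- NA_real_
      if (eval_every > 0L && (ep %% eval_every == 0L || ep == run$epochs)) {
        dice <- training_dice(model, td)
        if (verbose) {
          message(sprintf("epoch %3d  loss %.4f  dice %.4f", ep, ep_loss,
                          dice))
        }
      }
      history[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss,
                                      dice = dice)
      if (!is.null(log_file)) {
        cat(jsonlite::toJSON(list(epoch = ep, loss = ep_loss, dice = dice),
                             auto_unbox = TRUE, digits = NA, na = "null"),
            "\n", sep = "", file = log_file, append = TRUE)
      }
      if (!is.null(stop_dice) && !is.na(dice) && dice >= stop_dice) break
    }
    history[!vapply(history, is.null, logical(1))]
  })
  out <- list(model = model, history = do.call(rbind, history))
  class(out) <- "mipc_fit"
  out
}

# macro-averaged foreground Dice of argmax predictions on tensors
training_dice <- function(model, td) {
  logits <- model_fwd(model, tn_const(td$images), train = FALSE)$value
  pred <- logits_to_labels(logits, model$cfg$num_classes)
  classes <- sort(unique(as.integer(td$labels)))
  classes <- classes[classes != 0L]
  if (length(classes) == 0L) classes <- 1L
  mean(vapply(classes, function(k) {
    dice_coefficient(pred == k, td$labels == k)
  }, numeric(1)))
}

#' @export
print.mipc_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<mipc_fit: %d epochs, final loss %.4f, final dice %s>\n",
              nrow(h), h$loss[nrow(h)],
              formatC(h$dice[nrow(h)], digits = 4, format = "f")))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full [model_config()] plus every parameter
#' value and batch-norm running statistic, so `load_checkpoint()` rebuilds
#' an identical model.
#' @param model an `mipc_model`.
#' @param path checkpoint file path (RDS).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the restored `mipc_model`.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  values <- lapply(model$params, function(p) p$value)
  bn <- bn_states(model$layers)
  saveRDS(list(format = "mipcnet-checkpoint-v1", cfg = unclass(model$cfg),
               values = values, bn = bn), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "mipcnet-checkpoint-v1")) {
    stop("not a recognised checkpoint: ", path)
  }
  cfg <- ck$cfg
  cfg$attention <- do.call(attention_params, cfg$attention[
    c("reduction_ratio", "spatial_kernel", "scale_init")])
  cfg <- do.call(model_config, cfg[setdiff(names(cfg), "num_conv_stages")])
  model <- build_model(cfg)
  stopifnot(length(model$params) == length(ck$values))
  for (i in seq_along(model$params)) {
    model$params[[i]]$value <- ck$values[[i]]
  }
  restore_bn_states(model$layers, ck$bn)
  model
}

bn_states <- function(obj) {
  out <- list()
  walk <- function(o) {
    if (is.environment(o) && identical(o$kind, "batchnorm")) {
      out[[length(out) + 1L]] <<- list(mean = o$run_mean, var = o$run_var)
      return(invisible())
    }
    if (is.list(o)) for (el in o) {
      if (is.list(el) || is.environment(el)) walk(el)
    }
    invisible()
  }
  walk(obj)
  out
}

restore_bn_states <- function(obj, states) {
  i <- 0L
  walk <- function(o) {
    if (is.environment(o) && identical(o$kind, "batchnorm")) {
      i <<- i + 1L
      o$run_mean <- states[[i]]$mean
      o$run_var <- states[[i]]$var
      return(invisible())
    }
    if (is.list(o)) for (el in o) {
      if (is.list(el) || is.environment(el)) walk(el)
    }
    invisible()
  }
  walk(obj)
  stopifnot(i == length(states))
  invisible(obj)
}

#' Evaluate a model on a dataset
#'
#' Predicts every image and scores predictions against the ground-truth
#' masks with [evaluate_cases()].
#' @param model an `mipc_model`.
#' @param dataset a `phantom_dataset` or list of `image`/`mask` pairs.
#' @param spacing per-axis pixel spacing for the Hausdorff distance.
#' @return a `metrics_report`.
#' @export
evaluate_model <- function(model, dataset, spacing = 1) {
  td <- dataset_tensors(dataset)
  logits <- model_fwd(model, tn_const(td$images), train = FALSE)$value
  pred <- logits_to_labels(logits, model$cfg$num_classes)
  cases <- lapply(seq_len(dim(pred)[1]), function(i) {
    list(pred = pred[i, , ], truth = td$labels[i, , ])
  })
  evaluate_cases(cases, spacing = spacing)
}
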