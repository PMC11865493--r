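#' Save a trained model as a checkpoint directory
#'
#' Writes the parameters (`params.rds`) together with a JSON sidecar
#' (`checkpoint.json`) holding the network configuration, the training
#' seed, the best epoch and its validation loss, so a checkpoint is
#' self-describing and replayable.
#'
#' @param model a `unet_model`.
#' @param dir checkpoint directory (created if needed).
#' @param record optional training record (data frame from
#'   [train_restorer()]).
#' @param seed optional training seed to record.
#' @return Invisibly, `dir`.
#' @export
save_model <- function(model, dir, record = NULL, seed = NULL) {
  stopifnot(inherits(model, "unet_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  side <- list(config = unclass(model$config), seed = seed)
  if (!is.null(record) && nrow(record)) {
    best <- which.min(record$val_loss)
    side$best_epoch <- record$epoch[best]
    side$best_val_loss <- record$val_loss[best]
    side$epochs_run <- nrow(record)
  }
  jsonlite::write_json(side, file.path(dir, "checkpoint.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir directory written by [save_model()].
#' @return A `unet_model`.
#' @export
load_model <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "checkpoint.json"),
                              simplifyVector = TRUE)
  cfg <- network_config(depth = side$config$depth,
                        base_filters = side$config$base_filters,
                        residual_output = side$config$residual_output)
  model <- build_network(cfg, seed = 0L)
  params <- readRDS(file.path(dir, "params.rds"))
  stopifnot(identical(sort(names(params)), sort(names(model$params))))
  model$params <- params
  model
}

#' Training configuration
#'
#' Defaults: adaptive-moment gradient descent (Adam) at learning rate 1e-4,
#' batches of 16 patches, early stopping on the validation loss with
#' patience 10. All settings are exposed because the original optimization
#' schedule is not part of the model contract.
#'
#' @param epochs maximum number of epochs (>= 1).
#' @param batch_size patches per gradient step.
#' @param learning_rate Adam step size.
#' @param validation_fraction fraction of patches held out when the caller
#'   splits (see [build_training_set()]).
#' @param seed integer seed; fixes the batch order, so two runs with the
#'   same seed and data produce identical loss curves.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping; `Inf` disables early stopping.
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 50L, batch_size = 16L,
                            learning_rate = 1e-4,
                            validation_fraction = 0.2, seed = NULL,
                            early_stop_patience = 10) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (!(validation_fraction > 0 && validation_fraction < 1))
    stop("validation_fraction must be in (0, 1)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction, seed = seed,
                 early_stop_patience = early_stop_patience),
            class = "training_config")
}

# forward(+backward) over a small GEMM batch; grads summed over the batch
chunk_loss_grad <- function(model, patches, sparams, want_grad = TRUE) {
  nb <- length(patches)
  n <- nrow(patches[[1]]$lr)
  m <- ncol(patches[[1]]$lr)
  xb <- array(unlist(lapply(patches, `[[`, "lr")), dim = c(n, m, nb))
  fw <- unet_forward(model, xb, keep = want_grad)
  yb <- if (nb == 1L) array(fw$y, dim = c(n, m, 1L)) else fw$y
  radius <- (sparams$ssim_window - 1L) %/% 2L
  losses <- numeric(nb)
  g_y <- if (want_grad) array(0, dim = c(n, m, nb)) else NULL
  for (b in seq_len(nb)) {
    lg <- .scop_fwd_bwd_cpp(patches[[b]]$hr, yb[, , b], patches[[b]]$gamma,
                            sparams$c1, sparams$c2, radius,
                            sparams$ssim_sigma, want_grad)
    losses[b] <- lg$loss
    if (want_grad) g_y[, , b] <- lg$grad
  }
  if (!want_grad) return(list(loss_sum = sum(losses)))
  grads <- unet_backward(model, fw$cache, g_y)
  list(loss_sum = sum(losses), grads = grads)
}

# one gradient step's worth of patches; processed in small sub-chunks (the
# batched tap-GEMMs are fastest when the padded buffers stay cache-sized)
# and averaged over the whole batch
batch_loss_grad <- function(model, patches, sparams, want_grad = TRUE,
                            chunk = 4L) {
  nb <- length(patches)
  acc <- NULL
  loss_sum <- 0
  for (start in seq(1, nb, by = chunk)) {
    idx <- start:min(start + chunk - 1, nb)
    part <- chunk_loss_grad(model, patches[idx], sparams, want_grad)
    loss_sum <- loss_sum + part$loss_sum
    if (want_grad)
      acc <- if (is.null(acc)) part$grads
             else mapply(`+`, acc, part$grads, SIMPLIFY = FALSE)
  }
  if (!want_grad) return(list(loss = loss_sum / nb))
  list(loss = loss_sum / nb, grads = lapply(acc, `/`, nb))
}

validation_loss <- function(model, patches, sparams) {
  batch_loss_grad(model, patches, sparams, want_grad = FALSE)$loss
}

#' Train a restoration model with the prioritized structural loss
#'
#' Seeded, reproducible minimization of [scop_loss()] over co-registered
#' patch pairs with precomputed per-pixel exponent maps (the loss weights
#' depend only on the targets, never on predictions). The model state with
#' the best validation loss is returned together with the per-epoch loss
#' record.
#'
#' @param model an initialized `unet_model` (see [build_network()]).
#' @param train_patches,val_patches lists of `patch_pair` objects (each
#'   with `lr`, `hr` and `gamma` rasters).
#' @param tconf a [training_config()].
#' @param sparams a [scop_params()].
#' @param verbose print a line per epoch.
#' @return List with `model` (best-validation checkpoint), `record` (data
#'   frame: epoch, train_loss, val_loss) and `best_epoch`.
#' @export
train_restorer <- function(model, train_patches, val_patches,
                           tconf = training_config(),
                           sparams = scop_params(), verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"),
            inherits(tconf, "training_config"),
            inherits(sparams, "scop_params"))
  if (!length(train_patches) || !length(val_patches))
    stop("training and validation patch sets must be nonempty")
  for (p in c(train_patches, val_patches))
    if (is.null(p$lr) || is.null(p$hr) || is.null(p$gamma))
      stop("every patch needs lr, hr and gamma rasters")

  params <- model$params
  mom <- lapply(params, function(w) w * 0)
  vel <- lapply(params, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  record <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  stall <- 0L

  with_seed(tconf$seed, {
    for (epoch in seq_len(tconf$epochs)) {
      order_idx <- sample.int(length(train_patches))
      batch_losses <- numeric(0)
      for (start in seq(1, length(order_idx), by = tconf$batch_size)) {
        idx <- order_idx[start:min(start + tconf$batch_size - 1,
                                   length(order_idx))]
        model$params <- params
        lg <- batch_loss_grad(model, train_patches[idx], sparams)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", epoch)
        t_step <- t_step + 1L
        for (nm in names(params)) {
          g <- lg$grads[[nm]]
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g^2
          mhat <- mom[[nm]] / (1 - b1^t_step)
          vhat <- vel[[nm]] / (1 - b2^t_step)
          params[[nm]] <- params[[nm]] -
            tconf$learning_rate * mhat / (sqrt(vhat) + eps)
        }
        batch_losses <- c(batch_losses, lg$loss)
      }
      model$params <- params
      vloss <- validation_loss(model, val_patches, sparams)
      if (!is.finite(vloss))
        stop("non-finite validation loss at epoch ", epoch)
      record <- rbind(record,
                      data.frame(epoch = epoch,
                                 train_loss = mean(batch_losses),
                                 val_loss = vloss))
      if (verbose)
        message(sprintf("epoch %d: train %.5f  val %.5f", epoch,
                        mean(batch_losses), vloss))
      if (vloss < best_val) {
        best_val <- vloss
        best_params <- params
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tconf$early_stop_patience) break
      }
    }
  })
  model$params <- best_params
  list(model = model, record = record, best_epoch = best_epoch)
}
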