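#' Training configuration
#'
#' Hyper-parameters for [leafseg_train()].  Defaults follow common practice
#' for single-class instance segmentation: SGD with momentum 0.937, weight
#' decay 5e-4 on convolution weights, a linear warmup followed by a linear
#' decay of the learning rate, and mosaic augmentation disabled for the
#' final `close_mosaic` epochs so the network finishes on whole images.
#'
#' @param epochs training epochs.
#' @param batch_size images per optimization step.
#' @param lr0 initial learning rate (after warmup).
#' @param lrf final learning rate as a fraction of `lr0`.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on convolution weights.
#' @param warmup_epochs linear warmup length (may be fractional).
#' @param close_mosaic number of final epochs with mosaic switched off.
#' @param augment an [augment_config()]; set `NULL` to train without
#'   augmentation.
#' @param seed integer seed controlling initialization, shuffling and
#'   augmentation draws.
#' @param verbose print a line per epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 250L, batch_size = 16L, lr0 = 0.01,
                         lrf = 0.01, momentum = 0.937, weight_decay = 5e-4,
                         warmup_epochs = 3, close_mosaic = 10L,
                         augment = augment_config(), seed = NULL,
                         verbose = TRUE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr0 > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0, lrf = lrf,
                 momentum = momentum, weight_decay = weight_decay,
                 warmup_epochs = warmup_epochs,
                 close_mosaic = as.integer(close_mosaic), augment = augment,
                 seed = seed, verbose = isTRUE(verbose)),
            class = "train_config")
}

# read a dataset directory produced by generate_dataset() (or following the
# same manifest layout) into memory at the network input size
load_samples <- function(dir, img_size) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    stop("no manifest.csv in ", dir, call. = FALSE)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    img <- read_image_png(man$image[i])
    if (dim(img)[1L] != img_size || dim(img)[2L] != img_size)
      img <- clamp01(array(as.numeric(EBImage::resize(
        img, w = img_size, h = img_size, filter = "bilinear")),
        c(img_size, img_size, 3L)))
    list(image = img, ann = read_annotation_txt(man$annotation[i]),
         label_path = if ("label" %in% names(man)) man$label[i] else NA_character_)
  })
}

# polygon annotation -> assignment targets at the working resolution
targets_from_ann <- function(ann, size) {
  labels <- suppressWarnings(polygons_to_mask(ann, size, size))
  instances_from_labels(labels)
}

sgd_step <- function(params, lr, momentum, weight_decay) {
  for (p in params) {
    if (is.null(p$g)) next
    g <- p$g
    if (weight_decay > 0 && isTRUE(p$decay)) g <- g + weight_decay * p$v
    if (is.null(p$mom)) p$mom <- g * 0
    p$mom <- momentum * p$mom + g
    p$v <- p$v - lr * p$mom
  }
  invisible(NULL)
}

#' Fit a leaf instance segmentation model
#'
#' The main fitting function.  Loads a dataset directory (as written by
#' [generate_dataset()] or [cli] `convert`), builds the configured network
#' and optimizes the composite detection/segmentation loss with SGD.
#' Returns a fitted-model object with the usual methods: `print`,
#' `summary`, `predict` (instance label maps for new images), and `plot`
#' (training curve).
#'
#' @param data training data: a directory containing `manifest.csv`, or a
#'   list of `list(image =, ann =)` samples already in memory.
#' @param model a [model_config()] or a prebuilt/pretrained `leafseg_net`
#'   to continue training.
#' @param config a [train_config()].
#' @param val optional validation data (same forms as `data`); when given,
#'   segmentation metrics are computed on it after the final epoch.
#' @return an object of class `leafseg_model`: list with `net`, `history`
#'   (per-epoch losses), `val_metrics` (a `metric_report` or `NULL`),
#'   `model_config`, `train_config` and `elapsed` (seconds).
#' @seealso [predict_instances()], [evaluate_dataset()]
#' @export
leafseg_train <- function(data, model = model_config(), config = train_config(),
                          val = NULL) {
  stopifnot(inherits(config, "train_config"))
  t_start <- proc.time()[3L]
  if (!is.null(config$seed)) set.seed(config$seed)
  net <- if (inherits(model, "leafseg_net")) model else build_model(model)
  cfg <- net$cfg
  samples <- if (is.character(data)) load_samples(data, cfg$img_size) else data
  n <- length(samples)
  if (n < 1L) stop("empty training set", call. = FALSE)
  bs <- min(config$batch_size, n)
  steps_per_epoch <- ceiling(n / bs)
  warmup_steps <- max(1, config$warmup_epochs * steps_per_epoch)
  total_steps <- config$epochs * steps_per_epoch
  hist <- matrix(0, config$epochs, 5L,
                 dimnames = list(NULL, c("loss", "box", "cls", "dfl", "mask")))
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    mosaic_on <- !is.null(config$augment) &&
      epoch <= config$epochs - config$close_mosaic
    ord <- sample.int(n)
    ep_parts <- c(box = 0, cls = 0, dfl = 0, mask = 0)
    nb <- 0L
    for (b in seq_len(steps_per_epoch)) {
      idx <- ord[((b - 1L) * bs + 1L):min(b * bs, n)]
      imgs <- array(0, c(cfg$img_size, cfg$img_size, 3L, length(idx)))
      targets <- vector("list", length(idx))
      ok <- TRUE
      for (j in seq_along(idx)) {
        sm <- samples[[idx[j]]]
        if (!is.null(config$augment)) {
          pool <- samples[-idx[j]]
          aug <- augment_sample(sm$image, sm$ann, config$augment,
                                pool = pool, use_mosaic = mosaic_on)
          sm <- list(image = aug$image, ann = aug$ann)
        }
        imgs[, , , j] <- sm$image
        tg <- targets_from_ann(sm$ann, cfg$img_size)
        targets[[j]] <- tg
      }
      step <- step + 1L
      lr <- if (step <= warmup_steps) config$lr0 * step / warmup_steps else {
        frac <- (step - warmup_steps) / max(total_steps - warmup_steps, 1)
        config$lr0 * (1 - frac * (1 - config$lrf))
      }
      ad_tape_reset(TRUE)
      out <- net_forward(net, ad_tensor(imgs), training = TRUE)
      L <- compute_loss(net, out, targets)
      ad_zero_grad(net$params)
      ad_backward(L$total)
      sgd_step(net$params, lr, config$momentum, config$weight_decay)
      ad_tape_reset(FALSE)
      ep_parts <- ep_parts + L$parts
      nb <- nb + 1L
    }
    ep_parts <- ep_parts / nb
    hist[epoch, ] <- c(sum(ep_parts * LOSS_GAINS[names(ep_parts)]), ep_parts)
    if (config$verbose)
      cat(sprintf(
        "epoch %3d/%d  loss %.3f  (box %.3f cls %.3f dfl %.3f mask %.3f)\n",
        epoch, config$epochs, hist[epoch, 1L], ep_parts["box"],
        ep_parts["cls"], ep_parts["dfl"], ep_parts["mask"]))
  }
  fit <- structure(list(net = net,
                        history = as.data.frame(cbind(epoch = seq_len(config$epochs), hist)),
                        val_metrics = NULL, model_config = cfg,
                        train_config = config,
                        elapsed = proc.time()[3L] - t_start),
                   class = "leafseg_model")
  if (!is.null(val)) {
    vs <- if (is.character(val)) load_samples(val, cfg$img_size) else val
    fit$val_metrics <- evaluate_model(fit, vs)
  }
  fit
}

# run predictions over in-memory samples and score them against the
# rasterized annotations
evaluate_model <- function(fit, samples) {
  net <- if (inherits(fit, "leafseg_model")) fit$net else fit
  size <- net$cfg$img_size
  pred <- vector("list", length(samples))
  gt <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    pred[[i]] <- predict_instances(net, samples[[i]]$image)$labels
    gt[[i]] <- suppressWarnings(polygons_to_mask(samples[[i]]$ann, size, size))
  }
  evaluate_dataset(Map(function(p, g) list(ar = p, gt = g), pred, gt))
}

#' @export
print.leafseg_model <- function(x, ...) {
  cat("Leaf instance segmentation model\n")
  cat("  variant: ", x$model_config$variant, " (scale ", x$model_config$scale,
      ", ", format(n_params(x$net), big.mark = ","), " parameters)\n", sep = "")
  cat("  trained: ", nrow(x$history), " epochs, final loss ",
      sprintf("%.3f", x$history$loss[nrow(x$history)]), ", ",
      sprintf("%.1f", x$elapsed / 60), " min\n", sep = "")
  if (!is.null(x$val_metrics)) {
    agg <- x$val_metrics$aggregate
    cat(sprintf("  validation: SBD %.2f  FGBGDice %.2f  |DiC| %.2f\n",
                agg[["SBD"]], agg[["FGBGDice"]],
                agg[["AbsDiffFG"]]))
  }
  invisible(x)
}

#' @export
summary.leafseg_model <- function(object, ...) {
  print(object)
  h <- object$history
  cat("\nLoss components (first / median / final epoch):\n")
  for (cn in c("box", "cls", "dfl", "mask")) {
    cat(sprintf("  %-5s %8.3f %8.3f %8.3f\n", cn, h[[cn]][1L],
                stats::median(h[[cn]]), h[[cn]][nrow(h)]))
  }
  if (!is.null(object$val_metrics)) {
    cat("\nValidation metrics:\n")
    print(object$val_metrics)
  }
  invisible(object)
}

#' Predict method for fitted models
#'
#' @param object a `leafseg_model`.
#' @param newdata an `(H, W, 3)` image array, a PNG path, or a list/vector
#'   of either.
#' @param ... passed to [predict_instances()].
#' @return a `leafseg_prediction`, or a list of them for multiple images.
#' @export
predict.leafseg_model <- function(object, newdata, ...) {
  one <- function(im) {
    if (is.character(im)) im <- read_image_png(im)
    predict_instances(object$net, im, ...)
  }
  if (is.character(newdata) && length(newdata) > 1L)
    return(lapply(newdata, one))
  if (is.list(newdata) && !is.array(newdata))
    return(lapply(newdata, one))
  one(newdata)
}

#' @export
plot.leafseg_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss, 7.5 * h$box, 0.5 * h$cls,
                                   1.5 * h$dfl, h$mask),
                    type = "l", lty = 1, lwd = c(2, 1, 1, 1, 1),
                    col = c("black", "firebrick", "steelblue", "darkorange",
                            "forestgreen"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "box", "cls", "dfl", "mask"),
                   col = c("black", "firebrick", "steelblue", "darkorange",
                           "forestgreen"), lty = 1, bty = "n")
  invisible(x)
}
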