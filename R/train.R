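# Training and evaluation: seeded mini-batch optimization of the
# cross-entropy with Adam (or plain SGD), and deterministic evaluation
# into a metrics report.

#' Training configuration
#'
#' Defaults are the protocol's optimum: Adam, learning rate 1e-4, batch
#' size 32, 224x224 inputs. Images are scaled to `[0, 1]`; per-channel
#' standardization is available behind `standardize`.
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate positive step size.
#' @param batch_size mini-batch size.
#' @param epochs full passes over the training split.
#' @param image_size input side length; images are bilinearly resized.
#' @param seed integer seed covering weight use, data order and shuffles.
#' @param loss only `"cross_entropy"`.
#' @param standardize subtract/divide per-channel mean/sd estimated on the
#'   training split.
#' @return a `train_config` list.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 1e-4,
                         batch_size = 32L, epochs = 10L, image_size = 224L,
                         seed = 0L, loss = "cross_entropy", standardize = FALSE) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1, loss == "cross_entropy")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 loss = loss, standardize = standardize),
            class = "train_config")
}

# Load a manifest split into a list of [0,1]-scaled arrays + labels.
load_split_images <- function(records, image_size, standardize = FALSE, stats = NULL) {
  images <- lapply(records$path, function(p) resize_patch(read_patch(p), image_size) / 255)
  if (standardize) {
    if (is.null(stats)) {
      all_px <- vapply(images, function(a) c(apply(a, 3, mean), apply(a, 3, stats::sd)),
                       numeric(6))
      stats <- list(mean = rowMeans(all_px)[1:3], sd = pmax(rowMeans(all_px)[4:6], 1e-6))
    }
    images <- lapply(images, function(a) {
      for (c in 1:3) a[, , c] <- (a[, , c] - stats$mean[c]) / stats$sd[c]
      a
    })
  }
  list(images = images, stats = stats)
}

model_labels <- function(model, records) {
  col <- if (model$spec$num_classes == 2) "tumor_class" else "subtype"
  lab <- records[[col]]
  if (anyNA(lab)) stopf("manifest has unknown %s labels", col)
  lab
}

softmax_xent <- function(logits, y_idx) {
  # logits N x K, y_idx integer class per row; returns loss and dlogits
  p <- softmax(logits)
  n <- nrow(logits)
  picked <- p[cbind(seq_len(n), y_idx)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- p
  dl[cbind(seq_len(n), y_idx)] <- dl[cbind(seq_len(n), y_idx)] - 1
  list(loss = loss, dlogits = dl / n)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] - lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a network on a manifest
#'
#' Minimizes the cross-entropy over the `train` split with the configured
#' optimizer; the `val` split (when present) is evaluated after each
#' epoch. Fully seeded: weight initialization is fixed by the model, data
#' order and shuffles by `config$seed`, so two identical calls produce
#' identical models and histories.
#'
#' @param model a [build_network()] model.
#' @param manifest a `dataset_manifest` with split assignments.
#' @param config a [train_config()].
#' @param verbose print a line per epoch.
#' @return list with `model` (trained), `history` (data frame: epoch,
#'   train_loss, train_acc, val_loss, val_acc) and `norm_stats`.
#' @export
train_network <- function(model, manifest, config = train_config(), verbose = FALSE) {
  train_rec <- manifest$records[manifest$records$split == "train", , drop = FALSE]
  if (!nrow(train_rec)) stopf("empty training split")
  val_rec <- manifest$records[manifest$records$split == "val", , drop = FALSE]
  tr <- load_split_images(train_rec, config$image_size, config$standardize)
  val <- if (nrow(val_rec))
    load_split_images(val_rec, config$image_size, config$standardize, tr$stats)
  classes <- sort(unique(model_labels(model, manifest$records)))
  if (length(classes) != model$spec$num_classes)
    stopf("model expects %d classes; manifest has %d", model$spec$num_classes, length(classes))
  model$classes <- classes
  y_tr <- match(model_labels(model, train_rec), classes)
  y_val <- if (nrow(val_rec)) match(model_labels(model, val_rec), classes)
  mod <- model$modules
  params <- flatten_params(mod)
  state <- adam_init(params)
  n <- length(tr$images)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        f <- fm_from_images(tr$images[idx])
        fwd <- net_forward(mod, f, training = TRUE)
        mod <- fwd$mod
        lx <- softmax_xent(fwd$out$x, y_tr[idx])
        ep_loss <- ep_loss + lx$loss * length(idx)
        ep_correct <- ep_correct + sum(max.col(fwd$out$x, ties.method = "first") == y_tr[idx])
        bwd <- net_backward(mod, fwd$cache, lx$dlogits)
        grads <- flatten_grads(bwd$grads)
        if (config$optimizer == "adam") {
          st <- adam_step(params, grads, state, config$learning_rate)
          params <- st$params; state <- st$state
        } else {
          for (i in seq_along(params)) params[[i]] <- params[[i]] - config$learning_rate * grads[[i]]
        }
        mod <- assign_params(mod, params)$mod
      }
      row <- data.frame(epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(val)) {
        vl <- eval_pass(mod, val$images, y_val, config$batch_size)
        row$val_loss <- vl$loss; row$val_acc <- vl$acc
      }
      history <- rbind(history, row)
      if (verbose)
        message(sprintf("epoch %3d  train loss %.4f acc %.4f  val loss %s acc %s",
                        epoch, row$train_loss, row$train_acc,
                        ifelse(is.na(row$val_loss), "-", sprintf("%.4f", row$val_loss)),
                        ifelse(is.na(row$val_acc), "-", sprintf("%.4f", row$val_acc))))
    }
  })
  model$modules <- mod
  list(model = model, history = history, norm_stats = tr$stats)
}

eval_pass <- function(mod, images, y_idx, batch_size) {
  n <- length(images)
  loss <- 0; correct <- 0
  scores <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fwd <- net_forward(mod, fm_from_images(images[idx]), training = FALSE)
    if (!is.null(y_idx)) {
      loss <- loss + softmax_xent(fwd$out$x, y_idx[idx])$loss * length(idx)
      correct <- correct + sum(max.col(fwd$out$x, ties.method = "first") == y_idx[idx])
    }
    scores <- rbind(scores, fwd$out$x)
  }
  list(loss = loss / n, acc = correct / n, scores = scores)
}

#' Evaluate a trained network on a manifest split
#'
#' Deterministic forward passes (BN running statistics, fixed record
#' order) followed by a [metrics_report()]: binary metrics with positive
#' class `malignant` for two-class models, macro averaging otherwise. The
#' raw softmax score matrix is attached as `attr(report, "scores")`.
#'
#' @param model a trained `network_model` (with `classes` set; untrained
#'   models are evaluated against the sorted manifest labels).
#' @param manifest a `dataset_manifest`.
#' @param split which split to evaluate (`"test"` by default).
#' @param image_size input side length (defaults to the model spec's).
#' @param standardize,norm_stats optional standardization as in training.
#' @return a `metrics_report`.
#' @export
evaluate_network <- function(model, manifest, split = "test",
                             image_size = model$spec$input_size,
                             standardize = FALSE, norm_stats = NULL) {
  rec <- manifest$records[manifest$records$split == split, , drop = FALSE]
  if (!nrow(rec)) stopf("split '%s' is empty", split)
  classes <- model$classes %||% sort(unique(model_labels(model, rec)))
  y <- match(model_labels(model, rec), classes)
  if (anyNA(y)) stopf("labels in split not covered by model classes")
  imgs <- load_split_images(rec, image_size, standardize, norm_stats)
  ev <- eval_pass(model$modules, imgs$images, y, 32L)
  probs <- softmax(ev$scores)
  colnames(probs) <- classes
  report <- metrics_report(probs, classes[y])
  attr(report, "scores") <- probs
  report
}
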