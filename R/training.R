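# Dataset construction, label transforms, augmentation, MSE training with
# Adam, evaluation metrics, and the brute-force-invariance study comparing
# a plain MLP on flattened coordinates with the graph model.

#' Labeled dataset of configurations
#'
#' @param frames list of [configuration()] objects.
#' @param labels numeric vector, one label per frame (finite).
#' @param provenance character tags per frame (e.g. "base", "burst",
#'   "augmented"); recycled if length 1.
#' @return object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(frames, labels, provenance = "base") {
  if (length(frames) != length(labels))
    stop("frames and labels must have equal length")
  if (any(!is.finite(labels))) stop("labels must be finite")
  if (length(provenance) == 1) provenance <- rep(provenance, length(frames))
  structure(list(frames = frames, labels = as.numeric(labels),
                 provenance = provenance), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled dataset: %d frames (%s)\n", length(x$frames),
              paste(sprintf("%s: %d", names(table(x$provenance)),
                            table(x$provenance)), collapse = ", ")))
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$frames)

#' Cube-root label transform
#'
#' Models learn the cube root of n(Q6) rather than the raw count; the cube
#' root is interpretable as the radius of the crystalline domain and
#' compresses the label range around the transition region.
#'
#' @param y nonnegative numeric vector.
#' @return y^(1/3).
#' @export
cube_root_transform <- function(y) {
  if (any(y < 0)) stop("cube_root_transform requires nonnegative input")
  y^(1 / 3)
}

#' @rdname cube_root_transform
#' @param s transformed values to invert.
#' @export
cube_root_inverse <- function(s) s^3

#' Training hyperparameters
#'
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param epochs maximal number of epochs.
#' @param batch_size minibatch size.
#' @param split fraction of frames used for training, rest is hold-out
#'   validation (in (0,1), default 0.8).
#' @param n_aug_rot roto-translated copies added per frame in the loss.
#' @param n_aug_perm permuted copies added per frame in the loss.
#' @param seed RNG seed for the split, shuffling, and augmentation.
#' @param target_transform "identity" or "cube_root" (bookkeeping tag for
#'   reports; labels are supplied already transformed).
#' @param patience early-stopping patience in epochs on validation MSE.
#' @param clip global-norm gradient clip per minibatch (sum pooling over
#'   hundreds of nodes makes raw gradient norms large and noisy; clipping
#'   keeps the joint optimization of message maps and decoder stable).
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 100L, batch_size = 16L,
                         split = 0.8, n_aug_rot = 0L, n_aug_perm = 0L,
                         seed = 1L, target_transform = c("identity", "cube_root"),
                         patience = 20L, clip = 1.0) {
  if (split <= 0 || split >= 1) stop("split fraction must be in (0, 1)")
  if (learning_rate <= 0 || epochs < 1 || batch_size < 1) stop("invalid training parameters")
  if (n_aug_rot < 0 || n_aug_perm < 0) stop("augmentation counts must be >= 0")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), split = split,
                 n_aug_rot = as.integer(n_aug_rot),
                 n_aug_perm = as.integer(n_aug_perm), seed = as.integer(seed),
                 target_transform = match.arg(target_transform),
                 patience = as.integer(patience), clip = clip),
            class = "train_config")
}

# uniform random rotation matrix (via a uniform unit quaternion)
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# unwrap a cluster relative to its first particle so rigid motions can be
# applied without minimum-image breakage (valid for clusters smaller than
# half the box)
.unwrap_cluster <- function(config) {
  X <- config$positions
  L <- config$box$lengths
  ref <- X[1, ]
  d <- .min_image_mat(sweep(X, 2, ref), L)
  sweep(d, 2, ref, `+`)
}

#' Roto-translational data augmentation
#'
#' n copies of a configuration under uniformly random proper rotations
#' about the cluster centroid composed with uniform random translations,
#' re-wrapped into the box. Rigid motions preserve all pairwise
#' minimum-image distances for clusters smaller than half the box, so all
#' analytical CV labels carry over.
#'
#' @param config a [configuration()] (cluster re-centerable in its box).
#' @param n number of copies (>= 0).
#' @param seed RNG seed.
#' @return list of `n` configurations.
#' @export
augment_rotations <- function(config, n, seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(list())
  with_seed(seed, {
    Xu <- .unwrap_cluster(config)
    ctr <- colMeans(Xu)
    Xc <- sweep(Xu, 2, ctr)
    lapply(seq_len(n), function(i) {
      R <- .random_rotation()
      tr <- stats::runif(3, 0, config$box$lengths)
      configuration(sweep(Xc %*% t(R), 2, tr, `+`), config$box, config$id)
    })
  })
}

#' Permutational data augmentation
#'
#' n copies with particle rows shuffled by independent uniform
#' permutations; all analytical CV labels are invariant under this.
#'
#' @inheritParams augment_rotations
#' @return list of `n` configurations.
#' @export
augment_permutations <- function(config, n, seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(list())
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      pi <- sample.int(nrow(config$positions))
      configuration(config$positions[pi, , drop = FALSE], config$box, config$id)
    })
  })
}

# scalar prediction shared by both model families
.predict_scalar <- function(model, config) {
  if (inherits(model, "gnn_model")) {
    gnn_forward(model, config)[1]
  } else if (inherits(model, "mlp_cv")) {
    drop(mlp_forward(model$net, matrix(as.vector(t(config$positions)), 1)))
  } else stop("unsupported model type")
}

#' Augmented mean-squared-error loss of one frame
#'
#' Evaluates the model on the frame plus `n_aug_rot` freshly generated
#' roto-translated and `n_aug_perm` permuted copies, all sharing the
#' frame's label, and returns the mean squared error over the set (the
#' unaugmented frame is included with equal weight).
#'
#' @param model a `gnn_model` or `mlp_cv` baseline.
#' @param frame a [configuration()].
#' @param label the frame's (transformed) label.
#' @param n_aug_rot,n_aug_perm augmentation counts.
#' @param seed RNG seed for the generated copies.
#' @return mean squared error over the 1 + n_aug_rot + n_aug_perm copies.
#' @export
augmented_mse_loss <- function(model, frame, label, n_aug_rot = 0L,
                               n_aug_perm = 0L, seed = 1L) {
  copies <- c(list(frame),
              augment_rotations(frame, n_aug_rot, seed),
              augment_permutations(frame, n_aug_perm, seed + 1L))
  preds <- vapply(copies, function(cf) .predict_scalar(model, cf), 0)
  mean((preds - label)^2)
}

#' Plain-MLP baseline on flattened coordinates
#'
#' The "brute force" alternative to the graph model: a multilayer
#' perceptron mapping the flattened 3N coordinate vector directly to a
#' scalar CV estimate. It has no built-in invariances (permuting input
#' rows changes the output) and is used in the augmentation study.
#'
#' @param widths hidden layer widths (e.g. `c(512, 258, 128)`).
#' @param n_particles number of particles N (fixes the input size 3N).
#' @param seed RNG seed for initialization.
#' @return object of class `mlp_cv`.
#' @export
mlp_baseline <- function(widths, n_particles, seed = 1L) {
  if (any(widths < 1)) stop("widths must be positive")
  with_seed(seed, {
    net <- mlp_init(c(3L * n_particles, widths, 1L))
    structure(list(net = net, n_particles = as.integer(n_particles),
                   widths = widths), class = "mlp_cv")
  })
}

.split_dataset <- function(dataset, split, seed) {
  n <- length(dataset$frames)
  with_seed(seed, {
    idx <- sample.int(n)
    ntr <- max(1L, min(n - 1L, round(split * n)))
    list(train = idx[seq_len(ntr)], val = idx[-seq_len(ntr)])
  })
}

#' Train a CV model
#'
#' Gradient-based minimization of the (optionally augmented) mean squared
#' error with the Adam optimizer, an 80/20 train/hold-out split by
#' default, and early stopping on validation MSE. Returns the
#' best-validation parameters together with a training report.
#'
#' @param model a `gnn_model` or `mlp_cv`.
#' @param dataset a [labeled_dataset()] (labels already on the target
#'   scale, e.g. cube-root transformed).
#' @param tc a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best parameters) and `report` (class
#'   `train_report`: per-epoch train/validation MSE, seeds, epochs run).
#' @export
train_model <- function(model, dataset, tc, verbose = FALSE) {
  UseMethod("train_model")
}

.train_report <- function(train_mse, val_mse, tc, best_epoch) {
  structure(list(train_mse = train_mse, val_mse = val_mse,
                 seed = tc$seed, best_epoch = best_epoch,
                 target_transform = tc$target_transform),
            class = "train_report")
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("training report: %d epochs, best epoch %d (val MSE %.4g)\n",
              length(x$train_mse), x$best_epoch, x$val_mse[x$best_epoch]))
  invisible(x)
}

#' @export
train_model.gnn_model <- function(model, dataset, tc, verbose = FALSE) {
  if (length(dataset$frames) == 0) stop("dataset is empty")
  sp <- .split_dataset(dataset, tc$split, tc$seed)
  labels <- dataset$labels
  inputs <- lapply(dataset$frames, gnn_input, cutoff = model$config$cutoff)
  model <- fit_scalers(model, inputs[sp$train])
  theta <- get_parameters(model)
  opt <- adam_init(length(theta), lr = tc$learning_rate)
  best <- list(val = Inf, theta = theta, epoch = 0L)
  tr_hist <- numeric(0); va_hist <- numeric(0)
  stall <- 0L
  aug <- tc$n_aug_rot > 0 || tc$n_aug_perm > 0

  val_mse <- function(mod) {
    pr <- vapply(sp$val, function(i) .gnn_forward_cache(mod, inputs[[i]])$out[1], 0)
    mean((pr - labels[sp$val])^2)
  }

  for (ep in seq_len(tc$epochs)) {
    model <- set_parameters(model, theta)
    ep_losses <- c()
    with_seed(tc$seed + ep, {
      order_ix <- sample(sp$train)
      batches <- split(order_ix, ceiling(seq_along(order_ix) / tc$batch_size))
      for (bt in batches) {
        g <- numeric(length(theta)); loss <- 0; mtot <- 0L
        for (i in bt) {
          items <- list(inputs[[i]])
          if (aug) {
            aseed <- stats::runif(1, 1, 2^30)
            copies <- c(augment_rotations(dataset$frames[[i]], tc$n_aug_rot, aseed),
                        augment_permutations(dataset$frames[[i]], tc$n_aug_perm,
                                             aseed + 1))
            items <- c(items, lapply(copies, gnn_input,
                                     cutoff = model$config$cutoff))
          }
          for (it in items) {
            fwc <- .gnn_forward_cache(model, it)
            resid <- fwc$out[1] - labels[i]
            loss <- loss + resid^2
            bb <- .gnn_backward(model, it, fwc, 2 * resid, param_grad = TRUE)
            g <- g + bb$grad_flat
            mtot <- mtot + 1L
          }
        }
        g <- g / mtot
        gn <- sqrt(sum(g^2))
        if (is.finite(tc$clip) && gn > tc$clip) g <- g * (tc$clip / gn)
        st <- adam_step(opt, theta, g)
        theta <- st$theta; opt <- st$state
        model <- set_parameters(model, theta)
        ep_losses <- c(ep_losses, loss / mtot)
      }
    })
    if (any(!is.finite(ep_losses)))
      stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
    vm <- val_mse(model)
    tr_hist <- c(tr_hist, mean(ep_losses)); va_hist <- c(va_hist, vm)
    if (verbose) message(sprintf("epoch %3d  train %.5g  val %.5g", ep,
                                 mean(ep_losses), vm))
    if (vm < best$val - 1e-12) {
      best <- list(val = vm, theta = theta, epoch = ep); stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tc$patience) break
    }
  }
  model <- set_parameters(model, best$theta)
  list(model = model, report = .train_report(tr_hist, va_hist, tc, best$epoch),
       split = sp)
}

#' @export
train_model.mlp_cv <- function(model, dataset, tc, verbose = FALSE) {
  if (length(dataset$frames) == 0) stop("dataset is empty")
  sp <- .split_dataset(dataset, tc$split, tc$seed)
  labels <- dataset$labels
  flat <- t(vapply(dataset$frames,
                   function(cf) as.vector(t(cf$positions)),
                   numeric(3 * model$n_particles)))
  net <- model$net
  theta <- .flatten_params(list(net))
  opt <- adam_init(length(theta), lr = tc$learning_rate)
  best <- list(val = Inf, theta = theta, epoch = 0L)
  tr_hist <- numeric(0); va_hist <- numeric(0)
  stall <- 0L

  for (ep in seq_len(tc$epochs)) {
    ep_losses <- c()
    with_seed(tc$seed + ep, {
      order_ix <- sample(sp$train)
      batches <- split(order_ix, ceiling(seq_along(order_ix) / tc$batch_size))
      for (bt in batches) {
        rows <- list(); ys <- c()
        for (i in bt) {
          rows <- c(rows, list(flat[i, ]))
          ys <- c(ys, labels[i])
          if (tc$n_aug_rot > 0 || tc$n_aug_perm > 0) {
            aseed <- stats::runif(1, 1, 2^30)
            copies <- c(augment_rotations(dataset$frames[[i]], tc$n_aug_rot, aseed),
                        augment_permutations(dataset$frames[[i]], tc$n_aug_perm,
                                             aseed + 1))
            rows <- c(rows, lapply(copies, function(cf) as.vector(t(cf$positions))))
            ys <- c(ys, rep(labels[i], length(copies)))
          }
        }
        Xb <- do.call(rbind, rows)
        fw <- mlp_forward(net, Xb, cache = TRUE)
        resid <- drop(fw$out) - ys
        loss <- mean(resid^2)
        bw <- mlp_backward(net, fw, matrix(2 * resid / length(resid), ncol = 1))
        g <- .flatten_params(list(list(layers = bw$grads)))
        gn <- sqrt(sum(g^2))
        if (is.finite(tc$clip) && gn > tc$clip) g <- g * (tc$clip / gn)
        st <- adam_step(opt, theta, g)
        theta <- st$theta; opt <- st$state
        net <- .unflatten_params(list(net), theta)[[1]]
        ep_losses <- c(ep_losses, loss)
      }
    })
    if (any(!is.finite(ep_losses)))
      stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
    pr <- drop(mlp_forward(net, flat[sp$val, , drop = FALSE]))
    vm <- mean((pr - labels[sp$val])^2)
    tr_hist <- c(tr_hist, mean(ep_losses)); va_hist <- c(va_hist, vm)
    if (verbose) message(sprintf("epoch %3d  train %.5g  val %.5g", ep,
                                 mean(ep_losses), vm))
    if (vm < best$val - 1e-12) {
      best <- list(val = vm, theta = theta, epoch = ep); stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tc$patience) break
    }
  }
  model$net <- .unflatten_params(list(model$net), best$theta)[[1]]
  list(model = model, report = .train_report(tr_hist, va_hist, tc, best$epoch),
       split = sp)
}

#' Evaluate a model on a labeled dataset
#'
#' @param model a `gnn_model` or `mlp_cv`.
#' @param dataset a [labeled_dataset()].
#' @param threshold_for_crystal frames predicted above this value whose
#'   label is at or below it count as crystalline misclassifications
#'   (default 0.5, the cube-root scale convention).
#' @return list with `mse`, `pearson_r` (NA plus `pearson_error` flag when
#'   predictions are constant), `misclassified`, `predictions`.
#' @export
evaluate_model <- function(model, dataset, threshold_for_crystal = 0.5) {
  preds <- vapply(dataset$frames, function(cf) .predict_scalar(model, cf), 0)
  labels <- dataset$labels
  mse <- mean((preds - labels)^2)
  const <- stats::sd(preds) == 0 || stats::sd(labels) == 0
  r <- if (const) NA_real_ else stats::cor(preds, labels)
  mis <- sum(preds > threshold_for_crystal & labels <= threshold_for_crystal)
  list(mse = mse, pearson_r = r, pearson_error = const,
       misclassified = as.integer(mis), predictions = preds)
}

#' Brute-force invariance study
#'
#' Trains a plain-MLP baseline with an increasing number of augmented
#' copies per training step, in rotation or permutation mode, and
#' measures for each count the training MSE, hold-out MSE, and the MSE on
#' a large set of freshly augmented frames. With rotations the
#' test-on-augmented error converges in trend toward the hold-out error;
#' with permutations it does not, and the hold-out error grows as each
#' training step is diluted.
#'
#' @param dataset a [labeled_dataset()].
#' @param n_aug_values integer vector of augmentation counts (e.g.
#'   `c(0, 2, 8, 32)`).
#' @param mode "rotation" or "permutation".
#' @param seed RNG seed.
#' @param widths baseline hidden widths.
#' @param tc_template [train_config()] carried hyperparameters (its
#'   augmentation counts are overridden per run).
#' @param n_test_aug augmented copies per frame in the test set.
#' @return data.frame with columns n_aug, train_mse, holdout_mse, aug_mse.
#' @export
augmentation_study <- function(dataset, n_aug_values = c(0L, 2L, 8L, 32L),
                               mode = c("rotation", "permutation"),
                               seed = 1L, widths = c(64L, 32L, 16L),
                               tc_template = train_config(epochs = 60L,
                                                          patience = 60L,
                                                          seed = 1L),
                               n_test_aug = 4L) {
  mode <- match.arg(mode)
  np <- nrow(dataset$frames[[1]]$positions)
  # fixed augmented test set: fresh copies of every frame
  test_frames <- list(); test_labels <- c()
  for (i in seq_along(dataset$frames)) {
    cps <- if (mode == "rotation")
      augment_rotations(dataset$frames[[i]], n_test_aug, seed + 7919L + i)
    else augment_permutations(dataset$frames[[i]], n_test_aug, seed + 7919L + i)
    test_frames <- c(test_frames, cps)
    test_labels <- c(test_labels, rep(dataset$labels[i], length(cps)))
  }
  test_set <- labeled_dataset(test_frames, test_labels, "augmented")

  out <- lapply(n_aug_values, function(na) {
    tc <- tc_template
    tc$seed <- as.integer(seed)
    tc$n_aug_rot <- if (mode == "rotation") as.integer(na) else 0L
    tc$n_aug_perm <- if (mode == "permutation") as.integer(na) else 0L
    mod <- mlp_baseline(widths, np, seed = seed)
    fit <- train_model(mod, dataset, tc)
    tr_idx <- fit$split$train; va_idx <- fit$split$val
    tr_set <- labeled_dataset(dataset$frames[tr_idx], dataset$labels[tr_idx])
    va_set <- labeled_dataset(dataset$frames[va_idx], dataset$labels[va_idx])
    data.frame(n_aug = na,
               train_mse = evaluate_model(fit$model, tr_set)$mse,
               holdout_mse = evaluate_model(fit$model, va_set)$mse,
               aug_mse = evaluate_model(fit$model, test_set)$mse)
  })
  do.call(rbind, out)
}

#' Cumulative correlation trace of a model against its references
#'
#' For each step index t, the Pearson correlation over all frames up to t
#' between the model prediction series and the droplet-size (n) and
#' crystalline-count (n(Q6)) reference series; used to diagnose when a
#' model tracks density rather than order.
#'
#' @param model_series,n_series,nq6_series aligned numeric series.
#' @return data.frame with columns step, r_model_n, r_model_nq6 (NA where
#'   a series is still constant).
#' @export
correlation_trace <- function(model_series, n_series, nq6_series) {
  T <- length(model_series)
  if (T < 3 || length(n_series) != T || length(nq6_series) != T)
    stop("need at least 3 aligned points")
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }
  steps <- 2:T
  data.frame(
    step = steps,
    r_model_n = vapply(steps, function(t)
      safe_cor(model_series[1:t], n_series[1:t]), 0),
    r_model_nq6 = vapply(steps, function(t)
      safe_cor(model_series[1:t], nq6_series[1:t]), 0))
}
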