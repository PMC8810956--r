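#' Architecture of the 3D patch classifier
#'
#' The binary LTP classifier: three same-padded 3x3x3 convolution stages
#' (16, 32 and 64 feature maps), 2x2x2 max pooling after the first two
#' stages, then fully connected layers of 512 and 128 rectified-linear
#' units and a single sigmoid output. With the standard 32x32x8 input the
#' stage outputs are 16@8x32x32, 32@4x16x16 and 64@2x8x8, giving an
#' 8,192-unit flattened vector before the first fully connected layer.
#'
#' @param input_shape Integer triple `(x, y, depth)` of the patch grid.
#' @param channels Number of input channels.
#' @param conv_feature_maps Feature maps per convolution stage.
#' @param fc_units Sizes of the two fully connected layers.
#' @param pool_after Logical per conv stage: is a 2x2x2 max pool applied
#'   after it? The printed stage sizes force pooling after stages 1 and 2
#'   only.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_shape = c(32L, 32L, 8L), channels = 3L,
                         conv_feature_maps = c(16L, 32L, 64L),
                         fc_units = c(512L, 128L),
                         pool_after = c(TRUE, TRUE, FALSE)) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 2L)) {
    stop("input_shape must be three sizes >= 2")
  }
  if (length(conv_feature_maps) != length(pool_after)) {
    stop("pool_after must have one entry per convolution stage")
  }
  structure(
    list(input_shape = input_shape, channels = as.integer(channels),
         conv_kernel = c(3L, 3L, 3L), pool_kernel = c(2L, 2L, 2L),
         conv_feature_maps = as.integer(conv_feature_maps),
         fc_units = as.integer(fc_units),
         pool_after = as.logical(pool_after), activation = "relu",
         output = "sigmoid"),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  st <- infer_stage_shapes(x)
  cat("<network_spec> 3D CNN\n")
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  conv%d: %d feature maps @ %dx%dx%d%s\n", i,
                st$feature_maps[i], st$depth[i], st$height[i], st$width[i],
                if (x$pool_after[i]) "  + 2x2x2 max pool" else ""))
  }
  cat(sprintf("  flatten: %d -> fc %s -> sigmoid\n",
              attr(st, "flatten_units"),
              paste(x$fc_units, collapse = " -> ")))
  invisible(x)
}

#' Analytic shape propagation through the network
#'
#' Same-padded convolutions preserve the spatial grid; each pooling stage
#' halves all three spatial axes. Stages whose input has an odd spatial
#' size at a pooling step are rejected.
#'
#' @param spec A [network_spec()].
#' @return Data frame with one row per convolution stage and columns
#'   `stage`, `feature_maps`, `depth`, `height`, `width` (sizes of that
#'   stage's output, depth = axial). Attributes `flatten_units` and
#'   `fc_units` give the classifier-head sizes.
#' @export
infer_stage_shapes <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  size <- spec$input_shape  # (x, y, z)
  out <- data.frame(stage = integer(0), feature_maps = integer(0),
                    depth = integer(0), height = integer(0), width = integer(0))
  for (i in seq_along(spec$conv_feature_maps)) {
    out <- rbind(out, data.frame(stage = i,
                                 feature_maps = spec$conv_feature_maps[i],
                                 depth = size[3], height = size[2],
                                 width = size[1]))
    if (spec$pool_after[i]) {
      if (any(size %% 2L != 0L)) {
        stop("pooling stage ", i, " sees a non-divisible spatial size (",
             paste(size, collapse = "x"), ")")
      }
      size <- size %/% 2L
    }
  }
  attr(out, "flatten_units") <- prod(size) * utils::tail(spec$conv_feature_maps, 1)
  attr(out, "fc_units") <- spec$fc_units
  out
}

#' Training configuration for the 3D CNN
#'
#' Binary cross-entropy against the sigmoid output, Adam optimiser,
#' early stopping on validation loss. Every field is logged with the run.
#'
#' @param learning_rate Initial Adam step size.
#' @param lr_decay Multiplicative learning-rate decay per epoch.
#' @param batch_size Minibatch size.
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without improvement of
#'   the monitored validation quantity); the best state is returned.
#' @param monitor `"val_auc"` (default) or `"val_loss"` — the quantity
#'   early stopping watches on the validation split.
#' @param weight_decay L2 penalty coefficient (decoupled, AdamW-style).
#' @param seed Integer seed for weight initialisation and shuffling.
#' @param verbose Print per-epoch losses.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, lr_decay = 0.92,
                         batch_size = 32L, epochs = 40L, patience = 8L,
                         monitor = c("val_auc", "val_loss"),
                         weight_decay = 1e-4, seed = 1L,
                         verbose = FALSE) {
  monitor <- match.arg(monitor)
  structure(list(loss = "binary_crossentropy", optimizer = "adam",
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 monitor = monitor, weight_decay = weight_decay,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# He-style initialisation; scale = 0 gives an all-zero network
init_cnn_params <- function(spec, seed = 1L, scale = 1) {
  st <- infer_stage_shapes(spec)
  flat <- attr(st, "flatten_units")
  withr::with_seed(seed, {
    p <- list()
    cin <- spec$channels
    for (i in seq_along(spec$conv_feature_maps)) {
      cout <- spec$conv_feature_maps[i]
      fan_in <- cin * 27L
      p[[paste0("Wc", i)]] <- matrix(stats::rnorm(cout * fan_in) *
                                       scale * sqrt(2 / fan_in), cout, fan_in)
      p[[paste0("bc", i)]] <- numeric(cout)
      cin <- cout
    }
    sizes <- c(flat, spec$fc_units, 1L)
    for (i in seq_len(length(sizes) - 1L)) {
      fan_in <- sizes[i]
      sd <- if (i == length(sizes) - 1L) sqrt(1 / fan_in) else sqrt(2 / fan_in)
      p[[paste0("Wf", i)]] <- matrix(stats::rnorm(sizes[i + 1] * fan_in) *
                                       scale * sd, sizes[i + 1], fan_in)
      p[[paste0("bf", i)]] <- numeric(sizes[i + 1])
    }
    p
  })
}

# stage dims (x, y, z, channels) of every conv input
.conv_dims <- function(spec) {
  dims <- list()
  size <- spec$input_shape
  cin <- spec$channels
  for (i in seq_along(spec$conv_feature_maps)) {
    dims[[i]] <- as.integer(c(size, cin))
    cin <- spec$conv_feature_maps[i]
    if (spec$pool_after[i]) size <- size %/% 2L
  }
  dims
}

# forward pass; X is (flattened input) x B with values already in [0, 1]
cnn_forward <- function(params, X, spec, keep_cache = FALSE) {
  dims <- .conv_dims(spec)
  cache <- list(a = list(), pre = list(), pool = list())
  a <- X
  for (i in seq_along(spec$conv_feature_maps)) {
    z <- conv3d_fwd(a, dims[[i]], params[[paste0("Wc", i)]],
                    params[[paste0("bc", i)]])
    r <- z * (z > 0)
    if (keep_cache) {
      cache$a[[i]] <- a
      cache$pre[[i]] <- z
    }
    if (spec$pool_after[i]) {
      pdims <- as.integer(c(dims[[i]][1:3], spec$conv_feature_maps[i]))
      pl <- maxpool3d_fwd(r, pdims)
      if (keep_cache) cache$pool[[i]] <- pl$argmax
      a <- pl$out
    } else {
      a <- r
    }
  }
  stage_out <- a  # flattened 64@2x8x8
  f1 <- params$Wf1 %*% a + params$bf1
  a1 <- f1 * (f1 > 0)
  f2 <- params$Wf2 %*% a1 + params$bf2
  a2 <- f2 * (f2 > 0)
  logits <- drop(params$Wf3 %*% a2 + params$bf3)
  probs <- stats::plogis(logits)
  out <- list(probs = probs, logits = logits)
  if (keep_cache) {
    out$cache <- c(cache, list(flat = stage_out, f1 = f1, a1 = a1,
                               f2 = f2, a2 = a2, X = X))
  }
  out
}

# backward pass; returns gradients for every parameter
cnn_backward <- function(params, spec, fwd, y) {
  cache <- fwd$cache
  B <- length(y)
  dlog <- matrix((fwd$probs - y) / B, nrow = 1)
  g <- list()
  g$Wf3 <- dlog %*% t(cache$a2)
  g$bf3 <- sum(dlog)
  da2 <- t(params$Wf3) %*% dlog
  df2 <- da2 * (cache$f2 > 0)
  g$Wf2 <- df2 %*% t(cache$a1)
  g$bf2 <- rowSums(df2)
  da1 <- t(params$Wf2) %*% df2
  df1 <- da1 * (cache$f1 > 0)
  g$Wf1 <- df1 %*% t(cache$flat)
  g$bf1 <- rowSums(df1)
  da <- t(params$Wf1) %*% df1

  dims <- .conv_dims(spec)
  for (i in rev(seq_along(spec$conv_feature_maps))) {
    if (spec$pool_after[i]) {
      n_in <- prod(dims[[i]][1:3]) * spec$conv_feature_maps[i]
      da <- maxpool3d_bwd(da, cache$pool[[i]], n_in)
    }
    dz <- da * (cache$pre[[i]] > 0)
    bw <- conv3d_bwd(cache$a[[i]], dims[[i]], params[[paste0("Wc", i)]], dz,
                     need_dx = (i > 1L))  # the input gradient is never used
    g[[paste0("Wc", i)]] <- bw$dW
    g[[paste0("bc", i)]] <- drop(bw$db)
    da <- bw$dX
  }
  g
}

.bce_loss <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

# convert a patch set (or raw-array list) into the model input matrix
patches_to_matrix <- function(patches, spec = network_spec()) {
  n_in <- prod(spec$input_shape) * spec$channels
  X <- matrix(0, n_in, length(patches))
  for (i in seq_along(patches)) {
    d <- patches[[i]]$data
    if (length(d) != n_in) {
      stop("patch '", patches[[i]]$id %||% i, "' has ", length(d),
           " values; the network expects ", n_in,
           " (32x32x8 voxels x 3 channels)")
    }
    X[, i] <- as.integer(d) / 255
  }
  X
}

patch_labels <- function(patches) {
  as.numeric(vapply(patches, `[[`, "", "label") == "positive")
}

new_trained_model <- function(spec, params, log = NULL, config = NULL) {
  structure(list(spec = spec, params = params, training_log = log,
                 config = config),
            class = "trained_model")
}

#' Create an untrained model (for testing and warm starts)
#'
#' @param spec A [network_spec()].
#' @param seed Seed for the random initialisation.
#' @param init `"he"` for scaled random weights, `"zero"` for an all-zero
#'   network (whose sigmoid output is exactly 0.5 everywhere).
#' @return A `trained_model` with no training log.
#' @export
init_model <- function(spec = network_spec(), seed = 1L,
                       init = c("he", "zero")) {
  init <- match.arg(init)
  new_trained_model(spec, init_cnn_params(spec, seed,
                                          scale = if (init == "zero") 0 else 1))
}

#' Train the 3D CNN patch classifier
#'
#' Minibatch Adam on binary cross-entropy. Validation loss is evaluated
#' after every epoch; the returned model carries the parameter state with
#' the best validation loss (early stopping with `config$patience`).
#' Training and validation patches must come from disjoint cases — the
#' split is at patient level.
#'
#' When `augment_fn` is supplied (as the phantom pipeline does with
#' [augment_patch()]), the positive training patches are re-augmented with
#' fresh random transforms at the start of every epoch, so the network
#' never sees the same positive twice — the usual way random augmentation
#' is applied during training.
#'
#' @param train_patches,val_patches `patch_set`s (or lists of patches).
#' @param spec A [network_spec()].
#' @param config A [train_config()].
#' @param augment_fn Optional `function(patch)` applied to every positive
#'   training patch at each epoch start (online augmentation).
#' @return A `trained_model` with fields `spec`, `params`, `training_log`
#'   (data frame of per-epoch train/validation losses) and `config`.
#' @export
train_cnn <- function(train_patches, val_patches, spec = network_spec(),
                      config = train_config(), augment_fn = NULL) {
  if (length(val_patches) == 0L) stop("validation set is empty")
  y <- patch_labels(train_patches)
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; both classes are required")
  }
  overlap <- intersect(unique(vapply(train_patches, `[[`, "", "case_id")),
                       unique(vapply(val_patches, `[[`, "", "case_id")))
  if (length(overlap)) {
    stop("cases appear in both training and validation splits: ",
         paste(overlap, collapse = ", "))
  }
  X <- patches_to_matrix(train_patches, spec)
  Xv <- patches_to_matrix(val_patches, spec)
  yv <- patch_labels(val_patches)
  n <- ncol(X)
  pos_ids <- which(y == 1)

  withr::with_seed(config$seed, {
    params <- init_cnn_params(spec, seed = sample.int(.Machine$integer.max, 1))
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate
    wd <- config$weight_decay
    weight_keys <- grep("^W", names(params), value = TRUE)
    t <- 0L
    # monitored score: larger is better
    score_of <- function(vl, vauc) {
      if (config$monitor == "val_auc") vauc else -vl
    }
    best <- list(score = -Inf, params = params, epoch = 0L)
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0), val_auc = numeric(0))
    wait <- 0L
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate * (config$lr_decay %||% 1)^(epoch - 1)
      if (!is.null(augment_fn) && length(pos_ids)) {
        for (i in pos_ids) {
          X[, i] <- as.integer(augment_fn(train_patches[[i]])$data) / 255
        }
      }
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1L, n)]
        fwd <- cnn_forward(params, X[, ids, drop = FALSE], spec,
                           keep_cache = TRUE)
        ep_loss <- ep_loss + .bce_loss(fwd$logits, y[ids])
        nb <- nb + 1L
        g <- cnn_backward(params, spec, fwd, y[ids])
        t <- t + 1L
        for (k in names(params)) {
          m[[k]] <- b1 * m[[k]] + (1 - b1) * g[[k]]
          v[[k]] <- b2 * v[[k]] + (1 - b2) * g[[k]]^2
          mh <- m[[k]] / (1 - b1^t)
          vh <- v[[k]] / (1 - b2^t)
          params[[k]] <- params[[k]] - lr * mh / (sqrt(vh) + eps)
        }
        if (wd > 0) {
          for (k in weight_keys) params[[k]] <- params[[k]] * (1 - lr * wd)
        }
      }
      val_fwd <- cnn_forward(params, Xv, spec)
      vl <- .bce_loss(val_fwd$logits, yv)
      vauc <- if (length(unique(yv)) > 1L) {
        roc_auc(val_fwd$probs, yv)
      } else {
        NA_real_
      }
      log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                   val_loss = vl, val_auc = vauc))
      if (config$verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  val AUC %s", epoch,
                        ep_loss / nb, vl,
                        if (is.na(vauc)) "-" else sprintf("%.4f", vauc)))
      }
      sc <- score_of(vl, vauc)
      if (is.na(sc)) sc <- -vl  # single-class validation: fall back to loss
      if (sc > best$score + 1e-6) {
        best <- list(score = sc, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    new_trained_model(spec, best$params, log, config)
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> 3D CNN")
  if (!is.null(x$training_log) && nrow(x$training_log)) {
    cat(sprintf(": %d epochs, best val loss %.4f", nrow(x$training_log),
                min(x$training_log$val_loss)))
  }
  cat("\n")
  invisible(x)
}

#' Classification probabilities for a set of patches
#'
#' @param model A `trained_model`.
#' @param patches A `patch_set`, a list of patches, or a numeric matrix
#'   with one flattened patch per column (values in `[0, 1]`).
#' @param batch_size Forward-pass batch size.
#' @return Numeric vector of probabilities in `[0, 1]`, named by patch id
#'   when ids are available.
#' @export
predict_proba <- function(model, patches, batch_size = 64L) {
  stopifnot(inherits(model, "trained_model"))
  if (is.matrix(patches)) {
    X <- patches
    ids <- colnames(patches)
    n_in <- prod(model$spec$input_shape) * model$spec$channels
    if (nrow(X) != n_in) {
      stop("input matrix has ", nrow(X), " rows; the network expects ", n_in)
    }
  } else {
    X <- patches_to_matrix(patches, model$spec)
    ids <- vapply(patches, function(p) p$id %||% NA_character_, "")
  }
  n <- ncol(X)
  probs <- numeric(n)
  if (n == 0L) return(probs)
  for (start in seq(1L, n, by = batch_size)) {
    ids_b <- start:min(start + batch_size - 1L, n)
    probs[ids_b] <- cnn_forward(model$params, X[, ids_b, drop = FALSE],
                                model$spec)$probs
  }
  if (!is.null(ids) && !anyNA(ids)) names(probs) <- ids
  probs
}

#' Stage-by-stage output shapes of an actual forward pass
#'
#' Runs a real forward pass and records the tensor shape after every
#' convolution stage — the empirical counterpart of
#' [infer_stage_shapes()].
#'
#' @param model A `trained_model` (or [init_model()] result).
#' @param n Batch size of the probe input (zeros).
#' @return Data frame like [infer_stage_shapes()]'s.
#' @export
forward_stage_shapes <- function(model, n = 2L) {
  spec <- model$spec
  dims <- .conv_dims(spec)
  X <- matrix(0, prod(spec$input_shape) * spec$channels, n)
  a <- X
  out <- data.frame(stage = integer(0), feature_maps = integer(0),
                    depth = integer(0), height = integer(0), width = integer(0))
  for (i in seq_along(spec$conv_feature_maps)) {
    z <- conv3d_fwd(a, dims[[i]], model$params[[paste0("Wc", i)]],
                    model$params[[paste0("bc", i)]])
    cmaps <- spec$conv_feature_maps[i]
    sp <- dims[[i]][1:3]
    stopifnot(nrow(z) == prod(sp) * cmaps)  # shape realised by the tensor
    out <- rbind(out, data.frame(stage = i, feature_maps = cmaps,
                                 depth = sp[3], height = sp[2], width = sp[1]))
    r <- z * (z > 0)
    if (spec$pool_after[i]) {
      a <- maxpool3d_fwd(r, as.integer(c(sp, cmaps)))$out
    } else {
      a <- r
    }
  }
  attr(out, "flatten_units") <- nrow(a)
  out
}

#' Save / load a trained model (spec + config + weights in one archive)
#'
#' @param model A `trained_model`.
#' @param path Output `.rds` path.
#' @return `path` / the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  structure(m, class = "trained_model")
}
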