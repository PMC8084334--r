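#' Joint multi-species distribution models
#'
#' All models predict, for a location where a plant was observed, a
#' categorical probability distribution over the m species: the probability
#' that the observed specimen belongs to species s, conditional on an
#' observation. The convolutional model reads the full environmental tensor
#' and can exploit landscape spatial structure; the punctual deep network
#' uses the same architecture but receives the constant-tensor encoding of
#' the punctual vector, so differences in performance isolate the value of
#' the landscape.
#'
#' @name models
NULL

#' Define a convolutional species distribution model
#'
#' The backbone is a configuration choice. The default `"small"` backbone is
#' 3 conv/pool blocks with global average pooling and a dense feature layer
#' (feature_dim 256) — trainable on a CPU at desk scale. The
#' `"inception_v3_compat"` preset reproduces the input/output contract of
#' the large reference backbone (64 x 64 patches, feature_dim 2048); it is a
#' configuration option, not exercised by the test suite, and is not the
#' genuine Inception graph.
#'
#' @param patch_size pixels per patch side (must be divisible by
#'   `2^length(channels)`).
#' @param channels convolution widths of the successive blocks.
#' @param feature_dim size of the feature vector `z` (`NULL` = width of the
#'   last block, via global average pooling alone).
#' @param dropout dropout rate applied to `z` before the species head.
#' @param backbone `"small"` or `"inception_v3_compat"` (overrides
#'   `channels`/`feature_dim`).
#' @param readout `"gap_center"` (global average pooling concatenated with
#'   the centre 2x2 cells of the last feature map — the default for the
#'   small backbone, since the patch is centred on the occurrence) or
#'   plain `"gap"`.
#' @return An unfitted model object of class `sdm_model`.
#' @export
cnn_sdm <- function(patch_size = 64L, channels = c(64, 128, 256),
                    feature_dim = 256, dropout = 0.7, backbone = "small",
                    readout = "gap") {
  backbone <- match.arg(backbone, c("small", "inception_v3_compat"))
  readout <- match.arg(readout, c("gap_center", "gap"))
  if (backbone == "inception_v3_compat") {
    patch_size <- 64L
    channels <- c(64, 128, 256, 512, 1024)
    feature_dim <- 2048
    readout <- "gap"
  }
  if (patch_size %% 2^length(channels) != 0)
    stop("patch_size must be divisible by 2^", length(channels))
  structure(list(type = "cnn", backbone = backbone,
                 patch_size = as.integer(patch_size), channels = channels,
                 feature_dim = feature_dim, dropout = dropout,
                 readout = readout, fitted = FALSE),
            class = "sdm_model")
}

#' Define the punctual deep model (constant-tensor encoding)
#'
#' Identical architecture to [cnn_sdm()]; every input layer is the
#' occurrence-point value repeated over all pixels, so the model is blind to
#' the landscape by construction. Default dropout 0.5.
#'
#' @inheritParams cnn_sdm
#' @export
dnn_sdm <- function(patch_size = 64L, channels = c(64, 128, 256),
                    feature_dim = 256, dropout = 0.5, backbone = "small",
                    readout = "gap") {
  m <- cnn_sdm(patch_size, channels, feature_dim, dropout, backbone, readout)
  m$type <- "dnn"
  m
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model> %s (%s), patch %d, channels %s, feature_dim %s%s\n",
              toupper(x$type), x$backbone, x$patch_size,
              paste(x$channels, collapse = "/"),
              x$feature_dim %||% tail(x$channels, 1),
              if (x$fitted) sprintf(", fitted (%d species)", length(x$species))
              else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Channel normalization statistics from the training tensors. The
# structure-only ablation is exempt: its layers are already standardized
# per tensor.
channel_norm <- function(Tarr, exempt) {
  C <- dim(Tarr)[1]
  if (exempt) return(list(mu = numeric(C), sd = rep(1, C), exempt = TRUE))
  m <- matrix(Tarr, C)
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans(m^2) - mu^2)
  sdv[sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv, exempt = FALSE)
}

apply_norm <- function(xb, norm) (xb - norm$mu) / norm$sd  # recycles on dim 1

# Transform + normalize a channel-first batch (C, H, W, B). Vectorized over
# the batch: rotation draws one per-occurrence direction (keyed by epoch and
# occurrence index) and transforms the four direction groups in single array
# operations; permutation redraws independent per-layer pixel permutations
# from a per-(epoch, batch) key; mean/standardize are deterministic
# closed-form batch operations.
prep_batch <- function(xb, kind, seed, epoch, indices, norm) {
  split_moments(prep_raw_batch(xb, kind, seed, epoch, indices, norm))
}

# The network's input encoding: each (already transformed and
# channel-normalized) tensor layer is standardized over its own patch, and
# the deleted patch moments (per-layer mean and sd) are re-injected as a
# side vector appended to the feature vector. Information per ablation is
# exactly preserved — the mean model keeps its layer means, the permutation
# model its value moments, the structure-only model its arrangement — while
# every model trains on equally conditioned inputs.
split_moments <- function(xb) {
  d <- dim(xb)
  C <- d[1]; hw <- d[2] * d[3]; B <- d[4]
  M <- aperm(array(xb, c(C, hw, B)), c(2, 1, 3))
  dim(M) <- c(hw, C * B)
  mu <- colMeans(M)
  sdv <- sqrt(pmax(colMeans(M^2) - mu^2, 0))
  scl <- ifelse(sdv < 1e-12, Inf, sdv)  # constant slice -> zeros
  M <- sweep(sweep(M, 2, mu), 2, scl, "/")
  dim(M) <- c(hw, C, B)
  x <- aperm(M, c(2, 1, 3))
  dim(x) <- d
  list(x = x, mom = rbind(matrix(mu, C, B), matrix(sdv, C, B)))
}

prep_raw_batch <- function(xb, kind, seed, epoch, indices, norm) {
  d <- dim(xb)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  hw <- H * W
  if (kind == "mean" || kind == "standardize") {
    M <- aperm(array(xb, c(C, hw, B)), c(2, 1, 3))  # (hw, C, B)
    dim(M) <- c(hw, C * B)
    mu <- colMeans(M)
    if (kind == "mean") {
      M[] <- rep(mu, each = hw)
    } else {
      sdv <- sqrt(colMeans(M^2) - mu^2)
      sdv[sdv < 1e-12] <- Inf  # constant layer -> zeros
      M <- sweep(sweep(M, 2, mu), 2, sdv, "/")
    }
    dim(M) <- c(hw, C, B)
    xb <- aperm(M, c(2, 1, 3))
    dim(xb) <- d
  } else if (kind == "rotation") {
    if (H != W) stop("rotation requires a square patch")
    qs <- vapply(indices, function(i)
      with_seed(ablation_key(seed, epoch, i), sample.int(4L, 1L) - 1L), 0L)
    for (q in 1:3) {
      grp <- which(qs == q)
      if (length(grp) == 0) next
      sub <- xb[, , , grp, drop = FALSE]
      for (r in seq_len(q))  # 90 deg ccw: swap spatial dims, reverse rows
        sub <- aperm(sub, c(1, 3, 2, 4))[, W:1, , , drop = FALSE]
      xb[, , , grp] <- sub
    }
  } else if (kind == "permutation") {
    key <- ablation_key(seed, epoch, indices[1])
    M <- aperm(xb, c(2, 3, 1, 4))
    dim(M) <- c(hw, C * B)
    ord <- with_seed(key, order(rep(seq_len(C * B), each = hw),
                                stats::runif(hw * C * B)))
    M <- matrix(as.numeric(M)[ord], hw, C * B)
    dim(M) <- c(H, W, C, B)
    xb <- aperm(M, c(3, 1, 2, 4))
  }
  apply_norm(xb, norm)
}

#' Train a species distribution model
#'
#' Stochastic gradient descent with momentum and dropout on the
#' cross-entropy loss. The configured ablation transform is re-applied to
#' every tensor at every access, during training and validation alike.
#' Validation runs every `validation_period` epochs and the returned
#' checkpoint is the one with the highest validation mean per-species top-k
#' accuracy. The label space is fixed to all species present in the full
#' occurrence set.
#'
#' @param model an unfitted [cnn_sdm()] or [dnn_sdm()].
#' @param occurrences an occurrence set with a `partition` column holding
#'   non-empty `train` and `validation` classes.
#' @param stack an expanded, filled [raster_stack].
#' @param config a [train_config()].
#' @param transform an [ablation_spec()] (default: identity).
#' @param verbose print per-epoch progress.
#' @param xcache optional environment memoizing tensor extraction across
#'   models trained on the same data (used by [run_experiment()]).
#' @return The fitted model, with `$history` (epoch, lr, train loss,
#'   validation score) and `$params` at the best validation checkpoint.
#' @export
train_sdm <- function(model, occurrences, stack, config = train_config(),
                      transform = ablation_spec("none"), verbose = FALSE,
                      xcache = NULL) {
  stopifnot(inherits(model, "sdm_model"), inherits(config, "train_config"))
  species <- sort(unique(occurrences$species_id))
  m <- length(species)
  itr <- which(occurrences$partition == "train")
  iva <- which(occurrences$partition == "validation")
  if (length(itr) == 0 || length(iva) == 0)
    stop("training and validation partitions must be non-empty")
  if (!all(occurrences$species_id[iva] %in% species))
    stop("validation species outside the label space")
  dropout <- config$dropout %||% model$dropout
  mode <- if (model$type == "dnn") "punctual" else "tensor"
  Xtr <- cached_extract(occurrences[itr, ], stack, model$patch_size, mode,
                        xcache, "train")
  Xva <- cached_extract(occurrences[iva, ], stack, model$patch_size, mode,
                        xcache, "validation")
  ytr <- match(occurrences$species_id[itr], species)
  yva <- match(occurrences$species_id[iva], species)
  norm <- channel_norm(Xtr, exempt = transform$kind == "standardize")
  C <- dim(Xtr)[1]
  params <- nn_init(model$channels, model$feature_dim, C, m,
                    seed = config$seed * 31 + 7, readout = model$readout)
  v <- zero_like(params)
  kck <- min(config$checkpoint_k, m)
  best <- list(score = -Inf, params = params)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_score = numeric())
  ntr <- length(itr)
  for (epoch in seq_len(config$max_epochs)) {
    lr <- lr_schedule(epoch, config)
    epoch_loss <- 0
    with_seed(config$seed * 131071 + epoch, {
      ord <- sample.int(ntr)
      starts <- seq(1, ntr, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, ntr)]
        xb <- Xtr[, , , idx, drop = FALSE]
        pb <- prep_batch(xb, transform$kind, transform$seed, epoch, idx, norm)
        B <- length(idx)
        mask <- if (dropout > 0)
          matrix((stats::runif(ncol(params$head$W) * B) >= dropout) /
                   (1 - dropout), ncol = B)
        else NULL
        fwd <- nn_forward(params, pb$x, mask, pb$mom)
        P <- softmax_cols(fwd$logits)
        epoch_loss <- epoch_loss + cross_entropy(P, ytr[idx]) * B
        dlogits <- P
        dlogits[cbind(ytr[idx], seq_len(B))] <-
          dlogits[cbind(ytr[idx], seq_len(B))] - 1
        dlogits <- dlogits / B
        grads <- nn_backward(params, fwd, dlogits, mask)
        st <- sgd_step(params, grads, v, lr, config$momentum)
        params <- st$params; v <- st$v
      }
    })
    val_score <- NA_real_
    if (epoch %% config$validation_period == 0) {
      Pv <- predict_array(params, Xva, transform, norm, config$batch_size,
                          epoch = 0L, index_offset = ntr)
      ranks <- rank_matrix(t(Pv$prob), yva)
      val_score <- mean_species_topk_from_ranks(ranks, yva, kck)
      if (val_score > best$score) best <- list(score = val_score, params = params)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = epoch_loss / ntr,
                                   val_score = val_score))
    if (verbose)
      cat(sprintf("epoch %3d lr %.5f loss %.4f val %s\n", epoch, lr,
                  epoch_loss / ntr,
                  ifelse(is.na(val_score), "-", sprintf("%.4f", val_score))))
  }
  model$params <- best$params
  model$best_val_score <- best$score
  model$history <- hist
  model$norm <- norm
  model$species <- species
  model$transform <- transform
  model$config <- config
  model$fitted <- TRUE
  model
}

cached_extract <- function(points, stack, patch_size, mode, xcache, tag) {
  if (is.null(xcache))
    return(extract_batch(points, stack, patch_size, mode))
  key <- paste(tag, mode, patch_size, nrow(points))
  if (is.null(xcache[[key]]))
    xcache[[key]] <- extract_batch(points, stack, patch_size, mode)
  xcache[[key]]
}

# Forward an entire (C, ps, ps, N) array in minibatches (no dropout),
# applying the model's transform per access with test-time keys.
predict_array <- function(params, Xarr, transform, norm, batch_size,
                          epoch = 0L, index_offset = 0L) {
  n <- dim(Xarr)[4]
  probs <- NULL; logits <- NULL; feats <- NULL
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    xb <- Xarr[, , , idx, drop = FALSE]
    pb <- prep_batch(xb, transform$kind, transform$seed, epoch,
                     idx + index_offset, norm)
    fwd <- nn_forward(params, pb$x, NULL, pb$mom)
    P <- softmax_cols(fwd$logits)
    probs <- cbind(probs, P)
    logits <- cbind(logits, fwd$logits)
    feats <- cbind(feats, fwd$z)
  }
  list(prob = probs, logits = logits, z = feats)
}

#' Predict species probabilities at points
#'
#' @param object a fitted `sdm_model`.
#' @param points data frame with `lon`, `lat` columns.
#' @param stack the raster stack used in training.
#' @param transform ablation applied at prediction time (defaults to the
#'   transform the model was trained with, as the protocol requires).
#' @param xcache optional extraction cache environment.
#' @param ... unused.
#' @return A `prediction_bundle`: per-observation feature vectors `z`
#'   (n x feature_dim), `logits` (`beta_s . z + alpha_s`, n x m),
#'   `probabilities` (n x m, rows sum to 1), `species` labels and
#'   `score_type = "logit"` (the score fed to AUC/TSS for neural models).
#' @export
predict.sdm_model <- function(object, points, stack, transform = NULL,
                              xcache = NULL, ...) {
  if (!isTRUE(object$fitted)) stop("model is not fitted")
  if (is.null(transform)) transform <- object$transform
  mode <- if (object$type == "dnn") "punctual" else "tensor"
  Xarr <- cached_extract(points, stack, object$patch_size, mode, xcache,
                         "predict")
  out <- predict_array(object$params, Xarr, transform, object$norm,
                       object$config$batch_size)
  structure(list(z = t(out$z), logits = t(out$logits),
                 probabilities = t(out$prob), species = object$species,
                 score_type = "logit"),
            class = "prediction_bundle")
}

#' @export
print.prediction_bundle <- function(x, ...) {
  cat(sprintf("<prediction_bundle> %d observations x %d species (%s scores)\n",
              nrow(x$probabilities), ncol(x$probabilities), x$score_type))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-contained serialized container: architecture
#' spec, weights, channel normalization, species labels, training history
#' and the exact transform identifier.
#'
#' @param model a fitted `sdm_model` (or baseline).
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
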