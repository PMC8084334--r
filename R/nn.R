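#' Network primitives
#'
#' A small convolutional backbone implemented directly on BLAS: 3x3 "same"
#' convolutions realized as nine shifted matrix products on channel-first
#' arrays `(C, H, W, B)`, ReLU, 2x2 average pooling, global average pooling
#' to a feature vector `z`, an optional dense feature layer, inverted
#' dropout, and a linear species head with a softmax link. Everything is
#' deterministic under seed.
#'
#' @name nn
NULL

## ---- layer kernels ---------------------------------------------------------

# "Same" 3x3 convolution on a (C, H, W, B) channel-first batch; im2col +
# gemm in compiled code. The forward cache keeps the im2col matrix for the
# backward pass.
conv3_forward <- function(x, W, b) {
  out <- conv3_fwd_cpp(x, W, b, dim(x))
  out$in_dim <- dim(x)
  out
}

conv3_backward <- function(dy, cache, W) {
  conv3_bwd_cpp(dy, cache$im, cache$wm, cache$in_dim, dim(W)[1])
}

pool2_forward <- function(x) {
  d <- dim(x)
  ro <- seq(1, d[2], 2); re <- seq(2, d[2], 2)
  co <- seq(1, d[3], 2); ce <- seq(2, d[3], 2)
  (x[, ro, co, , drop = FALSE] + x[, re, co, , drop = FALSE] +
   x[, ro, ce, , drop = FALSE] + x[, re, ce, , drop = FALSE]) / 4
}

pool2_backward <- function(dy, in_dim) {
  dx <- array(0, in_dim)
  ro <- seq(1, in_dim[2], 2); re <- seq(2, in_dim[2], 2)
  co <- seq(1, in_dim[3], 2); ce <- seq(2, in_dim[3], 2)
  q <- dy / 4
  dx[, ro, co, ] <- q; dx[, re, co, ] <- q
  dx[, ro, ce, ] <- q; dx[, re, ce, ] <- q
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  m <- array(x, c(d[1], d[2] * d[3], d[4]))
  z <- colMeans(aperm(m, c(2, 1, 3)))  # (C, B)
  if (is.null(dim(z))) z <- matrix(z, d[1], d[4])
  z
}

gap_backward <- function(dz, in_dim) {
  # spread each channel gradient uniformly over the spatial cells
  hw <- in_dim[2] * in_dim[3]
  dx <- aperm(array(rep(as.numeric(dz) / hw, each = hw),
                    c(hw, in_dim[1], in_dim[4])), c(2, 1, 3))
  dim(dx) <- in_dim
  dx
}

softmax_cols <- function(L) {
  mx <- apply(L, 2, max)
  P <- exp(sweep(L, 2, mx))
  sweep(P, 2, colSums(P), "/")
}

## ---- public operations -----------------------------------------------------

#' Softmax species head
#'
#' Categorical probabilities over species from a feature vector:
#' `y_s = exp(beta_s . z + alpha_s) / sum_j exp(beta_j . z + alpha_j)`,
#' computed with max-subtraction for overflow safety.
#'
#' @param z feature vector (length `feature_dim`) or matrix
#'   (`feature_dim x n`).
#' @param head list with `W` (`m x feature_dim` species coefficients
#'   `beta_s`) and `b` (length-`m` intercepts `alpha_s`).
#' @return Probability vector (or `m x n` matrix) summing to 1 per
#'   observation.
#' @export
softmax_head <- function(z, head) {
  zm <- if (is.matrix(z)) z else matrix(z, ncol = 1)
  if (ncol(head$W) != nrow(zm))
    stop("feature dimension mismatch: head expects ", ncol(head$W))
  L <- head$W %*% zm + head$b
  if (any(!is.finite(L))) stop("non-finite logits")
  P <- softmax_cols(L)
  if (is.matrix(z)) P else as.numeric(P)
}

#' Multinomial cross-entropy loss
#'
#' `-log(p_true)` per observation, averaged over the batch; probabilities
#' are floored at 1e-12 for numeric safety.
#'
#' @param probabilities probability vector (one observation) or `m x n`
#'   matrix (columns are observations).
#' @param true_species integer species index (1-based into the label
#'   space), one per observation.
#' @export
cross_entropy <- function(probabilities, true_species) {
  P <- if (is.matrix(probabilities)) probabilities else matrix(probabilities, ncol = 1)
  stopifnot(length(true_species) == ncol(P))
  p <- P[cbind(true_species, seq_len(ncol(P)))]
  mean(-log(pmax(p, 1e-12)))
}

#' Step-decay learning-rate schedule
#'
#' `initial_lr * 10^(-d)` where `d` is the number of configured drop epochs
#' less than or equal to `epoch`.
#'
#' @param epoch epoch counter (>= 0).
#' @param config a [train_config()].
#' @export
lr_schedule <- function(epoch, config) {
  stopifnot(epoch >= 0)
  config$initial_lr * 10^(-sum(config$lr_drop_epochs <= epoch))
}

#' Training configuration
#'
#' Defaults follow the reference recipe: SGD at initial rate 0.1 divided by
#' 10 before epochs 90, 130, 150 and 170, momentum 0.9, validation every 5
#' epochs with the checkpoint chosen by the best validation mean per-species
#' top-k accuracy.
#'
#' @param initial_lr initial learning rate.
#' @param lr_drop_epochs strictly increasing epochs at which the rate is
#'   divided by 10.
#' @param momentum SGD momentum.
#' @param max_epochs training epochs.
#' @param validation_period validate every this many epochs.
#' @param batch_size minibatch size.
#' @param checkpoint_k `k` of the validation MSA_k used for checkpoint
#'   selection (clamped to the species count).
#' @param dropout optional override of the model's dropout rate.
#' @param seed integer seed controlling init, shuffling and dropout.
#' @export
train_config <- function(initial_lr = 0.1,
                         lr_drop_epochs = c(90, 130, 150, 170),
                         momentum = 0.9, max_epochs = 180,
                         validation_period = 5, batch_size = 64,
                         checkpoint_k = 30, dropout = NULL, seed = 1) {
  if (is.unsorted(lr_drop_epochs, strictly = TRUE))
    stop("lr_drop_epochs must be strictly increasing")
  structure(list(initial_lr = initial_lr, lr_drop_epochs = lr_drop_epochs,
                 momentum = momentum, max_epochs = max_epochs,
                 validation_period = validation_period,
                 batch_size = batch_size, checkpoint_k = checkpoint_k,
                 dropout = dropout, seed = as.integer(seed)),
            class = "train_config")
}

## ---- parameter init / forward / backward over the whole net ---------------

nn_init <- function(channels, feature_dim, c_in, m, seed, readout = "gap",
                    n_moments = 2L * c_in) {
  with_seed(seed, {
    params <- list(conv = list(), feat = NULL, head = NULL, readout = readout)
    cprev <- c_in
    for (f in channels) {
      sdv <- sqrt(2 / (9 * cprev))
      params$conv[[length(params$conv) + 1L]] <-
        list(W = array(stats::rnorm(f * cprev * 9, sd = sdv), c(f, cprev, 3, 3)),
             b = numeric(f))
      cprev <- f
    }
    if (readout == "gap_center") cprev <- cprev * 5L
    cprev <- cprev + n_moments
    if (!is.null(feature_dim) && feature_dim != cprev) {
      params$feat <- list(W = matrix(stats::rnorm(feature_dim * cprev,
                                                  sd = sqrt(2 / cprev)),
                                     feature_dim, cprev),
                          b = numeric(feature_dim))
      cprev <- feature_dim
    }
    params$head <- list(W = matrix(stats::rnorm(m * cprev, sd = sqrt(1 / cprev)),
                                   m, cprev),
                        b = numeric(m))
    params
  })
}

center_cells <- function(d) {
  # the four cells around the patch center of an even (h x w) map
  h <- d[2]; w <- d[3]
  list(ri = c(h %/% 2, h %/% 2 + 1L), ci = c(w %/% 2, w %/% 2 + 1L))
}

# Forward pass. x: (C, H, W, B); moments: optional (2C, B) side vector of
# per-layer patch means and sds, appended to the pooled features.
# dropout_mask NULL at test time.
nn_forward <- function(params, x, dropout_mask = NULL, moments = NULL) {
  caches <- list()
  a <- x
  for (i in seq_along(params$conv)) {
    cv <- conv3_forward(a, params$conv[[i]]$W, params$conv[[i]]$b)
    r <- pmax(cv$y, 0)
    p <- pool2_forward(r)
    caches[[i]] <- list(im = cv$im, wm = cv$wm, in_dim = cv$in_dim,
                        pre = cv$y, r_dim = dim(r))
    a <- p
  }
  z0 <- gap_forward(a)                       # (C_last, B)
  if (identical(params$readout, "gap_center")) {
    cc <- center_cells(dim(a))
    ctr <- a[, cc$ri, cc$ci, , drop = FALSE]  # (C, 2, 2, B)
    dim(ctr) <- c(dim(a)[1] * 4, dim(a)[4])
    z0 <- rbind(z0, ctr)
  }
  n_pooled <- nrow(z0)
  if (!is.null(moments)) z0 <- rbind(z0, moments)
  feat_pre <- NULL
  z <- z0
  if (!is.null(params$feat)) {
    feat_pre <- params$feat$W %*% z0 + params$feat$b
    z <- pmax(feat_pre, 0)
  }
  zd <- if (is.null(dropout_mask)) z else z * dropout_mask
  logits <- params$head$W %*% zd + params$head$b
  list(logits = logits, z = z, zd = zd, z0 = z0, feat_pre = feat_pre,
       gap_in_dim = dim(a), n_pooled = n_pooled, caches = caches)
}

# Backward from dlogits; returns gradients with the params structure.
nn_backward <- function(params, fwd, dlogits, dropout_mask = NULL) {
  g <- list(conv = vector("list", length(params$conv)), feat = NULL, head = NULL)
  g$head <- list(W = dlogits %*% t(fwd$zd), b = rowSums(dlogits))
  dz <- t(params$head$W) %*% dlogits
  if (!is.null(dropout_mask)) dz <- dz * dropout_mask
  if (!is.null(params$feat)) {
    dz <- dz * (fwd$feat_pre > 0)
    g$feat <- list(W = dz %*% t(fwd$z0), b = rowSums(dz))
    dz <- t(params$feat$W) %*% dz
  }
  dz <- dz[seq_len(fwd$n_pooled), , drop = FALSE]  # moment inputs are leaves
  if (identical(params$readout, "gap_center")) {
    C <- fwd$gap_in_dim[1]
    da <- gap_backward(dz[seq_len(C), , drop = FALSE], fwd$gap_in_dim)
    cc <- center_cells(fwd$gap_in_dim)
    dctr <- dz[-seq_len(C), , drop = FALSE]
    dim(dctr) <- c(C, 2, 2, fwd$gap_in_dim[4])
    da[, cc$ri, cc$ci, ] <- da[, cc$ri, cc$ci, ] + dctr
  } else {
    da <- gap_backward(dz, fwd$gap_in_dim)
  }
  for (i in rev(seq_along(params$conv))) {
    cache <- fwd$caches[[i]]
    dr <- pool2_backward(da, cache$r_dim)
    dpre <- dr * (cache$pre > 0)
    cb <- conv3_backward(dpre, cache, params$conv[[i]]$W)
    g$conv[[i]] <- list(W = cb$dW, b = cb$db)
    da <- cb$dx
  }
  g
}

# SGD + momentum update; state v mirrors params. Returns list(params, v).
sgd_step <- function(params, grads, v, lr, momentum) {
  upd <- function(p, gr, vv) {
    vv <- momentum * vv - lr * gr
    list(p = p + vv, v = vv)
  }
  for (i in seq_along(params$conv)) {
    u <- upd(params$conv[[i]]$W, grads$conv[[i]]$W, v$conv[[i]]$W)
    params$conv[[i]]$W <- u$p; v$conv[[i]]$W <- u$v
    u <- upd(params$conv[[i]]$b, grads$conv[[i]]$b, v$conv[[i]]$b)
    params$conv[[i]]$b <- u$p; v$conv[[i]]$b <- u$v
  }
  if (!is.null(params$feat)) {
    u <- upd(params$feat$W, grads$feat$W, v$feat$W)
    params$feat$W <- u$p; v$feat$W <- u$v
    u <- upd(params$feat$b, grads$feat$b, v$feat$b)
    params$feat$b <- u$p; v$feat$b <- u$v
  }
  u <- upd(params$head$W, grads$head$W, v$head$W)
  params$head$W <- u$p; v$head$W <- u$v
  u <- upd(params$head$b, grads$head$b, v$head$b)
  params$head$b <- u$p; v$head$b <- u$v
  list(params = params, v = v)
}

zero_like <- function(params) {
  z <- params
  for (i in seq_along(z$conv)) {
    z$conv[[i]]$W[] <- 0; z$conv[[i]]$b[] <- 0
  }
  if (!is.null(z$feat)) { z$feat$W[] <- 0; z$feat$b[] <- 0 }
  z$head$W[] <- 0; z$head$b[] <- 0
  z
}
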