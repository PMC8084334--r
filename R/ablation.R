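#' Tensor ablation transforms
#'
#' Four transformations that selectively destroy information in an
#' environmental tensor, applied identically to every tensor during both
#' training and testing:
#'
#' * `rotation` — one of the four square rotations (0/90/180/270 degrees)
#'   drawn uniformly, the same rotation applied to all layers: orientation
#'   is removed, everything else kept.
#' * `permutation` — an independent uniform pixel permutation per layer:
#'   spatial structure is destroyed, the per-layer value distribution kept.
#' * `mean` — every layer collapsed to its constant mean: both structure
#'   and variability removed, only punctual-scale information kept.
#' * `standardize` — each layer centered and divided by its (population)
#'   standard deviation: location and scale removed, structure kept.
#'
#' Random draws are re-sampled at every tensor access (data-augmentation
#' style) from a counter-based key so runs are reproducible.
#'
#' @name ablation
NULL

#' Ablation specification
#'
#' @param kind one of `"none"`, `"rotation"`, `"permutation"`, `"mean"`,
#'   `"standardize"`.
#' @param seed base seed of the per-access random stream.
#' @export
ablation_spec <- function(kind = "none", seed = 1) {
  kind <- match.arg(kind, c("none", "rotation", "permutation", "mean",
                            "standardize"))
  structure(list(kind = kind, seed = as.integer(seed)), class = "ablation_spec")
}

# Deterministic per-access key (kept below 2^31).
ablation_key <- function(seed, epoch, index) {
  as.integer((as.double(seed) * 2654435761 + epoch * 40503 + index) %% 2147483647)
}

# 90-degree counter-clockwise rotation applied q times to a square matrix.
rot90m <- function(m, q) {
  q <- q %% 4
  if (q == 0) return(m)
  for (i in seq_len(q)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

# ---- matrix-level kernels shared by the public API and the training loop --

ablate_slices <- function(vals, kind, key) {
  # vals: (H, W, L) array; returns transformed array of identical shape
  d <- dim(vals)
  switch(kind,
    none = vals,
    rotation = {
      if (d[1] != d[2]) stop("rotation requires a square patch")
      q <- with_seed(key, sample.int(4L, 1L) - 1L)
      if (q == 0) vals
      else {
        out <- vals
        for (l in seq_len(d[3])) out[, , l] <- rot90m(vals[, , l], q)
        out
      }
    },
    permutation = {
      n <- d[1] * d[2]
      perms <- with_seed(key, replicate(d[3], sample.int(n), simplify = FALSE))
      out <- vals
      for (l in seq_len(d[3])) {
        sl <- vals[, , l]
        out[, , l] <- matrix(sl[perms[[l]]], d[1], d[2])
      }
      out
    },
    mean = {
      mu <- colMeans(matrix(vals, d[1] * d[2], d[3]))
      array(rep(mu, each = d[1] * d[2]), d)
    },
    standardize = {
      m <- matrix(vals, d[1] * d[2], d[3])
      mu <- colMeans(m)
      sdv <- sqrt(colMeans(m^2) - mu^2)        # population sd
      sdv[sdv == 0] <- Inf                      # constant layer -> zeros
      array(sweep(sweep(m, 2, mu), 2, sdv, "/"), d)
    },
    stop("unknown ablation kind: ", kind))
}

wrap_like <- function(x, vals) {
  structure(list(values = vals, center = x$center, layer_names = x$layer_names),
            class = "env_tensor")
}

#' Random square rotation of a tensor
#'
#' @param x an `env_tensor` with a square patch.
#' @param key integer random key for this access.
#' @export
rotate_random <- function(x, key = 1) wrap_like(x, ablate_slices(x$values, "rotation", key))

#' Independent per-layer random pixel permutation
#' @inheritParams rotate_random
#' @export
permute_random <- function(x, key = 1) wrap_like(x, ablate_slices(x$values, "permutation", key))

#' Collapse each layer to its mean value
#'
#' Idempotent; the result is a fixed point of the operation and equals the
#' constant-tensor encoding of the layer means.
#' @param x an `env_tensor`.
#' @export
mean_collapse <- function(x) wrap_like(x, ablate_slices(x$values, "mean", 0L))

#' Standardize each layer to mean 0, population sd 1
#'
#' Keeps the spatial arrangement (pixel rank order) of each non-constant
#' layer while deleting its location and scale; constant layers map to
#' all-zero.
#' @param x an `env_tensor`.
#' @export
standardize_structure <- function(x) wrap_like(x, ablate_slices(x$values, "standardize", 0L))

#' Apply an ablation spec to a tensor
#'
#' @param x an `env_tensor`.
#' @param spec an [ablation_spec].
#' @param epoch,index access counters identifying this draw; the same
#'   (seed, epoch, index) always yields the same transform.
#' @export
apply_ablation <- function(x, spec, epoch = 0L, index = 1L) {
  stopifnot(inherits(spec, "ablation_spec"))
  wrap_like(x, ablate_slices(x$values, spec$kind,
                             ablation_key(spec$seed, epoch, index)))
}
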