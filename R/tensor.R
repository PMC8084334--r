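#' Environmental tensors and punctual vectors
#'
#' An environmental tensor is the `patch_size x patch_size x L` array of
#' layer values extracted around one ground point, each layer sliced from
#' its own native grid — so the geographic extent of a slice depends on that
#' layer's pixel size. A punctual vector is the length-`L` vector of
#' center-pixel values, i.e. what a classical punctual SDM sees.
#'
#' @name env_tensor
NULL

# Center convention: the point's pixel sits at 0-based index
# (patch_size %/% 2, patch_size %/% 2) of the patch, i.e. row/column 33
# (1-based) of a 64-pixel patch. Used consistently for tensors, punctual
# vectors and the constant-tensor encoding.
patch_offsets <- function(patch_size) {
  c0 <- patch_size %/% 2L
  seq_len(patch_size) - 1L - c0
}

# Window of one layer around (row, col), padded with the layer's fill value
# where it overflows the grid.
layer_window <- function(layer, row, col, patch_size) {
  off <- patch_offsets(patch_size)
  rows <- row + off
  cols <- col + off
  nr <- nrow(layer$grid); nc <- ncol(layer$grid)
  out <- matrix(layer_fill_value(layer), patch_size, patch_size)
  rok <- rows >= 1 & rows <= nr
  cok <- cols >= 1 & cols <= nc
  if (any(rok) && any(cok))
    out[rok, cok] <- layer$grid[rows[rok], cols[cok], drop = FALSE]
  out
}

#' Extract the environmental tensor at a point
#'
#' For each layer of an expanded stack, takes the `patch_size x patch_size`
#' window of that layer's native grid whose center pixel contains the point.
#' Windows overflowing a grid edge are padded with that layer's sentinel
#' fill value, so near-edge occurrences need no buffer zone.
#'
#' @param point length-2 ground coordinate `(x, y)`.
#' @param stack an expanded, filled [raster_stack].
#' @param patch_size pixels per patch side (>= 1).
#' @return An object of class `env_tensor`: `values` is a
#'   `patch_size x patch_size x L` array, with `center` and `layer_names`.
#' @export
extract_tensor <- function(point, stack, patch_size = 64L) {
  stopifnot(inherits(stack, "raster_stack"))
  if (!isTRUE(stack$expanded))
    stop("stack must be expanded (expand_categorical) before extraction")
  if (patch_size < 1) stop("patch_size must be >= 1")
  inside <- vapply(stack$layers, function(l) point_in_layer(point, l), TRUE)
  if (!all(inside))
    stop("point (", point[1], ", ", point[2], ") is outside layer(s): ",
         paste(names(stack$layers)[!inside], collapse = ", "))
  L <- length(stack$layers)
  vals <- array(0, c(patch_size, patch_size, L))
  for (i in seq_len(L)) {
    l <- stack$layers[[i]]
    rc <- point_to_pixel(point, l)
    vals[, , i] <- layer_window(l, rc[1], rc[2], patch_size)
  }
  structure(list(values = vals, center = as.numeric(point),
                 layer_names = names(stack$layers)),
            class = "env_tensor")
}

#' Extract the punctual environmental vector at a point
#'
#' The center-pixel value of every layer; equals the center pixel of
#' [extract_tensor()]'s output for each layer.
#'
#' @inheritParams extract_tensor
#' @return An object of class `punctual_vector` with named `values`.
#' @export
extract_punctual_vector <- function(point, stack) {
  stopifnot(inherits(stack, "raster_stack"))
  if (!isTRUE(stack$expanded))
    stop("stack must be expanded (expand_categorical) before extraction")
  inside <- vapply(stack$layers, function(l) point_in_layer(point, l), TRUE)
  if (!all(inside))
    stop("point (", point[1], ", ", point[2], ") is outside layer(s): ",
         paste(names(stack$layers)[!inside], collapse = ", "))
  v <- vapply(stack$layers, function(l) {
    rc <- point_to_pixel(point, l)
    l$grid[rc[1], rc[2]]
  }, 0)
  structure(list(values = v, center = as.numeric(point)),
            class = "punctual_vector")
}

#' Constant-tensor encoding of a punctual vector
#'
#' Repeats each vector entry over all pixels of its layer, producing a
#' tensor whose every layer slice is constant. This is the punctual deep
#' network's input encoding: the same convolutional architecture as the
#' tensor model, but blind to the landscape by construction.
#'
#' @param vector a [punctual_vector] (or bare numeric vector).
#' @param patch_size pixels per patch side.
#' @export
vector_to_constant_tensor <- function(vector, patch_size = 64L) {
  v <- if (inherits(vector, "punctual_vector")) vector$values else vector
  center <- if (inherits(vector, "punctual_vector")) vector$center else c(NA, NA)
  L <- length(v)
  vals <- array(rep(v, each = patch_size * patch_size),
                c(patch_size, patch_size, L))
  structure(list(values = vals, center = center,
                 layer_names = names(v)),
            class = "env_tensor")
}

#' @export
print.env_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<env_tensor> %d x %d x %d at (%g, %g)\n", d[1], d[2], d[3],
              x$center[1], x$center[2]))
  invisible(x)
}

#' Export a tensor to a plain-text array container
#'
#' Debug-oriented serialization: JSON holding the dimensions, layer names
#' and values (column-major), analogous to a compressed array archive.
#'
#' @param x an `env_tensor`.
#' @param path output path.
#' @export
write_env_tensor <- function(x, path) {
  jsonlite::write_json(list(dim = dim(x$values), center = x$center,
                            layer_names = x$layer_names,
                            values = as.numeric(x$values)),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a tensor written by [write_env_tensor()]
#' @param path file path.
#' @export
read_env_tensor <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(values = array(o$values, o$dim), center = o$center,
                 layer_names = o$layer_names),
            class = "env_tensor")
}

# Internal: extract a whole occurrence set as a channel-first batch array
# (L, patch, patch, N), the layout the network consumes. mode "tensor" reads
# true windows; mode "punctual" builds the constant-tensor encoding.
extract_batch <- function(points, stack, patch_size, mode = c("tensor", "punctual")) {
  mode <- match.arg(mode)
  L <- length(stack$layers)
  n <- nrow(points)
  out <- array(0, c(L, patch_size, patch_size, n))
  for (i in seq_len(n)) {
    p <- c(points$lon[i], points$lat[i])
    if (mode == "tensor") {
      x <- extract_tensor(p, stack, patch_size)$values
    } else {
      v <- extract_punctual_vector(p, stack)$values
      x <- vector_to_constant_tensor(v, patch_size)$values
    }
    out[, , , i] <- aperm(x, c(3, 1, 2))
  }
  out
}
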