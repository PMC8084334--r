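#' Activation maps of the learnt features
#'
#' The last-layer neurons `z = phi(x)` act as latent environmental
#' descriptors. Mapping each neuron over a spatial grid — evaluating the
#' feature extractor on the tensor at the center of every quadrat, then
#' averaging over coarser blocks — renders the geographic signature of what
#' the network learnt (e.g. mountain ranges, coastal belts).
#'
#' @name activation_maps
NULL

#' Evaluate all feature-extractor neurons over a spatial grid
#'
#' Quadrat centers tile the common extent of the stack at `fine_resolution`
#' ground units; the model's tensor (with its transform) is extracted and
#' forwarded at each center, all neurons in one pass.
#'
#' @param model a fitted `sdm_model`.
#' @param stack the raster stack.
#' @param fine_resolution quadrat side in ground units.
#' @param transform ablation applied at evaluation (defaults to the
#'   model's training transform).
#' @return An `activation_grid`: `values` is an `ny x nx x feature_dim`
#'   array plus quadrat center coordinates.
#' @export
grid_activations <- function(model, stack, fine_resolution, transform = NULL) {
  if (!isTRUE(model$fitted)) stop("model is not fitted")
  if (is.null(transform)) transform <- model$transform
  px <- vapply(stack$layers, `[[`, 0, "pixel_size")
  if (fine_resolution < min(px))
    warning("grid resolution is finer than the finest raster pixel")
  ext <- stack_extent(stack)
  nx <- floor((ext$xmax - ext$xmin) / fine_resolution)
  ny <- floor((ext$ymax - ext$ymin) / fine_resolution)
  if (nx < 1 || ny < 1) stop("fine_resolution exceeds the stack extent")
  xs <- ext$xmin + (seq_len(nx) - 0.5) * fine_resolution
  ys <- ext$ymax - (seq_len(ny) - 0.5) * fine_resolution
  pts <- expand.grid(lon = xs, lat = ys)[, c("lon", "lat")]
  mode <- if (model$type == "dnn") "punctual" else "tensor"
  Xarr <- extract_batch(pts, stack, model$patch_size, mode)
  out <- predict_array(model$params, Xarr, transform, model$norm,
                       model$config$batch_size)
  fd <- nrow(out$z)
  vals <- array(t(out$z), c(nx, ny, fd))   # row-major fill: lon fastest
  vals <- aperm(vals, c(2, 1, 3))          # (ny, nx, neuron)
  structure(list(values = vals, x = xs, y = ys,
                 fine_resolution = fine_resolution, model_species = model$species,
                 head = model$params$head),
            class = "activation_grid")
}

stack_extent <- function(stack) {
  xmin <- max(vapply(stack$layers, function(l) l$origin[1], 0))
  ymax <- min(vapply(stack$layers, function(l) l$origin[2], 0))
  xmax <- min(vapply(stack$layers, function(l)
    l$origin[1] + ncol(l$grid) * l$pixel_size, 0))
  ymin <- max(vapply(stack$layers, function(l)
    l$origin[2] - nrow(l$grid) * l$pixel_size, 0))
  list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
}

#' Block-average a fine grid to a coarse one
#'
#' Arithmetic mean over `block_factor x block_factor` groups of fine cells;
#' partial blocks at the edges are averaged over the available cells. With
#' the reference geometry (1 km quadrats, 10 km blocks) each full block
#' averages 100 fine cells.
#'
#' @param fine numeric matrix (or `ny x nx x d` array, averaged slice-wise).
#' @param block_factor fine cells per coarse cell side (>= 1).
#' @export
block_average <- function(fine, block_factor) {
  stopifnot(block_factor >= 1)
  if (length(dim(fine)) == 3) {
    slices <- lapply(seq_len(dim(fine)[3]), function(i)
      block_average(fine[, , i], block_factor))
    return(array(unlist(slices), c(dim(slices[[1]]), length(slices))))
  }
  if (block_factor == 1) return(fine)
  ri <- ceiling(seq_len(nrow(fine)) / block_factor)
  ci <- ceiling(seq_len(ncol(fine)) / block_factor)
  sums <- rowsum(fine, ri)
  sums <- t(rowsum(t(sums), ci))
  cnt <- table(ri) %o% table(ci)
  out <- sums / as.numeric(cnt)
  dimnames(out) <- NULL
  out
}

#' Linear species response over an activation grid
#'
#' Reuses the gridded activations with the species head: the map of
#' `beta_s . z + alpha_s`, the model's habitat-suitability-like score for
#' one species.
#'
#' @param grid an [grid_activations()] result.
#' @param species species identifier.
#' @return Numeric matrix (ny x nx).
#' @export
species_response_map <- function(grid, species) {
  s <- match(species, grid$model_species)
  if (is.na(s)) stop("unknown species: ", species)
  d <- dim(grid$values)
  zmat <- matrix(grid$values, d[1] * d[2], d[3])
  matrix(zmat %*% grid$head$W[s, ] + grid$head$b[s], d[1], d[2])
}

#' Write a map as an ASCII grid (and optionally a PNG rendering)
#'
#' @param m numeric matrix (row 1 = north).
#' @param path output `.asc` path.
#' @param origin,pixel_size georeferencing of the map.
#' @param png optional PNG path for a quick-look rendering.
#' @export
write_map <- function(m, path, origin = c(0, nrow(m)), pixel_size = 1,
                      png = NULL) {
  write_asc(raster_layer(m, name = "map", origin = origin,
                         pixel_size = pixel_size), path)
  if (!is.null(png)) {
    grDevices::png(png, width = 480, height = 480)
    op <- graphics::par(mar = c(1, 1, 1, 1))
    graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
                    col = grDevices::hcl.colors(64, "viridis"))
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(path)
}
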