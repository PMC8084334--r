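#' Environmental raster layers and stacks
#'
#' A `raster_layer` is a single environmental variable on a regular grid:
#' a numeric matrix (row 1 = northernmost row), an upper-left origin in
#' ground coordinates, a pixel size in ground units, a variable kind
#' (`quantitative`, `ordinal`, `boolean` or `categorical`) and a logical
#' nodata mask marking undefined pixels (sea, missing coverage, ...).
#' Layers in one stack may have different pixel sizes; each keeps its own
#' geotransform.
#'
#' @param grid numeric matrix of pixel values; `NA` entries are treated as
#'   undefined and added to the nodata mask.
#' @param name layer name.
#' @param origin length-2 numeric, ground coordinates `(x, y)` of the grid's
#'   upper-left corner.
#' @param pixel_size ground units per pixel (> 0).
#' @param kind one of `"quantitative"`, `"ordinal"`, `"boolean"`,
#'   `"categorical"`.
#' @param nodata_mask optional logical matrix, `TRUE` where undefined.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, name, origin = c(0, nrow(grid)), pixel_size = 1,
                         kind = "quantitative", nodata_mask = NULL) {
  stopifnot(is.matrix(grid), pixel_size > 0, length(origin) == 2)
  kind <- match.arg(kind, c("quantitative", "ordinal", "boolean", "categorical"))
  if (is.null(nodata_mask)) nodata_mask <- is.na(grid)
  nodata_mask <- nodata_mask | is.na(grid)
  stopifnot(identical(dim(grid), dim(nodata_mask)))
  structure(list(name = name, grid = grid, origin = as.numeric(origin),
                 pixel_size = pixel_size, kind = kind,
                 nodata_mask = nodata_mask, fill_value = NULL),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  cat(sprintf("<raster_layer> %s [%s] %d x %d, pixel %g, %d undefined\n",
              x$name, x$kind, nrow(x$grid), ncol(x$grid), x$pixel_size,
              sum(x$nodata_mask)))
  invisible(x)
}

#' Build a raster stack
#'
#' An ordered collection of [raster_layer] objects sharing a coordinate
#' system (but not necessarily a resolution).
#'
#' @param layers list of `raster_layer` objects.
#' @return An object of class `raster_stack` with an `expanded` flag that is
#'   `TRUE` once categorical variables have been one-hot expanded.
#' @export
raster_stack <- function(layers) {
  stopifnot(length(layers) >= 1,
            all(vapply(layers, inherits, TRUE, "raster_layer")))
  names(layers) <- vapply(layers, `[[`, "", "name")
  structure(list(layers = layers,
                 expanded = !any(vapply(layers, `[[`, "", "kind") == "categorical")),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layers%s\n", length(x$layers),
              if (x$expanded) " (expanded)" else ""))
  for (l in x$layers) print(l)
  invisible(x)
}

#' Number of layers in a stack
#' @param stack a `raster_stack`.
#' @export
n_layers <- function(stack) length(stack$layers)

#' Fill undefined pixels with a sentinel below the valid minimum
#'
#' Undefined pixels (sea, missing data) must carry a numeric value before a
#' model can consume the layer. The sentinel is chosen strictly below the
#' minimum of the valid pixels so it is distinguishable from any real value:
#' `min_valid - margin_fraction * (max_valid - min_valid)`, falling back to
#' `min_valid - 1` for a constant layer.
#'
#' @param layer a [raster_layer].
#' @param margin_fraction fraction of the valid range used as margin
#'   (default 0.1).
#' @return The layer with undefined pixels replaced by the fill value; the
#'   nodata mask is retained for provenance and `fill_value` is recorded.
#' @export
fill_undefined <- function(layer, margin_fraction = 0.1) {
  stopifnot(inherits(layer, "raster_layer"), margin_fraction > 0)
  valid <- layer$grid[!layer$nodata_mask]
  if (length(valid) == 0)
    stop("layer '", layer$name, "' has no valid pixels")
  fv <- layer_fill_value(layer, margin_fraction)
  layer$grid[layer$nodata_mask] <- fv
  layer$fill_value <- fv
  layer
}

# Sentinel value for a layer; computed on demand so edge padding can use it
# even when the layer has no undefined pixels.
layer_fill_value <- function(layer, margin_fraction = 0.1) {
  if (!is.null(layer$fill_value)) return(layer$fill_value)
  valid <- layer$grid[!layer$nodata_mask]
  if (length(valid) == 0) stop("layer '", layer$name, "' has no valid pixels")
  lo <- min(valid); hi <- max(valid)
  if (hi > lo) lo - margin_fraction * (hi - lo) else lo - 1
}

#' One-hot expansion of categorical layers
#'
#' Each categorical variable with `c` observed classes is replaced by `c`
#' boolean presence/absence layers, one per class, ordered by ascending class
#' value so the layer order is reproducible. Non-categorical layers pass
#' through unchanged. At every valid pixel exactly one derived layer holds 1.
#'
#' @param stack a [raster_stack], not yet expanded.
#' @return The expanded stack (`expanded` flag set).
#' @export
expand_categorical <- function(stack) {
  stopifnot(inherits(stack, "raster_stack"))
  if (isTRUE(stack$expanded)) stop("stack is already expanded")
  out <- list()
  for (l in stack$layers) {
    if (l$kind != "categorical") { out[[length(out) + 1L]] <- l; next }
    valid <- l$grid[!l$nodata_mask]
    if (length(valid) == 0)
      stop("categorical layer '", l$name, "' has no valid pixels")
    classes <- sort(unique(valid))
    for (cl in classes) {
      g <- (l$grid == cl) * 1
      g[l$nodata_mask] <- NA
      out[[length(out) + 1L]] <- raster_layer(
        g, name = paste0(l$name, "_", format(cl, trim = TRUE)),
        origin = l$origin, pixel_size = l$pixel_size, kind = "boolean",
        nodata_mask = l$nodata_mask)
    }
  }
  st <- raster_stack(out)
  st$expanded <- TRUE
  st
}

#' Fill every layer of a stack
#' @param stack a `raster_stack`.
#' @param margin_fraction see [fill_undefined()].
#' @export
fill_stack <- function(stack, margin_fraction = 0.1) {
  stack$layers <- lapply(stack$layers, fill_undefined, margin_fraction)
  stack
}

## ---- point <-> pixel -------------------------------------------------------

# 1-based (row, col) of the pixel containing a ground point; GeoTIFF
# convention: origin at upper-left, rows increase southwards.
point_to_pixel <- function(point, layer) {
  col <- floor((point[1] - layer$origin[1]) / layer$pixel_size) + 1L
  row <- floor((layer$origin[2] - point[2]) / layer$pixel_size) + 1L
  c(row = row, col = col)
}

point_in_layer <- function(point, layer) {
  rc <- point_to_pixel(point, layer)
  rc[1] >= 1 && rc[1] <= nrow(layer$grid) && rc[2] >= 1 && rc[2] <= ncol(layer$grid)
}

## ---- plain-text raster I/O (ESRI ASCII grid) ------------------------------

#' Write a layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of values, northern
#' row first. Undefined pixels are written as the NODATA value.
#'
#' @param layer a [raster_layer].
#' @param path output path (conventionally `.asc`).
#' @param nodata sentinel written for undefined pixels.
#' @export
write_asc <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  g[layer$nodata_mask] <- nodata
  hdr <- c(paste("ncols", ncol(g)), paste("nrows", nrow(g)),
           paste("xllcorner", layer$origin[1]),
           paste("yllcorner", layer$origin[2] - nrow(g) * layer$pixel_size),
           paste("cellsize", layer$pixel_size),
           paste("NODATA_value", nodata))
  body <- apply(g, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file path.
#' @param name layer name (defaults to the file name without extension).
#' @param kind variable kind, see [raster_layer()].
#' @export
read_asc <- function(path, name = NULL, kind = "quantitative") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)],
                 function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
  g <- do.call(rbind, vals)
  stopifnot(nrow(g) == hdr$nrows, ncol(g) == hdr$ncols)
  mask <- !is.na(hdr$nodata_value) & g == hdr$nodata_value
  g[mask] <- NA
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raster_layer(g, name = name,
               origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
               pixel_size = hdr$cellsize, kind = kind, nodata_mask = mask)
}

#' Write a stack as ASCII grids plus a JSON manifest
#'
#' The manifest lists `file`, `name` and `kind` for every layer, in order,
#' so a stack round-trips through plain text.
#'
#' @param stack a `raster_stack`.
#' @param dir output directory (created if absent).
#' @return Path of the manifest.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(stack$layers, function(l) {
    f <- paste0(l$name, ".asc")
    write_asc(l, file.path(dir, f))
    list(file = f, name = l$name, kind = l$kind)
  })
  manifest <- file.path(dir, "stack.json")
  jsonlite::write_json(unname(entries), manifest, auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a stack from a JSON manifest
#' @param manifest path to the manifest written by [write_stack()].
#' @export
read_stack <- function(manifest) {
  entries <- jsonlite::read_json(manifest)
  base <- dirname(manifest)
  layers <- lapply(entries, function(e)
    read_asc(file.path(base, e$file), name = e$name, kind = e$kind))
  raster_stack(layers)
}

## ---- occurrence I/O --------------------------------------------------------

#' Read an occurrence table
#'
#' CSV with header columns `lon`, `lat`, `species_id` (and optionally
#' `partition`). Coordinates must be in the rasters' coordinate system; no
#' reprojection is performed.
#'
#' @param path CSV path.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "species_id")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns lon, lat, species_id")
  if (is.null(df$partition)) df$partition <- NA_character_
  structure(df, class = c("occurrence_set", "data.frame"))
}

#' Write an occurrence table
#' @param occ occurrence data frame.
#' @param path CSV path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}
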