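#' Synthetic landscapes and presence-only occurrence sets
#'
#' The simulator builds a world in which every downstream stage of the
#' pipeline is testable without external data: spatially autocorrelated
#' quantitative layers (Gaussian random fields), one categorical land-cover
#' layer (quantile-thresholded field), and species whose occurrence
#' intensity depends either on punctual environmental values, on the
#' neighborhood mean, or on neighborhood spatial structure alone. Species
#' frequencies follow a long-tail rank law (few frequent species, many rare
#' ones).
#'
#' @name synthetic_world
NULL

#' Gaussian random field layer
#'
#' Zero-mean unit-variance field synthesized by periodic convolution of
#' white noise with a Gaussian kernel of standard deviation
#' `correlation_length` pixels (FFT). `correlation_length = 0` yields white
#' noise. Deterministic under `seed`.
#'
#' @param shape length-2 integer grid size `(nrow, ncol)`.
#' @param correlation_length smoothing kernel sd in pixels (>= 0).
#' @param seed integer random seed.
#' @param name layer name.
#' @param pixel_size ground units per pixel.
#' @param origin upper-left corner ground coordinate.
#' @export
generate_grf_layer <- function(shape, correlation_length = 0, seed = 1,
                               name = "grf", pixel_size = 1,
                               origin = c(0, shape[1] * pixel_size)) {
  if (any(shape < 1)) stop("shape must be positive")
  if (correlation_length < 0) stop("correlation_length must be >= 0")
  g <- with_seed(seed, matrix(stats::rnorm(shape[1] * shape[2]), shape[1], shape[2]))
  if (correlation_length > 0)
    g <- gaussian_smooth_periodic(g, correlation_length)
  g <- (g - mean(g)) / stats::sd(g)
  raster_layer(g, name = name, origin = origin, pixel_size = pixel_size,
               kind = "quantitative")
}

# Periodic Gaussian smoothing via 2-D FFT.
gaussian_smooth_periodic <- function(g, sigma) {
  nr <- nrow(g); nc <- ncol(g)
  kr <- stats::dnorm(pmin(0:(nr - 1), nr - 0:(nr - 1)), sd = sigma)
  kc <- stats::dnorm(pmin(0:(nc - 1), nc - 0:(nc - 1)), sd = sigma)
  K <- outer(kr, kc)
  K <- K / sum(K)
  Re(stats::fft(stats::fft(g) * stats::fft(K), inverse = TRUE)) / (nr * nc)
}

#' Roughness-varying quantitative layer
#'
#' A unit-variance field whose local spatial structure varies across the
#' map while its pointwise value distribution stays standard normal
#' everywhere: a smooth mixing surface `a` in `[0, 1]` blends a fine-scale
#' and a coarse-scale unit-variance Gaussian field as
#' `sqrt(a) * fine + sqrt(1 - a) * coarse`. Where `a` is high the landscape
#' is fragmented (rough), where it is low it is smooth — but the mean and
#' variance carry no signal, so neighborhood structure is the only channel
#' through which such a layer can inform a species niche. This emulates
#' spatial variation in landscape fragmentation at constant habitat amount.
#'
#' @inheritParams generate_grf_layer
#' @param cl_fine correlation length of the fragmented component (0 =
#'   white noise).
#' @param cl_coarse correlation length of the smooth component; kept short
#'   so the dispersion of windowed statistics stays comparable between
#'   smooth and fragmented areas (value-distribution channels carry as
#'   little signal as possible).
#' @param cl_mix correlation length of the mixing surface.
#' @export
generate_roughness_layer <- function(shape, cl_fine = 0, cl_coarse = 3,
                                     cl_mix = 8, seed = 1,
                                     name = "rough", pixel_size = 1,
                                     origin = c(0, shape[1] * pixel_size)) {
  gf <- generate_grf_layer(shape, cl_fine, seed * 3 + 1, name, pixel_size)$grid
  gc <- generate_grf_layer(shape, cl_coarse, seed * 3 + 2, name, pixel_size)$grid
  a <- stats::pnorm(generate_grf_layer(shape, cl_mix, seed * 3 + 3, name,
                                       pixel_size)$grid)
  # both components have unit variance, so the blend is standard normal at
  # every pixel: the pointwise value distribution carries no information
  g <- sqrt(a) * gf + sqrt(1 - a) * gc
  raster_layer(g, name = name, origin = origin, pixel_size = pixel_size,
               kind = "quantitative")
}

#' Categorical land-cover layer
#'
#' A Gaussian random field cut at its empirical quantiles into `n_classes`
#' contiguous patches with (near) equal shares; every class is present.
#'
#' @inheritParams generate_grf_layer
#' @param n_classes number of land-cover classes (>= 2).
#' @export
generate_categorical_layer <- function(shape, n_classes = 5,
                                       correlation_length = 8, seed = 1,
                                       name = "landcover", pixel_size = 1,
                                       origin = c(0, shape[1] * pixel_size)) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (n_classes > prod(shape)) stop("n_classes exceeds pixel count")
  f <- generate_grf_layer(shape, correlation_length, seed, name, pixel_size,
                          origin)
  q <- stats::quantile(f$grid, probs = seq_len(n_classes - 1) / n_classes)
  g <- matrix(findInterval(f$grid, q) + 1, shape[1], shape[2])
  # quantile cuts on a continuous field guarantee presence of every class
  raster_layer(g, name = name, origin = origin, pixel_size = pixel_size,
               kind = "categorical")
}

#' Moran's I spatial autocorrelation on a grid (rook contiguity)
#'
#' @param g numeric matrix.
#' @return Moran's I; near 0 for white noise, approaching 1 for smooth
#'   fields.
#' @export
morans_i_grid <- function(g) {
  z <- g - mean(g)
  num_h <- sum(z[, -ncol(z)] * z[, -1])
  num_v <- sum(z[-nrow(z), ] * z[-1, ])
  W <- 2 * (nrow(g) * (ncol(g) - 1) + ncol(g) * (nrow(g) - 1))
  (length(g) / W) * (2 * (num_h + num_v)) / sum(z^2)
}

#' Define a species niche
#'
#' A niche maps the (expanded) environmental layers to an occurrence
#' intensity surface. Three modes probe different information channels:
#' `punctual` uses pixel values (a classical niche), `landscape_mean` uses
#' the neighborhood mean (habitat amount), and `landscape_structure` uses
#' the local spatial autocorrelation of the neighborhood (a windowed
#' Moran-type statistic: smooth versus fragmented surroundings), which is
#' invariant to the punctual value, to additive shifts and rescalings of
#' the layer, and to square rotations — only spatial arrangement carries
#' signal.
#'
#' @param species_id integer species identifier.
#' @param mode one of `"punctual"`, `"landscape_mean"`,
#'   `"landscape_structure"`.
#' @param layer_weights named numeric vector of per-layer coefficients
#'   (layers not named get weight 0).
#' @param window neighborhood radius in pixels (landscape modes, >= 1).
#' @param base_rate relative abundance weight (> 0).
#' @param offset intercept of the weighted sum before the softplus; large
#'   negative offsets turn a diffuse niche into a hotspot specialist
#'   (intensity near zero outside the top of the linear predictor).
#' @export
species_niche <- function(species_id, mode, layer_weights, window = 4,
                          base_rate = 1, offset = 0) {
  mode <- match.arg(mode, c("punctual", "landscape_mean", "landscape_structure"))
  if (mode != "punctual" && window < 1) stop("window must be >= 1")
  if (base_rate <= 0) stop("base_rate must be > 0")
  structure(list(species_id = as.integer(species_id), mode = mode,
                 layer_weights = layer_weights, window = window,
                 base_rate = base_rate, offset = offset),
            class = "species_niche")
}

# Mean of g over the window rows (r-up..r+down), cols (c-left..c+right) for
# every pixel, renormalized at edges to the cells actually inside the grid;
# summed-area table implementation.
box_mean <- function(g, up, down, left, right) {
  nr <- nrow(g); nc <- ncol(g)
  cs <- apply(g, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- cs  # S[i+1, j+1] = sum(g[1:i, 1:j])
  r1 <- pmax(1, seq_len(nr) - up); r2 <- pmin(nr, seq_len(nr) + down)
  c1 <- pmax(1, seq_len(nc) - left); c2 <- pmin(nc, seq_len(nc) + right)
  tot <- S[r2 + 1, c2 + 1, drop = FALSE] - S[r1, c2 + 1, drop = FALSE] -
         S[r2 + 1, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  cnt <- (r2 - r1 + 1) %o% (c2 - c1 + 1)
  tot / cnt
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Per-layer feature map for a niche mode.
niche_feature_map <- function(g, mode, w) {
  switch(mode,
    punctual = g,
    landscape_mean = box_mean(g, w, w, w, w),
    landscape_structure = local_morans(g, w),
    stop("unknown niche mode: ", mode))
}

# Windowed local spatial-autocorrelation statistic: the Moran-type lag-1
# autocorrelation of the (2w+1)^2 neighborhood around each pixel,
# (mean rook-neighbor product - window mean^2) / window variance.
# Invariant to additive shifts, to rescaling, and to the four square
# rotations; destroyed by pixel permutation; a constant window maps to 0.
local_morans <- function(g, w) {
  nr <- nrow(g); nc <- ncol(g)
  down <- g[c(2:nr, nr), , drop = FALSE]    # neighbor below (edge replicated)
  right <- g[, c(2:nc, nc), drop = FALSE]   # neighbor to the right
  bm <- function(x) box_mean(x, w, w, w, w)
  mu <- bm(g)
  # windowed neighbor covariance: each cross term is centered with its own
  # shifted-field mean, so additive shifts cancel exactly
  cv <- (bm(g * down) - mu * bm(down) + bm(g * right) - mu * bm(right)) / 2
  v <- bm(g * g) - mu^2
  out <- cv / pmax(v, 1e-12)
  out[v < 1e-10] <- 0
  out
}

#' Occurrence intensity surface of a species
#'
#' Softplus of the weighted sum of the niche's per-layer feature maps,
#' computed on the stack's common grid. Always strictly positive; a
#' structure niche on a constant layer yields the constant
#' `softplus(0)`.
#'
#' @param niche a [species_niche].
#' @param stack an expanded [raster_stack] whose layers share one grid.
#' @return A [raster_layer] named `intensity_<species_id>`.
#' @export
species_intensity <- function(niche, stack) {
  stopifnot(inherits(niche, "species_niche"), inherits(stack, "raster_stack"))
  if (!isTRUE(stack$expanded)) stop("stack must be expanded")
  dims <- vapply(stack$layers, function(l) dim(l$grid), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("species_intensity requires layers on a common grid")
  ref <- stack$layers[[1]]
  acc <- matrix(0, nrow(ref$grid), ncol(ref$grid))
  w <- niche$layer_weights
  for (nm in names(w)) {
    if (w[[nm]] == 0) next
    if (is.null(stack$layers[[nm]]))
      stop("niche references unknown layer '", nm, "'")
    acc <- acc + w[[nm]] *
      niche_feature_map(stack$layers[[nm]]$grid, niche$mode, niche$window)
  }
  raster_layer(softplus(acc + (niche$offset %||% 0)),
               name = paste0("intensity_", niche$species_id),
               origin = ref$origin, pixel_size = ref$pixel_size,
               kind = "quantitative")
}

#' Sample a presence-only occurrence set
#'
#' Species counts are multinomial with probabilities proportional to
#' `base_rate * rank^(-tail_exponent)` (rank = position in the niche list),
#' yielding a long-tail frequency distribution. Locations are drawn
#' per species proportional to the [species_intensity()] surface, with
#' uniform jitter inside the chosen pixel. Deterministic under `seed`.
#'
#' @param stack expanded stack (common grid).
#' @param niches list of [species_niche] objects, most common first.
#' @param n_total total number of occurrences.
#' @param tail_exponent rank-law exponent (0 = uniform expected counts).
#' @param seed integer seed.
#' @return An `occurrence_set` data frame with columns `lon`, `lat`,
#'   `species_id`, `partition` (unset).
#' @export
sample_occurrences <- function(stack, niches, n_total, tail_exponent = 1.2,
                               seed = 1) {
  stopifnot(length(niches) >= 1, n_total >= 1)
  m <- length(niches)
  base <- vapply(niches, `[[`, 0, "base_rate")
  p <- base * seq_len(m)^(-tail_exponent)
  p <- p / sum(p)
  with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1, n_total, p))
    rows <- list()
    for (s in seq_len(m)) {
      if (counts[s] == 0) next
      inten <- species_intensity(niches[[s]], stack)$grid
      if (!any(inten > 0)) stop("species ", niches[[s]]$species_id,
                                " has an all-zero intensity surface")
      pix <- sample.int(length(inten), counts[s], replace = TRUE,
                        prob = as.numeric(inten))
      rc <- arrayInd(pix, dim(inten))
      ref <- stack$layers[[1]]
      ps <- ref$pixel_size
      lon <- ref$origin[1] + (rc[, 2] - 1 + stats::runif(counts[s])) * ps
      lat <- ref$origin[2] - (rc[, 1] - 1 + stats::runif(counts[s])) * ps
      rows[[length(rows) + 1L]] <- data.frame(
        lon = lon, lat = lat, species_id = niches[[s]]$species_id)
    }
    df <- do.call(rbind, rows)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    rownames(df) <- NULL
    df$partition <- NA_character_
    structure(df, class = c("occurrence_set", "data.frame"))
  })
}

#' Partition occurrences into train / validation / test
#'
#' Uniform random split without stratification: `test_fraction` of all
#' records to test, then `validation_fraction` of the remaining training
#' records to validation. A rare species' sole record may land in test, in
#' which case it is absent from training.
#'
#' @param occ occurrence set.
#' @param test_fraction fraction of all records held out for test.
#' @param validation_fraction fraction of the training records used for
#'   validation.
#' @param seed integer seed.
#' @export
split_occurrences <- function(occ, test_fraction = 0.1,
                              validation_fraction = 0.1, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            validation_fraction > 0, validation_fraction < 1)
  n <- nrow(occ)
  with_seed(seed, {
    perm <- sample.int(n)
    n_test <- round(n * test_fraction)
    n_val <- round((n - n_test) * validation_fraction)
    part <- rep("train", n)
    part[perm[seq_len(n_test)]] <- "test"
    part[perm[n_test + seq_len(n_val)]] <- "validation"
    occ$partition <- part
    occ
  })
}

#' Generate a complete synthetic world
#'
#' Defaults describe the reference desk-scale world: a 256 x 256 grid, six
#' quantitative layers — three plain Gaussian random fields at three
#' correlation lengths (value niches) and three roughness-varying layers
#' (structure niches, see [generate_roughness_layer()]) — one 5-class
#' categorical land-cover layer, 40 species (half with structure-only
#' niches), 8000 occurrences with tail exponent 1.2, and patch size 32.
#' All sizes are configurable for smaller test worlds.
#'
#' @param grid_size grid side in pixels.
#' @param corr_lengths correlation lengths of the plain quantitative
#'   layers.
#' @param n_roughness number of roughness-varying layers.
#' @param n_classes classes of the categorical layer.
#' @param cat_corr_length correlation length of the categorical layer
#'   (default: the finest quantitative correlation length, so land-cover
#'   patches stay small relative to the roughness mosaic).
#' @param n_species number of species.
#' @param frac_structure fraction of species with `landscape_structure`
#'   niches (the rest are `punctual`).
#' @param n_occurrences total occurrences sampled.
#' @param tail_exponent long-tail rank exponent.
#' @param window structure/mean neighborhood radius in pixels.
#' @param signal target standard deviation of each species' linear
#'   predictor; weights are scaled by the feature map's empirical sd so
#'   punctual and structure species get comparable effect sizes.
#' @param n_guilds,guild_sd optional niche guild structure, see
#'   [make_niches()].
#' @param niche_offset intercept of every niche's linear predictor, see
#'   [species_niche()].
#' @param seed integer seed; the same seed reproduces the world exactly.
#' @return A list with `stack` (expanded + filled), `raw_stack`, `niches`,
#'   `occurrences` (split), and `seed`; class `synthetic_world`.
#' @export
synthetic_world <- function(grid_size = 256, corr_lengths = c(4, 8, 32),
                            n_roughness = 3, n_classes = 5,
                            cat_corr_length = min(corr_lengths),
                            n_species = 40, frac_structure = 0.5,
                            n_occurrences = 8000, tail_exponent = 1.2,
                            window = 3, signal = 3, n_guilds = NULL,
                            guild_sd = 0.25, niche_offset = 0, seed = 1) {
  shape <- c(grid_size, grid_size)
  layers <- lapply(seq_along(corr_lengths), function(i)
    generate_grf_layer(shape, corr_lengths[i], seed = seed * 131 + i,
                       name = paste0("env", i)))
  layers <- c(layers, lapply(seq_len(n_roughness), function(i)
    generate_roughness_layer(shape, seed = seed * 577 + 89 * i,
                             name = paste0("rough", i))))
  layers <- c(layers, list(generate_categorical_layer(
    shape, n_classes, correlation_length = cat_corr_length,
    seed = seed * 131 + length(corr_lengths) + 1)))
  raw <- raster_stack(layers)
  stack <- fill_stack(expand_categorical(raw))
  niches <- make_niches(stack, n_species, frac_structure, window, signal,
                        seed = seed * 997 + 17, n_guilds = n_guilds,
                        guild_sd = guild_sd, offset = niche_offset)
  occ <- sample_occurrences(stack, niches, n_occurrences, tail_exponent,
                            seed = seed * 7919 + 3)
  occ <- split_occurrences(occ, seed = seed * 104729 + 5)
  structure(list(stack = stack, raw_stack = raw, niches = niches,
                 occurrences = occ, seed = seed),
            class = "synthetic_world")
}

#' Draw a community of niches over a stack
#'
#' Each species weights 1-2 randomly chosen quantitative layers; structure
#' species prefer the roughness-varying layers (names starting with
#' `rough`) when present, value species the remaining quantitative layers.
#' Weights are scaled so the linear predictor of the intensity has
#' standard deviation `signal` over the grid, giving all modes comparable
#' selectivity.
#'
#' @inheritParams synthetic_world
#' @param stack expanded stack.
#' @param n_species species count.
#' @param n_guilds optional number of niche guilds: when set, species
#'   weight vectors are drawn as perturbations of shared guild prototypes
#'   (ecological response groups), so rare species share their niche axis
#'   with abundant guild mates — the regime in which a jointly learnt
#'   representation can transfer knowledge to species with very few
#'   records.
#' @param guild_sd relative size of the within-guild perturbation.
#' @export
make_niches <- function(stack, n_species, frac_structure = 0.5, window = 3,
                        signal = 3, seed = 1, n_guilds = NULL,
                        guild_sd = 0.25, offset = 0) {
  quant <- names(stack$layers)[
    vapply(stack$layers, `[[`, "", "kind") == "quantitative"]
  rough <- grep("^rough", quant, value = TRUE)
  plain <- setdiff(quant, rough)
  if (length(rough) == 0) rough <- quant
  if (length(plain) == 0) plain <- quant
  n_struct <- round(n_species * frac_structure)
  modes <- c(rep("landscape_structure", n_struct),
             rep("punctual", n_species - n_struct))
  with_seed(seed, {
    modes <- sample(modes)
    guilds <- if (!is.null(n_guilds)) {
      g_mode <- sample(modes, n_guilds, replace = TRUE)
      lapply(seq_len(n_guilds), function(g) {
        pool <- if (g_mode[g] == "landscape_structure") rough else plain
        w <- stats::rnorm(length(pool))
        names(w) <- pool
        list(mode = g_mode[g], w = w)
      })
    } else NULL
    # niche directions are stratified (greedy farthest-point selection from
    # random candidates) so a small community never degenerates into
    # near-collinear niches by draw luck
    dirs <- list(
      landscape_structure = spread_directions(n_struct, length(rough)),
      punctual = spread_directions(n_species - n_struct, length(plain)))
    used <- c(landscape_structure = 0L, punctual = 0L)
    lapply(seq_len(n_species), function(s) {
      if (is.null(guilds)) {
        mode <- modes[s]
        pool <- if (mode == "landscape_structure") rough else plain
        used[mode] <<- used[mode] + 1L
        w <- dirs[[mode]][used[mode], ]
        names(w) <- pool
      } else {
        g <- guilds[[sample(length(guilds), 1)]]
        mode <- g$mode
        w <- g$w + stats::rnorm(length(g$w), sd = guild_sd * stats::sd(g$w))
      }
      # scale to the target signal sd using the mode's feature maps
      fm <- vapply(names(w), function(nm)
        as.numeric(niche_feature_map(stack$layers[[nm]]$grid, mode, window)),
        numeric(length(stack$layers[[1]]$grid)))
      sdv <- stats::sd(as.numeric(fm %*% w))
      if (sdv > 0) w <- w * signal / sdv
      species_niche(s, mode, w, window = window, base_rate = 1,
                    offset = offset)
    })
  })
}

# n unit directions in d dimensions, spread by greedy farthest-point
# selection from a larger random candidate set (max-min on the absolute
# cosine, so sign flips still count as distinct niches via the sign draw).
spread_directions <- function(n, d) {
  if (n == 0) return(matrix(0, 0, d))
  if (d == 1) return(matrix(sample(c(-1, 1), n, replace = TRUE), n, 1))
  cand <- matrix(stats::rnorm(8 * max(n, 4) * d), ncol = d)
  cand <- cand / sqrt(rowSums(cand^2))
  picked <- integer(n)
  picked[1] <- 1L
  if (n > 1) {
    dmin <- rep(Inf, nrow(cand))
    for (i in 2:n) {
      dmin <- pmin(dmin, 1 - abs(cand %*% cand[picked[i - 1], ]))
      dmin[picked[seq_len(i - 1)]] <- -Inf
      picked[i] <- which.max(dmin)
    }
  }
  cand[picked, , drop = FALSE]
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
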