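test_that("grid Moran's I matches a dense-weight brute-force oracle", {
  for (s in 1:5) {
    set.seed(s)
    g <- matrix(rnorm(36), 6, 6)
    # oracle: classic binary rook-weight Moran's I via explicit double sum
    idx <- expand.grid(r = 1:6, c = 1:6)
    W <- 1 * (abs(outer(idx$r, idx$r, "-")) + abs(outer(idx$c, idx$c, "-")) == 1)
    z <- as.numeric(g) - mean(g)
    oracle <- (length(z) / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
    expect_equal(morans_i_grid(g), oracle, tolerance = 1e-12)
  }
})

test_that("Gaussian random fields meet the spatial autocorrelation contract", {
  # white noise: Moran's I within +-0.05 of 0 (Monte-Carlo over seeds)
  iw <- vapply(1:5, function(s)
    morans_i_grid(generate_grf_layer(c(128, 128), 0, seed = s)$grid), 0)
  expect_lt(max(abs(iw)), 0.05)
  # correlation length 16: strongly autocorrelated
  is <- vapply(1:3, function(s)
    morans_i_grid(generate_grf_layer(c(128, 128), 16, seed = s)$grid), 0)
  expect_gt(min(is), 0.5)
  # zero mean, unit variance, determinism
  l1 <- generate_grf_layer(c(64, 64), 8, seed = 9)
  l2 <- generate_grf_layer(c(64, 64), 8, seed = 9)
  expect_identical(l1$grid, l2$grid)
  expect_equal(mean(l1$grid), 0, tolerance = 1e-12)
  expect_equal(stats::sd(l1$grid), 1, tolerance = 1e-12)
  expect_error(generate_grf_layer(c(0, 4), 1), "positive")
  expect_error(generate_grf_layer(c(4, 4), -1), ">= 0")
})

test_that("categorical layers have near-equal class shares and expand cleanly", {
  l <- generate_categorical_layer(c(128, 128), 2, correlation_length = 10,
                                  seed = 2)
  shares <- table(l$grid) / length(l$grid)
  expect_equal(as.numeric(shares), c(0.5, 0.5), tolerance = 0.02)
  l5 <- generate_categorical_layer(c(64, 64), 5, correlation_length = 6,
                                   seed = 3)
  expect_setequal(unique(as.numeric(l5$grid)), 1:5)
  st <- expand_categorical(raster_stack(list(l5)))
  expect_equal(n_layers(st), 5)
  expect_true(all(Reduce(`+`, lapply(st$layers, `[[`, "grid")) == 1))
  expect_identical(generate_categorical_layer(c(32, 32), 3, 4, seed = 7)$grid,
                   generate_categorical_layer(c(32, 32), 3, 4, seed = 7)$grid)
  expect_error(generate_categorical_layer(c(2, 2), 5), "pixel count")
})

test_that("box_mean matches direct window averaging", {
  set.seed(8)
  g <- matrix(rnorm(64), 8, 8)
  bm <- patchSDM:::box_mean(g, 1, 2, 1, 1)
  for (r in c(1, 4, 8)) for (cc in c(1, 5, 8)) {
    rows <- max(1, r - 1):min(8, r + 2)
    cols <- max(1, cc - 1):min(8, cc + 1)
    expect_equal(bm[r, cc], mean(g[rows, cols]), tolerance = 1e-12)
  }
})

test_that("species intensity honors the niche mode contracts", {
  st <- tiny_expanded(seed = 11, n = 16)
  quant <- names(st$layers)[1]
  # zero weights -> constant softplus(0)
  n0 <- species_niche(1, "punctual", c(a = 0))
  i0 <- species_intensity(n0, st)
  expect_true(all(abs(i0$grid - log(2)) < 1e-12))
  # structure mode on a constant layer -> softplus(0)
  cst <- raster_stack(list(raster_layer(matrix(3, 16, 16), "flat")))
  cst$expanded <- TRUE
  ns <- species_niche(2, "landscape_structure", c(flat = 2), window = 3)
  expect_true(all(abs(species_intensity(ns, cst)$grid - log(2)) < 1e-9))
  # structure intensity is invariant to additive shifts of the layer
  set.seed(1)
  g <- matrix(rnorm(256), 16, 16)
  mk <- function(gg) {
    s <- raster_stack(list(raster_layer(gg, "q")))
    s$expanded <- TRUE
    species_intensity(species_niche(3, "landscape_structure", c(q = 1.5),
                                    window = 3), s)$grid
  }
  expect_equal(mk(g), mk(g + 7), tolerance = 1e-9)
  # ... and to rescaling (the statistic is a correlation)
  expect_equal(mk(g), mk(g * 3), tolerance = 1e-9)
  # unknown mode is rejected at niche construction
  expect_error(species_niche(4, "landscape_wiggle", c(a = 1)))
})

test_that("roughness layers vary arrangement but not the value distribution", {
  l <- generate_roughness_layer(c(128, 128), seed = 5)
  expect_equal(mean(l$grid), 0, tolerance = 0.05)
  expect_equal(stats::sd(l$grid), 1, tolerance = 0.05)
  # the local autocorrelation statistic genuinely varies across the map
  lm <- patchSDM:::local_morans(l$grid, 3)
  expect_gt(stats::sd(lm), 0.1)
  expect_identical(generate_roughness_layer(c(32, 32), seed = 5)$grid,
                   generate_roughness_layer(c(32, 32), seed = 5)$grid)
})

test_that("occurrence sampling follows intensity and the rank law", {
  st <- tiny_expanded(seed = 21, n = 48)
  quant <- names(st$layers)[1]
  # tail 0 with uniform base rates: counts uniform within multinomial noise
  nich <- lapply(1:5, function(s)
    species_niche(s, "punctual", stats::setNames(0, quant)))
  occ <- sample_occurrences(st, nich, 2000, tail_exponent = 0, seed = 3)
  cnt <- table(occ$species_id)
  expect_gt(stats::chisq.test(cnt)$p.value, 0.001)
  # importance sampling: strong positive weight concentrates occurrences
  # where the layer is high
  np <- species_niche(9, "punctual", stats::setNames(3 / stats::sd(st$layers[[quant]]$grid), quant))
  occ2 <- sample_occurrences(st, list(np), 400, tail_exponent = 0, seed = 4)
  vals <- vapply(seq_len(nrow(occ2)), function(i)
    extract_punctual_vector(c(occ2$lon[i], occ2$lat[i]), st)$values[[quant]], 0)
  expect_gt(mean(vals), mean(st$layers[[quant]]$grid) + 0.25)
  # determinism
  occ3 <- sample_occurrences(st, list(np), 50, 0, seed = 4)
  occ4 <- sample_occurrences(st, list(np), 50, 0, seed = 4)
  expect_identical(occ3$lon, occ4$lon)
})

test_that("long-tail exponent is recovered from simulated counts", {
  st <- tiny_expanded(seed = 31, n = 48)
  quant <- names(st$layers)[1]
  nich <- lapply(1:100, function(s)
    species_niche(s, "punctual", stats::setNames(0, quant)))
  occ <- sample_occurrences(st, nich, 5000, tail_exponent = 1.2, seed = 8)
  cnt <- sort(table(occ$species_id), decreasing = TRUE)
  cnt <- cnt[cnt >= 3]   # regression over the resolvable part of the tail
  fit <- stats::lm(log(as.numeric(cnt)) ~ log(seq_along(cnt)))
  expect_equal(unname(stats::coef(fit)[2]), -1.2, tolerance = 0.2)
})

test_that("occurrence splitting matches the 90/10 plus 10 percent protocol", {
  occ <- structure(data.frame(lon = runif(1000), lat = runif(1000),
                              species_id = sample(5, 1000, TRUE),
                              partition = NA_character_),
                   class = c("occurrence_set", "data.frame"))
  sp <- split_occurrences(occ, seed = 2)
  expect_equal(sum(sp$partition == "test"), 100)
  expect_equal(sum(sp$partition == "validation"), 90)
  expect_equal(sum(sp$partition == "train"), 810)
  expect_identical(split_occurrences(occ, seed = 2)$partition, sp$partition)
  # a species' sole record may land in test (unstratified split)
  occ$species_id[1] <- 99L
  found <- FALSE
  for (s in 1:50) {
    sp2 <- split_occurrences(occ, seed = s)
    if (sp2$partition[1] == "test") { found <- TRUE; break }
  }
  expect_true(found)
  expect_error(split_occurrences(occ, test_fraction = 0), "test_fraction")
})

test_that("synthetic worlds are exactly reproducible under their seed", {
  w1 <- tiny_world(seed = 17, n_occ = 120, grid = 48)
  w2 <- tiny_world(seed = 17, n_occ = 120, grid = 48)
  expect_identical(w1$occurrences, w2$occurrences)
  expect_identical(w1$stack$layers[[1]]$grid, w2$stack$layers[[1]]$grid)
})
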