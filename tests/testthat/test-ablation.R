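random_tensor <- function(seed = 1, ps = 8, L = 3) {
  set.seed(seed)
  structure(list(values = array(rnorm(ps * ps * L), c(ps, ps, L)),
                 center = c(0, 0), layer_names = paste0("l", seq_len(L))),
            class = "env_tensor")
}

test_that("random rotation preserves per-layer value multisets and shape", {
  x <- random_tensor(1)
  for (key in 1:20) {
    r <- rotate_random(x, key)
    expect_equal(dim(r$values), dim(x$values))
    for (l in 1:3)
      expect_equal(sort(as.numeric(r$values[, , l])),
                   sort(as.numeric(x$values[, , l])))
    # the same rotation is applied to every layer: layer-wise relationships
    # at the center pixel are preserved under the even-patch convention
    expect_identical(rotate_random(x, key)$values, r$values)
  }
  # 180-degree rotation applied twice is the identity
  expect_equal(patchSDM:::rot90m(patchSDM:::rot90m(x$values[, , 1], 2), 2),
               x$values[, , 1])
  # non-square patch is rejected
  bad <- structure(list(values = array(0, c(2, 3, 1)), center = c(0, 0),
                        layer_names = "a"), class = "env_tensor")
  expect_error(rotate_random(bad, 1), "square")
})

test_that("rotation draws are uniform over the four directions", {
  x <- random_tensor(2, ps = 4, L = 1)
  rots <- lapply(0:3, function(q) patchSDM:::rot90m(x$values[, , 1], q))
  draw <- vapply(1:10000, function(key) {
    v <- rotate_random(x, key)$values[, , 1]
    which(vapply(rots, function(r) isTRUE(all.equal(r, v)), TRUE)) - 1L
  }, 0L)
  freq <- tabulate(draw + 1L, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("random permutation destroys structure but keeps the multiset", {
  x <- random_tensor(3)
  p <- permute_random(x, 7)
  for (l in 1:3) {
    expect_equal(mean(p$values[, , l]), mean(x$values[, , l]))
    expect_equal(stats::sd(as.numeric(p$values[, , l])),
                 stats::sd(as.numeric(x$values[, , l])))
    expect_equal(sort(as.numeric(p$values[, , l])),
                 sort(as.numeric(x$values[, , l])))
  }
  # constant layer is unchanged
  cst <- structure(list(values = array(5, c(4, 4, 1)), center = c(0, 0),
                        layer_names = "c"), class = "env_tensor")
  expect_equal(permute_random(cst, 3)$values, cst$values)
  # determinism per key
  expect_identical(permute_random(x, 7)$values, p$values)
})

test_that("permutation collapses the spatial autocorrelation of smooth patches", {
  g <- generate_grf_layer(c(64, 64), 16, seed = 4)$grid
  patch <- g[1:32, 1:32]
  x <- structure(list(values = array(patch, c(32, 32, 1)), center = c(0, 0),
                      layer_names = "g"), class = "env_tensor")
  expect_gt(morans_i_grid(patch), 0.5)
  ip <- vapply(1:5, function(k)
    morans_i_grid(permute_random(x, k)$values[, , 1]), 0)
  expect_lt(max(abs(ip)), 0.05)
})

test_that("mean collapse averages, is idempotent and order-insensitive", {
  x <- structure(list(values = array(c(1, 5, 3, 7), c(2, 2, 1)),
                      center = c(0, 0), layer_names = "m"),
                 class = "env_tensor")
  m <- mean_collapse(x)
  expect_true(all(m$values == 4))
  expect_equal(mean_collapse(m)$values, m$values)
  y <- random_tensor(5)
  expect_equal(mean_collapse(permute_random(y, 2))$values,
               mean_collapse(y)$values)
  expect_equal(mean_collapse(rotate_random(y, 2))$values,
               mean_collapse(y)$values)
})

test_that("structure standardization deletes location and scale only", {
  x <- structure(list(values = array(c(0, 0, 2, 2), c(2, 2, 1)),
                      center = c(0, 0), layer_names = "s"),
                 class = "env_tensor")
  s <- standardize_structure(x)
  expect_equal(s$values[, , 1], matrix(c(-1, -1, 1, 1), 2, 2))
  y <- random_tensor(6)
  sy <- standardize_structure(y)
  for (l in 1:3) {
    expect_equal(mean(sy$values[, , l]), 0, tolerance = 1e-9)
    n <- length(sy$values[, , l])
    expect_equal(stats::sd(as.numeric(sy$values[, , l])) * sqrt((n - 1) / n),
                 1, tolerance = 1e-9)
    # pixel rank order within a layer is unchanged
    expect_equal(order(sy$values[, , l]), order(y$values[, , l]))
  }
  cst <- structure(list(values = array(5, c(3, 3, 1)), center = c(0, 0),
                        layer_names = "c"), class = "env_tensor")
  expect_true(all(standardize_structure(cst)$values == 0))
})

test_that("apply_ablation dispatches on the spec and is reproducible", {
  x <- random_tensor(8)
  expect_identical(apply_ablation(x, ablation_spec("none"), 1, 1)$values,
                   x$values)
  s1 <- apply_ablation(x, ablation_spec("permutation", seed = 3), 2, 5)
  s2 <- apply_ablation(x, ablation_spec("permutation", seed = 3), 2, 5)
  expect_identical(s1$values, s2$values)
  s3 <- apply_ablation(x, ablation_spec("permutation", seed = 3), 2, 6)
  expect_false(identical(s1$values, s3$values))
  expect_error(ablation_spec("blur"))
})

test_that("the batched transform path matches the per-tensor kernels", {
  set.seed(9)
  C <- 3; ps <- 6; B <- 4
  xb <- array(rnorm(C * ps * ps * B), c(C, ps, ps, B))
  norm <- list(mu = numeric(C), sd = rep(1, C))
  for (kind in c("mean", "standardize")) {
    got <- patchSDM:::prep_raw_batch(xb, kind, 1L, 1L, 1:B, norm)
    for (b in 1:B) {
      xt <- structure(list(values = aperm(got[, , , b], c(2, 3, 1)),
                           center = c(0, 0), layer_names = paste0("l", 1:C)),
                      class = "env_tensor")
      ref <- aperm(xb[, , , b], c(2, 3, 1))
      ref_t <- if (kind == "mean") {
        vapply(1:C, function(l) matrix(mean(ref[, , l]), ps, ps),
               matrix(0, ps, ps))
      } else {
        vapply(1:C, function(l) {
          sl <- ref[, , l]
          (sl - mean(sl)) / sqrt(mean(sl^2) - mean(sl)^2)
        }, matrix(0, ps, ps))
      }
      expect_equal(xt$values, array(ref_t, c(ps, ps, C)), tolerance = 1e-12)
    }
  }
  # rotation keeps multisets per layer and sample; permutation likewise
  for (kind in c("rotation", "permutation")) {
    got <- patchSDM:::prep_raw_batch(xb, kind, 1L, 2L, 1:B, norm)
    for (b in 1:B) for (l in 1:C)
      expect_equal(sort(as.numeric(got[l, , , b])),
                   sort(as.numeric(xb[l, , , b])))
  }
})
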