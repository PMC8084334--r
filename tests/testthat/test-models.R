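test_that("softmax head matches closed forms and brute-force evaluation", {
  head <- list(W = matrix(0, 4, 3), b = rep(1, 4))
  expect_equal(softmax_head(c(1, 2, 3), head), rep(0.25, 4))
  head2 <- list(W = matrix(c(0, 0), 2, 1), b = c(0, log(3)))
  expect_equal(softmax_head(5, head2), c(0.25, 0.75))
  # shift invariance of the logits
  head3 <- list(W = matrix(rnorm(6), 3, 2), b = c(1, -1, 2))
  head3b <- head3; head3b$b <- head3$b + 100
  z <- rnorm(2)
  expect_equal(softmax_head(z, head3), softmax_head(z, head3b))
  # brute force without max-subtraction, to 1e-10, on random instances
  for (s in 1:25) {
    set.seed(s)
    hd <- list(W = matrix(rnorm(12, sd = 2), 4, 3), b = rnorm(4))
    zz <- rnorm(3)
    ex <- exp(hd$W %*% zz + hd$b)
    expect_equal(softmax_head(zz, hd), as.numeric(ex / sum(ex)),
                 tolerance = 1e-10)
  }
  expect_error(softmax_head(c(1, 2), head), "dimension")
  expect_error(softmax_head(c(Inf, 0, 0), head), "non-finite")
})

test_that("cross entropy matches the multinomial log loss", {
  expect_equal(cross_entropy(c(1, 0, 0), 1), 0)
  m <- 4520
  expect_equal(cross_entropy(rep(1 / m, m), 17), log(m), tolerance = 1e-9)
  # monotone: more mass on the truth means lower loss
  expect_lt(cross_entropy(c(0.7, 0.2, 0.1), 1),
            cross_entropy(c(0.5, 0.3, 0.2), 1))
  # floored at 1e-12 rather than infinite
  expect_equal(cross_entropy(c(0, 1), 1), -log(1e-12))
  # batch form averages over observations
  P <- cbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(cross_entropy(P, c(1, 2)), mean(-log(c(0.5, 0.75))))
})

test_that("the learning-rate schedule reproduces the reference policy", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 0.1)
  expect_equal(lr_schedule(89, cfg), 0.1)
  expect_equal(lr_schedule(100, cfg), 0.01)
  expect_equal(lr_schedule(150, cfg), 1e-4)
  expect_equal(lr_schedule(170, cfg), 1e-5)
  expect_equal(lr_schedule(400, cfg), 1e-5)
  expect_error(train_config(lr_drop_epochs = c(10, 10)), "increasing")
})

test_that("analytic gradients match finite differences", {
  set.seed(2)
  C <- 3; H <- 8; B <- 5; m <- 4
  x <- array(rnorm(C * H * H * B), c(C, H, H, B))
  mom <- matrix(rnorm(2 * C * B), 2 * C, B)
  y <- sample(m, B, replace = TRUE)
  for (ro in c("gap", "gap_center")) {
    params <- patchSDM:::nn_init(c(4, 6), feature_dim = 7, c_in = C, m = m,
                                 seed = 3, readout = ro)
    loss_fn <- function(p) {
      f <- patchSDM:::nn_forward(p, x, NULL, mom)
      cross_entropy(patchSDM:::softmax_cols(f$logits), y)
    }
    f <- patchSDM:::nn_forward(params, x, NULL, mom)
    P <- patchSDM:::softmax_cols(f$logits)
    dl <- P
    dl[cbind(y, seq_len(B))] <- dl[cbind(y, seq_len(B))] - 1
    dl <- dl / B
    g <- patchSDM:::nn_backward(params, f, dl, NULL)
    eps <- 1e-6
    for (piece in list(c("conv", 1), c("conv", 2), "feat", "head")) {
      get <- function(p) if (length(piece) == 2)
        p$conv[[as.integer(piece[2])]]$W else p[[piece]]$W
      set <- function(p, v) {
        if (length(piece) == 2) p$conv[[as.integer(piece[2])]]$W <- v
        else p[[piece]]$W <- v
        p
      }
      ga <- if (length(piece) == 2) g$conv[[as.integer(piece[2])]]$W
            else g[[piece]]$W
      idx <- sample(length(get(params)), 8)
      for (i in idx) {
        pp <- params; v <- get(pp); v[i] <- v[i] + eps; pp <- set(pp, v)
        pm <- params; v <- get(pm); v[i] <- v[i] - eps; pm <- set(pm, v)
        expect_equal((loss_fn(pp) - loss_fn(pm)) / (2 * eps), ga[i],
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("training honors the validation and checkpoint contracts", {
  w <- tiny_world(seed = 7, n_species = 5, n_occ = 260, grid = 48)
  cfg <- train_config(initial_lr = 0.05, lr_drop_epochs = c(100),
                      max_epochs = 6, validation_period = 5, batch_size = 64,
                      checkpoint_k = 2, dropout = 0.1, seed = 2)
  mdl <- train_sdm(cnn_sdm(patch_size = 8, channels = c(6, 8)),
                   w$occurrences, w$stack, cfg)
  # validation is evaluated only at epochs that are multiples of 5
  expect_true(all(is.na(mdl$history$val_score[mdl$history$epoch %% 5 != 0])))
  expect_true(all(!is.na(mdl$history$val_score[mdl$history$epoch %% 5 == 0])))
  # the checkpoint's score is the maximum over the history
  expect_equal(mdl$best_val_score, max(mdl$history$val_score, na.rm = TRUE))
  expect_equal(mdl$history$lr[1], 0.05)
})

test_that("a one-species problem is trivially separable", {
  w <- tiny_world(seed = 9, n_species = 2, n_occ = 120, grid = 48)
  occ <- w$occurrences
  occ$species_id <- 1L   # degenerate single-species labels
  cfg <- fast_config(seed = 1, epochs = 3)
  mdl <- train_sdm(cnn_sdm(patch_size = 8, channels = c(4)),
                   occ, w$stack, cfg)
  expect_lt(utils::tail(mdl$history$train_loss, 1), 1e-6)
})

test_that("prediction bundles are valid and deterministic", {
  w <- tiny_world(seed = 12, n_species = 5, n_occ = 240, grid = 48)
  cfg <- fast_config(seed = 4, epochs = 2)
  mdl <- train_sdm(cnn_sdm(patch_size = 8, channels = c(6, 8)),
                   w$occurrences, w$stack, cfg)
  test <- w$occurrences[w$occurrences$partition == "test", ][1:6, ]
  b <- predict(mdl, test, w$stack)
  expect_equal(rowSums(b$probabilities), rep(1, 6), tolerance = 1e-9)
  expect_equal(dim(b$logits), c(6, 5))
  # two identical points give identical predictions
  dup <- test[c(1, 1), ]
  bd <- predict(mdl, dup, w$stack)
  expect_equal(bd$probabilities[1, ], bd$probabilities[2, ])
  # unfitted model refuses to predict
  expect_error(predict(cnn_sdm(), test, w$stack), "not fitted")
  # retraining with the same seed reproduces the predictions exactly
  mdl2 <- train_sdm(cnn_sdm(patch_size = 8, channels = c(6, 8)),
                    w$occurrences, w$stack, cfg)
  expect_equal(predict(mdl2, test, w$stack)$logits, b$logits)
})

test_that("the punctual deep model ignores non-center pixels", {
  w <- tiny_world(seed = 13, n_species = 4, n_occ = 220, grid = 48)
  cfg <- fast_config(seed = 5, epochs = 2)
  dnn <- train_sdm(dnn_sdm(patch_size = 8, channels = c(6, 8)),
                   w$occurrences, w$stack, cfg)
  test <- w$occurrences[w$occurrences$partition == "test", ][1:4, ]
  b1 <- predict(dnn, test, w$stack)
  # scramble every stack layer while keeping the center-pixel values of the
  # test points: the punctual model must not notice
  st2 <- w$stack
  for (nm in names(st2$layers)) {
    l <- st2$layers[[nm]]
    keep <- vapply(seq_len(nrow(test)), function(i)
      patchSDM:::point_to_pixel(c(test$lon[i], test$lat[i]), l), numeric(2))
    g <- matrix(stats::rnorm(length(l$grid), sd = 3), nrow(l$grid))
    g[t(keep)] <- l$grid[t(keep)]
    st2$layers[[nm]]$grid <- g
  }
  b2 <- predict(dnn, test, st2)
  expect_equal(b1$probabilities, b2$probabilities, tolerance = 1e-9)
})

test_that("checkpoints round-trip through serialization", {
  w <- tiny_world(seed = 14, n_species = 3, n_occ = 150, grid = 48)
  mdl <- train_sdm(cnn_sdm(patch_size = 8, channels = c(4)),
                   w$occurrences, w$stack, fast_config(epochs = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(mdl, path)
  back <- load_checkpoint(path)
  test <- w$occurrences[w$occurrences$partition == "test", ][1:3, ]
  expect_equal(predict(back, test, w$stack)$logits,
               predict(mdl, test, w$stack)$logits)
  expect_identical(back$transform$kind, mdl$transform$kind)
})
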