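#' Punctual tree baselines: random forest and boosted trees
#'
#' Classical punctual SDM baselines operating on the environmental vector
#' at the occurrence point. Implemented from first principles (no tree
#' library is assumed): greedy binary CART with the Gini criterion for
#' classification and variance reduction for regression, bagged with
#' per-node feature subsampling for the random forest, and Friedman's
#' multiclass gradient boosting with shallow regression trees for the
#' boosted-trees model. Reference hyperparameters are the defaults:
#' 100 trees of maximum depth 16 for the forest, tree depth 2 for boosting.
#'
#' @name baselines
NULL

## ---- generic CART ----------------------------------------------------------

# Grow one tree. X: n x p matrix; for classification y is an integer class
# in 1..K and leaves hold class proportions; for regression y is numeric
# and leaves hold leaf_value(y_in_leaf). Returns parallel node vectors.
grow_tree <- function(X, y, K = NULL, max_depth = 16, mtry = ncol(X),
                      min_split = 2, leaf_value = NULL) {
  n_nodes <- 0L
  feature <- integer(); threshold <- numeric()
  left <- integer(); right <- integer(); value <- list()
  new_node <- function() {
    n_nodes <<- n_nodes + 1L
    feature[n_nodes] <<- NA_integer_; threshold[n_nodes] <<- NA_real_
    left[n_nodes] <<- 0L; right[n_nodes] <<- 0L; value[n_nodes] <<- list(NULL)
    n_nodes
  }
  classification <- !is.null(K)
  node_value <- if (classification)
    function(idx) tabulate(y[idx], K) / length(idx)
  else
    function(idx) leaf_value(y[idx])
  queue <- list(list(id = new_node(), idx = seq_len(nrow(X)), depth = 0L))
  while (length(queue) > 0) {
    nd <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    idx <- nd$idx
    make_leaf <- nd$depth >= max_depth || length(idx) < min_split ||
      (classification && length(unique(y[idx])) == 1L) ||
      (!classification && stats::var(y[idx]) == 0)
    sp <- NULL
    if (!make_leaf) {
      feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
      sp <- best_split(X, y, idx, feats, K)
      if (is.null(sp)) make_leaf <- TRUE
    }
    if (make_leaf) {
      value[[nd$id]] <- node_value(idx)
    } else {
      feature[nd$id] <- sp$feature; threshold[nd$id] <- sp$threshold
      go_left <- X[idx, sp$feature] <= sp$threshold
      l <- new_node(); r <- new_node()
      left[nd$id] <- l; right[nd$id] <- r
      queue[[length(queue) + 1L]] <- list(id = l, idx = idx[go_left],
                                          depth = nd$depth + 1L)
      queue[[length(queue) + 1L]] <- list(id = r, idx = idx[!go_left],
                                          depth = nd$depth + 1L)
    }
  }
  list(feature = feature, threshold = threshold, left = left, right = right,
       value = value, classification = classification)
}

# Best (feature, threshold) over candidate features; NULL if no valid split.
best_split <- function(X, y, idx, feats, K) {
  out <- best_split_cpp(X, idx, feats, as.numeric(y),
                        if (is.null(K)) 0L else as.integer(K))
  if (out$feature < 0) NULL else out[c("feature", "threshold")]
}

# Route all rows of X through a tree; returns the leaf value per row
# (matrix n x K for classification, numeric for regression).
predict_tree <- function(tree, X, K = NULL) {
  n <- nrow(X)
  node <- rep(1L, n)
  repeat {
    internal <- !is.na(tree$feature[node])
    if (!any(internal)) break
    ii <- which(internal)
    f <- tree$feature[node[ii]]
    thr <- tree$threshold[node[ii]]
    goes_left <- X[cbind(ii, f)] <= thr
    node[ii] <- ifelse(goes_left, tree$left[node[ii]], tree$right[node[ii]])
  }
  if (tree$classification) {
    out <- matrix(0, n, K)
    for (nd in unique(node))
      out[node == nd, ] <- matrix(tree$value[[nd]], sum(node == nd), K,
                                  byrow = TRUE)
    out
  } else {
    vapply(node, function(nd) tree$value[[nd]], 0)
  }
}

## ---- random forest ---------------------------------------------------------

#' Fit the random-forest baseline
#'
#' Bagged Gini CARTs with per-node feature subsampling
#' (`mtry = floor(sqrt(p))` by default), returning averaged leaf class
#' proportions as categorical probabilities over all species.
#'
#' @param vectors `n x p` matrix of punctual environmental vectors.
#' @param labels species identifier per row.
#' @param n_trees number of trees (default 100).
#' @param max_depth maximum tree depth (default 16).
#' @param mtry features tried per split.
#' @param seed integer seed.
#' @param species label space; defaults to the species present in
#'   `labels`, but should be the full species list when some species occur
#'   only in the test set (they then get zero probability everywhere).
#' @return A fitted object of classes `rf_baseline`, `sdm_baseline`.
#' @export
fit_rf_baseline <- function(vectors, labels, n_trees = 100, max_depth = 16,
                            mtry = NULL, seed = 1,
                            species = sort(unique(labels))) {
  vectors <- as.matrix(vectors)
  if (length(unique(labels)) < 2) stop("need at least two species to fit a classifier")
  y <- match(labels, species)
  K <- length(species)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(vectors))))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(t) {
    bidx <- sample.int(nrow(vectors), replace = TRUE)
    grow_tree(vectors[bidx, , drop = FALSE], y[bidx], K = K,
              max_depth = max_depth, mtry = mtry)
  }))
  structure(list(trees = trees, species = species, K = K,
                 n_trees = n_trees, max_depth = max_depth, mtry = mtry),
            class = c("rf_baseline", "sdm_baseline"))
}

#' Fit the boosted-trees baseline
#'
#' Friedman multiclass gradient boosting: per round and per species, a
#' depth-limited regression tree is fitted to the softmax residuals and its
#' leaves take the standard Newton-style values. The reference depth is 2.
#'
#' @inheritParams fit_rf_baseline
#' @param tree_depth maximum depth of each regression tree (default 2).
#' @param n_rounds boosting rounds.
#' @param learning_rate shrinkage per round.
#' @export
fit_bt_baseline <- function(vectors, labels, tree_depth = 2, n_rounds = 100,
                            learning_rate = 0.3, seed = 1,
                            species = sort(unique(labels))) {
  vectors <- as.matrix(vectors)
  if (length(unique(labels)) < 2) stop("need at least two species to fit a classifier")
  y <- match(labels, species)
  K <- length(species)
  n <- nrow(vectors)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  Fm <- matrix(0, n, K)
  leaf_fun <- function(r) {
    den <- sum(abs(r) * (1 - abs(r)))
    if (den < 1e-12) 0 else (K - 1) / K * sum(r) / den
  }
  rounds <- with_seed(seed, lapply(seq_len(n_rounds), function(rd) {
    P <- exp(Fm - apply(Fm, 1, max))
    P <- P / rowSums(P)
    lapply(seq_len(K), function(k) {
      r <- Y[, k] - P[, k]
      tr <- grow_tree(vectors, r, K = NULL, max_depth = tree_depth,
                      leaf_value = leaf_fun)
      Fm[, k] <<- Fm[, k] + learning_rate * predict_tree(tr, vectors)
      tr
    })
  }))
  structure(list(rounds = rounds, species = species, K = K,
                 learning_rate = learning_rate, tree_depth = tree_depth),
            class = c("bt_baseline", "sdm_baseline"))
}

#' Predict with a tree baseline
#'
#' @param object a fitted baseline.
#' @param newdata either an `n x p` matrix of punctual vectors, or a data
#'   frame of points (`lon`, `lat`) together with `stack`.
#' @param stack optional raster stack used to extract punctual vectors from
#'   points.
#' @param ... unused.
#' @return A `prediction_bundle` with categorical `probabilities`
#'   (`score_type = "probability"`: trees have no logits, so AUC/TSS use
#'   the probabilities directly).
#' @export
predict.sdm_baseline <- function(object, newdata, stack = NULL, ...) {
  X <- baseline_matrix(newdata, stack)
  P <- if (inherits(object, "rf_baseline")) {
    acc <- matrix(0, nrow(X), object$K)
    for (tr in object$trees) acc <- acc + predict_tree(tr, X, object$K)
    acc / length(object$trees)
  } else {
    Fm <- matrix(0, nrow(X), object$K)
    for (rdtrees in object$rounds)
      for (k in seq_len(object$K))
        Fm[, k] <- Fm[, k] + object$learning_rate * predict_tree(rdtrees[[k]], X)
    P <- exp(Fm - apply(Fm, 1, max))
    P / rowSums(P)
  }
  structure(list(z = NULL, logits = log(pmax(P, 1e-12)), probabilities = P,
                 species = object$species, score_type = "probability"),
            class = "prediction_bundle")
}

baseline_matrix <- function(newdata, stack) {
  if (is.data.frame(newdata) && all(c("lon", "lat") %in% names(newdata))) {
    if (is.null(stack)) stop("stack required to extract vectors from points")
    t(vapply(seq_len(nrow(newdata)), function(i)
      extract_punctual_vector(c(newdata$lon[i], newdata$lat[i]), stack)$values,
      numeric(length(stack$layers))))
  } else as.matrix(newdata)
}

#' Punctual design matrix of an occurrence set
#'
#' @param occ occurrence data frame with `lon`, `lat`.
#' @param stack expanded, filled stack.
#' @export
punctual_matrix <- function(occ, stack) baseline_matrix(occ, stack)
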