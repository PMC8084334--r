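#' Set-valued and pseudo-absence evaluation metrics
#'
#' The primary metric family ranks, for each test observation, the true
#' species within the model's sorted categorical probabilities: the top-k
#' accuracy `A_k` is the fraction of observations whose true species ranks
#' within the top k; `SA_{k,s}` averages the indicator within species s, and
#' `MSA_k` averages `SA_{k,s}` over species so frequent species carry no
#' extra weight. AUC and TSS are computed per species against weighted
#' pseudo-absences drawn from other species' occurrences.
#'
#' @name evaluation
NULL

# Pessimistic competition rank of the truth per observation: the true
# species is ranked after every species with an equal score, so a constant
# predictor gets rank m.
rank_matrix <- function(P, truths) {
  pt <- P[cbind(seq_len(nrow(P)), truths)]
  rowSums(P >= pt)
}

#' Rank of the true species in each prediction
#'
#' @param bundle a `prediction_bundle` (or any list with a
#'   `probabilities` matrix and `species` labels).
#' @param truths vector of true species identifiers, one per observation
#'   (row of the probability matrix).
#' @return Integer vector of ranks `r_i` in `1..m` (class `rank_table`,
#'   with the truths as attribute). Ties are resolved pessimistically.
#' @export
compute_ranks <- function(bundle, truths) {
  P <- bundle$probabilities
  ti <- match(truths, bundle$species)
  if (anyNA(ti)) stop("truth outside the model's label space")
  stopifnot(length(ti) == nrow(P))
  structure(rank_matrix(P, ti), truths = truths, class = "rank_table")
}

#' Top-k accuracy over all test observations
#'
#' @param ranks a `rank_table` (or bare integer ranks).
#' @param k set size (>= 1).
#' @export
topk_accuracy <- function(ranks, k) {
  if (length(ranks) == 0) stop("empty test set")
  stopifnot(k >= 1)
  mean(ranks <= k)
}

#' Per-species and mean per-species top-k accuracy
#'
#' `SA_{k,s}` is the mean of the top-k indicator within species `s`;
#' `MSA_k` is the unweighted mean of `SA_{k,s}` over species present in the
#' test set, so duplicating a species' observations leaves it unchanged.
#'
#' @param ranks a `rank_table` carrying its truths, or bare ranks combined
#'   with `truths`.
#' @param k set size.
#' @param truths species labels (unnecessary if `ranks` is a `rank_table`).
#' @return List with `sa` (named per-species accuracies) and `msa`.
#' @export
mean_species_topk <- function(ranks, k, truths = attr(ranks, "truths")) {
  stopifnot(!is.null(truths), length(truths) == length(ranks))
  sa <- tapply((ranks <= k) * 1, truths, mean)
  list(sa = sa, msa = mean(sa))
}

mean_species_topk_from_ranks <- function(ranks, truths, k) {
  mean(tapply((ranks <= k) * 1, truths, mean))
}

#' Accuracy curves over a range of k
#'
#' @param ranks a `rank_table`.
#' @param ks integer vector of k values.
#' @return data frame with columns `k`, `a_k`, `msa_k`.
#' @export
accuracy_curves <- function(ranks, ks) {
  truths <- attr(ranks, "truths")
  data.frame(k = ks,
             a_k = vapply(ks, function(k) topk_accuracy(ranks, k), 0),
             msa_k = vapply(ks, function(k)
               mean_species_topk(ranks, k, truths)$msa, 0))
}

#' Weighted pseudo-absence draw
#'
#' For each species, one pseudo-absence per presence is sampled without
#' replacement from the other species' test occurrences, each occurrence
#' weighted by the inverse of its species' total count in the test set (so
#' every other species carries total weight 1 and frequent species are not
#' over-represented; this is equivalent to first drawing a species uniformly
#' and then one of its occurrences).
#'
#' @param truths species identifier of every test observation.
#' @param seed integer seed.
#' @return A `pseudo_absence_draw`: named list per species with `presence`
#'   and `absence` observation indices.
#' @export
draw_pseudo_absences <- function(truths, seed = 1) {
  species <- sort(unique(truths))
  if (length(species) < 2) stop("need at least two species in the test set")
  counts <- table(truths)
  w_all <- 1 / as.numeric(counts[as.character(truths)])
  with_seed(seed, {
    draw <- lapply(species, function(s) {
      pres <- which(truths == s)
      cand <- which(truths != s)
      if (length(pres) > length(cand))
        stop("species ", s, ": more presences than available pseudo-absences")
      abs_idx <- cand[sample.int(length(cand), length(pres),
                                 prob = w_all[cand])]
      list(presence = pres, absence = abs_idx)
    })
    names(draw) <- as.character(species)
    structure(draw, class = "pseudo_absence_draw")
  })
}

#' Mann-Whitney AUC of one species
#'
#' Probability that a presence scores above a pseudo-absence; ties count
#' one half.
#'
#' @param presence_scores,absence_scores numeric score vectors.
#' @export
species_auc <- function(presence_scores, absence_scores) {
  np <- length(presence_scores); na <- length(absence_scores)
  stopifnot(np >= 1, na >= 1)
  r <- rank(c(presence_scores, absence_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Per-species AUC report over a pseudo-absence draw
#'
#' @param scores `n x m` score matrix (logits for neural models,
#'   categorical probabilities for tree baselines).
#' @param species column labels of `scores`.
#' @param draw a [draw_pseudo_absences()] result.
#' @return List with per-species `auc` and the mean `ms_auc`.
#' @export
ms_auc <- function(scores, species, draw) {
  auc <- vapply(names(draw), function(s) {
    col <- match(as_species_type(s, species), species)
    species_auc(scores[draw[[s]]$presence, col],
                scores[draw[[s]]$absence, col])
  }, 0)
  list(auc = auc, ms_auc = mean(auc))
}

as_species_type <- function(s, species) {
  if (is.numeric(species)) as.numeric(s) else s
}

#' Per-species TSS with min-max scaling and a global threshold search
#'
#' Each species' scores are min-max scaled over all test observations
#' (constant scores map to 0.5). The true skill statistic
#' (sensitivity + specificity - 1) is evaluated on a grid of 101 thresholds
#' in `[0, 1]` (prediction positive when the scaled score >= threshold);
#' one global threshold maximizing the species-mean TSS is retained, and
#' `MS_TSS` is that maximum.
#'
#' @inheritParams ms_auc
#' @param thresholds threshold grid (default 101 values in `[0, 1]`).
#' @return List with the `tss` per species at the chosen `threshold`,
#'   `ms_tss`, and the full `grid` of species-mean TSS per threshold.
#' @export
ms_tss <- function(scores, species, draw, thresholds = seq(0, 1, length.out = 101)) {
  scaled <- apply(scores, 2, function(x) {
    lo <- min(x); hi <- max(x)
    if (hi > lo) (x - lo) / (hi - lo) else rep(0.5, length(x))
  })
  tss_mat <- vapply(names(draw), function(s) {
    col <- match(as_species_type(s, species), species)
    ps <- scaled[draw[[s]]$presence, col]
    as_ <- scaled[draw[[s]]$absence, col]
    vapply(thresholds, function(t)
      mean(ps >= t) + mean(as_ < t) - 1, 0)
  }, numeric(length(thresholds)))
  grid <- rowMeans(tss_mat)
  best <- which.max(grid)
  list(tss = tss_mat[best, ], threshold = thresholds[best],
       ms_tss = grid[best], grid = grid)
}

#' Full evaluation report for a prediction bundle
#'
#' Ranks, accuracy curves, and the pseudo-absence AUC/TSS protocol. The
#' score fed to AUC/TSS follows the bundle's `score_type`: logits for
#' neural models, categorical probabilities for tree baselines.
#'
#' @param bundle a `prediction_bundle` for the test observations.
#' @param truths true species of each test observation.
#' @param ks k values of the accuracy curves.
#' @param seed seed of the pseudo-absence draw.
#' @return An `evaluation_report` list.
#' @export
evaluate_sdm <- function(bundle, truths, ks = c(1, 5, 10, 30), seed = 1) {
  ranks <- compute_ranks(bundle, truths)
  curves <- accuracy_curves(ranks, ks)
  draw <- draw_pseudo_absences(truths, seed)
  scores <- if (identical(bundle$score_type, "logit")) bundle$logits
            else bundle$probabilities
  auc <- ms_auc(scores, bundle$species, draw)
  tss <- ms_tss(scores, bundle$species, draw)
  structure(list(ranks = ranks, curves = curves,
                 sa = mean_species_topk(ranks, max(ks))$sa,
                 auc = auc$auc, ms_auc = auc$ms_auc,
                 tss = tss$tss, ms_tss = tss$ms_tss,
                 threshold = tss$threshold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$curves, row.names = FALSE)
  cat(sprintf("MS_AUC %.3f  MS_TSS %.3f (threshold %.2f)\n",
              x$ms_auc, x$ms_tss, x$threshold))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes a per-species CSV (`<prefix>_species.csv`) and a JSON summary
#' (`<prefix>_summary.json`) with the accuracy curves, MS_AUC, MS_TSS and
#' the chosen threshold.
#'
#' @param report an `evaluation_report`.
#' @param prefix output path prefix.
#' @export
write_evaluation_report <- function(report, prefix) {
  sp <- names(report$sa)
  df <- data.frame(species = sp, sa = as.numeric(report$sa),
                   auc = report$auc[sp], tss = report$tss[sp])
  utils::write.csv(df, paste0(prefix, "_species.csv"), row.names = FALSE)
  jsonlite::write_json(list(curves = report$curves, ms_auc = report$ms_auc,
                            ms_tss = report$ms_tss,
                            threshold = report$threshold),
                       paste0(prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(prefix)
}
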