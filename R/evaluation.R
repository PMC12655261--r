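# align a list of distance matrices to the dataset's chain order;
# errors on id mismatch
.aligned_matrices <- function(matrices, ids) {
  lapply(matrices, function(m) {
    if (is.null(rownames(m)) || !setequal(rownames(m), ids)) {
      abort("distance matrix ids do not match dataset chains")
    }
    unclass(m)[ids, ids]
  })
}

# per-metric n x k matrices of neighbour indices under leave-one-out:
# the held-out chain is excluded from its own neighbourhood; distance
# ties broken lexicographically by chain id
.neighbor_index <- function(matrices, ids, k) {
  n <- length(ids)
  if (k > n - 1L) abort("k exceeds n - 1")
  lapply(matrices, function(m) {
    nbv <- vapply(seq_len(n), function(i) {
      d <- m[i, ]
      d[i] <- Inf
      order(d, ids)[seq_len(k)]
    }, integer(k))
    if (k == 1L) matrix(nbv, ncol = 1L) else t(nbv)
  })
}

# vectorised ensemble LOOCV given precomputed neighbour indices
.ensemble_predict <- function(neighbors, labels_int, members) {
  scores <- vapply(members, function(mn) {
    nb <- neighbors[[mn]]
    rowMeans(matrix(labels_int[nb], nrow(nb), ncol(nb)))
  }, numeric(nrow(neighbors[[members[1L]]])))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  votes <- (scores > 0.5) * 1L
  n_pos <- rowSums(votes)
  n_neg <- length(members) - n_pos
  ensemble_score <- rowMeans(scores)
  final <- ifelse(n_pos > n_neg, 1L,
                  ifelse(n_neg > n_pos, 0L,
                         as.integer(ensemble_score >= 0.5)))
  list(scores = scores, votes = votes, final = final,
       ensemble_score = ensemble_score)
}

#' Leave-one-out cross-validation of the KNN majority-voting ensemble
#'
#' Each chain in turn is held out and predicted by the k-nearest-
#' neighbour base models (one per metric) trained on all remaining
#' chains; base votes are fused by [majority_vote()] logic. Entirely
#' deterministic.
#'
#' @param dataset A labelled [chain_dataset()] (n >= 3).
#' @param matrices Named list of `distance_matrix` objects covering the
#'   ensemble members; computed from `dataset` if `NULL`.
#' @param config An [ensemble_config()].
#' @return Object of class `drugspace_loocv`: list with `predictions`
#'   (per-chain tibble of truth, per-metric votes and scores, final
#'   label and ensemble score), `metrics` (one-row [compute_metrics()]
#'   tibble including AUC), and `config`.
#' @export
loocv <- function(dataset, matrices = NULL, config = ensemble_config()) {
  stopifnot(inherits(dataset, "chain_dataset"))
  if (is.null(dataset$labels)) abort("dataset has no labels")
  ids <- chain_ids(dataset)
  if (length(ids) < 3L) abort("LOOCV needs at least 3 chains")
  if (is.null(matrices)) matrices <- pairwise_matrices(dataset, config$members)
  if (!all(config$members %in% names(matrices))) {
    abort(paste0("missing distance matrix for ensemble member(s): ",
                 toString(setdiff(config$members, names(matrices)))))
  }
  mats <- .aligned_matrices(matrices[config$members], ids)
  nb <- .neighbor_index(mats, ids, config$k)
  truth <- dataset$labels$label
  pred <- .ensemble_predict(nb, truth, config$members)

  predictions <- tibble(chain_id = ids, truth = truth)
  for (mn in config$members) {
    predictions[[paste0("vote_", mn)]] <- pred$votes[, mn]
    predictions[[paste0("score_", mn)]] <- pred$scores[, mn]
  }
  predictions$final_label <- pred$final
  predictions$ensemble_score <- pred$ensemble_score

  metrics <- compute_metrics(pred$final, truth, scores = pred$ensemble_score)
  structure(
    list(predictions = predictions, metrics = metrics, config = config,
         neighbors = nb),
    class = "drugspace_loocv"
  )
}

#' @export
print.drugspace_loocv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    paste0("<drugspace_loocv> n = %d | accuracy %.2f%% | precision %.2f%% | ",
           "recall %.2f%% | F1 %.2f%% | AUC %.4f\n"),
    nrow(x$predictions), m$accuracy, m$precision, m$recall, m$f1, m$auc
  ))
  invisible(x)
}

#' @export
tidy.drugspace_loocv <- function(x, ...) x$predictions

#' @export
glance.drugspace_loocv <- function(x, ...) x$metrics

#' Classification metrics from predictions and truth
#'
#' Accuracy, precision, recall and F1 (all as percentages, positive
#' class = druggable = 1) with the underlying confusion counts, plus
#' rank-based AUC when continuous scores are supplied. When no positive
#' predictions exist, precision is reported as 0 with a warning flag.
#'
#' @param predicted Integer vector of predicted labels (0/1).
#' @param truth Integer vector of true labels (0/1).
#' @param scores Optional continuous scores for [roc_auc()].
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`
#'   (percent), `auc` (fraction or `NA`), `tp`, `fp`, `tn`, `fn`,
#'   `precision_defined`.
#' @export
compute_metrics <- function(predicted, truth, scores = NULL) {
  if (length(predicted) == 0L) abort("empty predictions")
  if (length(predicted) != length(truth)) abort("length mismatch")
  tp <- sum(predicted == 1L & truth == 1L)
  fp <- sum(predicted == 1L & truth == 0L)
  tn <- sum(predicted == 0L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  precision_defined <- (tp + fp) > 0L
  if (!precision_defined) {
    warn("no positive predictions: precision reported as 0")
  }
  precision <- if (precision_defined) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  auc <- if (!is.null(scores) && length(unique(truth)) == 2L) {
    roc_auc(scores, truth)
  } else {
    NA_real_
  }
  tibble(
    accuracy = 100 * (tp + tn) / length(truth),
    precision = 100 * precision,
    recall = 100 * recall,
    f1 = 100 * f1,
    auc = auc,
    tp = tp, fp = fp, tn = tn, fn = fn,
    precision_defined = precision_defined
  )
}

#' Area under the ROC curve via the rank statistic
#'
#' Equivalent to the probability that a random positive outscores a
#' random negative, with ties counted half (mid-rank convention); an
#' all-equal score vector therefore gives exactly 0.5.
#'
#' @param scores Continuous scores (larger = more positive).
#' @param labels True labels (0/1); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("roc_auc requires both classes present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Permutation test of the ensemble's LOOCV accuracy
#'
#' The class labels are uniformly shuffled `m` times while every
#' distance matrix (and hence every neighbourhood) stays fixed; the
#' LOOCV ensemble accuracy is recomputed for each shuffle, building a
#' null distribution under no feature-label association. The empirical
#' p-value is `(b + 1) / (m + 1)` where `b` counts permutations with
#' accuracy greater than or equal to the observed one (the conservative
#' convention). Labelling is not re-run inside replicates.
#'
#' @param dataset A labelled [chain_dataset()].
#' @param matrices Named list of distance matrices (computed if `NULL`).
#' @param config An [ensemble_config()].
#' @param m Number of permutations (default 1000).
#' @param seed Integer seed for the shuffles.
#' @return Object of class `drugspace_permutation`: list with
#'   `observed_accuracy`, `null_accuracies`, `b`, `m`, `p_value`.
#' @export
permutation_test <- function(dataset, matrices = NULL,
                             config = ensemble_config(), m = 1000L,
                             seed = 1L) {
  m <- as.integer(m)
  if (m < 1L) abort("m must be >= 1")
  ids <- chain_ids(dataset)
  if (is.null(matrices)) matrices <- pairwise_matrices(dataset, config$members)
  mats <- .aligned_matrices(matrices[config$members], ids)
  nb <- .neighbor_index(mats, ids, config$k)
  truth <- dataset$labels$label
  n <- length(truth)

  observed <- mean(.ensemble_predict(nb, truth, config$members)$final == truth)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null_acc <- vapply(seq_len(m), function(r) {
    perm <- sample(truth)
    mean(.ensemble_predict(nb, perm, config$members)$final == perm)
  }, numeric(1))

  b <- sum(null_acc >= observed)
  structure(
    list(
      observed_accuracy = 100 * observed,
      null_accuracies = 100 * null_acc,
      b = b, m = m, p_value = (b + 1) / (m + 1), seed = seed
    ),
    class = "drugspace_permutation"
  )
}

#' @export
print.drugspace_permutation <- function(x, ...) {
  cat(sprintf(
    paste0("<drugspace_permutation> observed accuracy %.2f%% | null mean ",
           "%.2f%% (max %.2f%%) | b = %d of m = %d | p = %.4g\n"),
    x$observed_accuracy, mean(x$null_accuracies), max(x$null_accuracies),
    x$b, x$m, x$p_value
  ))
  invisible(x)
}

#' @export
tidy.drugspace_permutation <- function(x, ...) {
  tibble(replicate = seq_len(x$m), null_accuracy = x$null_accuracies)
}

#' @export
glance.drugspace_permutation <- function(x, ...) {
  tibble(
    observed_accuracy = x$observed_accuracy,
    null_mean = mean(x$null_accuracies),
    null_max = max(x$null_accuracies),
    b = x$b, m = x$m, p_value = x$p_value
  )
}

#' Labelling and ensemble ablation study
#'
#' Two comparisons: (a) labels from the full pipeline (k-means +
#' correcting algorithms) versus the correction-free pipeline, each
#' evaluated by LOOCV against its own labels; (b) the full four-model
#' ensemble versus the ensemble with the density model subtracted, on
#' the corrected labels. Reports signed accuracy deltas relative to the
#' full arm.
#'
#' @param dataset A [chain_dataset()] with complex annotations (labels,
#'   if present, are recomputed by the labelling pipeline).
#' @param matrices Optional distance matrices over the disassembled
#'   chains (computed if `NULL`).
#' @param config An [ensemble_config()].
#' @param seed Seed for the labelling clustering.
#' @return Tibble with one row per arm: `study`, `arm`, `accuracy`,
#'   `precision`, `recall`, `f1`, `auc`, `delta_accuracy`.
#' @export
ablation_suite <- function(dataset, matrices = NULL,
                           config = ensemble_config(), seed = 1L) {
  full <- label_pipeline(dataset, seed = seed, apply_corrections = TRUE)
  ablated <- label_pipeline(dataset, seed = seed, apply_corrections = FALSE)
  if (is.null(matrices)) matrices <- pairwise_matrices(full, config$members)

  res_full <- glance(loocv(full, matrices, config))
  res_abl <- glance(loocv(ablated, matrices, config))
  res_drop <- glance(loocv(full, matrices, drop_model(config, "density")))

  out <- dplyr::bind_rows(
    dplyr::mutate(res_full, study = "labeling",
                  arm = "full (k-means + corrections)"),
    dplyr::mutate(res_abl, study = "labeling", arm = "ablated (raw k-means)"),
    dplyr::mutate(res_full, study = "ensemble", arm = "four-model ensemble"),
    dplyr::mutate(res_drop, study = "ensemble", arm = "density model dropped")
  )
  ref <- rep(res_full$accuracy, each = 2L)
  out$delta_accuracy <- out$accuracy - ref
  dplyr::select(out, "study", "arm", "accuracy", "precision", "recall",
                "f1", "auc", "delta_accuracy")
}

#' Neighbourhood-quality diagnostics per chain and metric
#'
#' For every chain and metric: a distance-based confidence
#' `1 / (1 + mean distance to the k nearest neighbours / median of all
#' pairwise distances)` (normalising by the median makes the score
#' comparable across metrics with different scales; a degenerate
#' all-zero matrix gives confidence 1), the agreement of the k
#' neighbours with the predicted label, the same-class ratio against
#' the true label, the mean neighbour distance, and the per-rank
#' distances for ranks 1-5.
#'
#' @param matrices Named list of distance matrices.
#' @param labels Tibble `chain_id, label` (or named 0/1 vector).
#' @param predictions Optional per-chain predicted labels (tibble
#'   `chain_id, final_label` or named vector); defaults to each base
#'   model's own KNN vote.
#' @param k Neighbourhood size (default 5).
#' @return Tibble: `chain_id`, `metric`, `confidence`,
#'   `neighbor_agreement`, `same_class_ratio`, `mean_neighbor_distance`,
#'   `rank1`..`rank5` distances (NA beyond k), `correct`.
#' @export
neighbor_diagnostics <- function(matrices, labels, predictions = NULL,
                                 k = 5L) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.integer(labels$label), labels$chain_id)
  }
  ids <- names(labels)
  n <- length(ids)
  if (k > n - 1L) abort("k exceeds n - 1")
  mats <- .aligned_matrices(matrices, ids)
  nb <- .neighbor_index(mats, ids, k)

  pred_vec <- NULL
  if (!is.null(predictions)) {
    if (is.data.frame(predictions)) {
      pred_vec <- stats::setNames(as.integer(predictions$final_label),
                                  predictions$chain_id)[ids]
    } else {
      pred_vec <- as.integer(predictions[ids])
    }
  }

  ranks <- min(5L, k)
  purrr::map_dfr(names(mats), function(mn) {
    m <- mats[[mn]]
    med <- stats::median(m[upper.tri(m)])
    idx <- nb[[mn]]
    nb_lab <- matrix(labels[idx], n, k)
    nb_dist <- t(vapply(seq_len(n), function(i) m[i, idx[i, ]], numeric(k)))
    mean_d <- rowMeans(nb_dist)
    conf <- if (med == 0) rep(1, n) else 1 / (1 + mean_d / med)
    base_pred <- as.integer(rowMeans(nb_lab) > 0.5)
    used_pred <- if (is.null(pred_vec)) base_pred else pred_vec
    out <- tibble(
      chain_id = ids,
      metric = mn,
      confidence = conf,
      neighbor_agreement = rowMeans(nb_lab == used_pred),
      same_class_ratio = rowMeans(nb_lab == labels[ids]),
      mean_neighbor_distance = mean_d,
      correct = used_pred == labels[ids]
    )
    for (r in seq_len(5L)) {
      out[[paste0("rank", r)]] <- if (r <= ranks) nb_dist[, r] else NA_real_
    }
    out
  })
}
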