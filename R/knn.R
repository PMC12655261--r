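#' K-nearest-neighbour prediction from precomputed distances
#'
#' Classifies one test sample from its distances to the training chains
#' under a single metric. The k nearest training chains vote; ties in
#' distance at the k-th rank are broken lexicographically by chain id so
#' the neighbourhood is fully deterministic. The continuous score is the
#' fraction of positive neighbours.
#'
#' @param test_distances Named numeric vector: distance from the test
#'   sample to each training chain.
#' @param train_labels Named integer vector (0/1) over the same chains.
#' @param k Neighbourhood size; must be odd and at most the training
#'   size (default 5).
#' @param metric Metric name recorded in the output.
#' @return One-row tibble: `metric`, `predicted_label`,
#'   `positive_score`, plus list-columns `neighbor_ids` and
#'   `neighbor_distances` (ascending).
#' @export
knn_predict <- function(test_distances, train_labels, k = 5L,
                        metric = NA_character_) {
  k <- as.integer(k)
  if (k %% 2L == 0L) abort("k must be odd")
  if (k > length(test_distances)) abort("k exceeds the training size")
  ids <- names(test_distances)
  if (is.null(ids) || !setequal(ids, names(train_labels))) {
    abort("test_distances and train_labels must be named over the same chains")
  }
  ord <- order(test_distances, ids)[seq_len(k)]
  nb_ids <- ids[ord]
  nb_lab <- train_labels[nb_ids]
  score <- sum(nb_lab == 1L) / k
  tibble(
    metric = metric,
    predicted_label = as.integer(score > 0.5),
    positive_score = score,
    neighbor_ids = list(nb_ids),
    neighbor_distances = list(unname(test_distances[ord]))
  )
}

#' Majority-vote fusion of base KNN predictions
#'
#' The final class is the label receiving the most base-model votes. An
#' even split (possible with four voters) is resolved by the ensemble
#' score — the mean of the base models' positive-neighbour fractions —
#' against 0.5 (>= 0.5 predicts positive). The ensemble score is always
#' reported for ROC analysis.
#'
#' @param base_predictions Tibble of base predictions (rows from
#'   [knn_predict()] for one sample across metrics).
#' @return One-row tibble: `final_label`, `ensemble_score`, `votes`
#'   (list-column of the named base votes).
#' @export
majority_vote <- function(base_predictions) {
  if (nrow(base_predictions) == 0L) abort("no base predictions")
  votes <- base_predictions$predicted_label
  score <- mean(base_predictions$positive_score)
  n_pos <- sum(votes == 1L)
  n_neg <- sum(votes == 0L)
  final <- if (n_pos > n_neg) 1L
    else if (n_neg > n_pos) 0L
    else as.integer(score >= 0.5)
  tibble(
    final_label = final,
    ensemble_score = score,
    votes = list(stats::setNames(votes, base_predictions$metric))
  )
}

#' Ensemble configuration
#'
#' @param members Metric names of the base models (default all four).
#' @param k KNN neighbourhood size (odd; default 5).
#' @return List of class `ensemble_config`.
#' @export
ensemble_config <- function(members = metric_names(), k = 5L) {
  if (length(members) < 2L) abort("an ensemble needs at least 2 base models")
  if (k %% 2L == 0L) abort("k must be odd")
  structure(list(members = members, k = as.integer(k)),
            class = "ensemble_config")
}

#' Remove one base model from an ensemble
#'
#' Used by the ablation study (e.g. subtracting the density model, which
#' leaves three voters and makes vote ties impossible).
#'
#' @param config An [ensemble_config()].
#' @param metric Name of the member to drop.
#' @return The reduced [ensemble_config()].
#' @export
drop_model <- function(config, metric) {
  if (!metric %in% config$members) {
    abort(paste0("'", metric, "' is not an ensemble member"))
  }
  ensemble_config(setdiff(config$members, metric), config$k)
}
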