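#' Disassemble complexes into deduplicated chains
#'
#' Multi-chain complexes are deconstructed into their constituent
#' chains; the complex id is retained on every chain so a high-scoring
#' chain can later be traced back to its complex. Chains that are exact
#' duplicates (same sequence, same secondary-structure profile, same PTM
#' annotation set) are removed, keeping the first occurrence in dataset
#' order.
#'
#' @param dataset A [chain_dataset()].
#' @return A [chain_dataset()] containing the surviving chains.
#' @export
disassemble <- function(dataset) {
  stopifnot(inherits(dataset, "chain_dataset"))
  sites <- ptm_sites_by_chain(dataset)
  sig <- vapply(seq_len(nrow(dataset$chains)), function(i) {
    s <- sites[[i]]
    ord <- order(s$ptm_type, s$start, s$end)
    paste(
      dataset$chains$sequence[i],
      paste(sprintf("%.9f", unlist(dataset$chains[i, c("fH", "fE", "fT", "fC")])),
            collapse = ","),
      paste(s$ptm_type[ord], s$start[ord], s$end[ord], collapse = ";"),
      sep = "|"
    )
  }, character(1))
  keep <- !duplicated(sig)
  ids <- dataset$chains$chain_id[keep]
  chain_dataset(
    dataset$chains[keep, ],
    dataset$ptm_sites[dataset$ptm_sites$chain_id %in% ids, ],
    dataset$complexes,
    if (is.null(dataset$labels)) NULL
    else dataset$labels[dataset$labels$chain_id %in% ids, ]
  )
}

#' K-means clustering under the L1 metric (k-medians)
#'
#' Lloyd-style alternation on the 4-dimensional secondary-structure
#' proportion vectors: points are assigned to the centroid at smallest
#' L1 distance and centroids are updated to the component-wise median of
#' their members. Runs to assignment convergence (or 100 iterations),
#' keeping the best of `n_restarts` seeded initialisations by total
#' within-cluster L1 cost. Deterministic given `seed`.
#'
#' @param ss Numeric matrix of secondary-structure proportions with
#'   chain ids as row names (or a data frame with `chain_id`, `fH`,
#'   `fE`, `fT`, `fC`).
#' @param k Number of clusters (default 2: druggable vs not).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 10).
#' @param max_iter Iteration cap per restart (default 100).
#' @return Object of class `l1_kmeans`: list with `k`, `centroids`
#'   (k x 4), `assignments` (named integer vector of cluster indices),
#'   `cost`, `seed` and `polarity` (`NULL` until [assign_polarity()]).
#' @export
kmeans_l1 <- function(ss, k = 2L, seed = 1L, n_restarts = 10L,
                      max_iter = 100L) {
  if (is.data.frame(ss)) {
    ids <- as.character(ss$chain_id)
    ss <- as.matrix(ss[, c("fH", "fE", "fT", "fC")])
    rownames(ss) <- ids
  }
  if (is.null(rownames(ss))) rownames(ss) <- as.character(seq_len(nrow(ss)))
  n <- nrow(ss)
  n_distinct <- nrow(unique(ss))
  if (n_distinct < k) {
    abort(paste0("need at least k = ", k, " distinct points, got ",
                 n_distinct))
  }

  l1_to_centroids <- function(centroids) {
    # n x k matrix of L1 distances
    vapply(seq_len(nrow(centroids)), function(j) {
      rowSums(abs(ss - matrix(centroids[j, ], n, ncol(ss), byrow = TRUE)))
    }, numeric(n))
  }

  run_once <- function() {
    # initial centroids: k distinct points sampled uniformly
    u <- unique(ss)
    centroids <- u[sample.int(nrow(u), k), , drop = FALSE]
    assign_prev <- rep(0L, n)
    for (iter in seq_len(max_iter)) {
      d <- l1_to_centroids(centroids)
      assign_cur <- max.col(-d, ties.method = "first")
      if (identical(assign_cur, assign_prev)) break
      assign_prev <- assign_cur
      for (j in seq_len(k)) {
        members <- ss[assign_cur == j, , drop = FALSE]
        if (nrow(members) == 0L) {
          # re-seed an emptied cluster at the point farthest from its
          # nearest surviving centroid (deterministic)
          far <- which.max(apply(d, 1L, min))
          centroids[j, ] <- ss[far, ]
        } else {
          centroids[j, ] <- apply(members, 2L, stats::median)
        }
      }
    }
    d <- l1_to_centroids(centroids)
    assignment <- max.col(-d, ties.method = "first")
    cost <- sum(d[cbind(seq_len(n), assignment)])
    list(centroids = centroids, assignment = assignment, cost = cost)
  }

  best <- NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    fit <- run_once()
    if (is.null(best) || fit$cost < best$cost) best <- fit
  }

  assignments <- stats::setNames(best$assignment, rownames(ss))
  structure(
    list(k = k, centroids = best$centroids, assignments = assignments,
         cost = best$cost, seed = seed, polarity = NULL),
    class = "l1_kmeans"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.l1_kmeans <- function(x, ...) {
  cat(sprintf("<l1_kmeans> k = %d, n = %d, within-cluster L1 cost = %.4f\n",
              x$k, length(x$assignments), x$cost))
  if (!is.null(x$polarity)) {
    cat("polarity:", paste(seq_along(x$polarity), x$polarity,
                           sep = " -> ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Map clusters to druggability polarity
#'
#' The cluster more enriched for chains from positively annotated
#' complexes — the larger fraction of its members coming from positive
#' complexes — becomes the positive cluster. Enrichment, rather than
#' the raw share of positive-complex chains, is used because positive
#' complexes also contribute their non-druggable partner chains, which
#' under class imbalance would otherwise swamp the count. An exact tie
#' is broken toward the smaller cluster, keeping positives rare (and
#' toward the lower cluster index if sizes also tie).
#'
#' @param model An [kmeans_l1()] fit (k = 2).
#' @param dataset The [chain_dataset()] the model was fitted on (for
#'   complex annotations).
#' @return The model with `polarity` set (character vector indexed by
#'   cluster: `"positive"` / `"negative"`).
#' @export
assign_polarity <- function(model, dataset) {
  stopifnot(inherits(model, "l1_kmeans"), model$k == 2L)
  pos_cplx <- dataset$complexes$complex_id[
    dataset$complexes$annotation == "positive"
  ]
  if (length(pos_cplx) == 0L) {
    abort("no positively annotated complexes in dataset")
  }
  ids <- names(model$assignments)
  from_pos <- dataset$chains$complex_id[match(ids, dataset$chains$chain_id)] %in%
    pos_cplx
  sizes <- vapply(1:2, function(j) sum(model$assignments == j), numeric(1))
  share <- vapply(1:2, function(j) sum(from_pos & model$assignments == j),
                  numeric(1)) / pmax(sizes, 1L)
  pos_cluster <- if (share[1L] > share[2L]) 1L
    else if (share[2L] > share[1L]) 2L
    else if (sizes[1L] < sizes[2L]) 1L
    else if (sizes[2L] < sizes[1L]) 2L
    else 1L
  model$polarity <- ifelse(1:2 == pos_cluster, "positive", "negative")
  model
}

# labels implied by cluster polarity, as a tibble(chain_id, label)
cluster_labels <- function(model) {
  if (is.null(model$polarity)) abort("polarity not assigned")
  tibble(
    chain_id = names(model$assignments),
    label = as.integer(model$polarity[model$assignments] == "positive")
  )
}

#' Correcting Algorithm 1: rescue all-negative positive complexes
#'
#' Every complex annotated positive must carry at least one positively
#' labelled chain. For any positive complex whose chains are all
#' labelled 0, the chain with the smallest L1 distance between its
#' secondary-structure profile and the positive cluster centroid is
#' relabelled 1 (ties broken by chain id order). All other labels are
#' untouched.
#'
#' @param labels Tibble `chain_id, label`.
#' @param model An [kmeans_l1()] fit with polarity assigned.
#' @param dataset The [chain_dataset()] (annotations + SS profiles).
#' @return Corrected labels tibble, with a `flips` attribute listing the
#'   relabelled chain ids.
#' @export
correcting_algorithm_1 <- function(labels, model, dataset) {
  if (is.null(model$polarity)) abort("polarity not assigned")
  pos_centroid <- model$centroids[which(model$polarity == "positive"), ]
  flips <- character(0)
  pos_cplx <- dataset$complexes$complex_id[
    dataset$complexes$annotation == "positive"
  ]
  for (cx in pos_cplx) {
    members <- dataset$chains$chain_id[dataset$chains$complex_id == cx]
    members <- members[members %in% labels$chain_id]
    if (length(members) == 0L) next
    lab <- labels$label[match(members, labels$chain_id)]
    if (any(lab == 1L)) next
    ss <- as.matrix(
      dataset$chains[match(members, dataset$chains$chain_id),
                     c("fH", "fE", "fT", "fC")]
    )
    d <- rowSums(abs(ss - matrix(pos_centroid, nrow(ss), 4L, byrow = TRUE)))
    pick <- members[order(d, members)][1L]
    labels$label[labels$chain_id == pick] <- 1L
    flips <- c(flips, pick)
  }
  attr(labels, "flips") <- flips
  labels
}

#' Correcting Algorithm 2: confirm unannotated complexes negative
#'
#' Every chain of every complex without a druggability annotation is
#' labelled 0; any positive label assigned there by clustering is
#' reverted. Positive complexes are untouched.
#'
#' @param labels Tibble `chain_id, label`.
#' @param dataset The [chain_dataset()].
#' @return Corrected labels tibble, with a `reverted` attribute listing
#'   the relabelled chain ids.
#' @export
correcting_algorithm_2 <- function(labels, dataset) {
  unann <- dataset$complexes$complex_id[
    dataset$complexes$annotation == "unannotated"
  ]
  members <- dataset$chains$chain_id[dataset$chains$complex_id %in% unann]
  hit <- labels$chain_id %in% members & labels$label == 1L
  labels$label[hit] <- 0L
  attr(labels, "reverted") <- labels$chain_id[hit]
  labels
}

#' Disassembly-and-labelling pipeline
#'
#' Disassembles complexes into deduplicated chains, clusters their
#' secondary-structure proportions with [kmeans_l1()] (k = 2), maps
#' clusters to polarity, and (optionally) applies Correcting Algorithms
#' 1 then 2. With `apply_corrections = FALSE` the raw polarity-mapped
#' cluster assignment is returned, reproducing the correction-free
#' ablation arm.
#'
#' @param dataset A [chain_dataset()] with complex annotations.
#' @param seed Integer seed for the clustering restarts.
#' @param apply_corrections Apply the two correcting algorithms
#'   (default `TRUE`).
#' @param n_restarts Restarts for [kmeans_l1()].
#' @return A labelled [chain_dataset()]; the fitted cluster model and
#'   the correction audit are attached as attributes `cluster_model`,
#'   `flips` and `reverted`.
#' @export
label_pipeline <- function(dataset, seed = 1L, apply_corrections = TRUE,
                           n_restarts = 10L) {
  d <- disassemble(dataset)
  model <- kmeans_l1(d$chains, k = 2L, seed = seed, n_restarts = n_restarts)
  model <- assign_polarity(model, d)
  labels <- cluster_labels(model)
  flips <- character(0)
  reverted <- character(0)
  if (apply_corrections) {
    labels <- correcting_algorithm_1(labels, model, d)
    flips <- attr(labels, "flips")
    labels <- correcting_algorithm_2(labels, d)
    reverted <- attr(labels, "reverted")
  }
  out <- chain_dataset(d$chains, d$ptm_sites, d$complexes,
                       labels[, c("chain_id", "label")])
  attr(out, "cluster_model") <- model
  attr(out, "flips") <- flips
  attr(out, "reverted") <- reverted
  out
}
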