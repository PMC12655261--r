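# Independent brute-force oracles used to pin the package's optimised
# implementations. Each is written from the definition, not the code
# path it checks.

# All monotone warping paths from (1,1) to (m,n); returned as a list of
# two-column index matrices. Cached by shape since path sets depend only
# on (m, n).
.path_cache <- new.env(parent = emptyenv())

monotone_paths <- function(m, n) {
  key <- paste(m, n)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  recurse <- function(i, j) {
    if (i == m && j == n) return(list(matrix(c(i, j), 1L)))
    out <- list()
    for (step in list(c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
      ni <- i + step[1L]
      nj <- j + step[2L]
      if (ni <= m && nj <= n) {
        for (tail in recurse(ni, nj)) {
          out[[length(out) + 1L]] <- rbind(c(i, j), tail)
        }
      }
    }
    out
  }
  paths <- recurse(1L, 1L)
  .path_cache[[key]] <- paths
  paths
}

# DTW by exhaustive enumeration over every monotone warping path
dtw_brute_force <- function(a, b) {
  paths <- monotone_paths(length(a), length(b))
  min(vapply(paths, function(p) sum(abs(a[p[, 1L]] - b[p[, 2L]])),
             numeric(1)))
}

# sliding-window hydropathy distance by direct enumeration of every
# stride-s offset (KD profile, unit weights, L1, W = shorter length)
hydro_brute_force <- function(seq_short, seq_long, step = 2L) {
  kd <- kd_scale()
  a <- unname(kd[strsplit(seq_short, "")[[1]]])
  b <- unname(kd[strsplit(seq_long, "")[[1]]])
  if (length(a) > length(b)) {
    tmp <- a
    a <- b
    b <- tmp
  }
  costs <- vapply(0:((length(b) - length(a)) %/% step), function(t) {
    sum(abs(a - b[step * t + seq_along(a)])) / length(a)
  }, numeric(1))
  min(costs)
}

# AUC as the fraction of concordant positive-negative pairs (ties half)
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# best 2-partition of rows of x under total within-cluster L1 cost with
# component-wise median centroids (exhaustive, n <= 12)
best_l1_partition <- function(x) {
  n <- nrow(x)
  best_cost <- Inf
  best_assign <- NULL
  for (mask in 1:(2^(n - 1) - 1)) { # fix point 1 in cluster 1
    assign <- c(1L, as.integer(bitwAnd(mask, 2^(0:(n - 2))) > 0) + 1L)
    cost <- 0
    for (g in 1:2) {
      mem <- x[assign == g, , drop = FALSE]
      if (nrow(mem) == 0L) {
        cost <- Inf
        break
      }
      ctr <- apply(mem, 2L, median)
      cost <- cost + sum(abs(sweep(mem, 2L, ctr)))
    }
    if (cost < best_cost) {
      best_cost <- cost
      best_assign <- assign
    }
  }
  list(assignment = best_assign, cost = best_cost)
}

# exhaustive knn: sort all training chains by (distance, id), majority
knn_brute_force <- function(test_distances, train_labels, k) {
  ids <- names(test_distances)
  ord <- ids[order(test_distances, ids)][seq_len(k)]
  lab <- train_labels[ord]
  list(ids = ord, label = as.integer(mean(lab) > 0.5), score = mean(lab))
}
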