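#' The Kyte-Doolittle hydropathy scale
#'
#' Fixed per-residue hydropathy values from the published Kyte-Doolittle
#' table; positive values are hydrophobic. This scale drives the
#' sliding-window hydropathy metric.
#'
#' @return Named numeric vector of length 20 (names are one-letter
#'   residue codes).
#' @export
#' @examples
#' kd_scale()[["I"]] # 4.5, the most hydrophobic residue
kd_scale <- function() {
  c(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
  )
}

#' Kyte-Doolittle hydropathy of a single residue
#'
#' @param residue One of the 20 standard one-letter residue codes.
#'   Ambiguity codes (X, B, Z, ...) are rejected.
#' @return Hydropathy value (unitless).
#' @export
kd_value <- function(residue) {
  v <- kd_scale()[residue]
  if (length(residue) != 1L || is.na(v)) {
    abort(paste0("not a standard amino-acid letter: '", residue, "'"))
  }
  unname(v)
}

# KD profile of a sequence string; errors on non-standard letters
hydro_profile <- function(sequence) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  v <- kd_scale()[letters]
  if (anyNA(v)) {
    abort(paste0(
      "sequence contains non-standard letters: ",
      toString(unique(letters[is.na(v)]))
    ))
  }
  unname(v)
}

# coerce a chain argument: a plain sequence string, a list with
# $sequence/$ptm_sites/$ss, or a chains-tibble row
.as_chain <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    return(list(sequence = x,
                ptm_sites = tibble(ptm_type = character(),
                                   start = integer(), end = integer()),
                ss = NULL))
  }
  if (is.data.frame(x) && nrow(x) == 1L && "sequence" %in% names(x)) {
    ss <- NULL
    if (all(c("fH", "fE", "fT", "fC") %in% names(x))) {
      ss <- c(fH = x$fH, fE = x$fE, fT = x$fT, fC = x$fC)
    }
    return(list(sequence = x$sequence,
                ptm_sites = tibble(ptm_type = character(),
                                   start = integer(), end = integer()),
                ss = ss))
  }
  if (is.list(x) && !is.null(x$sequence)) {
    if (is.null(x$ptm_sites)) {
      x$ptm_sites <- tibble(ptm_type = character(),
                            start = integer(), end = integer())
    }
    return(x)
  }
  abort("cannot interpret argument as a protein chain")
}

#' Extract one chain from a dataset
#'
#' @param dataset A [chain_dataset()].
#' @param id Chain identifier.
#' @return List with `sequence`, `ptm_sites` (tibble) and `ss` (named
#'   numeric of the four secondary-structure fractions), suitable for the
#'   pairwise distance functions.
#' @export
dataset_chain <- function(dataset, id) {
  stopifnot(inherits(dataset, "chain_dataset"))
  row <- dataset$chains[dataset$chains$chain_id == id, ]
  if (nrow(row) != 1L) abort(paste0("unknown chain_id: ", id))
  list(
    sequence = row$sequence,
    ptm_sites = dataset$ptm_sites[dataset$ptm_sites$chain_id == id,
                                  c("ptm_type", "start", "end")],
    ss = c(fH = row$fH, fE = row$fE, fT = row$fT, fC = row$fC)
  )
}

#' Configuration of the sliding-window hydropathy metric
#'
#' @param step Window stride in residues (default 2).
#' @param weights Per-position weights along the shorter chain; `NULL`
#'   (the default) means all 1.
#' @param norm_order Exponent p of the windowed Lp mean (default 1).
#' @param normalizer Total weight W dividing the windowed sum; `NULL`
#'   (the default) uses the length of the shorter chain.
#' @return List of class `hydro_config`.
#' @export
hydro_config <- function(step = 2L, weights = NULL, norm_order = 1,
                         normalizer = NULL) {
  step <- as.integer(step)
  if (step < 1L) abort("step must be >= 1")
  if (!is.null(weights) && any(weights <= 0)) abort("weights must be positive")
  if (norm_order < 1) abort("norm_order must be >= 1")
  structure(
    list(step = step, weights = weights, norm_order = norm_order,
         normalizer = normalizer),
    class = "hydro_config"
  )
}

#' Sliding-window hydropathy distance between two chains
#'
#' The shorter chain's Kyte-Doolittle profile traverses the longer
#' chain's profile at stride `step`; at each offset the weighted Lp mean
#' of absolute hydropathy differences over the shorter chain is taken,
#' and the minimum across offsets is the distance. Symmetric by
#' construction (roles are assigned by length, ties keep argument
#' order), zero for identical sequences.
#'
#' @param chain_a,chain_b Chains (sequence strings, [dataset_chain()]
#'   results, or anything with a `$sequence`).
#' @param config A [hydro_config()].
#' @return Non-negative scalar.
#' @export
#' @examples
#' hydro_distance("GG", "IIGG") # a perfectly matching window exists: 0
hydro_distance <- function(chain_a, chain_b, config = hydro_config()) {
  a <- hydro_profile(.as_chain(chain_a)$sequence)
  b <- hydro_profile(.as_chain(chain_b)$sequence)
  if (length(a) > length(b)) {
    tmp <- a
    a <- b
    b <- tmp
  }
  w <- config$weights %||% rep(1, length(a))
  if (length(w) != length(a)) {
    abort("weights must have one entry per residue of the shorter chain")
  }
  W <- config$normalizer %||% length(a)
  hydro_min_cost_cpp(a, b, config$step, w, config$norm_order, W)
}

#' Null-coalescing helper
#' @param x,y `y` is returned when `x` is `NULL`.
#' @return `x` unless it is `NULL`, else `y`.
#' @name op-null-default
#' @keywords internal
#' @export
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Effective sequence length of a chain
#'
#' The residue position of the most terminal PTM site, irrespective of
#' modification class: `max(end)` over all annotated intervals. Chains
#' without any PTM annotation fall back to their full sequence length,
#' so downstream densities are well defined (and zero).
#'
#' @param chain A chain (see [dataset_chain()]).
#' @return Integer residue count >= 1.
#' @export
effective_length <- function(chain) {
  chain <- .as_chain(chain)
  if (nrow(chain$ptm_sites) == 0L) {
    return(nchar(chain$sequence))
  }
  max(chain$ptm_sites$end)
}

#' Per-type PTM density vector of a chain
#'
#' For each of the seven modification categories, the number of
#' annotated sites of that type divided by the chain's
#' [effective_length()]. Overlapping or duplicated sites each count
#' once. A chain without annotations yields the all-zero vector.
#'
#' @param chain A chain.
#' @return Named numeric vector of length 7 (sites per residue of
#'   effective length), in [ptm_types()] order.
#' @export
ptm_density_vector <- function(chain) {
  chain <- .as_chain(chain)
  counts <- table(factor(chain$ptm_sites$ptm_type, levels = ptm_types()))
  dens <- as.vector(counts) / effective_length(chain)
  names(dens) <- ptm_types()
  dens
}

#' PTM density distance between two chains
#'
#' Lp norm (default p = 1) of the difference of the two 7-dimensional
#' per-type density vectors.
#'
#' @param chain_a,chain_b Chains.
#' @param norm_order Norm exponent p (default 1).
#' @return Non-negative scalar.
#' @export
ptm_density_distance <- function(chain_a, chain_b, norm_order = 1) {
  d <- abs(ptm_density_vector(chain_a) - ptm_density_vector(chain_b))
  if (norm_order == 1) sum(d) else sum(d^norm_order)^(1 / norm_order)
}

#' Relative PTM position profile of a chain
#'
#' Each modified interval `[a, b]` is represented by its central residue
#' `floor((a + b) / 2)`; relative positions are centres divided by the
#' [effective_length()], giving values in (0, 1]. Positions are grouped
#' by modification type and sorted ascending.
#'
#' @param chain A chain.
#' @return List with `effective_length`, `centers` (tibble: `ptm_type`,
#'   `start`, `end`, `center`, `rel_pos`) and `positions` (named list of
#'   7 ascending numeric vectors, empty for absent types).
#' @export
relative_position_profile <- function(chain) {
  chain <- .as_chain(chain)
  l_eff <- effective_length(chain)
  sites <- chain$ptm_sites
  center <- floor((sites$start + sites$end) / 2)
  centers <- tibble(
    ptm_type = sites$ptm_type, start = sites$start, end = sites$end,
    center = as.integer(center), rel_pos = center / l_eff
  )
  positions <- lapply(ptm_types(), function(tp) {
    sort(centers$rel_pos[centers$ptm_type == tp])
  })
  names(positions) <- ptm_types()
  list(effective_length = l_eff, centers = centers, positions = positions)
}

#' Dynamic-time-warping cost between two position sequences
#'
#' Minimum cumulative pointwise distance `|r - s|` over all monotone
#' warping paths, with boundary `D[0,0] = 0` and infinite borders.
#' Symmetric; zero iff the sequences are identical.
#'
#' @param seq_a,seq_b Non-empty ascending numeric vectors.
#' @return Non-negative scalar.
#' @export
#' @examples
#' dtw_cost(c(0.1, 0.9), c(0.1, 0.5, 0.9)) # 0.4
dtw_cost <- function(seq_a, seq_b) {
  if (length(seq_a) == 0L || length(seq_b) == 0L) {
    abort("dtw_cost requires non-empty sequences")
  }
  dtw_cost_cpp(as.numeric(seq_a), as.numeric(seq_b))
}

#' PTM distribution distance via per-type dynamic time warping
#'
#' For each of the seven modification categories, the DTW cost between
#' the two chains' ascending relative-position sequences is computed; a
#' category absent from a chain is represented by the single
#' pseudo-position (default 2, outside the normalised `[0, 1]` range) so
#' absence is penalised, and a category absent from both chains
#' contributes 0. The distance is the sum of the seven per-type costs.
#'
#' @param chain_a,chain_b Chains.
#' @param missing_pseudo_position Placeholder position for an absent
#'   category; must exceed 1.
#' @return Non-negative scalar.
#' @export
ptm_dtw_distance <- function(chain_a, chain_b, missing_pseudo_position = 2) {
  if (missing_pseudo_position <= 1) {
    abort("missing_pseudo_position must exceed 1 (outside [0, 1])")
  }
  pa <- relative_position_profile(chain_a)$positions
  pb <- relative_position_profile(chain_b)$positions
  total <- 0
  for (tp in ptm_types()) {
    ra <- pa[[tp]]
    rb <- pb[[tp]]
    if (length(ra) == 0L) ra <- missing_pseudo_position
    if (length(rb) == 0L) rb <- missing_pseudo_position
    total <- total + dtw_cost_cpp(ra, rb)
  }
  total
}

#' Secondary-structure composition distance between two chains
#'
#' L1 norm of the difference of the two 4-dimensional proportion vectors
#' (helix, strand, turn, coil). Bounded above by 2 on the simplex.
#'
#' @param chain_a,chain_b Chains with secondary-structure profiles, or
#'   plain numeric vectors of the four fractions.
#' @return Scalar in `[0, 2]`.
#' @export
ss_distance <- function(chain_a, chain_b) {
  get_ss <- function(x) {
    if (is.numeric(x) && length(x) == 4L) return(unname(x))
    ss <- .as_chain(x)$ss
    if (is.null(ss)) abort("chain has no secondary-structure profile")
    unname(ss)
  }
  sum(abs(get_ss(chain_a) - get_ss(chain_b)))
}

# ---- pairwise matrices ----------------------------------------------------

new_distance_matrix <- function(values, ids, metric) {
  dimnames(values) <- list(ids, ids)
  structure(values, metric_name = metric,
            class = c("distance_matrix", class(values)))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> metric '%s', %d chains\n",
              attr(x, "metric_name"), nrow(x)))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE],
                    6L))
  invisible(x)
}

#' Names of the four chain metrics
#' @return `c("hydro", "density", "dtw", "sec")`.
#' @export
metric_names <- function() c("hydro", "density", "dtw", "sec")

#' Full pairwise distance matrix under one metric
#'
#' @param dataset A [chain_dataset()] with at least two chains.
#' @param metric One of `"hydro"` (sliding-window hydropathy),
#'   `"density"` (L1 on the 7-dim PTM density vectors), `"dtw"`
#'   (summed per-type DTW of relative PTM positions) or `"sec"` (L1 on
#'   secondary-structure proportions).
#' @param config Optional [hydro_config()] (hydro metric only).
#' @return A `distance_matrix`: symmetric numeric matrix with zero
#'   diagonal, chain ids as dimnames, and the metric name attached.
#' @export
pairwise_matrix <- function(dataset, metric = metric_names(),
                            config = hydro_config()) {
  stopifnot(inherits(dataset, "chain_dataset"))
  metric <- match.arg(metric)
  ids <- chain_ids(dataset)
  n <- length(ids)
  if (n < 2L) abort("pairwise_matrix needs at least two chains")

  if (metric == "density") {
    dens <- t(vapply(ids, function(id)
      ptm_density_vector(dataset_chain(dataset, id)), numeric(7L)))
    m <- as.matrix(stats::dist(dens, method = "manhattan"))
  } else if (metric == "sec") {
    ss <- as.matrix(dataset$chains[, c("fH", "fE", "fT", "fC")])
    m <- as.matrix(stats::dist(ss, method = "manhattan"))
  } else if (metric == "hydro") {
    profiles <- lapply(dataset$chains$sequence, hydro_profile)
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        a <- profiles[[i]]
        b <- profiles[[j]]
        if (length(a) > length(b)) {
          tmp <- a
          a <- b
          b <- tmp
        }
        w <- config$weights %||% rep(1, length(a))
        W <- config$normalizer %||% length(a)
        m[i, j] <- m[j, i] <-
          hydro_min_cost_cpp(a, b, config$step, w, config$norm_order, W)
      }
    }
  } else { # dtw
    sites <- ptm_sites_by_chain(dataset)
    seqs <- dataset$chains$sequence
    pos <- lapply(seq_len(n), function(i) {
      prof <- relative_position_profile(
        list(sequence = seqs[i], ptm_sites = sites[[i]])
      )$positions
      lapply(prof, function(p) if (length(p) == 0L) 2 else p)
    })
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        tot <- 0
        for (tp in ptm_types()) {
          tot <- tot + dtw_cost_cpp(pos[[i]][[tp]], pos[[j]][[tp]])
        }
        m[i, j] <- m[j, i] <- tot
      }
    }
  }
  new_distance_matrix(m, ids, metric)
}

#' Pairwise matrices for several metrics at once
#'
#' @inheritParams pairwise_matrix
#' @param metrics Character vector of metric names.
#' @return Named list of `distance_matrix` objects.
#' @export
pairwise_matrices <- function(dataset, metrics = metric_names(),
                              config = hydro_config()) {
  out <- lapply(metrics, function(mn) pairwise_matrix(dataset, mn, config))
  names(out) <- metrics
  out
}

#' Tidy a distance matrix into long form
#'
#' @param x A `distance_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `chain_a`, `chain_b`, `metric`,
#'   `distance`, one row per unordered pair (upper triangle).
#' @export
tidy.distance_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(
    chain_a = ids[idx[, 1L]],
    chain_b = ids[idx[, 2L]],
    metric = attr(x, "metric_name"),
    distance = x[idx]
  )
}
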