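# Physicochemical property tables over the 20 residues, used by the
# PseAAC-variant featurizer. Values are the canonical published scales:
# Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity, side-chain mass,
# isoelectric point, and Grantham polarity.
aa_property_table <- function() {
  aa <- amino_acids()
  tbl <- rbind(
    hydropathy = kd_scale()[aa],
    hydrophilicity = c(
      A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
      I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
      R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3
    )[aa],
    side_chain_mass = c(
      A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82,
      I = 57, K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72,
      R = 101, S = 31, T = 45, V = 43, W = 130, Y = 107
    )[aa],
    isoelectric_point = c(
      A = 6.00, C = 5.07, D = 2.77, E = 3.22, F = 5.48, G = 5.97,
      H = 7.59, I = 6.02, K = 9.74, L = 5.98, M = 5.74, N = 5.41,
      P = 6.30, Q = 5.65, R = 10.76, S = 5.68, T = 5.60, V = 5.96,
      W = 5.89, Y = 5.66
    )[aa],
    polarity = c(
      A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2, G = 9.0, H = 10.4,
      I = 5.2, K = 11.3, L = 4.9, M = 5.7, N = 11.6, P = 8.0, Q = 10.5,
      R = 10.5, S = 9.2, T = 8.6, V = 5.9, W = 5.4, Y = 6.2
    )[aa]
  )
  colnames(tbl) <- aa
  tbl
}

# standardize each property to zero mean / unit variance over 20 residues
standardized_properties <- function(properties = NULL) {
  tbl <- properties %||% aa_property_table()
  t(apply(tbl, 1L, function(v) (v - mean(v)) / stats::sd(v)))
}

.check_sequence <- function(sequence) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- !(letters %in% amino_acids())
  if (any(bad)) {
    abort(paste0("sequence contains non-standard letters: ",
                 toString(unique(letters[bad]))))
  }
  letters
}

#' Gapped-dipeptide (g-gap) frequency features
#'
#' Counts ordered residue pairs `(s[i], s[i + gap + 1])` separated by
#' `gap` intervening residues and normalises by the number of such
#' pairs, yielding a 400-dimensional frequency vector over all ordered
#' residue pairs in fixed alphabetical order (first residue varies
#' slowest).
#'
#' @param sequence Amino-acid string; must have length >= `gap + 2`.
#' @param gap Number of intervening residues (default 2).
#' @return Named numeric vector of length 400 summing to 1.
#' @export
#' @examples
#' f <- ggap_features("AAAA")
#' f[["AA"]] # the single (A, A) pair: 1
ggap_features <- function(sequence, gap = 2L) {
  letters <- .check_sequence(sequence)
  L <- length(letters)
  if (L < gap + 2L) {
    abort(paste0("sequence too short for gap = ", gap,
                 " (needs >= ", gap + 2L, " residues)"))
  }
  aa <- amino_acids()
  pair_names <- as.vector(t(outer(aa, aa, paste0)))
  i <- seq_len(L - gap - 1L)
  pairs <- paste0(letters[i], letters[i + gap + 1L])
  counts <- table(factor(pairs, levels = pair_names))
  out <- as.vector(counts) / length(i)
  names(out) <- pair_names
  out
}

#' PseAAC-variant sequence features
#'
#' A 50-dimensional pseudo-amino-acid composition variant: 25
#' sequence-order correlation factors (5 physicochemical properties at
#' tiers 1..lambda, each `theta[P, j] = mean((P(s[i]) - P(s[i+j]))^2)`
#' over standardized property values), followed by the 5
#' sequence-averaged standardized property values, followed by the 20
#' amino-acid frequencies.
#'
#' @param sequence Amino-acid string of length >= `lambda + 1`.
#' @param lambda Number of correlation tiers (default 5).
#' @param properties Optional 5 x 20 property matrix (rows = properties,
#'   columns = residues in [amino_acids()] order); defaults to the
#'   canonical hydropathy / hydrophilicity / side-chain mass /
#'   isoelectric point / polarity set. Standardized internally.
#' @return Named numeric vector of length `5 * lambda + 5 + 20`.
#' @export
pseaac_features <- function(sequence, lambda = 5L, properties = NULL) {
  letters <- .check_sequence(sequence)
  L <- length(letters)
  if (L < lambda + 1L) {
    abort(paste0("sequence shorter than lambda + 1 = ", lambda + 1L))
  }
  props <- standardized_properties(properties)
  vals <- props[, letters, drop = FALSE] # properties x L

  theta <- numeric(0)
  for (pn in rownames(props)) {
    v <- vals[pn, ]
    for (j in seq_len(lambda)) {
      th <- mean((v[seq_len(L - j)] - v[seq_len(L - j) + j])^2)
      theta <- c(theta, stats::setNames(th, paste0("theta_", pn, "_", j)))
    }
  }
  prop_means <- rowMeans(vals)
  names(prop_means) <- paste0("mean_", rownames(props))
  freqs <- as.vector(table(factor(letters, levels = amino_acids()))) / L
  names(freqs) <- paste0("freq_", amino_acids())
  c(theta, prop_means, freqs)
}

#' Featurize every chain of a dataset
#'
#' @param dataset A [chain_dataset()] (or a data frame with `chain_id`
#'   and `sequence` columns).
#' @param scheme `"pseaac"` (50 dims) or `"ggap"` (400 dims).
#' @param ... Passed to [pseaac_features()] or [ggap_features()].
#' @return Tibble with `chain_id` plus one column per feature.
#' @export
featurize_chains <- function(dataset, scheme = c("pseaac", "ggap"), ...) {
  scheme <- match.arg(scheme)
  chains <- if (inherits(dataset, "chain_dataset")) dataset$chains
            else as_tibble(dataset)
  fn <- if (scheme == "pseaac") pseaac_features else ggap_features
  feats <- lapply(chains$sequence, fn, ...)
  out <- as_tibble(do.call(rbind, feats))
  dplyr::bind_cols(tibble(chain_id = chains$chain_id), out)
}
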