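#' Configuration for the synthetic chain/complex generator
#'
#' Defines the class-conditional distributions from which labelled
#' synthetic datasets are drawn. The defaults emulate the statistical
#' structure of a curated drug-binding chain collection: 36 positive and
#' 106 negative chains, multi-chain complexes of 1-4 chains, sequences
#' of 40-120 residues, secondary-structure proportions on the 4-simplex,
#' and per-type PTM site counts with class-dependent rates. A single
#' scalar `class_separation` in `[0, 1]` interpolates every
#' class-conditional parameter between the common (null) value at 0 and
#' the fully separated value at 1, so each feature family carries signal
#' independently.
#'
#' @param n_positive,n_negative Chain counts per class (defaults 36 and
#'   106).
#' @param class_separation Scalar in `[0, 1]` scaling all
#'   class-conditional gaps (default 1).
#' @param complex_size_range Integer range of complex sizes (default
#'   `c(1, 4)`).
#' @param sequence_length_range Residue-count range (default
#'   `c(40, 120)`).
#' @param ss_concentration Dirichlet concentration (total) for the
#'   secondary-structure proportions (default 30).
#' @param ss_mean_positive,ss_mean_negative Class-conditional mean SS
#'   proportion vectors at full separation (H, E, T, C).
#' @param ptm_rate_positive,ptm_rate_negative Per-type Poisson means of
#'   PTM site counts at full separation, in [ptm_types()] order.
#' @param ptm_position_mean_positive,ptm_position_mean_negative Mean
#'   relative location of PTM site clusters at full separation.
#' @param hydro_block_length Length of the hydrophobic motif inserted
#'   into positive-class sequences at full separation (scaled by
#'   `class_separation`; default 12).
#' @param hydro_block_alphabet Residues the motif is drawn from.
#' @param ambiguous_ss_fraction Fraction of positive chains whose SS
#'   profile is drawn from the null distribution instead, creating the
#'   ambiguous cases that exercise Correcting Algorithm 1 (default
#'   0.15).
#' @param signal Named logical list switching the class signal of each
#'   feature family (`hydro`, `density`, `dtw`, `sec`) on or off;
#'   used to construct datasets where only one metric is informative.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_positive = 36L,
                             n_negative = 106L,
                             class_separation = 1,
                             complex_size_range = c(1L, 4L),
                             sequence_length_range = c(40L, 120L),
                             ss_concentration = 30,
                             ss_mean_positive = c(0.55, 0.12, 0.10, 0.23),
                             ss_mean_negative = c(0.15, 0.45, 0.15, 0.25),
                             ptm_rate_positive =
                               c(1.5, 3.0, 3.0, 2.5, 1.5, 1.5, 1.2),
                             ptm_rate_negative =
                               c(0.4, 1.0, 1.0, 0.3, 0.3, 1.2, 0.1),
                             ptm_position_mean_positive = 0.30,
                             ptm_position_mean_negative = 0.70,
                             hydro_block_length = 12L,
                             hydro_block_alphabet = c("I", "L", "V", "F"),
                             ambiguous_ss_fraction = 0.15,
                             signal = list(hydro = TRUE, density = TRUE,
                                           dtw = TRUE, sec = TRUE)) {
  if (n_positive < 1L || n_negative < 1L) {
    abort("chain counts must be >= 1")
  }
  if (class_separation < 0 || class_separation > 1) {
    abort("class_separation must lie in [0, 1]")
  }
  if (ss_concentration <= 0) abort("Dirichlet concentration must be positive")
  if (any(ptm_rate_positive < 0) || any(ptm_rate_negative < 0)) {
    abort("PTM rates must be non-negative")
  }
  structure(
    list(
      n_positive = as.integer(n_positive),
      n_negative = as.integer(n_negative),
      class_separation = class_separation,
      complex_size_range = as.integer(complex_size_range),
      sequence_length_range = as.integer(sequence_length_range),
      ss_concentration = ss_concentration,
      ss_mean_positive = ss_mean_positive,
      ss_mean_negative = ss_mean_negative,
      ptm_rate_positive = ptm_rate_positive,
      ptm_rate_negative = ptm_rate_negative,
      ptm_position_mean_positive = ptm_position_mean_positive,
      ptm_position_mean_negative = ptm_position_mean_negative,
      hydro_block_length = as.integer(hydro_block_length),
      hydro_block_alphabet = hydro_block_alphabet,
      ambiguous_ss_fraction = ambiguous_ss_fraction,
      signal = signal
    ),
    class = "generator_config"
  )
}

# residue sampling frequencies; positives biased hydrophobic at full
# separation
.residue_freqs <- function(sep, positive, hydro_signal) {
  aa <- amino_acids()
  base <- rep(1 / 20, 20)
  names(base) <- aa
  hydrophobic <- c("A", "C", "F", "I", "L", "M", "V")
  target <- base
  target[hydrophobic] <- target[hydrophobic] * 2.5
  target <- target / sum(target)
  lam <- if (positive && hydro_signal) sep else 0
  (1 - lam) * base + lam * target
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# interpolate a class parameter toward its separated value
.blend <- function(mid, target, lam) (1 - lam) * mid + lam * target

#' Generate a labelled synthetic chain/complex dataset
#'
#' Chains are drawn per class: sequences from class-biased residue
#' frequencies with a hydrophobic motif inserted into positives (signal
#' for the hydropathy metric); secondary-structure proportions from
#' class-conditional Dirichlet distributions (signal for the SS metric
#' and the labelling clustering); per-type PTM site counts from
#' class-dependent Poisson rates, with positions placed as a clustered
#' point process on the chain and converted to intervals of 3-8
#' residues (signal for the density and DTW metrics). Chains are
#' grouped into complexes of 1-4 chains; every complex containing a
#' positive chain is annotated positive, all others are unannotated.
#' Deterministic given `seed`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A labelled [chain_dataset()] (ground-truth chain labels and
#'   complex annotations).
#' @export
generate_dataset <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  sep <- config$class_separation
  sig <- config$signal
  n_pos <- config$n_positive
  n_neg <- config$n_negative
  n <- n_pos + n_neg
  positive <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  ids <- c(sprintf("P%03d", seq_len(n_pos)), sprintf("N%03d", seq_len(n_neg)))

  ss_mid <- (config$ss_mean_positive + config$ss_mean_negative) / 2
  rate_mid <- (config$ptm_rate_positive + config$ptm_rate_negative) / 2
  pos_mid <- (config$ptm_position_mean_positive +
                config$ptm_position_mean_negative) / 2

  ambiguous <- positive &
    stats::runif(n) < ifelse(positive, config$ambiguous_ss_fraction, 0)

  sequences <- character(n)
  ss <- matrix(0, n, 4L)
  ptm_rows <- vector("list", n)

  for (i in seq_len(n)) {
    L <- sample(seq(config$sequence_length_range[1L],
                    config$sequence_length_range[2L]), 1L)
    freqs <- .residue_freqs(sep, positive[i], isTRUE(sig$hydro))
    letters <- sample(amino_acids(), L, replace = TRUE, prob = freqs)
    if (positive[i] && isTRUE(sig$hydro)) {
      blk_len <- round(sep * config$hydro_block_length)
      if (blk_len > 0L && blk_len < L) {
        at <- sample(seq_len(L - blk_len + 1L), 1L)
        letters[at:(at + blk_len - 1L)] <-
          sample(config$hydro_block_alphabet, blk_len, replace = TRUE)
      }
    }
    sequences[i] <- paste(letters, collapse = "")

    ss_lam <- if (isTRUE(sig$sec) && !ambiguous[i]) sep else 0
    ss_mean <- .blend(
      ss_mid,
      if (positive[i]) config$ss_mean_positive else config$ss_mean_negative,
      ss_lam
    )
    ss[i, ] <- .rdirichlet1(config$ss_concentration * ss_mean)

    rate_lam <- if (isTRUE(sig$density)) sep else 0
    rates <- .blend(
      rate_mid,
      if (positive[i]) config$ptm_rate_positive else config$ptm_rate_negative,
      rate_lam
    )
    pos_lam <- if (isTRUE(sig$dtw)) sep else 0
    mu <- .blend(
      pos_mid,
      if (positive[i]) config$ptm_position_mean_positive
      else config$ptm_position_mean_negative,
      pos_lam
    )

    rows <- list()
    for (tk in seq_along(ptm_types())) {
      cnt <- stats::rpois(1L, rates[tk])
      if (cnt == 0L) next
      center_rel <- stats::rbeta(1L, mu * 6, (1 - mu) * 6)
      rel <- pmin(pmax(center_rel + stats::rnorm(cnt, 0, 0.08), 0.02), 0.98)
      width <- sample(3:8, cnt, replace = TRUE)
      center <- pmax(1L, pmin(L, as.integer(round(rel * L))))
      start <- pmax(1L, center - width %/% 2L)
      end <- pmin(L, start + width - 1L)
      start <- pmax(1L, end - width + 1L)
      rows[[length(rows) + 1L]] <- tibble(
        chain_id = ids[i], ptm_type = ptm_types()[tk],
        start = start, end = end
      )
    }
    ptm_rows[[i]] <- if (length(rows) > 0) dplyr::bind_rows(rows) else NULL
  }

  # complex assembly: each positive chain anchors a positive complex
  # with 0..(max size - 1) negative partner chains; remaining negatives
  # form unannotated complexes of 1..max size
  smin <- config$complex_size_range[1L]
  smax <- config$complex_size_range[2L]
  complex_of <- character(n)
  cplx_counter <- 0L
  neg_pool <- which(!positive)
  for (i in which(positive)) {
    cplx_counter <- cplx_counter + 1L
    cid <- sprintf("CPX%03d", cplx_counter)
    complex_of[i] <- cid
    n_partners <- sample(0:(smax - 1L), 1L)
    n_partners <- min(n_partners, length(neg_pool))
    if (n_partners > 0L) {
      partners <- neg_pool[seq_len(n_partners)]
      neg_pool <- neg_pool[-seq_len(n_partners)]
      complex_of[partners] <- cid
    }
  }
  while (length(neg_pool) > 0L) {
    cplx_counter <- cplx_counter + 1L
    cid <- sprintf("CPX%03d", cplx_counter)
    sz <- min(sample(seq(max(smin, 1L), smax), 1L), length(neg_pool))
    complex_of[neg_pool[seq_len(sz)]] <- cid
    neg_pool <- neg_pool[-seq_len(sz)]
  }

  chains <- tibble(
    chain_id = ids, complex_id = complex_of, sequence = sequences,
    fH = ss[, 1L], fE = ss[, 2L], fT = ss[, 3L], fC = ss[, 4L]
  )
  ptm <- dplyr::bind_rows(ptm_rows[!vapply(ptm_rows, is.null, logical(1))])
  if (nrow(ptm) == 0L) {
    ptm <- tibble(chain_id = character(), ptm_type = character(),
                  start = integer(), end = integer())
  }
  cplx_ids <- unique(complex_of)
  has_pos <- vapply(cplx_ids, function(cid) any(positive[complex_of == cid]),
                    logical(1))
  complexes <- tibble(
    complex_id = cplx_ids,
    annotation = ifelse(has_pos, "positive", "unannotated")
  )
  labels <- tibble(chain_id = ids, label = as.integer(positive))
  chain_dataset(chains, ptm, complexes, labels)
}

#' Generate a null dataset (no feature-label association)
#'
#' [generate_dataset()] with `class_separation` forced to 0: every
#' feature family is drawn from the common distribution regardless of
#' class, so the labels carry no information. Used for
#' permutation-test calibration.
#'
#' @inheritParams generate_dataset
#' @return A labelled [chain_dataset()].
#' @export
generate_null_dataset <- function(config = generator_config(), seed = 1L) {
  config$class_separation <- 0
  generate_dataset(config, seed = seed)
}
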