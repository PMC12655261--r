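# Small in-code fixtures shared across test files.

toy_chains <- function() {
  tibble::tibble(
    chain_id = c("A1", "A2", "B1"),
    complex_id = c("cplxA", "cplxA", "cplxB"),
    sequence = c("MKTAYIAKQRGG", "GGIILVVAAKMM", "ACDEFGHIKLMN"),
    fH = c(0.40, 0.10, 0.25),
    fE = c(0.20, 0.50, 0.25),
    fT = c(0.10, 0.20, 0.25),
    fC = c(0.30, 0.20, 0.25)
  )
}

toy_ptm <- function() {
  tibble::tibble(
    chain_id = c("A1", "A1", "A2"),
    ptm_type = c("PKC-phosphorylation", "N-glycosylation", "USP-domain"),
    start = c(3L, 8L, 2L),
    end = c(5L, 10L, 7L)
  )
}

toy_dataset <- function() {
  chain_dataset(
    toy_chains(), toy_ptm(),
    tibble::tibble(complex_id = c("cplxA", "cplxB"),
                   annotation = c("positive", "unannotated")),
    tibble::tibble(chain_id = c("A1", "A2", "B1"), label = c(1L, 0L, 0L))
  )
}

random_sequence <- function(len) {
  paste(sample(amino_acids(), len, replace = TRUE), collapse = "")
}

random_ss <- function() {
  v <- stats::rgamma(4L, shape = 2)
  v <- v / sum(v)
  c(fH = v[1], fE = v[2], fT = v[3], fC = v[4])
}

# a random standalone chain (list form) with optional PTM sites
random_chain <- function(max_len = 60L, max_sites = 4L) {
  len <- sample(10:max_len, 1L)
  n_sites <- sample(0:max_sites, 1L)
  sites <- if (n_sites > 0L) {
    start <- sample.int(len, n_sites, replace = TRUE)
    width <- sample(0:5, n_sites, replace = TRUE)
    tibble::tibble(
      ptm_type = sample(ptm_types(), n_sites, replace = TRUE),
      start = start,
      end = pmin(len, start + width)
    )
  } else {
    tibble::tibble(ptm_type = character(), start = integer(),
                   end = integer())
  }
  list(sequence = random_sequence(len), ptm_sites = sites, ss = random_ss())
}

# a small random complex configuration for labelling property tests
random_complex_dataset <- function(n_pos = 2L, n_neg = 6L) {
  cfg <- generator_config(
    n_positive = n_pos, n_negative = n_neg,
    class_separation = stats::runif(1),
    ambiguous_ss_fraction = stats::runif(1, 0, 0.6)
  )
  generate_dataset(cfg, seed = sample.int(1e6, 1L))
}
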