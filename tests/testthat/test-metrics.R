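test_that("Kyte-Doolittle lookup matches the published table", {
  expect_equal(kd_value("I"), 4.5)
  expect_equal(kd_value("R"), -4.5)
  expect_equal(kd_value("G"), -0.4)
  expect_length(kd_scale(), 20L)
  expect_error(kd_value("X"), "X")
  expect_error(kd_value("B"), "B")
})

test_that("sliding-window hydropathy distance handles hand-checked cases", {
  # identical sequences: zero self-distance
  expect_equal(hydro_distance("MKTAYIAK", "MKTAYIAK"), 0)
  # GG against IIGG: offsets t = 0 (cost 4.9) and t = 1 (cost 0)
  expect_equal(hydro_distance("GG", "IIGG"), 0)
  # swap invariance
  expect_equal(hydro_distance("IIGG", "GG"), hydro_distance("GG", "IIGG"))
  # equal lengths collapse to the single alignment
  expect_equal(
    hydro_distance("GI", "IG"),
    (abs(-0.4 - 4.5) + abs(4.5 - (-0.4))) / 2
  )
  # odd length difference: terminal offset not force-included
  expect_equal(hydro_distance("GG", "IIIGG"), hydro_brute_force("GG", "IIIGG"))
  expect_error(hydro_distance("GXG", "GGGG"), "non-standard")
})

test_that("hydropathy distance equals brute-force offset enumeration", {
  set.seed(101)
  for (i in 1:200) {
    a <- random_sequence(sample(2:30, 1L))
    b <- random_sequence(sample(2:30, 1L))
    expect_equal(hydro_distance(a, b), hydro_brute_force(a, b),
                 tolerance = 1e-12)
  }
})

test_that("hydro and dtw configs validate their parameters", {
  expect_error(hydro_config(step = 0), "step")
  expect_error(hydro_config(weights = c(1, -1)), "positive")
  expect_error(hydro_config(norm_order = 0.5), "norm_order")
  expect_error(ptm_dtw_distance("AA", "AA", missing_pseudo_position = 0.9),
               "exceed 1")
})

test_that("effective length is the most terminal PTM end, with fallback", {
  ch <- list(
    sequence = random_sequence(20L),
    ptm_sites = tibble::tibble(
      ptm_type = c("PKC-phosphorylation", "N-glycosylation"),
      start = c(3L, 10L), end = c(5L, 14L)
    )
  )
  expect_equal(effective_length(ch), 14L)
  # no sites: fall back to full sequence length
  expect_equal(effective_length(random_sequence(80L)), 80L)
  ch$ptm_sites <- tibble::tibble(ptm_type = "USP-domain",
                                 start = 7L, end = 7L)
  expect_equal(effective_length(ch), 7L)
})

test_that("PTM density vector counts sites per effective residue", {
  ch <- list(
    sequence = random_sequence(120L),
    ptm_sites = tibble::tibble(
      ptm_type = c("PKC-phosphorylation", "PKC-phosphorylation",
                   "N-glycosylation"),
      start = c(10L, 40L, 95L), end = c(12L, 44L, 100L)
    )
  )
  dens <- ptm_density_vector(ch)
  expect_length(dens, 7L)
  expect_equal(unname(dens[["PKC-phosphorylation"]]), 2 / 100)
  expect_equal(sum(dens > 0), 2L)
  # zero-PTM chain: all-zero vector
  expect_equal(unname(ptm_density_vector(random_sequence(30L))), rep(0, 7L))
  # one site of each type, L_eff = 50: all densities equal
  ch7 <- list(
    sequence = random_sequence(60L),
    ptm_sites = tibble::tibble(
      ptm_type = ptm_types(),
      start = c(5L, 10L, 15L, 20L, 25L, 30L, 48L),
      end = c(6L, 11L, 16L, 21L, 26L, 31L, 50L)
    )
  )
  expect_equal(unname(ptm_density_vector(ch7)), rep(1 / 50, 7L))
})

test_that("PTM density distance is the Lp norm of the difference", {
  a <- list(sequence = random_sequence(100L),
            ptm_sites = tibble::tibble(ptm_type = "PKC-phosphorylation",
                                       start = c(10L, 20L),
                                       end = c(12L, 100L)))
  b <- list(sequence = random_sequence(100L),
            ptm_sites = tibble::tibble(ptm_type = "PKC-phosphorylation",
                                       start = 10L, end = 100L))
  expect_equal(ptm_density_distance(a, b), 0.02 - 0.01)
  expect_equal(ptm_density_distance(a, a), 0)
  set.seed(11)
  for (i in 1:20) {
    x <- random_chain()
    y <- random_chain()
    expect_equal(ptm_density_distance(x, y), ptm_density_distance(y, x))
  }
})

test_that("relative positions use floored interval centres over L_eff", {
  ch <- list(
    sequence = random_sequence(20L),
    ptm_sites = tibble::tibble(ptm_type = "N-glycosylation",
                               start = 10L, end = 14L)
  )
  prof <- relative_position_profile(ch)
  expect_equal(prof$effective_length, 14L)
  expect_equal(prof$centers$center, 12L)
  expect_equal(prof$centers$rel_pos, 12 / 14)

  # half-integer midpoint floored: [2, 5] -> centre 3
  ch$ptm_sites <- tibble::tibble(
    ptm_type = c("N-glycosylation", "USP-domain"),
    start = c(2L, 10L), end = c(5L, 10L)
  )
  prof <- relative_position_profile(ch)
  expect_equal(prof$centers$center, c(3L, 10L))
  expect_equal(prof$centers$rel_pos[1], 0.3)
  # terminal single-residue site at L_eff: r = 1
  expect_equal(prof$positions[["USP-domain"]], 1)
  # per-type lists ascend
  set.seed(12)
  for (i in 1:20) {
    p <- relative_position_profile(random_chain())$positions
    for (v in p) expect_false(is.unsorted(v))
  }
})

test_that("dtw cost matches hand cases and exhaustive path enumeration", {
  expect_equal(dtw_cost(0.5, 0.5), 0)
  expect_equal(dtw_cost(c(0.1, 0.9), c(0.1, 0.5, 0.9)), 0.4)
  # degenerate pointwise case against the pseudo-position
  expect_equal(dtw_cost(0.5, 2), 1.5)
  expect_error(dtw_cost(numeric(0), 1), "empty")

  set.seed(13)
  for (i in 1:300) {
    a <- sort(runif(sample(1:6, 1L)))
    b <- sort(runif(sample(1:6, 1L)))
    expect_equal(dtw_cost(a, b), dtw_brute_force(a, b), tolerance = 1e-12)
  }
})

test_that("per-type dtw distance penalises absent categories", {
  a <- list(sequence = random_sequence(20L),
            ptm_sites = tibble::tibble(ptm_type = "USP-domain",
                                       start = 20L, end = 20L))
  b <- random_sequence(20L) # no annotations at all
  # single present type at r = 1 vs absence: |1 - 2| = 1
  expect_equal(ptm_dtw_distance(a, b), 1)
  # both chains lacking every type: zero
  expect_equal(ptm_dtw_distance(b, random_sequence(10L)), 0)
  expect_equal(ptm_dtw_distance(a, a), 0)
})

test_that("moving a site away from its counterpart never shrinks dtw", {
  # single-site profiles of one shared type; distance must be
  # non-decreasing as the second chain's site moves away
  # both chains share a terminal anchor site so L_eff stays fixed at
  # 100 while one PKC site drifts away from its counterpart at 50
  base <- list(
    sequence = paste(rep("A", 100L), collapse = ""),
    ptm_sites = tibble::tibble(
      ptm_type = c("PKC-phosphorylation", "N-glycosylation"),
      start = c(50L, 100L), end = c(50L, 100L)
    )
  )
  prev <- -Inf
  for (pos in seq(50L, 98L, by = 8L)) {
    other <- list(
      sequence = base$sequence,
      ptm_sites = tibble::tibble(
        ptm_type = c("PKC-phosphorylation", "N-glycosylation"),
        start = c(pos, 100L), end = c(pos, 100L)
      )
    )
    d <- ptm_dtw_distance(base, other)
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("secondary-structure distance is the simplex L1", {
  expect_equal(ss_distance(c(0.25, 0.25, 0.25, 0.25),
                           c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(ss_distance(c(1, 0, 0, 0), c(0, 1, 0, 0)), 2)
  expect_equal(ss_distance(c(0.4, 0.3, 0.2, 0.1), c(0.3, 0.3, 0.2, 0.2)),
               0.2)
  set.seed(14)
  for (i in 1:50) {
    a <- random_ss()
    b <- random_ss()
    expect_lte(ss_distance(a, b), 2)
    expect_equal(ss_distance(a, b), ss_distance(b, a))
  }
})

test_that("pairwise matrices are symmetric, zero-diagonal and consistent", {
  ds <- toy_dataset()
  for (mn in metric_names()) {
    m <- pairwise_matrix(ds, mn)
    expect_equal(rownames(m), chain_ids(ds))
    expect_equal(unname(diag(m)), rep(0, 3))
    expect_lt(max(abs(m - t(m))), 1e-9)
    expect_true(all(m >= 0))
  }
  # entries equal the direct pairwise calls
  ha <- dataset_chain(ds, "A1")
  hb <- dataset_chain(ds, "B1")
  expect_equal(pairwise_matrix(ds, "hydro")["A1", "B1"],
               hydro_distance(ha, hb))
  expect_equal(pairwise_matrix(ds, "density")["A1", "B1"],
               ptm_density_distance(ha, hb))
  expect_equal(pairwise_matrix(ds, "dtw")["A1", "B1"],
               ptm_dtw_distance(ha, hb))
  expect_equal(pairwise_matrix(ds, "sec")["A1", "B1"], ss_distance(ha, hb))

  # identical chains give the all-zero matrix
  same <- toy_chains()[c(1, 1, 1), ]
  same$chain_id <- c("c1", "c2", "c3")
  same$complex_id <- "cx"
  ds_same <- chain_dataset(same)
  for (mn in metric_names()) {
    expect_equal(max(pairwise_matrix(ds_same, mn)), 0)
  }
  expect_error(pairwise_matrix(ds, "euclid"), "arg")
})

test_that("density and dtw metrics are scale-free in sequence length", {
  # proportionally scaled annotations on a doubled sequence leave both
  # PTM metrics unchanged
  a <- list(
    sequence = paste(rep("A", 50L), collapse = ""),
    ptm_sites = tibble::tibble(
      ptm_type = c("PKC-phosphorylation", "USP-domain"),
      start = c(10L, 50L), end = c(10L, 50L)
    )
  )
  a2 <- list(
    sequence = paste(rep("A", 100L), collapse = ""),
    ptm_sites = tibble::tibble(
      ptm_type = c("PKC-phosphorylation", "USP-domain"),
      start = c(20L, 100L), end = c(20L, 100L)
    )
  )
  b <- list(
    sequence = paste(rep("G", 50L), collapse = ""),
    ptm_sites = tibble::tibble(ptm_type = "USP-domain",
                               start = 50L, end = 50L)
  )
  expect_gt(ptm_dtw_distance(a, b), 0)
  # same relative site positions on a doubled chain: dtw unchanged
  expect_equal(ptm_dtw_distance(a, b), ptm_dtw_distance(a2, b))
  # site count scaled with length: densities (hence distance) unchanged
  a_dense <- list(
    sequence = a2$sequence,
    ptm_sites = tibble::tibble(
      ptm_type = rep(c("PKC-phosphorylation", "USP-domain"), each = 2L),
      start = c(20L, 60L, 80L, 100L), end = c(20L, 60L, 80L, 100L)
    )
  )
  expect_equal(ptm_density_vector(a), ptm_density_vector(a_dense))
})
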