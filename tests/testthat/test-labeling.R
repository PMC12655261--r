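test_that("disassembly keeps one record per distinct chain", {
  ds <- toy_dataset()
  expect_equal(nrow(disassemble(ds)$chains), 3L)

  # duplicate chain across complexes: first occurrence survives
  chains <- toy_chains()
  dup <- chains[1, ]
  dup$chain_id <- "A1copy"
  dup$complex_id <- "cplxB"
  chains <- rbind(chains, dup)
  ptm <- rbind(toy_ptm(),
               tibble::tibble(chain_id = "A1copy",
                              ptm_type = c("PKC-phosphorylation",
                                           "N-glycosylation"),
                              start = c(3L, 8L), end = c(5L, 10L)))
  ds_dup <- chain_dataset(chains, ptm)
  out <- disassemble(ds_dup)
  expect_equal(nrow(out$chains), 3L)
  expect_true("A1" %in% out$chains$chain_id)
  expect_false("A1copy" %in% out$chains$chain_id)

  # same sequence but different annotations is NOT a duplicate
  ptm2 <- ptm
  ptm2$start[ptm2$chain_id == "A1copy"][1] <- 4L
  out2 <- disassemble(chain_dataset(chains, ptm2))
  expect_equal(nrow(out2$chains), 4L)

  # complex membership is retained for retroactive localization
  expect_equal(
    out$chains$complex_id[out$chains$chain_id == "A1"], "cplxA"
  )
})

test_that("L1 k-means recovers planted groups and matches brute force", {
  set.seed(21)
  make_groups <- function() {
    g1 <- t(replicate(5, pmax(c(0.8, 0.1, 0.05, 0.05) +
                                c(stats::rnorm(1, 0, 0.02), 0, 0, 0), 0)))
    g2 <- t(replicate(5, pmax(c(0.1, 0.8, 0.05, 0.05) +
                                c(0, stats::rnorm(1, 0, 0.02), 0, 0), 0)))
    x <- rbind(g1, g2)
    x / rowSums(x)
  }
  for (rep in 1:5) {
    x <- make_groups()
    rownames(x) <- sprintf("c%02d", 1:10)
    fit <- kmeans_l1(x, k = 2L, seed = rep)
    # recovered partition must equal the brute-force optimum
    oracle <- best_l1_partition(x)
    same <- identical(unname(fit$assignments), oracle$assignment) ||
      identical(unname(3L - fit$assignments), oracle$assignment)
    expect_true(same)
    expect_equal(fit$cost, oracle$cost, tolerance = 1e-12)
    # planted groups recovered exactly
    expect_length(unique(fit$assignments[1:5]), 1L)
    expect_length(unique(fit$assignments[6:10]), 1L)
    expect_false(fit$assignments[1] == fit$assignments[6])
  }
})

test_that("L1 k-means is deterministic and rejects degenerate input", {
  set.seed(22)
  x <- matrix(runif(40), 10, 4)
  rownames(x) <- letters[1:10]
  f1 <- kmeans_l1(x, seed = 99L)
  f2 <- kmeans_l1(x, seed = 99L)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$centroids, f2$centroids)

  ident <- matrix(0.25, 5, 4)
  expect_error(kmeans_l1(ident, k = 2L, seed = 1L), "distinct")
})

test_that("polarity goes to the positive-complex-enriched cluster", {
  ds <- toy_dataset() # cplxA positive holds A1, A2; cplxB unannotated
  model <- structure(
    list(
      k = 2L,
      centroids = rbind(c(0.4, 0.2, 0.1, 0.3), c(0.25, 0.25, 0.25, 0.25)),
      assignments = c(A1 = 1L, A2 = 1L, B1 = 2L),
      cost = 0, seed = 1L, polarity = NULL
    ),
    class = "l1_kmeans"
  )
  m <- assign_polarity(model, ds)
  # cluster 1 members are 100% from the positive complex
  expect_equal(m$polarity, c("positive", "negative"))

  # equal raw shares of positive-complex chains: enrichment decides
  model$assignments <- c(A1 = 1L, A2 = 2L, B1 = 2L)
  m2 <- assign_polarity(model, ds)
  expect_equal(m2$polarity[1], "positive")

  # exact enrichment tie: the smaller cluster becomes positive
  chains4 <- rbind(toy_chains(),
                   tibble::tibble(chain_id = c("B2", "B3"),
                                  complex_id = "cplxB",
                                  sequence = c("MKAY", "GGLL"),
                                  fH = 0.25, fE = 0.25, fT = 0.25,
                                  fC = 0.25))
  ds4 <- chain_dataset(chains4, toy_ptm(), toy_dataset()$complexes)
  model$assignments <- c(A1 = 1L, B2 = 1L, A2 = 2L, B1 = 2L, B3 = 2L)
  m3 <- assign_polarity(model, ds4)
  # enrichment 1/2 vs ... cluster 1 = {A1, B2}: 1/2; cluster 2 =
  # {A2, B1, B3}: 1/3 -> cluster 1 positive outright
  expect_equal(m3$polarity[1], "positive")
  model$assignments <- c(A1 = 1L, B2 = 1L, A2 = 2L, B1 = 2L)
  # two clusters of two, each half from the positive complex: size tie
  # falls back to the lower index
  m4 <- assign_polarity(model, ds4)
  expect_equal(m4$polarity[1], "positive")

  # no positive complexes is an error
  ds_neg <- chain_dataset(toy_chains(), toy_ptm(),
                          tibble::tibble(complex_id = c("cplxA", "cplxB"),
                                         annotation = "unannotated"))
  expect_error(assign_polarity(model, ds_neg), "no positively annotated")
})

test_that("Correcting Algorithm 1 rescues all-negative positive complexes", {
  ds <- toy_dataset()
  model <- structure(
    list(k = 2L,
         centroids = rbind(c(0.4, 0.2, 0.1, 0.3), c(0.1, 0.5, 0.2, 0.2)),
         assignments = c(A1 = 2L, A2 = 2L, B1 = 2L),
         cost = 0, seed = 1L, polarity = c("positive", "negative")),
    class = "l1_kmeans"
  )
  labels <- tibble::tibble(chain_id = c("A1", "A2", "B1"), label = 0L)
  out <- correcting_algorithm_1(labels, model, ds)
  # A1's SS profile (0.4, 0.2, 0.1, 0.3) IS the positive centroid
  expect_equal(out$label[out$chain_id == "A1"], 1L)
  expect_equal(sum(out$label), 1L)
  expect_equal(attr(out, "flips"), "A1")

  # a positive complex already holding a positive chain is untouched
  labels2 <- tibble::tibble(chain_id = c("A1", "A2", "B1"),
                            label = c(0L, 1L, 0L))
  out2 <- correcting_algorithm_1(labels2, model, ds)
  expect_equal(out2$label, labels2$label)
  expect_length(attr(out2, "flips"), 0L)

  # distance ties break by chain id order
  chains <- toy_chains()
  chains[c(1, 2), c("fH", "fE", "fT", "fC")] <-
    rbind(c(0.3, 0.3, 0.2, 0.2), c(0.3, 0.3, 0.2, 0.2))
  ds_tie <- chain_dataset(chains, toy_ptm(),
                          toy_dataset()$complexes)
  out3 <- correcting_algorithm_1(labels, model, ds_tie)
  expect_equal(attr(out3, "flips"), "A1")
})

test_that("Correcting Algorithm 2 reverts positives in unannotated complexes", {
  ds <- toy_dataset()
  labels <- tibble::tibble(chain_id = c("A1", "A2", "B1"),
                           label = c(1L, 0L, 1L))
  out <- correcting_algorithm_2(labels, ds)
  expect_equal(out$label[out$chain_id == "B1"], 0L) # reverted
  expect_equal(out$label[out$chain_id == "A1"], 1L) # positive complex kept
  expect_equal(attr(out, "reverted"), "B1")
  # already all-negative unannotated complex unchanged
  out2 <- correcting_algorithm_2(out, ds)
  expect_equal(out2$label, out$label)
})

test_that("label pipeline postconditions hold on random complex layouts", {
  set.seed(23)
  for (i in 1:40) {
    ds <- random_complex_dataset(n_pos = sample(2:4, 1L),
                                 n_neg = sample(5:9, 1L))
    lab <- label_pipeline(ds, seed = i)
    stat <- dplyr::left_join(
      lab$chains[, c("chain_id", "complex_id")], lab$labels, by = "chain_id"
    ) %>%
      dplyr::left_join(lab$complexes, by = "complex_id") %>%
      dplyr::group_by(.data$complex_id, .data$annotation) %>%
      dplyr::summarise(n_pos = sum(.data$label), .groups = "drop")
    # every positive complex keeps >= 1 positive chain
    expect_true(all(stat$n_pos[stat$annotation == "positive"] >= 1L))
    # every unannotated complex is all-negative
    expect_true(all(stat$n_pos[stat$annotation == "unannotated"] == 0L))
  }
})

test_that("corrections-off equals raw polarity-mapped clustering", {
  set.seed(24)
  ds <- random_complex_dataset(n_pos = 3L, n_neg = 8L)
  lab_off <- label_pipeline(ds, seed = 5L, apply_corrections = FALSE)
  model <- attr(lab_off, "cluster_model")
  raw <- as.integer(model$polarity[model$assignments] == "positive")
  expect_equal(lab_off$labels$label, raw)
  # determinism: identical labels for identical seeds
  lab_off2 <- label_pipeline(ds, seed = 5L, apply_corrections = FALSE)
  expect_identical(lab_off$labels, lab_off2$labels)
})

test_that("correction order does not matter and changes are bounded", {
  set.seed(25)
  for (i in 1:20) {
    ds <- random_complex_dataset(n_pos = 2L, n_neg = 6L)
    d <- disassemble(ds)
    model <- assign_polarity(kmeans_l1(d$chains, seed = i), d)
    labels <- drugspace:::cluster_labels(model)

    a12 <- correcting_algorithm_2(
      correcting_algorithm_1(labels, model, d), d
    )
    a21 <- correcting_algorithm_1(
      correcting_algorithm_2(labels, d), model, d
    )
    # algorithms act on disjoint complex sets, so order is irrelevant
    expect_equal(a12$label, a21$label)

    # algorithm 1 flips at most one label per positive complex
    flips <- attr(correcting_algorithm_1(labels, model, d), "flips")
    n_pos_cplx <- sum(d$complexes$annotation == "positive")
    expect_lte(length(flips), n_pos_cplx)
    # algorithm 2 never creates a positive label
    expect_lte(sum(correcting_algorithm_2(labels, d)$label),
               sum(labels$label))
  }
})
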