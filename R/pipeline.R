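#' End-to-end druggability pipeline
#'
#' Chains the stages simulate (or load) -> distances -> label ->
#' evaluate -> permutation test -> ablation -> diagnostics, writing
#' every artifact (TSV tables, JSON reports and a reproducibility
#' manifest with the configuration hash and seeds) into `out_dir`.
#'
#' @param config Named list (or path to a JSON file) with optional
#'   entries: `seed` (default 1), `k` (default 5), `members` (default
#'   all four metrics), `apply_corrections` (default `TRUE`),
#'   `permutations` (default 200), `generator` (arguments for
#'   [generator_config()]), and `input` (named paths `fasta`, `ss`,
#'   `ptm`, `labels` to load a dataset instead of simulating one).
#' @param out_dir Output directory, created if needed.
#' @param stages Character vector of stages to run, in dependency order;
#'   default all.
#' @return Named list of the in-memory results (`dataset`, `labeled`,
#'   `matrices`, `loocv`, `permutation`, `ablation`, `diagnostics`),
#'   invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = "drugspace-run",
                         stages = c("simulate", "distances", "label",
                                    "evaluate", "permtest", "ablate",
                                    "diagnose")) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  seed <- as.integer(config$seed %||% 1L)
  k <- as.integer(config$k %||% 5L)
  members <- config$members %||% metric_names()
  ecfg <- ensemble_config(members, k)
  m_perm <- as.integer(config$permutations %||% 200L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  res <- list()
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(code, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  if ("simulate" %in% stages || is.null(config$input)) {
    res$dataset <- stage("simulate", {
      gcfg <- do.call(generator_config, config$generator %||% list())
      ds <- generate_dataset(gcfg, seed = seed)
      write_chain_dataset(ds, file.path(out_dir, "dataset"))
      ds
    })
  } else {
    res$dataset <- stage("load", {
      inp <- config$input
      read_chain_dataset(inp$fasta, inp$ss, inp$ptm, inp$labels)
    })
  }

  if ("label" %in% stages) {
    res$labeled <- stage("label", {
      lab <- label_pipeline(
        res$dataset, seed = seed,
        apply_corrections = isTRUE(config$apply_corrections %||% TRUE)
      )
      readr::write_tsv(lab$labels, file.path(out_dir, "labels.tsv"))
      model <- attr(lab, "cluster_model")
      jsonlite::write_json(
        list(
          centroids = model$centroids, polarity = model$polarity,
          cost = model$cost, flips = attr(lab, "flips"),
          reverted = attr(lab, "reverted")
        ),
        file.path(out_dir, "clustering.json"),
        auto_unbox = TRUE, digits = NA
      )
      lab
    })
  } else {
    res$labeled <- res$dataset
  }

  if ("distances" %in% stages) {
    res$matrices <- stage("distances", {
      mats <- pairwise_matrices(res$labeled, members)
      for (mn in names(mats)) {
        write_distance_matrix(
          mats[[mn]], file.path(out_dir, paste0("distance_", mn, ".tsv"))
        )
      }
      mats
    })
  }

  if ("evaluate" %in% stages) {
    res$loocv <- stage("evaluate", {
      fit <- loocv(res$labeled, res$matrices, ecfg)
      readr::write_tsv(fit$predictions, file.path(out_dir, "predictions.tsv"))
      jsonlite::write_json(as.list(fit$metrics),
                           file.path(out_dir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA)
      fit
    })
  }

  if ("permtest" %in% stages) {
    res$permutation <- stage("permtest", {
      pt <- permutation_test(res$labeled, res$matrices, ecfg,
                             m = m_perm, seed = seed)
      jsonlite::write_json(glance(pt) %>% as.list(),
                           file.path(out_dir, "permutation.json"),
                           auto_unbox = TRUE, digits = NA)
      pt
    })
  }

  if ("ablate" %in% stages) {
    res$ablation <- stage("ablate", {
      ab <- ablation_suite(res$dataset, res$matrices, ecfg, seed = seed)
      readr::write_tsv(ab, file.path(out_dir, "ablation.tsv"))
      ab
    })
  }

  if ("diagnose" %in% stages) {
    res$diagnostics <- stage("diagnose", {
      dg <- neighbor_diagnostics(
        res$matrices, res$labeled$labels,
        predictions = if (!is.null(res$loocv)) res$loocv$predictions,
        k = min(k, nrow(res$labeled$chains) - 1L)
      )
      readr::write_tsv(dg, file.path(out_dir, "diagnostics.tsv"))
      dg
    })
  }

  manifest <- list(
    seed = seed, k = k, members = members,
    permutations = m_perm,
    config_hash = rlang::hash(config),
    stages = stages,
    n_chains = nrow(res$labeled$chains)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
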