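#' Read a chain dataset from FASTA plus annotation tables
#'
#' Sequences come from a FASTA file whose record headers carry the chain
#' id as the first whitespace-separated token and, optionally, the
#' complex id as the second (chains without one form their own
#' single-chain complex). Secondary-structure proportions, PTM sites and
#' labels arrive as tab-separated tables with header rows. Every record
#' referencing an unknown chain id, violating the simplex constraint, or
#' using a PTM type outside the seven-category vocabulary is rejected.
#'
#' @param fasta_path FASTA file of amino-acid sequences.
#' @param ss_table_path TSV with columns `chain_id, fH, fE, fT, fC`.
#' @param ptm_table_path TSV with columns `chain_id, ptm_type, start,
#'   end` (1-based inclusive residue intervals).
#' @param labels_path Optional TSV in one of two schemas, detected from
#'   the header: complex-level `complex_id, annotation`
#'   (positive/unannotated) or chain-level `chain_id, label` (0/1).
#' @return A [chain_dataset()].
#' @export
read_chain_dataset <- function(fasta_path, ss_table_path, ptm_table_path,
                               labels_path = NULL) {
  for (p in c(fasta_path, ss_table_path, ptm_table_path, labels_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  seqs <- Biostrings::readAAStringSet(fasta_path)
  header <- strsplit(names(seqs), "\\s+")
  ids <- vapply(header, `[[`, character(1), 1L)
  cplx <- vapply(header, function(h) if (length(h) >= 2L) h[[2L]] else h[[1L]],
                 character(1))

  ss <- readr::read_tsv(ss_table_path, show_col_types = FALSE)
  unknown <- setdiff(ss$chain_id, ids)
  if (length(unknown) > 0) {
    abort(paste0("SS rows reference unknown chain_id(s): ", toString(unknown)))
  }
  missing_ss <- setdiff(ids, ss$chain_id)
  if (length(missing_ss) > 0) {
    abort(paste0("no SS row for chain(s): ", toString(missing_ss)))
  }
  ss <- ss[match(ids, ss$chain_id), ]

  chains <- tibble(
    chain_id = ids, complex_id = cplx,
    sequence = unname(as.character(seqs)),
    fH = ss$fH, fE = ss$fE, fT = ss$fT, fC = ss$fC
  )

  ptm <- readr::read_tsv(ptm_table_path, show_col_types = FALSE)

  complexes <- NULL
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- readr::read_tsv(labels_path, show_col_types = FALSE)
    if (all(c("complex_id", "annotation") %in% names(lab))) {
      unknown <- setdiff(lab$complex_id, cplx)
      if (length(unknown) > 0) {
        abort(paste0("label rows reference unknown complex_id(s): ",
                     toString(unknown)))
      }
      extra <- setdiff(cplx, lab$complex_id)
      complexes <- rbind(
        lab[, c("complex_id", "annotation")],
        tibble(complex_id = extra, annotation = "unannotated")
      )
    } else if (all(c("chain_id", "label") %in% names(lab))) {
      unknown <- setdiff(lab$chain_id, ids)
      if (length(unknown) > 0) {
        abort(paste0("label rows reference unknown chain_id(s): ",
                     toString(unknown)))
      }
      labels <- lab[, c("chain_id", "label")]
    } else {
      abort(paste0(
        "labels table must have columns (complex_id, annotation) or ",
        "(chain_id, label)"
      ))
    }
  }

  chain_dataset(chains, ptm, complexes, labels)
}

#' Write a chain dataset as FASTA plus annotation tables
#'
#' Inverse of [read_chain_dataset()]: writes `chains.fasta` (chain id
#' and complex id in the header), `ss.tsv`, `ptm.tsv`, `complexes.tsv`
#' and, when labels are present, `labels.tsv` into `dir`.
#'
#' @param dataset A [chain_dataset()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_chain_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "chain_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "chains.fasta"),
    ss = file.path(dir, "ss.tsv"),
    ptm = file.path(dir, "ptm.tsv"),
    complexes = file.path(dir, "complexes.tsv"),
    labels = file.path(dir, "labels.tsv")
  )
  seqs <- Biostrings::AAStringSet(dataset$chains$sequence)
  names(seqs) <- paste(dataset$chains$chain_id, dataset$chains$complex_id)
  Biostrings::writeXStringSet(seqs, paths[["fasta"]])
  readr::write_tsv(
    dataset$chains[, c("chain_id", "fH", "fE", "fT", "fC")], paths[["ss"]]
  )
  readr::write_tsv(dataset$ptm_sites, paths[["ptm"]])
  readr::write_tsv(dataset$complexes, paths[["complexes"]])
  if (is.null(dataset$labels)) {
    paths <- paths[names(paths) != "labels"]
  } else {
    readr::write_tsv(dataset$labels, paths[["labels"]])
  }
  invisible(paths)
}

#' Write a distance matrix as TSV
#'
#' Tab-separated with chain ids both as a leading `chain_id` column and
#' as column headers; full double precision, so a write/read round trip
#' reproduces values exactly. Asymmetric input is an error.
#'
#' @param x A `distance_matrix` (or plain symmetric matrix with
#'   dimnames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(x, path) {
  m <- unclass(x)
  if (nrow(m) != ncol(m)) abort("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-9) abort("distance matrix must be symmetric")
  df <- as_tibble(as.data.frame(m, check.names = FALSE))
  df <- tibble(chain_id = rownames(m)) %>% dplyr::bind_cols(df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a distance matrix from TSV
#'
#' @param path TSV written by [write_distance_matrix()].
#' @param metric Metric name to attach (default: parsed from the file
#'   name if it contains one of [metric_names()], else `"unknown"`).
#' @return A `distance_matrix`, with id order as stored.
#' @export
read_distance_matrix <- function(path, metric = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- df$chain_id
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(ids) || anyDuplicated(colnames(m))) {
    abort("duplicate chain_id in distance matrix header")
  }
  if (!identical(as.character(ids), colnames(m))) {
    abort("row and column headers of distance matrix disagree")
  }
  if (is.null(metric)) {
    hit <- metric_names()[vapply(metric_names(), grepl, logical(1),
                                 x = basename(path), fixed = TRUE)]
    metric <- if (length(hit) == 1L) hit else "unknown"
  }
  storage.mode(m) <- "double"
  new_distance_matrix(m, as.character(ids), metric)
}
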