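#' The seven modification categories tracked by the framework
#'
#' Six post-translational modification classes (N-myristoylation, three
#' kinase phosphorylation classes, cAMP/cGMP-dependent kinase
#' phosphorylation, N-glycosylation) plus the ubiquitin-specific protease
#' (USP) domain, treated as a seventh annotation category. The vocabulary
#' is closed: any other token in a PTM table is an error.
#'
#' @return Character vector of length 7, in canonical order.
#' @export
#' @examples
#' ptm_types()
ptm_types <- function() {
  c(
    "N-myristoylation",
    "PKC-phosphorylation",
    "CK2-phosphorylation",
    "Tyr-kinase-phosphorylation",
    "cAMP-cGMP-PK-phosphorylation",
    "N-glycosylation",
    "USP-domain"
  )
}

#' The twenty standard amino-acid one-letter codes
#'
#' @return Character vector of length 20, alphabetical.
#' @export
amino_acids <- function() {
  c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
}

# simplex tolerance for secondary-structure proportion vectors
.ss_tol <- 1e-6

#' Assemble a validated chain dataset
#'
#' Bundles per-chain records (sequence plus secondary-structure
#' proportions), PTM site annotations, complex membership and optional
#' binary druggability labels into a single validated container. Every
#' invariant is checked eagerly: violations raise errors rather than
#' being silently clamped.
#'
#' @param chains Data frame with columns `chain_id`, `complex_id`,
#'   `sequence` (20-letter amino-acid alphabet), and the four
#'   secondary-structure fractions `fH`, `fE`, `fT`, `fC` which must be
#'   in `[0, 1]` and sum to 1 within `1e-6`.
#' @param ptm_sites Data frame with columns `chain_id`, `ptm_type` (one
#'   of [ptm_types()]), `start`, `end` (1-based inclusive residue
#'   indices, within the chain). May be empty.
#' @param complexes Data frame with columns `complex_id`, `annotation`
#'   (`"positive"` for a known drug-binding complex, else
#'   `"unannotated"`). If `NULL`, one unannotated complex per distinct
#'   `complex_id` is created.
#' @param labels Optional data frame with columns `chain_id`, `label`
#'   (0/1); every chain must receive exactly one label.
#'
#' @return An object of class `chain_dataset`: a list with tibbles
#'   `chains`, `ptm_sites`, `complexes` and (possibly `NULL`) `labels`.
#' @export
#' @examples
#' chains <- tibble::tibble(
#'   chain_id = c("A1", "B1"), complex_id = c("cplxA", "cplxB"),
#'   sequence = c("MKTAYIAKQR", "GGIILVVAAK"),
#'   fH = c(0.4, 0.1), fE = c(0.2, 0.5), fT = c(0.1, 0.2), fC = c(0.3, 0.2)
#' )
#' chain_dataset(chains)
chain_dataset <- function(chains, ptm_sites = NULL, complexes = NULL,
                          labels = NULL) {
  chains <- as_tibble(chains)
  need <- c("chain_id", "complex_id", "sequence", "fH", "fE", "fT", "fC")
  miss <- setdiff(need, names(chains))
  if (length(miss) > 0) {
    abort(paste0("`chains` is missing column(s): ", toString(miss)))
  }
  chains <- chains[, need]
  chains$chain_id <- as.character(chains$chain_id)
  chains$complex_id <- as.character(chains$complex_id)

  if (anyDuplicated(chains$chain_id)) {
    abort(paste0(
      "duplicate chain_id: ",
      toString(unique(chains$chain_id[duplicated(chains$chain_id)]))
    ))
  }
  if (any(!nzchar(chains$sequence))) abort("empty sequence")
  bad <- grepl(paste0("[^", paste(amino_acids(), collapse = ""), "]"),
               chains$sequence)
  if (any(bad)) {
    abort(paste0(
      "sequence with non-standard letters for chain(s): ",
      toString(chains$chain_id[bad])
    ))
  }

  ss <- as.matrix(chains[, c("fH", "fE", "fT", "fC")])
  if (any(!is.finite(ss)) || any(ss < 0) || any(ss > 1)) {
    abort("secondary-structure fractions must lie in [0, 1]")
  }
  off <- abs(rowSums(ss) - 1) > .ss_tol
  if (any(off)) {
    abort(paste0(
      "secondary-structure fractions must sum to 1 (chain(s): ",
      toString(chains$chain_id[off]), ")"
    ))
  }

  if (is.null(ptm_sites)) {
    ptm_sites <- tibble(
      chain_id = character(), ptm_type = character(),
      start = integer(), end = integer()
    )
  }
  ptm_sites <- as_tibble(ptm_sites)[, c("chain_id", "ptm_type", "start", "end")]
  ptm_sites$chain_id <- as.character(ptm_sites$chain_id)
  ptm_sites$ptm_type <- as.character(ptm_sites$ptm_type)
  ptm_sites$start <- as.integer(ptm_sites$start)
  ptm_sites$end <- as.integer(ptm_sites$end)

  unk <- setdiff(ptm_sites$ptm_type, ptm_types())
  if (length(unk) > 0) {
    abort(paste0("unknown ptm_type token(s): ", toString(unk)))
  }
  orphan <- setdiff(ptm_sites$chain_id, chains$chain_id)
  if (length(orphan) > 0) {
    abort(paste0("PTM rows reference unknown chain_id(s): ", toString(orphan)))
  }
  if (nrow(ptm_sites) > 0) {
    len <- nchar(chains$sequence)[match(ptm_sites$chain_id, chains$chain_id)]
    bad <- ptm_sites$start < 1L | ptm_sites$end < ptm_sites$start |
      ptm_sites$end > len
    if (any(bad)) {
      abort(paste0(
        "PTM interval outside [1, chain length] (1-based inclusive) for ",
        "chain(s): ", toString(unique(ptm_sites$chain_id[bad]))
      ))
    }
  }

  if (is.null(complexes)) {
    complexes <- tibble(
      complex_id = unique(chains$complex_id),
      annotation = "unannotated"
    )
  }
  complexes <- as_tibble(complexes)[, c("complex_id", "annotation")]
  complexes$complex_id <- as.character(complexes$complex_id)
  if (anyDuplicated(complexes$complex_id)) abort("duplicate complex_id")
  if (!all(complexes$annotation %in% c("positive", "unannotated"))) {
    abort("complex annotation must be 'positive' or 'unannotated'")
  }
  dangling <- setdiff(chains$complex_id, complexes$complex_id)
  if (length(dangling) > 0) {
    abort(paste0("chain complex_id(s) missing from complexes: ",
                 toString(dangling)))
  }

  if (!is.null(labels)) {
    labels <- as_tibble(labels)[, c("chain_id", "label")]
    labels$chain_id <- as.character(labels$chain_id)
    labels$label <- as.integer(labels$label)
    if (!all(labels$label %in% c(0L, 1L))) abort("labels must be 0 or 1")
    if (anyDuplicated(labels$chain_id)) abort("duplicate label rows")
    if (!setequal(labels$chain_id, chains$chain_id)) {
      abort("every chain must have exactly one label")
    }
    labels <- labels[match(chains$chain_id, labels$chain_id), ]
  }

  structure(
    list(chains = chains, ptm_sites = ptm_sites, complexes = complexes,
         labels = labels),
    class = "chain_dataset"
  )
}

#' @export
print.chain_dataset <- function(x, ...) {
  n_pos <- sum(x$complexes$annotation == "positive")
  cat(sprintf(
    "<chain_dataset> %d chains, %d complexes (%d positive), %d PTM sites\n",
    nrow(x$chains), nrow(x$complexes), n_pos, nrow(x$ptm_sites)
  ))
  if (!is.null(x$labels)) {
    cat(sprintf("labels: %d positive / %d negative\n",
                sum(x$labels$label == 1L), sum(x$labels$label == 0L)))
  }
  invisible(x)
}

#' Chain identifiers of a dataset, in storage order
#' @param dataset A [chain_dataset()].
#' @return Character vector.
#' @export
chain_ids <- function(dataset) {
  stopifnot(inherits(dataset, "chain_dataset"))
  dataset$chains$chain_id
}

#' Per-chain PTM sites as a named list
#'
#' @param dataset A [chain_dataset()].
#' @return Named list (one element per chain, in dataset order) of
#'   tibbles with columns `ptm_type`, `start`, `end`.
#' @keywords internal
ptm_sites_by_chain <- function(dataset) {
  ids <- chain_ids(dataset)
  out <- lapply(ids, function(id) {
    dataset$ptm_sites[dataset$ptm_sites$chain_id == id,
                      c("ptm_type", "start", "end")]
  })
  names(out) <- ids
  out
}
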