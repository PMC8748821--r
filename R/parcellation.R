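#' Canonical cortical communities and subcortical structures
#'
#' Seven cortical functional communities (Yeo-style) and seven subcortical
#' structures used throughout the pipeline for network-level aggregation.
#'
#' @name networks
NULL

#' @rdname networks
#' @export
cortical_communities <- c(
  "visual", "somatomotor", "dorsal_attention", "ventral_attention",
  "limbic", "frontoparietal", "default_mode"
)

#' @rdname networks
#' @export
subcortical_labels <- c(
  "amygdala", "hippocampus", "globus_pallidus", "nucleus_accumbens",
  "putamen", "caudate", "thalamus"
)

#' Build a default parcellation
#'
#' Deterministically assigns `n_regions` regions to the 7 cortical
#' communities and 7 subcortical structures, in equal proportions with
#' largest-remainder apportionment (earlier labels in the fixed order absorb
#' remainders). Stands in for an atlas such as the 246-region Brainnetome
#' parcellation when only community structure matters.
#'
#' @param n_regions Number of regions; at least 14 so every label is
#'   non-empty.
#' @return A tibble with columns `region_id` (1-based, contiguous),
#'   `region_name`, `network` (community or subcortical label), and
#'   `is_subcortical`.
#' @examples
#' default_parcellation(28)
#' @export
default_parcellation <- function(n_regions) {
  if (!is.numeric(n_regions) || length(n_regions) != 1L || n_regions < 14) {
    abort_input("n_regions must be a single number >= 14 (one region per label)")
  }
  n_regions <- as.integer(n_regions)
  labels <- c(cortical_communities, subcortical_labels)
  sizes <- apportion_equal(n_regions, length(labels))
  network <- rep(labels, times = sizes)
  tibble::tibble(
    region_id = seq_len(n_regions),
    region_name = sprintf("%s_%02d", network,
                          stats::ave(seq_len(n_regions), network,
                                     FUN = seq_along)),
    network = network,
    is_subcortical = network %in% subcortical_labels
  )
}

# largest-remainder apportionment of n into k equal shares; deterministic
# (remainders go to the earliest labels)
apportion_equal <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  base + as.integer(seq_len(k) <= rem)
}

#' Parcellation from explicit community sizes
#'
#' @param community_sizes Named integer vector; names must be drawn from the
#'   7 communities and 7 subcortical labels, each appearing once.
#' @return A parcellation tibble as in [default_parcellation()].
#' @export
parcellation_from_sizes <- function(community_sizes) {
  labels <- c(cortical_communities, subcortical_labels)
  if (is.null(names(community_sizes)) ||
      !all(names(community_sizes) %in% labels)) {
    abort_input("community_sizes must be named by community/subcortical labels")
  }
  if (anyDuplicated(names(community_sizes))) {
    abort_input("duplicated label in community_sizes")
  }
  sizes <- community_sizes[order(match(names(community_sizes), labels))]
  if (any(sizes < 1)) abort_input("every listed label needs >= 1 region")
  network <- rep(names(sizes), times = sizes)
  n <- length(network)
  tibble::tibble(
    region_id = seq_len(n),
    region_name = sprintf("%s_%02d", network,
                          stats::ave(seq_len(n), network, FUN = seq_along)),
    network = network,
    is_subcortical = network %in% subcortical_labels
  )
}

check_parcellation <- function(parcellation, n_regions = NULL) {
  req <- c("region_id", "region_name", "network")
  if (!all(req %in% names(parcellation))) {
    abort_input(sprintf("parcellation must have columns: %s",
                        paste(req, collapse = ", ")))
  }
  ids <- parcellation$region_id
  if (!identical(as.integer(ids), seq_along(ids))) {
    abort_input("region_ids must be unique and contiguous from 1")
  }
  known <- c(cortical_communities, subcortical_labels, "subcortical")
  bad <- setdiff(unique(parcellation$network), known)
  if (length(bad)) {
    abort_input(sprintf("unknown network label(s): %s",
                        paste(bad, collapse = ", ")))
  }
  if (!is.null(n_regions) && nrow(parcellation) != n_regions) {
    abort_input(sprintf("parcellation has %d regions, expected %d",
                        nrow(parcellation), n_regions))
  }
  invisible(parcellation)
}
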