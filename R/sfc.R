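#' Threshold and binarize a connectivity matrix
#'
#' Retains the strongest edges of a weighted connectivity matrix: the cutoff
#' is the `percentile`-th percentile (type-7 quantile) of the upper-triangle
#' edge weights, and an edge survives iff its weight exceeds the cutoff.
#' By default ranking uses signed weights, so a 95% threshold keeps the top
#' 5% most-positive edges; `edge_rank = "absolute"` ranks by magnitude
#' instead (strong negative partial correlations then count as
#' connections).
#'
#' @param fc Symmetric connectivity matrix.
#' @param percentile Retention level in (0, 100); default 95.
#' @param edge_rank `"signed"` (default) or `"absolute"`.
#' @return Symmetric 0/1 adjacency matrix of class `sfc_graph` with zero
#'   diagonal and attribute `threshold` (the cutoff weight).
#' @export
threshold_binarize <- function(fc, percentile = 95,
                               edge_rank = c("signed", "absolute")) {
  edge_rank <- match.arg(edge_rank)
  w <- unclass(as.matrix(fc))
  check_finite(w, "connectivity matrix")
  if (nrow(w) != ncol(w)) abort_input("connectivity matrix must be square")
  if (percentile < 0 || percentile >= 100) {
    abort_input("percentile must lie in [0, 100)")
  }
  if (edge_rank == "absolute") w <- abs(w)
  if (percentile == 0) { # retain everything: complete graph minus diagonal
    a <- matrix(1L, nrow(w), ncol(w))
    diag(a) <- 0L
    dimnames(a) <- dimnames(w)
    return(structure(a, class = c("sfc_graph", class(a)),
                     threshold = -Inf, percentile = 0))
  }
  ut <- w[upper.tri(w)]
  if (diff(range(ut)) == 0) {
    abort_input("all edge weights are equal; threshold is undefined")
  }
  cutoff <- stats::quantile(ut, percentile / 100, names = FALSE)
  a <- (w > cutoff) * 1L
  a <- a * t(a) # symmetric by construction, but guard against asymmetric input
  a[a > 0] <- 1L
  diag(a) <- 0L
  dimnames(a) <- dimnames(w)
  structure(a, class = c("sfc_graph", class(a)), threshold = cutoff,
            percentile = percentile)
}

#' Stepwise walk counts from a seed set
#'
#' Counts, for each step distance `k = 1 .. max_step`, the number of
#' length-`k` walks on the binarized graph that start at any seed region and
#' end at each target region: `counts_k = (A^k)[seeds, ] summed over seeds`,
#' computed by iterated multiplication `counts_{k+1} = counts_k %*% A` in
#' exact integer (double) arithmetic. Step 1 is conventional seed
#' connectivity; higher steps capture progressively more indirect routes.
#' Revisits are allowed (walks, not simple paths).
#'
#' @param graph 0/1 adjacency matrix (see [threshold_binarize()]).
#' @param seeds Integer vector of seed region ids (row indices), non-empty.
#' @param max_step Largest step distance (default 5).
#' @return Numeric `max_step` x R matrix of non-negative integer counts,
#'   rows named `step1..stepK`. Counts beyond 2^53 abort (they would lose
#'   integer exactness).
#' @export
sfc_walk_counts <- function(graph, seeds, max_step = 5) {
  a <- unclass(as.matrix(graph))
  r <- nrow(a)
  if (!all(a %in% c(0, 1))) abort_input("graph must be a 0/1 adjacency matrix")
  if (any(diag(a) != 0)) abort_input("graph must have a zero diagonal")
  if (!isTRUE(all.equal(a, t(a)))) abort_input("graph must be symmetric")
  if (length(seeds) == 0L) abort_input("seed set is empty")
  seeds <- unique(as.integer(seeds))
  if (any(seeds < 1L | seeds > r)) abort_input("seed ids outside 1..R")
  if (max_step < 1) abort_input("max_step must be >= 1")
  max_step <- as.integer(max_step)

  counts <- matrix(0, max_step, r,
                   dimnames = list(paste0("step", seq_len(max_step)),
                                   colnames(a)))
  cur <- colSums(a[seeds, , drop = FALSE]) # step 1: sum of seed rows
  counts[1L, ] <- cur
  if (max_step > 1L) {
    for (k in 2:max_step) {
      cur <- drop(cur %*% a)
      if (any(cur >= 2^53)) {
        abort_input(sprintf("walk counts exceed 2^53 at step %d; reduce max_step or graph density", k))
      }
      counts[k, ] <- cur
    }
  }
  if (all(counts[1L, ] == 0)) {
    warning("all seeds are isolated; walk counts are zero", call. = FALSE)
  }
  counts
}

#' Z-normalize walk counts within each step
#'
#' Centers and scales each step's counts across regions using the
#' population (1/N) standard deviation, yielding the per-step "step
#' degrees" that are compared across subjects and groups. A step with
#' zero variance is returned as an all-zero row and flagged.
#'
#' @param raw_counts Steps x R count matrix from [sfc_walk_counts()].
#' @return Matrix of the same shape; attribute `degenerate_steps` lists
#'   zero-variance steps.
#' @export
z_normalize_steps <- function(raw_counts) {
  x <- as.matrix(raw_counts)
  check_finite(x, "raw_counts")
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  degenerate <- sd_pop == 0
  z <- (x - mu) / ifelse(degenerate, 1, sd_pop)
  z[degenerate, ] <- 0
  structure(z, degenerate_steps = which(degenerate))
}

#' Detect hub regions
#'
#' A region is a hub at a given step if its degree exceeds
#' `multiplier x mean(degree)`. Because z-normalized step degrees have mean
#' zero (making a multiplicative rule degenerate), degrees are first
#' shifted by their minimum to be non-negative (`shift = "min"`, default);
#' `shift = "none"` applies the rule to the values as given (appropriate
#' for raw counts).
#'
#' @param step_degrees Numeric vector of per-region degrees at one step, or
#'   a steps x R matrix (each row treated separately).
#' @param multiplier Hub criterion multiplier (default 1.5).
#' @param shift `"min"` (default) or `"none"`.
#' @return For a vector, an integer vector of hub region indices; for a
#'   matrix, a named list of such vectors per step.
#' @export
detect_hubs <- function(step_degrees, multiplier = 1.5,
                        shift = c("min", "none")) {
  shift <- match.arg(shift)
  if (is.matrix(step_degrees)) {
    out <- apply(step_degrees, 1L, detect_hubs, multiplier = multiplier,
                 shift = shift, simplify = FALSE)
    return(out)
  }
  d <- as.numeric(step_degrees)
  check_finite(d, "step_degrees")
  if (shift == "min") d <- d - min(d)
  if (any(d < 0)) abort_input("degrees must be non-negative (use shift = 'min')")
  which(d > multiplier * mean(d))
}

#' Run stepwise functional connectivity for a whole cohort
#'
#' Per subject: estimate partial correlation (unless connectivity matrices
#' are supplied), threshold and binarize, count walks from the seed set at
#' steps `1..max_step`, and z-normalize each step. Per-subject failures are
#' collected, not fatal.
#'
#' @param cohort An `sfc_cohort` (see [simulate_cohort()] /
#'   [read_cohort()]), or a list of per-subject connectivity matrices.
#' @param seeds Integer vector of seed region ids.
#' @param percentile Edge-retention percentile (default 95).
#' @param max_step Largest step distance (default 5).
#' @param rho Ridge parameter for connectivity estimation (default 0.5).
#' @param edge_rank Edge ranking convention, see [threshold_binarize()].
#' @return Object of class `sfc_result`: list with `z_degrees` (subjects x
#'   steps x R array), `raw_counts` (same shape), `subject_ids`, `seeds`,
#'   `max_step`, `failures` (tibble of subject id + message).
#' @export
run_sfc_cohort <- function(cohort, seeds, percentile = 95, max_step = 5,
                           rho = 0.5, edge_rank = "signed") {
  mats <- cohort_connectivity(cohort, rho = rho)
  ids <- names(mats)
  r <- nrow(mats[[1L]])
  z <- array(NA_real_, c(length(mats), max_step, r),
             dimnames = list(ids, paste0("step", seq_len(max_step)),
                             colnames(mats[[1L]])))
  raw <- z
  failures <- list()
  for (i in seq_along(mats)) {
    res <- tryCatch({
      g <- threshold_binarize(mats[[i]], percentile = percentile,
                              edge_rank = edge_rank)
      counts <- sfc_walk_counts(g, seeds, max_step = max_step)
      list(raw = counts, z = z_normalize_steps(counts))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble::tibble(subject_id = ids[i], message = conditionMessage(res))
    } else {
      raw[i, , ] <- res$raw
      z[i, , ] <- res$z
    }
  }
  structure(list(z_degrees = z, raw_counts = raw, subject_ids = ids,
                 seeds = sort(unique(as.integer(seeds))),
                 max_step = as.integer(max_step), percentile = percentile,
                 failures = dplyr::bind_rows(failures)),
            class = "sfc_result")
}

# coerce cohort-like input into a named list of connectivity matrices
cohort_connectivity <- function(cohort, rho = 0.5) {
  if (inherits(cohort, "sfc_cohort")) {
    ids <- cohort$phenotypes$subject_id
    mats <- purrr::map(cohort$timeseries, partial_correlation, rho = rho)
    names(mats) <- ids
    return(mats)
  }
  if (is.list(cohort) && all(purrr::map_lgl(cohort, is.matrix))) {
    if (is.null(names(cohort))) names(cohort) <- paste0("sub", seq_along(cohort))
    return(cohort)
  }
  abort_input("cohort must be an sfc_cohort or a list of connectivity matrices")
}

#' @export
print.sfc_result <- function(x, ...) {
  cat(sprintf(
    "<sfc_result> %d subjects, %d regions, steps 1-%d, %d seed region(s)\n",
    length(x$subject_ids), dim(x$z_degrees)[3L], x$max_step,
    length(x$seeds)))
  if (nrow(x$failures)) {
    cat(sprintf("  %d subject(s) failed\n", nrow(x$failures)))
  }
  invisible(x)
}
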