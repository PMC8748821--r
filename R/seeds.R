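#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR-adjusted p-values (q-values): `q_(i) = min_{j >= i}
#' (p_(j) * m / j)` clipped at 1 and mapped back to the input order. Thin
#' wrapper around [stats::p.adjust()] with domain checks.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.005, 0.05, 0.5))
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) abort_input("p must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort_input("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Correlate regional degree centrality with a phenotype
#'
#' Per-region Pearson correlation between degree centrality and a continuous
#' phenotype across subjects, with two-sided p-values from the exact t
#' transform (`t = r * sqrt(n-2) / sqrt(1-r^2)`, n-2 df) and BH-FDR
#' q-values. Regions with `q < alpha` form the seed set for stepwise
#' connectivity.
#'
#' @param degrees Numeric subjects x R matrix of degree centralities
#'   (columns named by region where available).
#' @param phenotype Numeric vector, one value per subject (e.g. WHR).
#' @param alpha FDR level for seed selection (default 0.05).
#' @param phenotype_name Label stored in the result (default "whr").
#' @return A tibble of class `sfc_effect_map` with columns `region_id`,
#'   `r`, `p`, `q`, `selected`, `sign`, plus attributes `alpha`,
#'   `phenotype`, `n_subjects`. Regions whose degree is constant across
#'   subjects get `r = 0`, `p = 1` and a `degenerate` flag.
#' @export
phenotype_association <- function(degrees, phenotype, alpha = 0.05,
                                  phenotype_name = "whr") {
  d <- as.matrix(degrees)
  check_finite(d, "degrees")
  n <- nrow(d)
  if (n < 4L) abort_input("need at least 4 subjects")
  if (length(phenotype) != n) abort_input("phenotype length must match subjects")
  check_finite(phenotype, "phenotype")
  if (stats::sd(phenotype) == 0) abort_input("phenotype is constant")

  sds <- apply(d, 2L, stats::sd)
  degenerate <- sds == 0
  r <- rep(0, ncol(d))
  r[!degenerate] <- drop(stats::cor(phenotype, d[, !degenerate, drop = FALSE]))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[degenerate] <- 1
  p <- pmin(p, 1)
  q <- bh_fdr(p)

  out <- tibble::tibble(
    region_id = seq_len(ncol(d)),
    region_name = colnames(d) %||% as.character(seq_len(ncol(d))),
    r = r, p = p, q = q,
    selected = q < alpha & !degenerate,
    sign = sign(r),
    degenerate = degenerate
  )
  structure(out,
            class = c("sfc_effect_map", class(out)),
            alpha = alpha, phenotype = phenotype_name, n_subjects = n)
}

#' Seed regions of an effect map
#'
#' @param effect_map Result of [phenotype_association()].
#' @return Integer vector of selected region ids (the seed set).
#' @export
seed_regions <- function(effect_map) {
  effect_map$region_id[effect_map$selected]
}

#' Bootstrap stability of the phenotype effect map
#'
#' Resamples `ceiling(frac * n)` subjects with replacement `n_boot` times,
#' recomputes the whole-brain degree-phenotype correlation map on each
#' resample, and reports the spatial Pearson correlation of every bootstrap
#' r-map with the full-sample map. High mean stability indicates the seed
#' map is not driven by a few subjects.
#'
#' @inheritParams phenotype_association
#' @param n_boot Number of bootstrap iterations (default 1000).
#' @param frac Fraction of subjects per resample (default 0.9). With
#'   `replace = FALSE` and `frac = 1` every iteration is the identity
#'   resample (useful for testing).
#' @param replace Resample with replacement (default `TRUE`).
#' @param rng_seed Master seed; per-iteration seeds are derived with
#'   [derive_seed()] and returned, so any iteration is reproducible alone.
#' @param max_retries Retries per iteration if a resample has a constant
#'   phenotype (default 10).
#' @return A tibble of class `sfc_stability` with columns `iteration`,
#'   `seed`, `stability`; attributes `mean` and `sd`.
#' @export
bootstrap_stability <- function(degrees, phenotype, n_boot = 1000,
                                frac = 0.9, replace = TRUE, rng_seed = 1L,
                                max_retries = 10L) {
  if (n_boot < 1) abort_input("n_boot must be >= 1")
  if (frac <= 0 || frac > 1) abort_input("frac must be in (0, 1]")
  d <- as.matrix(degrees)
  n <- nrow(d)
  m <- ceiling(frac * n)
  full_r <- phenotype_association(d, phenotype)$r

  one <- function(iter) {
    seed <- derive_seed(rng_seed, iter)
    for (try in 0:max_retries) {
      idx <- with_seed(seed + try, sample.int(n, m, replace = replace))
      if (stats::sd(phenotype[idx]) > 0) {
        boot_r <- phenotype_association(d[idx, , drop = FALSE],
                                        phenotype[idx])$r
        ok <- stats::sd(boot_r) > 0 && stats::sd(full_r) > 0
        return(c(seed, if (ok) stats::cor(full_r, boot_r) else NA_real_))
      }
    }
    abort_input(sprintf("iteration %d: constant phenotype after %d retries",
                        iter, max_retries))
  }
  res <- vapply(seq_len(n_boot), one, numeric(2))
  out <- tibble::tibble(iteration = seq_len(n_boot),
                        seed = as.integer(res[1L, ]),
                        stability = res[2L, ])
  structure(out, class = c("sfc_stability", class(out)),
            mean = mean(out$stability, na.rm = TRUE),
            sd = stats::sd(out$stability, na.rm = TRUE))
}

#' Average a regional vector within networks
#'
#' Stratifies per-region values (correlation coefficients, degrees) by the
#' parcellation's communities and subcortical structures, optionally
#' restricted to a subset of regions (e.g. the significant seeds only).
#'
#' @param values Numeric vector, one value per region.
#' @param parcellation Parcellation tibble (see [default_parcellation()]).
#' @param regions Optional integer vector restricting the average to these
#'   region ids. Networks left empty by the restriction get `NA`, not 0.
#' @return Tibble with columns `network`, `n_regions`, `mean_value`, in the
#'   canonical label order.
#' @export
stratify_by_network <- function(values, parcellation, regions = NULL) {
  check_parcellation(parcellation, n_regions = length(values))
  keep <- if (is.null(regions)) rep(TRUE, length(values)) else
    parcellation$region_id %in% regions
  labels <- c(cortical_communities, subcortical_labels, "subcortical")
  present <- intersect(labels, unique(parcellation$network))
  purrr::map_dfr(present, function(lab) {
    idx <- keep & parcellation$network == lab
    tibble::tibble(network = lab,
                   n_regions = sum(idx),
                   mean_value = if (any(idx)) mean(values[idx]) else NA_real_)
  })
}
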