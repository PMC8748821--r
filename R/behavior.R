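#' Permutation test of a Pearson correlation
#'
#' Observed `r = cor(x, y)` against a null distribution built by randomly
#' permuting `y` `n_perm` times. Two-sided p-value; the default add-one
#' convention `p = (1 + #{|r_null| >= |r|}) / (n_perm + 1)` is valid (never
#' zero); `convention = "plain"` gives the proportion `#{...} / n_perm`.
#'
#' @param x,y Numeric subject vectors, non-constant, length >= 5.
#' @param n_perm Number of permutations (default 5000).
#' @param rng_seed Seed for the permutation stream.
#' @param convention `"add_one"` (default) or `"plain"`.
#' @return List with `r`, `p_perm`, `n_perm`.
#' @export
permutation_correlation <- function(x, y, n_perm = 5000, rng_seed = 1L,
                                    convention = c("add_one", "plain")) {
  convention <- match.arg(convention)
  if (length(x) != length(y)) abort_input("x and y must have equal length")
  n <- length(x)
  if (n < 5L) abort_input("need at least 5 subjects")
  check_finite(x, "x"); check_finite(y, "y")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_input("constant input vector")
  }
  if (n_perm < 1) abort_input("n_perm must be >= 1")

  r_obs <- stats::cor(x, y)
  # permuted correlations in one matrix product: cor(x, y_perm) for all
  # permutations at once
  perm <- with_seed(rng_seed, {
    matrix(y[replicate(n_perm, sample.int(n))], n, n_perm)
  })
  r_null <- drop(stats::cor(x, perm))
  b <- sum(abs(r_null) >= abs(r_obs))
  p <- if (convention == "add_one") (1 + b) / (n_perm + 1) else b / n_perm
  list(r = r_obs, p_perm = p, n_perm = as.integer(n_perm))
}

tfeq_score_names <- c("restraint", "disinhibition", "hunger",
                      "restraint_plus_disinhibition", "total")

# ensure all five score combinations exist; composites derived from subscales
complete_tfeq <- function(tfeq) {
  t <- tibble::as_tibble(tfeq)
  req <- c("restraint", "disinhibition", "hunger")
  if (!all(req %in% names(t))) {
    abort_input(sprintf("tfeq must contain subscales: %s",
                        paste(req, collapse = ", ")))
  }
  t$restraint_plus_disinhibition <- t$restraint + t$disinhibition
  t$total <- t$restraint + t$disinhibition + t$hunger
  t[tfeq_score_names]
}

#' Associate network step degrees with eating-behavior scores
#'
#' Full grid of permutation correlations between each network's step degree
#' (at one chosen step, by default the largest) and each of the five TFEQ
#' score combinations: dietary restraint (1), disinhibition (2), hunger
#' (3), (1+2), and total (1+2+3). Composites are recomputed from the
#' subscales. BH-FDR is applied jointly across all tested (network, score)
#' pairs.
#'
#' @param network_degrees Subjects x networks numeric matrix (columns
#'   named), typically one step slice of [network_degree()].
#' @param tfeq Data frame with columns `restraint`, `disinhibition`,
#'   `hunger` (composites derived).
#' @param n_perm Permutations per pair (default 5000).
#' @param rng_seed Master seed; each pair uses a derived seed.
#' @param networks Optional character vector restricting the tested
#'   networks (e.g. those with significant group differences).
#' @param convention Permutation p convention, see
#'   [permutation_correlation()].
#' @return Tibble of class `sfc_behavior` with columns `network`, `score`,
#'   `r`, `p_perm`, `q`; attributes `n_perm`, `family_size`, `step` if
#'   known.
#' @export
associate_behavior <- function(network_degrees, tfeq, n_perm = 5000,
                               rng_seed = 1L, networks = NULL,
                               convention = "add_one") {
  nd <- as.matrix(network_degrees)
  if (is.null(colnames(nd))) abort_input("network_degrees needs column names")
  if (!is.null(networks)) {
    missing <- setdiff(networks, colnames(nd))
    if (length(missing)) {
      abort_input(sprintf("unknown network(s): %s",
                          paste(missing, collapse = ", ")))
    }
    nd <- nd[, networks, drop = FALSE]
  }
  if (ncol(nd) == 0L) abort_input("no networks to test")
  scores <- complete_tfeq(tfeq)
  if (nrow(scores) != nrow(nd)) abort_input("tfeq rows must match subjects")

  grid <- tidyr::expand_grid(network = colnames(nd),
                             score = tfeq_score_names)
  res <- purrr::pmap_dfr(
    list(grid$network, grid$score, seq_len(nrow(grid))),
    function(net, sc, i) {
      pc <- permutation_correlation(nd[, net], scores[[sc]], n_perm = n_perm,
                                    rng_seed = derive_seed(rng_seed, i),
                                    convention = convention)
      tibble::tibble(network = net, score = sc, r = pc$r, p_perm = pc$p_perm)
    })
  res$q <- bh_fdr(res$p_perm)
  structure(res, class = c("sfc_behavior", class(res)),
            n_perm = as.integer(n_perm), family_size = nrow(res))
}

#' Reshape a behavior association into the wide network-by-score layout
#'
#' One row per network, `r` and `q` columns for each of the five TFEQ score
#' combinations, mirroring how such results are reported.
#'
#' @param assoc Result of [associate_behavior()].
#' @return Wide tibble.
#' @export
behavior_table <- function(assoc) {
  tibble::as_tibble(assoc) |>
    tidyr::pivot_wider(id_cols = "network", names_from = "score",
                       values_from = c("r", "q"))
}
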