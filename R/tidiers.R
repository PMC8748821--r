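#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a phenotype effect map
#'
#' @param x An `sfc_effect_map`.
#' @param ... Unused.
#' @return The per-region tibble (`region_id`, `r`, `p`, `q`, `selected`).
#' @export
tidy.sfc_effect_map <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.sfc_effect_map
#' @export
glance.sfc_effect_map <- function(x, ...) {
  tibble::tibble(phenotype = attr(x, "phenotype"),
                 n_subjects = attr(x, "n_subjects"),
                 n_regions = nrow(x),
                 alpha = attr(x, "alpha"),
                 n_selected = sum(x$selected),
                 min_q = min(x$q))
}

#' Tidy a group contrast
#'
#' @param x An `sfc_contrast`.
#' @param level `"regional"` (default) or `"network"`.
#' @param ... Unused.
#' @export
tidy.sfc_contrast <- function(x, level = c("regional", "network"), ...) {
  level <- match.arg(level)
  out <- if (level == "network") x$network else x$regional
  if (is.null(out)) abort_input("contrast has no network-level table")
  out
}

#' @rdname tidy.sfc_contrast
#' @export
glance.sfc_contrast <- function(x, ...) {
  tibble::tibble(reference = x$groups[["reference"]],
                 test = x$groups[["test"]],
                 n_reference = x$n_per_group[1L],
                 n_test = x$n_per_group[2L],
                 variant = x$variant,
                 regional_family = x$family_sizes[["regional"]],
                 network_family = x$family_sizes[["network"]],
                 regional_discoveries = sum(x$regional$q < 0.05),
                 network_discoveries = if (is.null(x$network)) NA_integer_
                                       else sum(x$network$q < 0.05))
}

#' Tidy a behavior association
#'
#' @param x An `sfc_behavior`.
#' @param ... Unused.
#' @export
tidy.sfc_behavior <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.sfc_behavior
#' @export
glance.sfc_behavior <- function(x, ...) {
  tibble::tibble(n_perm = attr(x, "n_perm"),
                 family_size = attr(x, "family_size"),
                 n_significant = sum(x$q < 0.05),
                 min_q = min(x$q))
}

#' Tidy a stability bootstrap
#'
#' @param x An `sfc_stability`.
#' @param ... Unused.
#' @export
tidy.sfc_stability <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.sfc_stability
#' @export
glance.sfc_stability <- function(x, ...) {
  tibble::tibble(n_boot = nrow(x),
                 mean_stability = attr(x, "mean"),
                 sd_stability = attr(x, "sd"))
}
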