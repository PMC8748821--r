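#' Assign subjects to phenotype-defined groups
#'
#' `criteria = "bmi_whr"` reproduces the healthy-weight / overweight
#' definition: healthy weight iff `18.5 <= BMI < 25` and WHR at or below
#' the sex-specific cutoff (0.85 female / 0.90 male); overweight iff
#' `BMI >= 25` and WHR above the cutoff. `criteria = "who_whr"` applies the
#' WHO abdominal-obesity risk bands: low risk iff WHR < 0.80 (female) /
#' 0.95 (male); high risk iff WHR > 0.86 / 1.00. Subjects satisfying
#' neither conjunction are `unassigned`.
#'
#' @param phenotypes Data frame with columns `subject_id`, `sex`
#'   (`"male"`/`"female"`), `bmi`, `whr`.
#' @param criteria `"bmi_whr"` (default) or `"who_whr"`.
#' @return Tibble with `subject_id`, `group` (factor), `criteria`; rows
#'   with missing fields get group `NA` and an `error` message.
#' @examples
#' ph <- tibble::tibble(subject_id = "s1", sex = "female",
#'                      bmi = 22, whr = 0.80)
#' assign_groups(ph)
#' @export
assign_groups <- function(phenotypes, criteria = c("bmi_whr", "who_whr")) {
  criteria <- match.arg(criteria)
  req <- c("subject_id", "sex", "bmi", "whr")
  if (!all(req %in% names(phenotypes))) {
    abort_input(sprintf("phenotypes must have columns: %s",
                        paste(req, collapse = ", ")))
  }
  ph <- tibble::as_tibble(phenotypes)[req]
  bad_sex <- !(ph$sex %in% c("male", "female"))
  missing <- is.na(ph$bmi) | is.na(ph$whr) | bad_sex

  group <- rep("unassigned", nrow(ph))
  if (criteria == "bmi_whr") {
    cutoff <- ifelse(ph$sex == "female", 0.85, 0.90)
    healthy <- ph$bmi >= 18.5 & ph$bmi < 25 & ph$whr <= cutoff
    over <- ph$bmi >= 25 & ph$whr > cutoff
    group[healthy %in% TRUE] <- "healthy_weight"
    group[over %in% TRUE] <- "overweight"
    levels <- c("healthy_weight", "overweight", "unassigned")
  } else {
    low_cut <- ifelse(ph$sex == "female", 0.80, 0.95)
    high_cut <- ifelse(ph$sex == "female", 0.86, 1.00)
    group[(ph$whr < low_cut) %in% TRUE] <- "low_risk"
    group[(ph$whr > high_cut) %in% TRUE] <- "high_risk"
    levels <- c("low_risk", "high_risk", "unassigned")
  }
  group[missing] <- NA_character_
  tibble::tibble(
    subject_id = ph$subject_id,
    group = factor(group, levels = levels),
    criteria = criteria,
    error = ifelse(missing, "missing or invalid sex/bmi/whr", NA_character_)
  )
}

# vectorized two-sample t over the columns of x (group a) vs y (group b);
# returns mean difference a - b, t, df, p (two-sided)
two_sample_t <- function(xa, xb, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2L, stats::var); vb <- apply(xb, 2L, stats::var)
  if (variant == "welch") {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(va))
  }
  tt <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  list(diff = ma - mb, t = tt, df = df, p = p,
       mean_a = ma, mean_b = mb)
}

#' Regional and network-level group contrasts of step degrees
#'
#' Two-sample t-tests (Welch by default) of per-subject z-normalized step
#' degrees between the two assigned groups, at every step. Positive t means
#' the second group level (overweight / high risk) exceeds the first.
#' BH-FDR is applied within each step across regions — and, when a
#' parcellation is given, separately within each step across networks
#' (regions averaged per network per subject first).
#'
#' @param sfc Either an `sfc_result` or a subjects x steps x R numeric
#'   array of step degrees (dimnames on subjects required to match the
#'   assignment).
#' @param assignment Tibble from [assign_groups()]; `unassigned`/`NA`
#'   subjects are dropped.
#' @param parcellation Optional parcellation tibble enabling the
#'   network-level family.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return Object of class `sfc_contrast`: list of tibbles `regional`
#'   (`step`, `region_id`, `t`, `df`, `p`, `q`, group means) and `network`
#'   (or `NULL`), plus metadata (`groups`, `n_per_group`, `variant`,
#'   `family_sizes`).
#' @export
compare_groups <- function(sfc, assignment, parcellation = NULL,
                           variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  deg <- if (inherits(sfc, "sfc_result")) sfc$z_degrees else sfc
  if (length(dim(deg)) != 3L) {
    abort_input("step degrees must be a subjects x steps x regions array")
  }
  ids <- dimnames(deg)[[1L]] %||% as.character(seq_len(dim(deg)[1L]))
  asg <- assignment[match(ids, assignment$subject_id), ]
  lv <- levels(asg$group)[1:2] # first = reference (healthy/low), second = test
  ia <- which(asg$group %in% lv[2L]) # test group (overweight / high risk)
  ib <- which(asg$group %in% lv[1L])
  if (length(ia) < 3L || length(ib) < 3L) {
    abort_input(sprintf("need >= 3 subjects per group (got %s=%d, %s=%d)",
                        lv[2L], length(ia), lv[1L], length(ib)))
  }
  steps <- dim(deg)[2L]
  r <- dim(deg)[3L]

  regional <- purrr::map_dfr(seq_len(steps), function(k) {
    res <- two_sample_t(matrix(deg[ia, k, , drop = FALSE], length(ia), r),
                        matrix(deg[ib, k, , drop = FALSE], length(ib), r),
                        variant)
    tibble::tibble(step = k, region_id = seq_len(r),
                   t = res$t, df = res$df, p = res$p, q = bh_fdr(res$p),
                   mean_test = res$mean_a, mean_ref = res$mean_b)
  })

  network <- NULL
  if (!is.null(parcellation)) {
    nd <- network_degree(deg, parcellation)
    nets <- dimnames(nd)[[3L]]
    network <- purrr::map_dfr(seq_len(steps), function(k) {
      res <- two_sample_t(
        matrix(nd[ia, k, , drop = FALSE], length(ia), length(nets)),
        matrix(nd[ib, k, , drop = FALSE], length(ib), length(nets)),
        variant)
      tibble::tibble(step = k, network = nets,
                     t = res$t, df = res$df, p = res$p, q = bh_fdr(res$p),
                     mean_test = res$mean_a, mean_ref = res$mean_b)
    })
  }
  structure(list(regional = regional, network = network,
                 groups = c(reference = lv[1L], test = lv[2L]),
                 n_per_group = c(length(ib), length(ia)),
                 variant = variant,
                 family_sizes = c(regional = r,
                                  network = if (is.null(network)) NA_integer_
                                            else length(unique(network$network)))),
            class = "sfc_contrast")
}

#' Network-averaged step degrees
#'
#' Per subject and step, the mean step degree over the regions of each
#' community / subcortical structure.
#'
#' @param step_degrees Subjects x steps x R array (or `sfc_result`).
#' @param parcellation Parcellation tibble covering all R regions.
#' @return Subjects x steps x networks array.
#' @export
network_degree <- function(step_degrees, parcellation) {
  deg <- if (inherits(step_degrees, "sfc_result")) step_degrees$z_degrees
         else step_degrees
  r <- dim(deg)[3L]
  check_parcellation(parcellation, n_regions = r)
  labels <- intersect(c(cortical_communities, subcortical_labels,
                        "subcortical"),
                      unique(parcellation$network))
  out <- array(NA_real_, c(dim(deg)[1:2], length(labels)),
               dimnames = c(dimnames(deg)[1:2], list(labels)))
  for (lab in labels) {
    idx <- which(parcellation$network == lab)
    sub <- deg[, , idx, drop = FALSE]
    out[, , lab] <- apply(sub, c(1L, 2L), mean)
  }
  out
}

#' Collapse subcortical structures into one group
#'
#' Returns a copy of the parcellation where every subcortical label is
#' replaced by `"subcortical"`, matching the aggregation used when eating
#' behavior is associated with network degrees.
#'
#' @param parcellation Parcellation tibble.
#' @export
collapse_subcortical <- function(parcellation) {
  p <- parcellation
  p$network[p$is_subcortical] <- "subcortical"
  p
}

#' Balanced bootstrap group comparison
#'
#' Equalizes group sizes before contrasting: each iteration draws
#' `subsample_size` subjects from the larger (reference) group without
#' replacement and compares them against the full test group, collecting
#' the per-network t-statistics. Used for the WHO low- vs high-risk
#' sensitivity analysis (1000 draws of 51 low-risk subjects).
#'
#' @inheritParams compare_groups
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param subsample_size Subjects drawn from the reference group per
#'   iteration; defaults to the test-group size.
#' @param rng_seed Master seed (per-iteration seeds derived).
#' @param level `"network"` (default) or `"regional"` statistics collected.
#' @return Tibble of class `sfc_boot_contrast` with columns `iteration`,
#'   `seed`, `step`, unit column (`network` or `region_id`), `t`;
#'   attribute `summary` holds mean and sd of t per unit and step.
#' @export
balanced_bootstrap_compare <- function(sfc, assignment, parcellation = NULL,
                                       n_iter = 1000, subsample_size = NULL,
                                       rng_seed = 1L,
                                       level = c("network", "regional"),
                                       variant = "welch") {
  level <- match.arg(level)
  if (level == "network" && is.null(parcellation)) {
    abort_input("network-level bootstrap needs a parcellation")
  }
  deg <- if (inherits(sfc, "sfc_result")) sfc$z_degrees else sfc
  ids <- dimnames(deg)[[1L]] %||% as.character(seq_len(dim(deg)[1L]))
  asg <- assignment[match(ids, assignment$subject_id), ]
  lv <- levels(asg$group)[1:2]
  ref_idx <- which(asg$group %in% lv[1L])
  if (is.null(subsample_size)) subsample_size <- sum(asg$group %in% lv[2L])
  if (subsample_size > length(ref_idx)) {
    abort_input(sprintf("subsample_size %d exceeds %s group size %d",
                        subsample_size, lv[1L], length(ref_idx)))
  }
  res <- purrr::map_dfr(seq_len(n_iter), function(it) {
    seed <- derive_seed(rng_seed, it)
    take <- with_seed(seed, sample(ref_idx, subsample_size, replace = FALSE))
    keep <- sort(c(take, which(asg$group %in% lv[2L])))
    ct <- compare_groups(deg[keep, , , drop = FALSE], asg[keep, ],
                         parcellation = parcellation, variant = variant)
    tab <- if (level == "network") ct$network else ct$regional
    tab$iteration <- it
    tab$seed <- seed
    tab[c("iteration", "seed", "step",
          if (level == "network") "network" else "region_id", "t")]
  })
  unit <- if (level == "network") "network" else "region_id"
  summ <- res |>
    dplyr::group_by(.data$step, .data[[unit]]) |>
    dplyr::summarise(mean_t = mean(.data$t), sd_t = stats::sd(.data$t),
                     .groups = "drop")
  structure(res, class = c("sfc_boot_contrast", class(res)), summary = summ)
}

#' @export
print.sfc_contrast <- function(x, ...) {
  cat(sprintf("<sfc_contrast> %s (n=%d) vs %s (n=%d), %s t\n",
              x$groups["test"], x$n_per_group[2L],
              x$groups["reference"], x$n_per_group[1L], x$variant))
  nsig <- sum(x$regional$q < 0.05)
  cat(sprintf("  regional discoveries (q<0.05): %d of %d tests\n",
              nsig, nrow(x$regional)))
  if (!is.null(x$network)) {
    cat(sprintf("  network discoveries (q<0.05): %d of %d tests\n",
                sum(x$network$q < 0.05), nrow(x$network)))
  }
  invisible(x)
}
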