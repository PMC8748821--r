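#' Write a cohort to plain-text files
#'
#' One time-series TSV per subject (T rows x R columns, header = region
#' names), a phenotype TSV, a parcellation TSV and, when present, a
#' ground-truth JSON.
#'
#' @param cohort An `sfc_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble manifest of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  files <- character()

  for (id in names(cohort$timeseries)) {
    f <- file.path(ts_dir, paste0(id, ".tsv"))
    readr::write_tsv(tibble::as_tibble(cohort$timeseries[[id]]), f,
                     progress = FALSE)
    files <- c(files, f)
  }
  ph_file <- file.path(dir, "phenotypes.tsv")
  readr::write_tsv(cohort$phenotypes, ph_file, progress = FALSE)
  parc_file <- file.path(dir, "parcellation.tsv")
  readr::write_tsv(cohort$parcellation, parc_file, progress = FALSE)
  files <- c(files, ph_file, parc_file)

  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    gt$behavior_latents <- NULL # re-derivable from config + seed
    gt_file <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(gt, gt_file, auto_unbox = TRUE, digits = NA)
    files <- c(files, gt_file)
  }
  invisible(tibble::tibble(file = files))
}

#' Read a cohort from plain-text files
#'
#' Inverse of [write_cohort()]. Subject ids in the phenotype table must
#' match the time-series files one-to-one, and every time-series header
#' must match the parcellation's region names (region identity is checked
#' by name, not column order).
#'
#' @param dir Directory written by [write_cohort()] (or hand-assembled with
#'   the same layout).
#' @return An `sfc_cohort` (without ground truth unless
#'   `ground_truth.json` is present).
#' @export
read_cohort <- function(dir) {
  ph_file <- file.path(dir, "phenotypes.tsv")
  parc_file <- file.path(dir, "parcellation.tsv")
  if (!file.exists(ph_file)) abort_input("phenotypes.tsv not found")
  if (!file.exists(parc_file)) abort_input("parcellation.tsv not found")
  phenotypes <- readr::read_tsv(ph_file, show_col_types = FALSE,
                                progress = FALSE)
  req <- c("subject_id", "age", "sex", "bmi", "whr", "tfeq_restraint",
           "tfeq_disinhibition", "tfeq_hunger")
  if (!all(req %in% names(phenotypes))) {
    abort_input(sprintf("phenotypes.tsv lacks column(s): %s",
                        paste(setdiff(req, names(phenotypes)), collapse = ", ")))
  }
  extra <- setdiff(names(phenotypes), req)
  if (length(extra)) {
    warning(sprintf("ignoring extra phenotype column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(phenotypes$subject_id)) {
    abort_input("duplicate subject_id in phenotypes.tsv")
  }
  parcellation <- readr::read_tsv(parc_file, show_col_types = FALSE,
                                  progress = FALSE)
  if (!"is_subcortical" %in% names(parcellation)) {
    parcellation$is_subcortical <- parcellation$network %in% subcortical_labels
  }
  check_parcellation(parcellation)

  ts_dir <- file.path(dir, "timeseries")
  have <- sub("\\.tsv$", "", list.files(ts_dir, pattern = "\\.tsv$"))
  missing <- setdiff(phenotypes$subject_id, have)
  extra_ts <- setdiff(have, phenotypes$subject_id)
  if (length(missing)) {
    abort_input(sprintf("no time-series file for subject(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (length(extra_ts)) {
    warning(sprintf("ignoring time-series without phenotype row: %s",
                    paste(extra_ts, collapse = ", ")), call. = FALSE)
  }
  dims <- NULL
  timeseries <- purrr::map(phenotypes$subject_id, function(id) {
    x <- as.matrix(readr::read_tsv(file.path(ts_dir, paste0(id, ".tsv")),
                                   show_col_types = FALSE, progress = FALSE))
    if (!setequal(colnames(x), parcellation$region_name)) {
      abort_input(sprintf("subject %s: region columns do not match the parcellation", id))
    }
    x <- x[, parcellation$region_name, drop = FALSE]
    if (is.null(dims)) dims <<- dim(x)
    if (!identical(dim(x), dims)) {
      abort_input(sprintf("subject %s: time-series dimensions differ", id))
    }
    x
  })
  names(timeseries) <- phenotypes$subject_id

  gt_file <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_file)) {
    jsonlite::read_json(gt_file, simplifyVector = TRUE)
  }
  structure(list(phenotypes = tibble::as_tibble(phenotypes[req]),
                 timeseries = timeseries,
                 parcellation = parcellation,
                 ground_truth = ground_truth,
                 config = NULL),
            class = "sfc_cohort")
}

#' Pipeline configuration
#'
#' All analysis parameters with their conventional defaults: ridge 0.5,
#' seed selection at q < 0.05 on WHR with 1000 bootstrap resamples of 90%,
#' 95% edge-retention threshold, steps 1-5, hub multiplier 1.5, Welch
#' t-tests under the BMI+WHR group criteria, and 5000 permutations for the
#' behavior association at the largest step.
#'
#' @param rho Ridge regularization (default 0.5).
#' @param degree_mode Degree convention (default `"absolute"`).
#' @param alpha Seed-selection FDR level (default 0.05).
#' @param phenotype Seed phenotype column (default `"whr"`).
#' @param n_boot Bootstrap iterations for stability (default 1000).
#' @param boot_frac Bootstrap resample fraction (default 0.9).
#' @param percentile Edge-retention percentile (default 95).
#' @param max_step Largest step distance (default 5).
#' @param hub_multiplier Hub criterion (default 1.5).
#' @param edge_rank Edge ranking convention (default `"signed"`).
#' @param t_variant `"welch"` (default) or `"pooled"`.
#' @param criteria Group criteria (default `"bmi_whr"`).
#' @param n_perm Behavior permutations (default 5000).
#' @param behavior_step Step for behavior association (default `max_step`).
#' @param sensitivity Character vector of covariate adjustments applied
#'   before seed selection and SFC: any of `"age_sex"`, `"tfeq"` (default
#'   none).
#' @param rng_seed Master seed (default 1).
#' @return List of class `pipeline_config`; round-trips losslessly through
#'   [jsonlite::toJSON()].
#' @export
pipeline_config <- function(rho = 0.5, degree_mode = "absolute",
                            alpha = 0.05, phenotype = "whr", n_boot = 1000,
                            boot_frac = 0.9, percentile = 95, max_step = 5,
                            hub_multiplier = 1.5, edge_rank = "signed",
                            t_variant = "welch", criteria = "bmi_whr",
                            n_perm = 5000, behavior_step = max_step,
                            sensitivity = character(), rng_seed = 1L) {
  structure(list(rho = rho, degree_mode = degree_mode, alpha = alpha,
                 phenotype = phenotype, n_boot = as.integer(n_boot),
                 boot_frac = boot_frac, percentile = percentile,
                 max_step = as.integer(max_step),
                 hub_multiplier = hub_multiplier, edge_rank = edge_rank,
                 t_variant = t_variant, criteria = criteria,
                 n_perm = as.integer(n_perm),
                 behavior_step = as.integer(behavior_step),
                 sensitivity = as.character(sensitivity),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Run the full stepwise-connectivity pipeline
#'
#' Connectivity estimation, degree centrality (optionally residualized for
#' the requested sensitivity covariates), WHR seed selection with bootstrap
#' stability, stepwise walk counting from the selected seeds, hub
#' detection, group contrasts (regional and network level), and the
#' eating-behavior association for the networks flagged at the largest
#' step (plus the pooled subcortical group). Deterministic given
#' `config$rng_seed`.
#'
#' @param cohort An `sfc_cohort`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV/JSON and a manifest with content hashes is returned.
#' @return List of class `sfc_pipeline` with elements `degrees`,
#'   `effect_map`, `seeds`, `stability`, `sfc`, `hubs`, `assignment`,
#'   `contrast`, `behavior`, `stage_seeds`, and (if `out_dir` is used)
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(cohort, "sfc_cohort"),
            inherits(config, "pipeline_config"))
  stage_seeds <- purrr::set_names(
    purrr::map_int(1:4, \(i) derive_seed(config$rng_seed, i)),
    c("stability", "bootstrap_groups", "behavior", "reserved"))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  degrees <- run_stage("connectivity",
                       cohort_degrees(cohort, rho = config$rho,
                                      mode = config$degree_mode))
  if (length(config$sensitivity)) {
    cov <- pipeline_covariates(cohort, config$sensitivity)
    degrees <- run_stage("sensitivity", regress_out(degrees, cov))
  }
  phen <- cohort$phenotypes[[config$phenotype]]
  effect_map <- run_stage("seed_selection",
                          phenotype_association(degrees, phen,
                                                alpha = config$alpha,
                                                phenotype_name = config$phenotype))
  seeds <- seed_regions(effect_map)
  stability <- run_stage("stability",
                         bootstrap_stability(degrees, phen,
                                             n_boot = config$n_boot,
                                             frac = config$boot_frac,
                                             rng_seed = stage_seeds[["stability"]]))
  if (length(seeds) == 0L) {
    stop("pipeline stage 'sfc' failed: no seed regions at q < alpha",
         call. = FALSE)
  }
  sfc <- run_stage("sfc",
                   run_sfc_cohort(cohort, seeds,
                                  percentile = config$percentile,
                                  max_step = config$max_step,
                                  rho = config$rho,
                                  edge_rank = config$edge_rank))
  group_mean_z <- apply(sfc$z_degrees, c(2L, 3L), mean, na.rm = TRUE)
  hubs <- detect_hubs(group_mean_z, multiplier = config$hub_multiplier)

  assignment <- run_stage("groups",
                          assign_groups(cohort$phenotypes,
                                        criteria = config$criteria))
  parc_collapsed <- collapse_subcortical(cohort$parcellation)
  contrast <- run_stage("group_stats",
                        compare_groups(sfc, assignment,
                                       parcellation = cohort$parcellation,
                                       variant = config$t_variant))

  nd <- network_degree(sfc, parc_collapsed)
  step_k <- min(config$behavior_step, config$max_step)
  flagged <- contrast$network |>
    dplyr::filter(.data$step == step_k, .data$q < config$alpha) |>
    dplyr::pull("network")
  flagged <- unique(c(setdiff(flagged, subcortical_labels), "subcortical"))
  flagged <- intersect(colnames(nd[, step_k, ]), flagged)
  behavior <- run_stage("behavior",
                        associate_behavior(nd[, step_k, ],
                                           cohort_tfeq(cohort),
                                           n_perm = config$n_perm,
                                           rng_seed = stage_seeds[["behavior"]],
                                           networks = flagged))

  res <- structure(list(degrees = degrees, effect_map = effect_map,
                        seeds = seeds, stability = stability, sfc = sfc,
                        hubs = hubs, assignment = assignment,
                        contrast = contrast, behavior = behavior,
                        behavior_step = step_k,
                        stage_seeds = stage_seeds, config = config),
                   class = "sfc_pipeline")
  if (!is.null(out_dir)) res$manifest <- write_pipeline(res, out_dir)
  res
}

pipeline_covariates <- function(cohort, sensitivity) {
  ph <- cohort$phenotypes
  cov <- list()
  if ("age_sex" %in% sensitivity) {
    cov$age <- ph$age
    cov$sex <- as.integer(ph$sex == "male")
  }
  if ("tfeq" %in% sensitivity) {
    cov$tfeq_restraint <- ph$tfeq_restraint
    cov$tfeq_disinhibition <- ph$tfeq_disinhibition
  }
  if (!length(cov)) abort_input("unknown sensitivity adjustment")
  as.data.frame(cov)
}

# write every pipeline table and return a manifest with content hashes
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put_tsv <- function(x, name) {
    f <- file.path(out_dir, name)
    readr::write_tsv(tibble::as_tibble(x), f, progress = FALSE)
    paths <<- c(paths, f)
  }
  put_tsv(cbind(subject_id = rownames(res$degrees),
                as.data.frame(res$degrees)), "degrees.tsv")
  put_tsv(res$effect_map, "effect_map.tsv")
  put_tsv(res$stability, "stability.tsv")
  put_tsv(res$assignment, "group_assignment.tsv")
  put_tsv(res$contrast$regional, "contrast_regional.tsv")
  put_tsv(res$contrast$network, "contrast_network.tsv")
  put_tsv(tibble::as_tibble(res$behavior), "behavior.tsv")
  put_tsv(tidy_step_degrees(res$sfc), "step_degrees.tsv")
  put_tsv(purrr::imap_dfr(res$hubs, \(h, s) tibble::tibble(
    step = s, region_id = as.integer(h))), "hubs.tsv")

  summary_file <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    n_seeds = length(res$seeds), seeds = res$seeds,
    alpha = res$config$alpha,
    stability_mean = attr(res$stability, "mean"),
    stability_sd = attr(res$stability, "sd"),
    behavior_step = res$behavior_step,
    stage_seeds = as.list(res$stage_seeds),
    config = unclass(res$config)), summary_file,
    auto_unbox = TRUE, digits = NA)
  paths <- c(paths, summary_file)
  tibble::tibble(file = basename(paths),
                 md5 = vapply(paths, \(f) unname(tools::md5sum(f)),
                              character(1), USE.NAMES = FALSE))
}

# long-format per-subject step degrees
tidy_step_degrees <- function(sfc) {
  z <- sfc$z_degrees
  dn <- dimnames(z)
  out <- tidyr::expand_grid(subject_id = dn[[1L]], step = dn[[2L]],
                            region = dn[[3L]])
  # expand_grid varies the last column fastest; aperm to region x step x
  # subject makes column-major order match
  out$z_degree <- as.vector(aperm(z, c(3L, 2L, 1L)))
  out
}

#' @export
print.sfc_pipeline <- function(x, ...) {
  cat(sprintf("<sfc_pipeline> %d seed region(s) at q < %.2f; stability %.2f +/- %.2f\n",
              length(x$seeds), x$config$alpha,
              attr(x$stability, "mean"), attr(x$stability, "sd")))
  print(x$contrast)
  invisible(x)
}
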