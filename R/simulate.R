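#' Simulation settings for a synthetic cohort
#'
#' Collects every knob of the synthetic-cohort generator with defaults
#' matching the study conditions the pipeline targets: 301 subjects, a
#' 246-region parcellation with 7 cortical communities and 7 subcortical
#' structures, roughly a quarter of subjects overweight, 26 phenotype-
#' associated seed regions, and an eating-behavior correlation planted on
#' the somatomotor network.
#'
#' @param n_subjects Cohort size (default 301).
#' @param n_regions Number of regions (default 246; >= 20).
#' @param n_timepoints Timepoints per subject (default 200).
#' @param community_sizes Optional named sizes per label (see
#'   [parcellation_from_sizes()]); default equal apportionment.
#' @param within_community_covariance Baseline covariance between regions
#'   of the same community (default 0.3).
#' @param planted_effect_r Target population correlation between a true
#'   seed's degree centrality and WHR (default 0.3; in `[0, 1)`).
#' @param n_true_seeds Number of regions with planted WHR effects
#'   (default 26).
#' @param group_fraction Fraction of subjects drawn as overweight
#'   (default 0.25); `healthy_fraction` are drawn healthy-weight and the
#'   remainder satisfy neither group definition.
#' @param healthy_fraction Fraction drawn healthy-weight (default 0.35).
#' @param group_effect_magnitude Target Cohen's d of the overweight vs
#'   healthy-weight difference in network step degree (default 0.8).
#' @param group_effect_networks Networks carrying the group effect
#'   (default visual + somatomotor).
#' @param group_effect_sign Direction: -1 (default) means overweight lower.
#' @param behavior_effects Tibble with columns `network`, `score`
#'   (a TFEQ subscale), `r` (target correlation between that network's
#'   step degree and the score). Default: somatomotor-disinhibition -0.25.
#' @param behavior_effect_r Convenience scalar overriding the `r` of the
#'   default `behavior_effects` row.
#' @param noise_sd Additional white measurement noise on the time series
#'   (default 0; signal variance is 1).
#' @param bmi_whr_coupling Within-status correlation between BMI and WHR
#'   residuals (default 0.6, a free knob: the joint BMI-WHR model is not
#'   identified by the marginals).
#' @param rho Ridge parameter the downstream pipeline will use; stored so
#'   planted-effect calibration and analysis agree (default 0.5).
#' @param rng_seed Master seed (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 301, n_regions = 246,
                       n_timepoints = 200, community_sizes = NULL,
                       within_community_covariance = 0.3,
                       planted_effect_r = 0.3, n_true_seeds = 26,
                       group_fraction = 0.25, healthy_fraction = 0.35,
                       group_effect_magnitude = 0.8,
                       group_effect_networks = c("visual", "somatomotor"),
                       group_effect_sign = -1,
                       behavior_effects = NULL, behavior_effect_r = -0.25,
                       noise_sd = 0, bmi_whr_coupling = 0.6,
                       rho = 0.5, rng_seed = 1L) {
  if (n_regions < 20) abort_input("n_regions must be >= 20")
  if (planted_effect_r < 0 || planted_effect_r >= 1) {
    abort_input("planted_effect_r must lie in [0, 1)")
  }
  if (group_fraction + healthy_fraction > 1) {
    abort_input("group_fraction + healthy_fraction must be <= 1")
  }
  if (is.null(behavior_effects)) {
    behavior_effects <- tibble::tibble(network = "somatomotor",
                                       score = "disinhibition",
                                       r = behavior_effect_r)
  }
  if (!all(behavior_effects$score %in%
           c("restraint", "disinhibition", "hunger"))) {
    abort_input("behavior effects must target TFEQ subscales")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    n_timepoints = as.integer(n_timepoints),
    community_sizes = community_sizes,
    within_community_covariance = within_community_covariance,
    planted_effect_r = planted_effect_r,
    n_true_seeds = as.integer(n_true_seeds),
    group_fraction = group_fraction, healthy_fraction = healthy_fraction,
    group_effect_magnitude = group_effect_magnitude,
    group_effect_networks = group_effect_networks,
    group_effect_sign = group_effect_sign,
    behavior_effects = behavior_effects,
    noise_sd = noise_sd, bmi_whr_coupling = bmi_whr_coupling,
    rho = rho, rng_seed = as.integer(rng_seed)), class = "sim_config")
}

# ---------------------------------------------------------------------------
# frozen generator calibration (measured once with scratch pilot runs under
# the default estimation conditions T = 200, rho = 0.5, w = 0.3, R = 60;
# see the methods vignette for the measurement protocol)
# ---------------------------------------------------------------------------

# ratio of degree estimation noise to planted-slope signal: the total
# covariance modulation of a seed's clique edges is
# beta_total(r) = .whr_noise_to_signal * r / sqrt(1 - r^2)
.whr_noise_to_signal <- 0.55

# baseline covariance of the edges joining same-sign true seeds (the
# "seed clique"); modulation moves each clique edge around this value, so
# it never crosses zero for realistic WHR z-scores
.seed_clique_baseline <- 0.2
.seed_clique_max_size <- 5L

# covariance-shift amplitude per unit Cohen's d of the network step-degree
# group difference: amp = .group_amp_per_d * d
.group_amp_per_d <- 0.0256

# correlation between the behavior latent and the measured network step
# degree at the reference modulation amplitude 0.10 (rounding included):
# score loading = r_target / .behavior_latent_degree_r
.behavior_modulation_amp <- 0.10
.behavior_latent_degree_r <- 0.626

# sign convention of communities for planted WHR effects (mirrors the
# predominance of positive transmodal and negative sensory effects)
.community_effect_sign <- c(
  visual = -1, somatomotor = -1, dorsal_attention = -1,
  ventral_attention = 1, limbic = 1, frontoparietal = 1, default_mode = 1,
  amygdala = -1, hippocampus = -1, thalamus = -1, putamen = -1,
  globus_pallidus = 1, nucleus_accumbens = 1, caudate = 1
)

# truncated-normal draws by inverse-cdf (exact, vectorized)
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

# allocate true seeds round-robin over communities/subcortical labels (so
# planted effects spread across the whole parcellation, with signs from the
# community map), then group same-sign seeds into cliques of at most
# .seed_clique_max_size; the clique edges carry the planted WHR modulation
# and join true seeds only, so no other region receives planted signal
allocate_seed_cliques <- function(parcellation, n_true_seeds) {
  labels <- intersect(c(cortical_communities, subcortical_labels),
                      unique(parcellation$network))
  members <- split(parcellation$region_id, parcellation$network)[labels]
  capacity <- vapply(members, length, integer(1))
  if (n_true_seeds > sum(capacity)) {
    abort_input("n_true_seeds exceeds the number of regions")
  }
  used <- stats::setNames(integer(length(labels)), labels)
  seeds <- integer(); signs <- integer()
  lab_cycle <- rep(labels, length.out = sum(capacity))
  for (lab in lab_cycle) {
    if (length(seeds) >= n_true_seeds) break
    if (used[lab] + 1L > capacity[lab]) next
    used[lab] <- used[lab] + 1L
    seeds <- c(seeds, members[[lab]][used[lab]])
    signs <- c(signs, unname(.community_effect_sign[lab]))
  }
  cliques <- list()
  lone <- integer()
  for (s in c(1L, -1L)) {
    grp <- seeds[signs == s]
    if (length(grp) < 2L) {
      lone <- c(lone, grp)
      next
    }
    k <- ceiling(length(grp) / .seed_clique_max_size)
    sizes <- apportion_equal(length(grp), k)
    idx <- rep(seq_len(k), times = sizes)
    for (g in seq_len(k)) {
      cliques[[length(cliques) + 1L]] <- list(members = grp[idx == g],
                                              sign = s)
    }
  }
  list(seeds = sort(seeds),
       signs = stats::setNames(signs, seeds),
       cliques = cliques, lone = lone)
}

#' Generate a synthetic cohort with recoverable ground truth
#'
#' Draws per-subject region time series from zero-mean multivariate normal
#' distributions with block covariance (within-community covariance
#' `w`, between-community 0), then plants three recoverable effects by
#' modulating covariance entries per subject:
#'
#' * **WHR effect** — for each pair of true seed regions, the covariance of
#'   the edge joining them moves linearly with the subject's standardized
#'   WHR, scaled so the population correlation between a seed's estimated
#'   degree centrality and WHR approximates `planted_effect_r` under the
#'   default estimation conditions.
#' * **Group effect** — overweight subjects' within-network covariance in
#'   `group_effect_networks` is shifted so the network step degree differs
#'   between groups by about `group_effect_magnitude` standard deviations.
#' * **Behavior effect** — a per-subject latent modulates each behavior
#'   network's covariance, and the targeted TFEQ subscale loads on that
#'   latent so its correlation with the measured network step degree
#'   approximates the planted `r`.
#'
#' Phenotypes (age, sex, BMI, WHR, TFEQ) are drawn with sex-specific WHR
#' distributions and status-conditional BMI so the sex-specific group
#' cutoffs are exercised; TFEQ scores are integer, truncated at zero.
#' Identical config and seed reproduce the cohort exactly.
#'
#' @param config A [sim_config()] (or arguments forwarded to it via `...`).
#' @param ... Forwarded to [sim_config()] when `config` is missing.
#' @return An object of class `sfc_cohort`: list with `phenotypes`
#'   (tibble), `timeseries` (list of T x R matrices), `parcellation`, and
#'   `ground_truth` (true seeds, planted effect sizes, pairs, group and
#'   behavior effects, latent draws).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 20, n_regions = 28,
#'                                      n_timepoints = 50))
#' cohort$phenotypes
#' @export
simulate_cohort <- function(config = sim_config(...), ...) {
  cf <- config
  stopifnot(inherits(cf, "sim_config"))
  parc <- if (is.null(cf$community_sizes)) {
    default_parcellation(cf$n_regions)
  } else {
    parcellation_from_sizes(cf$community_sizes)
  }
  check_parcellation(parc, n_regions = cf$n_regions)
  n <- cf$n_subjects
  r <- cf$n_regions
  w <- cf$within_community_covariance

  with_seed(cf$rng_seed, {
    ## --- phenotypes -----------------------------------------------------
    sex <- ifelse(stats::runif(n) < 0.6047, "female", "male")
    age <- rtnorm(n, 40.44, 17.68, 18, 85)
    n_over <- round(cf$group_fraction * n)
    n_healthy <- round(cf$healthy_fraction * n)
    status <- sample(rep(c("overweight", "healthy", "intermediate"),
                         c(n_over, n_healthy, n - n_over - n_healthy)))
    cutoff <- ifelse(sex == "female", 0.85, 0.90)

    whr <- numeric(n)
    f <- sex == "female"
    idx <- status == "healthy"
    whr[idx & f] <- rtnorm(sum(idx & f), 0.76, 0.05, 0.55, 0.85)
    whr[idx & !f] <- rtnorm(sum(idx & !f), 0.81, 0.03, 0.60, 0.90)
    idx <- status == "overweight"
    whr[idx & f] <- rtnorm(sum(idx & f), 0.90, 0.04, 0.8501, 1.20)
    whr[idx & !f] <- rtnorm(sum(idx & !f), 0.98, 0.06, 0.9001, 1.20)
    idx <- status == "intermediate"
    whr[idx & f] <- rtnorm(sum(idx & f), 0.84, 0.06, 0.55, 1.20)
    whr[idx & !f] <- rtnorm(sum(idx & !f), 0.91, 0.05, 0.60, 1.20)

    # BMI: status-conditional band, coupled to the within-status WHR
    # residual; intermediates get the BMI band that violates their WHR side
    # so they satisfy neither group conjunction (stay unassigned)
    cpl <- cf$bmi_whr_coupling
    safe_sd <- function(v) if (length(v) < 2L) 1 else max(stats::sd(v), 1e-8)
    u <- (whr - stats::ave(whr, paste(status, sex), FUN = mean)) /
      stats::ave(whr, paste(status, sex), FUN = safe_sd)
    mix <- cpl * u + sqrt(1 - cpl^2) * stats::rnorm(n)
    bmi <- numeric(n)
    idx <- status == "healthy"
    bmi[idx] <- pmin(pmax(22.37 + 1.67 * mix[idx], 18.5), 24.99)
    idx <- status == "overweight"
    bmi[idx] <- pmin(pmax(31.07 + 4.60 * mix[idx], 25), 47.5)
    idx <- status == "intermediate" & whr > cutoff
    bmi[idx] <- pmin(pmax(23 + 1.5 * mix[idx], 18.5), 24.99)
    idx <- status == "intermediate" & whr <= cutoff
    bmi[idx] <- pmin(pmax(26.5 + 1.5 * mix[idx], 25), 47.5)

    z_whr <- as.numeric(scale(whr))

    ## --- planted structure ----------------------------------------------
    alloc <- allocate_seed_cliques(parc, cf$n_true_seeds)
    if (length(alloc$lone) && cf$planted_effect_r > 0) {
      warning(sprintf(
        "seed region(s) %s are the only ones of their effect sign and carry no clique edge; their planted effect is void",
        paste(alloc$lone, collapse = ", ")), call. = FALSE)
    }
    beta_total <- .whr_noise_to_signal * cf$planted_effect_r /
      sqrt(1 - cf$planted_effect_r^2)
    # per-edge modulation so every seed's summed edge modulation is
    # beta_total regardless of its clique size
    clique_edges <- purrr::map(alloc$cliques, function(cl) {
      m <- length(cl$members)
      list(pairs = utils::combn(cl$members, 2L), sign = cl$sign,
           beta_e = beta_total / (m - 1L))
    })
    group_amp <- .group_amp_per_d * cf$group_effect_magnitude *
      cf$group_effect_sign
    behav <- cf$behavior_effects
    behav_nets <- unique(behav$network)
    b_latent <- matrix(stats::rnorm(n * length(behav_nets)), n,
                       dimnames = list(NULL, behav_nets))

    net_members <- split(parc$region_id, parc$network)
    sigma0 <- diag(r)
    for (ids in net_members) sigma0[ids, ids] <- w
    diag(sigma0) <- 1

    subject_sigma <- function(i) {
      s <- sigma0
      for (ce in clique_edges) {
        v <- min(max(.seed_clique_baseline +
                       ce$sign * ce$beta_e * z_whr[i], 0.02), 0.8)
        for (e in seq_len(ncol(ce$pairs))) {
          a <- ce$pairs[1L, e]; b <- ce$pairs[2L, e]
          s[a, b] <- v
          s[b, a] <- v
        }
      }
      shift <- stats::setNames(numeric(length(net_members)),
                               names(net_members))
      if (status[i] == "overweight") {
        shift[cf$group_effect_networks] <-
          shift[cf$group_effect_networks] + group_amp
      }
      for (bn in behav_nets) {
        shift[bn] <- shift[bn] + .behavior_modulation_amp * b_latent[i, bn]
      }
      for (nm in names(shift)[shift != 0]) {
        ids <- net_members[[nm]]
        blk <- s[ids, ids]
        off <- pmin(pmax(blk + shift[nm], 0.02), 0.75)
        diag(off) <- 1
        s[ids, ids] <- off
      }
      s
    }

    ## --- time series ----------------------------------------------------
    t_len <- cf$n_timepoints
    timeseries <- vector("list", n)
    for (i in seq_len(n)) {
      s <- subject_sigma(i)
      ch <- tryCatch(chol(s), error = function(e) NULL)
      while (is.null(ch)) { # safeguard: blend toward identity until PD
        s <- 0.95 * s + 0.05 * diag(r)
        ch <- tryCatch(chol(s), error = function(e) NULL)
      }
      x <- matrix(stats::rnorm(t_len * r), t_len, r) %*% ch
      if (cf$noise_sd > 0) {
        x <- x + cf$noise_sd * matrix(stats::rnorm(t_len * r), t_len, r)
      }
      colnames(x) <- parc$region_name
      timeseries[[i]] <- x
    }

    ## --- TFEQ scores ----------------------------------------------------
    base <- list(restraint = c(7.5, 4.7), disinhibition = c(4.5, 3.0),
                 hunger = c(4.3, 3.2))
    over_shift <- c(restraint = 2.4, disinhibition = 1.7, hunger = 0)
    tfeq <- purrr::imap(base, function(ms, nm) {
      eff <- behav[behav$score == nm & behav$r != 0, ]
      zsc <- stats::rnorm(n)
      # scores carrying a planted network effect stay unconfounded by group
      # status, so the planted correlation is the score's only systematic
      # link to the connectome and ground truth stays interpretable
      shift <- if (nrow(eff)) 0 else over_shift[nm]
      if (nrow(eff)) {
        loading <- sum(eff$r) / .behavior_latent_degree_r
        if (abs(loading) > 1) {
          abort_input(sprintf(
            "planted behavior correlation %.2f for %s exceeds the attainable magnitude %.2f",
            sum(eff$r), nm, .behavior_latent_degree_r))
        }
        lat <- rowSums(b_latent[, eff$network, drop = FALSE]) /
          sqrt(nrow(eff))
        zsc <- loading * lat + sqrt(1 - loading^2) * zsc
      }
      raw <- ms[1L] + ms[2L] * zsc + shift * (status == "overweight")
      pmax(round(raw), 0)
    })

    phenotypes <- tibble::tibble(
      subject_id = sprintf("sub%04d", seq_len(n)),
      age = age, sex = sex, bmi = bmi, whr = whr,
      tfeq_restraint = tfeq$restraint,
      tfeq_disinhibition = tfeq$disinhibition,
      tfeq_hunger = tfeq$hunger
    )
    names(timeseries) <- phenotypes$subject_id

    seeds_true <- alloc$seeds
    effect_sizes <- stats::setNames(numeric(r), parc$region_name)
    effect_sizes[seeds_true] <- alloc$signs[as.character(seeds_true)] *
      cf$planted_effect_r
    ground_truth <- list(
      seed_regions_true = seeds_true,
      effect_sizes = effect_sizes,
      seed_cliques = alloc$cliques,
      group_effect_networks = cf$group_effect_networks,
      group_effect_sign = cf$group_effect_sign,
      group_effect_magnitude = cf$group_effect_magnitude,
      behavior_effects = behav,
      status = status,
      behavior_latents = b_latent
    )
    structure(list(phenotypes = phenotypes, timeseries = timeseries,
                   parcellation = parc, ground_truth = ground_truth,
                   config = cf),
              class = "sfc_cohort")
  })
}

#' @export
print.sfc_cohort <- function(x, ...) {
  cat(sprintf(
    "<sfc_cohort> %d subjects, %d regions x %d timepoints%s\n",
    nrow(x$phenotypes), ncol(x$timeseries[[1L]]), nrow(x$timeseries[[1L]]),
    if (is.null(x$ground_truth)) "" else
      sprintf(", %d true seed region(s)",
              length(x$ground_truth$seed_regions_true))))
  invisible(x)
}

#' TFEQ scores of a cohort as a tidy table
#'
#' @param cohort An `sfc_cohort`.
#' @return Tibble with subscales `restraint`, `disinhibition`, `hunger`.
#' @export
cohort_tfeq <- function(cohort) {
  ph <- cohort$phenotypes
  tibble::tibble(restraint = ph$tfeq_restraint,
                 disinhibition = ph$tfeq_disinhibition,
                 hunger = ph$tfeq_hunger)
}

#' Degree centrality matrix for a whole cohort
#'
#' Convenience wrapper: per-subject ridge partial correlation followed by
#' [degree_centrality()], stacked into a subjects x regions matrix.
#'
#' @param cohort An `sfc_cohort`.
#' @param rho Ridge parameter (default taken from the cohort's config,
#'   else 0.5).
#' @param mode Degree convention, see [degree_centrality()].
#' @return Subjects x regions numeric matrix with dimnames.
#' @export
cohort_degrees <- function(cohort, rho = NULL, mode = "absolute") {
  rho <- rho %||% (cohort$config$rho %||% 0.5)
  mats <- purrr::map(cohort$timeseries,
                     \(ts) degree_centrality(partial_correlation(ts, rho),
                                             mode = mode))
  out <- do.call(rbind, mats)
  rownames(out) <- cohort$phenotypes$subject_id
  out
}
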