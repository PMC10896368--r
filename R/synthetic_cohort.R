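#' Simulation configuration for multi-cohort aptamer proteomics
#'
#' Builds and validates the configuration of the synthetic-cohort generator.
#' The generator emulates the structure of a multi-cohort CSF SomaScan study of
#' the Alzheimer's disease (AD) continuum: log10 relative-fluorescence-unit
#' (RFU) values are Gaussian with per-plate batch shifts, CSF A-beta-42 and
#' pTau181 are bimodal (their mixture component defines the true A and T
#' labels), a fraction of aptamers carries planted stage-wise mean shifts
#' following one of four pseudo-trajectory archetypes, and clinical
#' trajectories (CDR-SB slopes, conversion times) are linked to true A+T+
#' status.
#'
#' @param n_samples_per_cohort named integer vector: number of samples per
#'   cohort. Default two cohorts, a discovery and a replication stage.
#' @param n_aptamers number of aptamers (analytes) on the simulated panel.
#' @param n_plates number of plates per cohort; samples are assigned
#'   round-robin so plate is not confounded with disease stage.
#' @param frac_effect fraction of aptamers carrying planted AT effects.
#' @param trajectory_mix nonnegative weights over the four archetypes
#'   \code{linear_up}, \code{up_down}, \code{linear_down}, \code{down_up};
#'   must sum to 1.
#' @param effect_size standardized mean shift per stage transition, in log10
#'   RFU units (delta).
#' @param batch_sd standard deviation of the per-plate additive shift (log10
#'   RFU).
#' @param noise_sd residual standard deviation (log10 RFU).
#' @param biomarker_separation distance between the two mixture-component
#'   means, in units of the component SD, for both A-beta-42 and pTau.
#' @param at_proportions probabilities over \code{A-T-}, \code{A+T-},
#'   \code{A+T+} (the A-T+ pattern is never generated); must sum to 1.
#' @param cdr_slopes named vector \code{c(negative=, positive=)}: mean CDR-SB
#'   progression slope (points/year) for signature-negative and -positive
#'   (true A+T+) individuals.
#' @param conversion_rates named vector \code{c(negative=, positive=)}:
#'   exponential hazard (events/year) of conversion to AD for each group.
#' @param followup_max maximum follow-up (years); censoring is uniform on
#'   (0, followup_max).
#' @param effect_aptamers optional character vector of aptamer IDs (in the
#'   \code{sprintf("APT\%05d", i)} naming) to carry the planted effects,
#'   overriding random placement; its length overrides \code{frac_effect}.
#'   Used e.g. to state an "other dementia" cohort whose planted mechanism is
#'   disjoint from the AD cohort's.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_samples_per_cohort = c(discovery = 400L, replication = 300L),
                              n_aptamers = 1000L,
                              n_plates = 4L,
                              frac_effect = 0.1,
                              trajectory_mix = c(linear_up = 0.25, up_down = 0.25,
                                                 linear_down = 0.25, down_up = 0.25),
                              effect_size = 0.15,
                              batch_sd = 0.05,
                              noise_sd = 0.2,
                              biomarker_separation = 5,
                              at_proportions = c("A-T-" = 0.47, "A+T-" = 0.19, "A+T+" = 0.34),
                              cdr_slopes = c(negative = 0.2, positive = 0.55),
                              conversion_rates = c(negative = 0.02, positive = 0.10),
                              followup_max = 15,
                              effect_aptamers = NULL,
                              seed = 1L) {
  if (is.null(names(n_samples_per_cohort)) || any(names(n_samples_per_cohort) == "")) {
    stop("field 'n_samples_per_cohort' must be a named vector of cohort sizes", call. = FALSE)
  }
  check_finite_vec(n_samples_per_cohort, "n_samples_per_cohort")
  if (any(n_samples_per_cohort < 1)) stop("field 'n_samples_per_cohort' must be positive", call. = FALSE)
  check_finite_scalar(n_aptamers, "n_aptamers")
  check_finite_scalar(n_plates, "n_plates")
  check_finite_scalar(frac_effect, "frac_effect")
  if (frac_effect < 0 || frac_effect > 1) stop("field 'frac_effect' must lie in [0,1]", call. = FALSE)
  check_finite_vec(trajectory_mix, "trajectory_mix")
  if (length(trajectory_mix) != 4L || any(trajectory_mix < 0)) {
    stop("field 'trajectory_mix' must be 4 nonnegative weights", call. = FALSE)
  }
  if (abs(sum(trajectory_mix) - 1) > 1e-12) {
    stop("field 'trajectory_mix' must sum to 1", call. = FALSE)
  }
  check_finite_scalar(effect_size, "effect_size")
  for (f in c("batch_sd", "noise_sd", "biomarker_separation")) {
    v <- get(f)
    check_finite_scalar(v, f)
    if (v <= 0) stop("field '", f, "' must be strictly positive", call. = FALSE)
  }
  check_finite_vec(at_proportions, "at_proportions")
  if (length(at_proportions) != 3L || abs(sum(at_proportions) - 1) > 1e-12) {
    stop("field 'at_proportions' must be 3 probabilities summing to 1", call. = FALSE)
  }
  check_finite_vec(cdr_slopes, "cdr_slopes")
  check_finite_vec(conversion_rates, "conversion_rates")
  if (any(conversion_rates <= 0)) stop("field 'conversion_rates' must be strictly positive", call. = FALSE)
  check_finite_scalar(followup_max, "followup_max")
  check_finite_scalar(seed, "seed")

  names(trajectory_mix) <- c("linear_up", "up_down", "linear_down", "down_up")
  names(at_proportions) <- AT_LEVELS
  structure(list(
    n_samples_per_cohort = stats::setNames(as.integer(n_samples_per_cohort),
                                           names(n_samples_per_cohort)),
    cohorts = names(n_samples_per_cohort),
    n_aptamers = as.integer(n_aptamers),
    n_plates = as.integer(n_plates),
    frac_effect = frac_effect,
    trajectory_mix = trajectory_mix,
    effect_size = effect_size,
    batch_sd = batch_sd,
    noise_sd = noise_sd,
    biomarker_separation = biomarker_separation,
    at_proportions = at_proportions,
    cdr_slopes = cdr_slopes,
    conversion_rates = conversion_rates,
    followup_max = followup_max,
    effect_aptamers = effect_aptamers,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Stage-wise planted mean shifts (log10 RFU) for each archetype, relative to
# the A-T- baseline, ordered (A-T-, A+T-, A+T+). Non-monotone archetypes end
# on the opposite side of baseline so that they remain detectable in the
# endpoint (A+T+ vs A-T-) comparison, as the analyzed trajectory groups are.
archetype_shifts <- function(archetype, delta) {
  switch(archetype,
    linear_up   = c(0, delta, 2 * delta),
    up_down     = c(0, delta, -delta),
    linear_down = c(0, -delta, -2 * delta),
    down_up     = c(0, -delta, delta),
    stop("unknown archetype: ", archetype)
  )
}

#' Simulate multi-cohort aptamer proteomics datasets with planted ground truth
#'
#' Generates one \code{proteomics_dataset} per configured cohort together with
#' sample metadata, longitudinal CDR-SB visits and a ground-truth record of
#' every planted quantity. Calibrator wells (3 technical-replicate wells per
#' plate) are appended to each matrix and referenced by
#' \code{replicate_groups}; per-aptamer-by-plate calibration and median scale
#' factors are emitted for QC.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a list with elements \code{datasets} (list of
#'   \code{proteomics_dataset}), \code{records} (list of per-cohort sample
#'   metadata data frames), \code{longitudinal} (per-cohort CDR-SB visit
#'   tables), and \code{truth} (a \code{ground_truth} list with per-aptamer
#'   and per-sample planted values).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  m <- config$n_aptamers
  aptamer_ids <- sprintf("APT%05d", seq_len(m))

  # planted aptamer effects
  if (!is.null(config$effect_aptamers)) {
    effect_idx <- sort(match(config$effect_aptamers, aptamer_ids))
    if (any(is.na(effect_idx))) stop("effect_aptamers not on the panel", call. = FALSE)
    n_eff <- length(effect_idx)
  } else {
    n_eff <- round(config$frac_effect * m)
    effect_idx <- if (n_eff > 0) sort(sample.int(m, n_eff)) else integer(0)
  }
  is_effect <- seq_len(m) %in% effect_idx
  archetype <- rep(NA_character_, m)
  if (n_eff > 0) {
    archetype[effect_idx] <- sample(names(config$trajectory_mix), n_eff,
                                    replace = TRUE, prob = config$trajectory_mix)
  }
  shifts <- matrix(0, nrow = m, ncol = 3, dimnames = list(aptamer_ids, AT_LEVELS))
  for (j in effect_idx) {
    shifts[j, ] <- archetype_shifts(archetype[j], config$effect_size)
  }
  baseline <- stats::runif(m, 2.5, 4.5)

  datasets <- list()
  records <- list()
  longitudinal <- list()
  sample_truth <- list()

  for (cohort in config$cohorts) {
    n <- config$n_samples_per_cohort[[cohort]]
    sample_ids <- sprintf("%s_S%05d", cohort, seq_len(n))
    at_true <- sample(AT_LEVELS, n, replace = TRUE, prob = config$at_proportions)
    at_idx <- match(at_true, AT_LEVELS)

    # CSF biomarkers: A+ = low A-beta-42 component, T+ = high pTau component
    sep <- config$biomarker_separation
    ab_sd <- 100; ab_lo <- 600; ab_hi <- ab_lo + sep * ab_sd
    pt_sd <- 5;   pt_lo <- 20;  pt_hi <- pt_lo + sep * pt_sd
    a_pos <- at_true %in% c("A+T-", "A+T+")
    t_pos <- at_true == "A+T+"
    abeta42 <- stats::rnorm(n, ifelse(a_pos, ab_lo, ab_hi), ab_sd)
    ptau <- stats::rnorm(n, ifelse(t_pos, pt_hi, pt_lo), pt_sd)
    abeta42 <- pmax(abeta42, 1)
    ptau <- pmax(ptau, 0.1)

    plates <- sprintf("%s_P%02d", cohort, seq_len(config$n_plates))
    plate_of_sample <- rep_len(plates, n)
    plate_shift <- stats::rnorm(config$n_plates, 0, config$batch_sd)
    names(plate_shift) <- plates

    logm <- matrix(baseline, nrow = n, ncol = m, byrow = TRUE) +
      t(shifts[, at_idx]) +
      plate_shift[plate_of_sample] +
      matrix(stats::rnorm(n * m, 0, config$noise_sd), nrow = n)

    # calibrator wells: one replicate group of 3 wells per plate, drawn around
    # a cohort-level calibrator profile with small technical noise
    cal_profile <- baseline + stats::rnorm(m, 0, 0.05)
    cal_rows <- list(); cal_ids <- character(0); cal_plate <- character(0)
    replicate_groups <- list()
    for (p in plates) {
      ids <- sprintf("%s_CAL_%s_r%d", cohort, sub(".*_", "", p), 1:3)
      wells <- matrix(cal_profile, nrow = 3, ncol = m, byrow = TRUE) +
        plate_shift[p] + matrix(stats::rnorm(3 * m, 0, 0.02), nrow = 3)
      cal_rows[[p]] <- wells
      cal_ids <- c(cal_ids, ids)
      cal_plate <- c(cal_plate, rep(p, 3))
      replicate_groups[[p]] <- ids
    }
    logm <- rbind(logm, do.call(rbind, cal_rows))
    all_ids <- c(sample_ids, cal_ids)
    rownames(logm) <- all_ids
    colnames(logm) <- aptamer_ids

    calib_scale <- matrix(stats::rnorm(m * config$n_plates, 1, 0.03),
                          nrow = m, dimnames = list(aptamer_ids, plates))
    median_scale <- calib_scale + stats::rnorm(m * config$n_plates, 0, 0.02)

    datasets[[cohort]] <- proteomics_dataset(
      rfu = 10^logm,
      plate_of_sample = stats::setNames(c(plate_of_sample, cal_plate), all_ids),
      cohort = cohort,
      calib_scale = calib_scale,
      median_scale = median_scale,
      replicate_groups = replicate_groups
    )

    # demographics and clinical ground truth
    age <- pmax(stats::rnorm(n, 70, 8), 45)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    sig_pos <- at_true == "A+T+"
    slope <- ifelse(sig_pos, config$cdr_slopes[["positive"]],
                    config$cdr_slopes[["negative"]]) + stats::rnorm(n, 0, 0.1)
    initial_cdr <- ifelse(sig_pos, pmax(stats::rnorm(n, 1.5, 0.5), 0), 0)
    conv_time <- stats::rexp(n, ifelse(sig_pos, config$conversion_rates[["positive"]],
                                       config$conversion_rates[["negative"]]))
    censor_time <- stats::runif(n, 0, config$followup_max)
    converted <- conv_time <= censor_time
    followup_years <- pmin(conv_time, censor_time)

    records[[cohort]] <- data.frame(
      sample_id = sample_ids,
      cohort = cohort,
      age = age,
      sex = sex,
      plate = plate_of_sample,
      abeta42 = abeta42,
      ptau = ptau,
      clinical_dx = ifelse(at_true == "A+T+", "AD", "CO"),
      at_status = NA_character_,
      followup_years = followup_years,
      converted = converted,
      stringsAsFactors = FALSE
    )

    # annual CDR-SB visits over up to 6 years of observed follow-up
    n_visits <- pmax(2L, pmin(6L, floor(followup_years) + 1L))
    vis <- data.frame(
      sample_id = rep(sample_ids, n_visits),
      years = unlist(lapply(n_visits, function(k) 0:(k - 1L))),
      stringsAsFactors = FALSE
    )
    vis$cdr_sb <- pmax(0, initial_cdr[match(vis$sample_id, sample_ids)] +
                         slope[match(vis$sample_id, sample_ids)] * vis$years +
                         stats::rnorm(nrow(vis), 0, 0.3))
    longitudinal[[cohort]] <- vis

    sample_truth[[cohort]] <- data.frame(
      sample_id = sample_ids,
      cohort = cohort,
      at_true = at_true,
      conversion_time = conv_time,
      censored = !converted,
      cdr_slope = slope,
      stringsAsFactors = FALSE
    )
  }

  truth <- structure(list(
    aptamers = data.frame(
      aptamer_id = aptamer_ids,
      is_effect = is_effect,
      archetype = archetype,
      shift_AposTneg = shifts[, "A+T-"],
      shift_AposTpos = shifts[, "A+T+"],
      row.names = NULL,
      stringsAsFactors = FALSE
    ),
    samples = do.call(rbind, c(sample_truth, list(make.row.names = FALSE)))
  ), class = "ground_truth")

  list(datasets = datasets, records = records,
       longitudinal = longitudinal, truth = truth)
}

#' Inject known QC failures into a dataset
#'
#' Corrupts a copy of the dataset so that exactly \code{n_bad_aptamers}
#' aptamers violate aptamer-level QC rules (alternating between a
#' scale-factor violation of |calibration - median| > 0.5 on one plate and a
#' replicate coefficient of variation above 0.15) and \code{n_bad_samples}
#' samples become interquartile-range outliers across essentially all
#' aptamers. The injected roster is recorded in the returned dataset's
#' \code{qc_truth} element so tests can check exact recovery.
#'
#' @param dataset a \code{proteomics_dataset}.
#' @param n_bad_aptamers,n_bad_samples number of aptamers / samples to corrupt.
#' @param seed integer seed for choosing the victims.
#' @return the corrupted \code{proteomics_dataset}, with a \code{qc_truth}
#'   list (\code{aptamers}, \code{samples}) naming the injected failures.
#' @export
inject_qc_failures <- function(dataset, n_bad_aptamers, n_bad_samples, seed = 1L) {
  stopifnot(inherits(dataset, "proteomics_dataset"))
  m <- length(dataset$aptamer_ids)
  real_samples <- setdiff(dataset$sample_ids, unlist(dataset$replicate_groups))
  if (n_bad_aptamers > m || n_bad_samples > length(real_samples)) {
    stop("requested more QC failures than matrix dimensions allow", call. = FALSE)
  }
  set.seed(seed)
  bad_apt <- if (n_bad_aptamers > 0) sample(dataset$aptamer_ids, n_bad_aptamers) else character(0)
  bad_smp <- if (n_bad_samples > 0) sample(real_samples, n_bad_samples) else character(0)

  have_reps <- length(dataset$replicate_groups) > 0
  for (i in seq_along(bad_apt)) {
    a <- bad_apt[i]
    if (i %% 2L == 1L || !have_reps) {
      # scale-factor violation on the first plate
      dataset$calib_scale[a, 1] <- dataset$median_scale[a, 1] + 0.6
    } else {
      # inflate one well per replicate group: CV of (2.5v, v, v) ~ 0.58
      for (grp in dataset$replicate_groups) {
        dataset$rfu[grp[1], a] <- dataset$rfu[grp[1], a] * 2.5
      }
    }
  }
  if (length(bad_smp) > 0) {
    dataset$rfu[bad_smp, ] <- dataset$rfu[bad_smp, , drop = FALSE] * 1e10
  }
  dataset$qc_truth <- list(aptamers = sort(bad_apt), samples = sort(bad_smp))
  dataset
}
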