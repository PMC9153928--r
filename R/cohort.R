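#' Population hyperparameters for the synthetic cohort
#'
#' Means and between-subject standard deviations of the generative subject
#' parameters, on the scales the simulator uses (log-odds for response
#' probabilities, log-seconds for reaction-time location). The defaults
#' emulate the trial cohort: 31 right-handed adults (17 women : 14 men),
#' ages truncated-normal 30.84 +/- 6.16 years on 19-42; visuospatial hit
#' and false-alarm rates near 0.83 / 0.07 and auditory-verbal near
#' 0.89 / 0.11; lognormal latencies with block means near 1.45-1.57 s and
#' within-block SDs near 0.45-0.55 s; practice improvement across blocks;
#' within-block fatigue whose direction differs by modality (hit rates sag
#' in both streams, false alarms rise only in the auditory-verbal stream);
#' latencies lengthening with age and a weak negative sound-volume effect.
#'
#' Entries named `*_mean`/`*_sd` are sampled per subject on the stated
#' scale; the remaining entries are population constants.
#'
#' @param ... Named overrides of individual entries.
#' @return A named list of hyperparameters.
#' @export
default_population <- function(...) {
  pop <- list(
    age_mean = 30.84, age_sd = 6.16, age_min = 19, age_max = 42,
    p_female = 17 / 31,
    # baseline response probabilities, logit scale
    hit_vs_mean = stats::qlogis(0.83), hit_vs_sd = 0.70,
    hit_av_mean = stats::qlogis(0.885), hit_av_sd = 0.70,
    fa_vs_mean = stats::qlogis(0.07), fa_vs_sd = 0.60,
    fa_av_mean = stats::qlogis(0.113), fa_av_sd = 0.60,
    # log-odds bump for false alarms on lure trials
    lure_fa_logodds = 0.7,
    # practice across the session, per block, log-odds
    train_hit = 0.09, train_fa = -0.08,
    # within-block fatigue: second-half shift, log-odds
    fatigue_hit_vs = -0.40, fatigue_hit_av = -0.15,
    fatigue_fa_vs = -0.10, fatigue_fa_av = 0.25,
    # lognormal latency parameters (log-seconds)
    rt_loc_vs_mean = 0.33, rt_loc_vs_sd = 0.15,
    rt_loc_av_mean = 0.40, rt_loc_av_sd = 0.15,
    rt_scale_mean = 0.32, rt_scale_sd = 0.04,
    rt_train = -0.028, rt_half = -0.030,
    age_rt_coeff = 0.008, volume_rt_coeff = -0.02
  )
  overrides <- list(...)
  stopifnot(all(names(overrides) %in% names(pop)))
  pop[names(overrides)] <- overrides
  pop
}

# exact truncated-normal sampler via inverse CDF; degenerate sd collapses
# to the (clamped) mean
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Sample generative subject profiles
#'
#' Draws per-subject parameters from [default_population()]-style
#' hyperparameters: age from a truncated normal, sex from the population
#' odds, response baselines on the logit scale, latency parameters on the
#' log scale, and a standardized per-subject sound-volume covariate
#' (constant across that subject's five conditions).
#'
#' @param n Number of subjects.
#' @param population Hyperparameter list, see [default_population()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per subject: identifiers, covariates
#'   (`sex`, `age`, `volume`) and ground-truth generative parameters
#'   (baseline probabilities on the probability scale, slopes on the
#'   log-odds / log scales).
#' @examples
#' sample_profiles(3, seed = 1)
#' @export
sample_profiles <- function(n, population = default_population(), seed = NULL) {
  p <- population
  with_seed_if(seed, {
    tibble::tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      sex = ifelse(stats::runif(n) < p$p_female, "female", "male"),
      age = rtruncnorm(n, p$age_mean, p$age_sd, p$age_min, p$age_max),
      volume = stats::rnorm(n),
      hit_vs = stats::plogis(stats::rnorm(n, p$hit_vs_mean, p$hit_vs_sd)),
      hit_av = stats::plogis(stats::rnorm(n, p$hit_av_mean, p$hit_av_sd)),
      fa_vs = stats::plogis(stats::rnorm(n, p$fa_vs_mean, p$fa_vs_sd)),
      fa_av = stats::plogis(stats::rnorm(n, p$fa_av_mean, p$fa_av_sd)),
      lure_fa_logodds = p$lure_fa_logodds,
      train_hit = p$train_hit,
      train_fa = p$train_fa,
      fatigue_hit_vs = p$fatigue_hit_vs,
      fatigue_hit_av = p$fatigue_hit_av,
      fatigue_fa_vs = p$fatigue_fa_vs,
      fatigue_fa_av = p$fatigue_fa_av,
      rt_loc_vs = stats::rnorm(n, p$rt_loc_vs_mean, p$rt_loc_vs_sd),
      rt_loc_av = stats::rnorm(n, p$rt_loc_av_mean, p$rt_loc_av_sd),
      rt_scale = pmax(stats::rnorm(n, p$rt_scale_mean, p$rt_scale_sd), 1e-6),
      rt_train = p$rt_train,
      rt_half = p$rt_half,
      age_rt_coeff = p$age_rt_coeff,
      volume_rt_coeff = p$volume_rt_coeff,
      age_center = p$age_mean
    )
  })
}

#' Cohort design: subjects x conditions x blocks
#'
#' @param n_subjects Number of subjects (default 31).
#' @param conditions Intervention labels; each subject receives every
#'   condition exactly once, in an independent uniform random order.
#' @param blocks_per_session Number of blocks (= number of conditions in
#'   the within-subject crossover; default 5).
#' @param spec_vs,spec_av Per-modality [block_spec()]s.
#' @param condition_effects Optional tibble
#'   `(condition, modality, hit_shift, fa_shift, rt_shift)` of additive
#'   shifts on the hit log-odds, false-alarm log-odds and log-latency
#'   location. Default: all zero (no intervention effect).
#' @return A list of class `dnb_design`.
#' @export
cohort_design <- function(n_subjects = 31,
                          conditions = c("silence", "pure_tone_240Hz",
                                         "BB_10Hz", "BB_16Hz", "BB_40Hz"),
                          blocks_per_session = length(conditions),
                          spec_vs = block_spec(alphabet_size = 9),
                          spec_av = block_spec(alphabet_size = 11),
                          condition_effects = NULL) {
  stopifnot(n_subjects >= 1, length(conditions) == blocks_per_session)
  if (is.null(condition_effects)) {
    condition_effects <- tidyr::expand_grid(
      condition = conditions,
      modality = c("visuospatial", "auditory_verbal")
    ) |>
      dplyr::mutate(hit_shift = 0, fa_shift = 0, rt_shift = 0)
  }
  stopifnot(all(c("condition", "modality", "hit_shift", "fa_shift",
                  "rt_shift") %in% names(condition_effects)))
  structure(
    list(
      n_subjects = as.integer(n_subjects), conditions = conditions,
      blocks_per_session = as.integer(blocks_per_session),
      spec_vs = spec_vs, spec_av = spec_av,
      condition_effects = tibble::as_tibble(condition_effects)
    ),
    class = "dnb_design"
  )
}

#' Simulate one subject's responses to an annotated block
#'
#' Bernoulli responding on the logit scale: on target trials the response
#' probability is `plogis(qlogis(hit) + train_hit * (block - 1) +
#' fatigue_hit * second_half + hit_shift)`; on non-target trials the
#' analogous false-alarm model applies, with `lure_fa_logodds` added on
#' lure trials. A responded trial gets a latency
#' `min(trial_duration, rlnorm(location, rt_scale))` where the location
#' collects the subject baseline, per-block practice, second-half shift,
#' centered-age and volume effects, and the condition's latency shift.
#'
#' @param annotated Tibble with `trial`, `is_target`, `is_lure` (one block,
#'   one modality), e.g. from [generate_sequence()].
#' @param profile One row of [sample_profiles()].
#' @param modality `"visuospatial"` or `"auditory_verbal"`.
#' @param condition Condition label (used to look up shifts).
#' @param block_index Time-block position, 1-based.
#' @param condition_effects Shift table as in [cohort_design()]; `NULL`
#'   means all shifts zero.
#' @param trial_duration Truncation bound for latencies, seconds.
#' @param seed Optional integer seed.
#' @return `annotated` plus columns `responded` (logical) and `rt`
#'   (seconds; `NA` when not responded).
#' @export
simulate_trials <- function(annotated, profile, modality = "visuospatial",
                            condition = "silence", block_index = 1,
                            condition_effects = NULL,
                            trial_duration = 3.330, seed = NULL) {
  stopifnot(all(c("trial", "is_target", "is_lure") %in% names(annotated)),
            block_index >= 1)
  pr <- as.list(profile)
  m <- if (startsWith(modality, "vis")) "vs" else "av"
  shifts <- c(hit_shift = 0, fa_shift = 0, rt_shift = 0)
  if (!is.null(condition_effects)) {
    row <- condition_effects[
      condition_effects$condition == condition &
        condition_effects$modality == modality, ]
    if (nrow(row) == 1) {
      shifts <- c(hit_shift = row$hit_shift, fa_shift = row$fa_shift,
                  rt_shift = row$rt_shift)
    }
  }
  n <- nrow(annotated)
  second_half <- annotated$trial > floor(max(annotated$trial) / 2)

  eta_hit <- stats::qlogis(pr[[paste0("hit_", m)]]) +
    pr$train_hit * (block_index - 1) +
    pr[[paste0("fatigue_hit_", m)]] * second_half +
    shifts[["hit_shift"]]
  eta_fa <- stats::qlogis(pr[[paste0("fa_", m)]]) +
    pr$train_fa * (block_index - 1) +
    pr[[paste0("fatigue_fa_", m)]] * second_half +
    pr$lure_fa_logodds * annotated$is_lure +
    shifts[["fa_shift"]]
  p_resp <- ifelse(annotated$is_target,
                   stats::plogis(eta_hit), stats::plogis(eta_fa))

  rt_loc <- pr[[paste0("rt_loc_", m)]] +
    pr$rt_train * (block_index - 1) +
    pr$rt_half * second_half +
    pr$age_rt_coeff * (pr$age - pr$age_center) +
    pr$volume_rt_coeff * pr$volume +
    shifts[["rt_shift"]]

  with_seed_if(seed, {
    responded <- stats::runif(n) < p_resp
    rt <- rep(NA_real_, n)
    k <- sum(responded)
    if (k > 0) {
      rt[responded] <- pmin(
        trial_duration,
        stats::rlnorm(k, rt_loc[responded], pr$rt_scale)
      )
    }
    dplyr::mutate(tibble::as_tibble(annotated),
                  responded = responded, rt = rt)
  })
}

#' Simulate a full within-subject cohort
#'
#' For each subject: an independent uniform random ordering of the
#' conditions over the time blocks, a fresh dual block per time block from
#' [generate_dual_block()], and responses from [simulate_trials()] for both
#' modalities. Fully reproducible from `seed` alone.
#'
#' @param design A [cohort_design()].
#' @param population Hyperparameters for [sample_profiles()].
#' @param seed Integer seed.
#' @return A tibble of class `dnb_trials`, one row per trial per modality:
#'   `subject_id`, `time_block`, `condition`, `modality`, `trial`,
#'   `stimulus`, `is_target`, `is_lure`, `responded`, `rt`. The
#'   ground-truth profile table is attached as attribute `"profiles"`
#'   (see [cohort_profiles()]) and the seed as attribute `"seed"`.
#' @examples
#' \donttest{
#' log <- simulate_cohort(cohort_design(n_subjects = 2), seed = 1)
#' dplyr::count(log, subject_id, modality)
#' }
#' @export
simulate_cohort <- function(design = cohort_design(),
                            population = default_population(), seed = 1) {
  seed <- as.integer(seed)
  profiles <- sample_profiles(design$n_subjects, population,
                              seed = derive_seed(seed, 0L))
  specs <- list(visuospatial = design$spec_vs,
                auditory_verbal = design$spec_av)
  rows <- purrr::map(seq_len(design$n_subjects), function(i) {
    prof <- profiles[i, ]
    order_i <- with_seed_if(
      derive_seed(seed, i, 999L),
      sample(design$conditions)
    )
    purrr::map(seq_len(design$blocks_per_session), function(b) {
      blk <- generate_dual_block(design$spec_vs, design$spec_av,
                                 seed = derive_seed(seed, i, b))
      purrr::map(names(specs), function(mod) {
        ann <- blk[blk$modality == mod,
                   c("trial", "stimulus", "is_target", "is_lure")]
        simulate_trials(
          ann, prof,
          modality = mod, condition = order_i[b], block_index = b,
          condition_effects = design$condition_effects,
          trial_duration = specs[[mod]]$trial_duration,
          seed = derive_seed(seed, i, b, match(mod, names(specs)))
        ) |>
          dplyr::mutate(
            subject_id = prof$subject_id, time_block = b,
            condition = order_i[b], modality = mod, .before = 1
          )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  attr(rows, "profiles") <- profiles
  attr(rows, "seed") <- seed
  class(rows) <- c("dnb_trials", class(rows))
  rows
}

#' Ground-truth profiles of a simulated cohort
#'
#' @param trials A `dnb_trials` tibble from [simulate_cohort()].
#' @return The profile tibble used to generate the log.
#' @export
cohort_profiles <- function(trials) {
  attr(trials, "profiles")
}

#' Read/write trial logs as CSV
#'
#' Column order and types are fixed so a written log reads back
#' identically.
#'
#' @param trials Trial-log tibble.
#' @param path File path.
#' @return `write_trial_log()`: `path` invisibly; `read_trial_log()`: the
#'   trial-log tibble.
#' @export
write_trial_log <- function(trials, path) {
  cols <- c("subject_id", "time_block", "condition", "modality", "trial",
            "stimulus", "is_target", "is_lure", "responded", "rt")
  readr::write_csv(dplyr::select(tibble::as_tibble(trials),
                                 dplyr::all_of(cols)), path)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    time_block = readr::col_integer(),
    condition = readr::col_character(),
    modality = readr::col_character(),
    trial = readr::col_integer(),
    stimulus = readr::col_integer(),
    is_target = readr::col_logical(),
    is_lure = readr::col_logical(),
    responded = readr::col_logical(),
    rt = readr::col_double()
  ))
}
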