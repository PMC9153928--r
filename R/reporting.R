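#' t-based confidence interval from summary statistics
#'
#' `mean +/- t(1 - (1-conf)/2, n-1) * sd / sqrt(n)`, the interval printed
#' in the descriptive tables. Undefined (`NA` bounds) for `n < 2`.
#'
#' @param mean,sd,n Stratum mean, SD and size.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble with `ci_lo` and `ci_hi`.
#' @examples
#' ci_t(1.554, 0.264, 31) # ~ (1.46, 1.65)
#' @export
ci_t <- function(mean, sd, n, conf = 0.95) {
  half <- ifelse(n >= 2, stats::qt(1 - (1 - conf) / 2, n - 1) * sd / sqrt(n),
                 NA_real_)
  tibble::tibble(ci_lo = mean - half, ci_hi = mean + half)
}

# n, mean, sd, t-based 95% CI, min, max of a numeric vector (NAs dropped)
mean_ci_stats <- function(x, conf = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- if (n >= 1) mean(x) else NA_real_
  s <- if (n >= 2) stats::sd(x) else NA_real_
  ci <- if (n >= 2) ci_t(m, s, n, conf) else tibble::tibble(ci_lo = NA_real_,
                                                            ci_hi = NA_real_)
  tibble::tibble(
    n = n, mean = m, sd = s,
    ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
    min = if (n >= 1) min(x) else NA_real_,
    max = if (n >= 1) max(x) else NA_real_
  )
}

#' Publication-style summary table of block outcomes and deltas
#'
#' Lays out one modality the way the trial's descriptive tables do: one
#' row per (group, parameter, sex stratum) with n, mean, SD, t-based 95%
#' CI, min, max, and -- for the delta parameters -- the P value of the
#' one-sample t-test of the mean delta against zero. Strata are `female`,
#' `male` and `total`; n counts non-missing values, so parameters with
#' undefined cells (response bias at extreme rates) show a reduced n.
#'
#' @param scores A `dnb_scores` tibble from [score_blocks()].
#' @param profiles Profile table carrying `subject_id` and `sex` (e.g.
#'   [cohort_profiles()]); omit to get a single `total` stratum.
#' @param by Grouping column: `"condition"` (intervention tables) or
#'   `"time_block"` (training tables).
#' @param modality Which modality to tabulate.
#' @return Tibble: `by` group, `parameter`, `sex`, `n`, `mean`, `sd`,
#'   `ci_lo`, `ci_hi`, `min`, `max`, `p_value`, `p_display`.
#' @export
render_summary <- function(scores, profiles = NULL, by = "condition",
                           modality = "visuospatial") {
  stopifnot(by %in% names(scores))
  mod <- modality
  whole <- tibble::as_tibble(scores) |>
    dplyr::filter(.data$modality == mod, .data$segment == "whole") |>
    dplyr::select(dplyr::all_of(c("subject_id", by, score_outcomes))) |>
    tidyr::pivot_longer(dplyr::all_of(score_outcomes),
                        names_to = "parameter", values_to = "value")
  deltas <- delta_scores(
    dplyr::filter(tibble::as_tibble(scores), .data$modality == mod)
  ) |>
    dplyr::mutate(parameter = paste0("delta_", .data$outcome)) |>
    dplyr::select(dplyr::all_of(c("subject_id", by, "parameter")),
                  value = "delta")
  long <- dplyr::bind_rows(whole, deltas)
  if (!is.null(profiles) && "sex" %in% names(profiles)) {
    long <- dplyr::left_join(long,
                             dplyr::select(profiles, "subject_id", "sex"),
                             by = "subject_id")
  } else {
    long$sex <- NA_character_
  }
  strata <- dplyr::bind_rows(
    dplyr::filter(long, !is.na(.data$sex)),
    dplyr::mutate(long, sex = "total")
  )
  out <- strata |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "parameter", "sex")))) |>
    dplyr::reframe(mean_ci_stats(.data$value)) |>
    dplyr::mutate(
      p_value = dplyr::if_else(
        startsWith(.data$parameter, "delta_") & .data$n >= 2 & .data$sd > 0,
        2 * stats::pt(-abs(.data$mean / (.data$sd / sqrt(.data$n))),
                      .data$n - 1),
        NA_real_
      ),
      p_display = format_p(.data$p_value)
    )
  param_levels <- c(
    "H", "delta_H", "F", "delta_F", "a_prime", "delta_a_prime",
    "b_double_prime", "wm", "delta_wm", "rt_mean", "delta_rt_mean", "rt_sd"
  )
  out |>
    dplyr::mutate(
      parameter = factor(.data$parameter, levels = param_levels),
      sex = factor(.data$sex, levels = c("female", "male", "total"))
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(by, "parameter", "sex"))))
}

pipeline_defaults <- function() {
  list(
    seed = 1,
    n_subjects = 31,
    conditions = c("silence", "pure_tone_240Hz", "BB_10Hz", "BB_16Hz",
                   "BB_40Hz"),
    n_trials = 145, n_back = 2, trial_duration = 3.330,
    max_targets = 40, lure_rate = 0.2,
    alphabet_vs = 9, alphabet_av = 11,
    rt_pool = "all",
    rank_outcome = "wm",
    covariates = c("sex", "age", "volume")
  )
}

#' Read a pipeline configuration
#'
#' Merges a YAML file or a named list over [pipeline_defaults()]; the
#' merged list, together with its `seed`, determines every pipeline output
#' byte-for-byte.
#'
#' @param config `NULL` (defaults), a path to a YAML file, or a named
#'   list of overrides.
#' @return The merged configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  cfg <- pipeline_defaults()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    stopifnot(is.list(config))
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown)) {
      stop("unknown config fields: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(config)] <- config
  }
  cfg
}

pipeline_design <- function(cfg) {
  cohort_design(
    n_subjects = cfg$n_subjects, conditions = cfg$conditions,
    spec_vs = block_spec(cfg$n_trials, cfg$n_back, cfg$trial_duration,
                         cfg$max_targets, cfg$lure_rate, cfg$alphabet_vs),
    spec_av = block_spec(cfg$n_trials, cfg$n_back, cfg$trial_duration,
                         cfg$max_targets, cfg$lure_rate, cfg$alphabet_av)
  )
}

#' Run the full simulate - score - analyze - report pipeline
#'
#' Simulates a cohort under the configuration, scores it, derives deltas,
#' discrepancies and ranks, runs the inferential battery (one-sample t on
#' deltas by condition and by time block, Friedman on the ranked
#' outcomes, repeated-measures ANCOVA of the condition effect per outcome,
#' and the dual-modality mixed model), and writes every artifact as CSV
#' plus a config copy and a run log. Identical configurations produce
#' identical output trees.
#'
#' @param config See [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("dualnback-"),
                         seed = NULL) {
  cfg <- pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  emit <- function(x, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(x, p)
    paths[[name]] <<- p
    p
  }

  paths$config <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, paths$config)
  say("stage=simulate seed=%d subjects=%d conditions=%d",
      cfg$seed, cfg$n_subjects, length(cfg$conditions))

  design <- pipeline_design(cfg)
  trials <- simulate_cohort(design, seed = cfg$seed)
  profiles <- cohort_profiles(trials)
  say("stage=simulate rows=%d", nrow(trials))
  emit(trials, "trial_log")
  emit(profiles, "profiles")

  say("stage=score rt_pool=%s", cfg$rt_pool)
  scores <- score_blocks(trials, rt_pool = cfg$rt_pool)
  emit(scores, "scores")
  emit(scores_long(scores), "scores_long")
  deltas <- delta_scores(scores)
  emit(deltas, "deltas")
  emit(discrepancy_scores(scores), "discrepancies")
  ranks <- purrr::map(score_outcomes, function(oc) {
    dplyr::mutate(rank_scores(scores, outcome = oc), outcome = oc,
                  .before = 1)
  }) |> dplyr::bind_rows()
  emit(ranks, "ranks")

  say("stage=analyze")
  emit(delta_t_tests(deltas, by = c("condition", "modality", "outcome")),
       "delta_tests_by_condition")
  emit(delta_t_tests(deltas, by = c("time_block", "modality", "outcome")),
       "delta_tests_by_time_block")

  whole <- dplyr::filter(tibble::as_tibble(scores), .data$segment == "whole")
  fri <- tidyr::expand_grid(
    modality = unique(whole$modality), outcome = score_outcomes
  ) |>
    purrr::pmap(function(modality, outcome) {
      rk <- rank_scores(scores, outcome = outcome)
      rk <- rk[rk$modality == modality & !is.na(rk$rank), ]
      res <- tryCatch(
        friedman_ranks(rk, value = "rank",
                       effect_label = paste(modality, outcome)),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(friedman_ranks(rk, value = "rank",
                                          effect_label = paste(modality,
                                                               outcome)))
        }
      )
      if (is.null(res)) return(NULL)
      dplyr::mutate(tidy(res), modality = modality, outcome = outcome,
                    .before = 1)
    }) |> dplyr::bind_rows()
  emit(fri, "friedman")

  covs <- intersect(cfg$covariates, names(profiles))
  whole_cov <- dplyr::left_join(
    whole, dplyr::select(profiles, dplyr::all_of(c("subject_id", covs))),
    by = "subject_id"
  )
  rma <- tidyr::expand_grid(
    modality = unique(whole$modality), outcome = score_outcomes
  ) |>
    purrr::pmap(function(modality, outcome) {
      d <- whole_cov[whole_cov$modality == modality, ]
      d$value <- d[[outcome]]
      if (any(is.na(d$value))) d <- d[stats::complete.cases(d$value), ]
      res <- tryCatch(
        suppressWarnings(rm_anova(d, value = "value", within = "condition",
                                  covariates = covs)),
        error = function(e) NULL
      )
      if (is.null(res)) return(NULL)
      dplyr::mutate(tidy(res), modality = modality, outcome = outcome,
                    .before = 1)
    }) |> dplyr::bind_rows()
  emit(rma, "rm_anova")

  mm <- purrr::map(score_outcomes, function(outcome) {
    d <- dplyr::left_join(
      whole,
      dplyr::select(profiles, dplyr::all_of(c("subject_id", covs))),
      by = "subject_id"
    )
    d$value <- d[[outcome]]
    d <- d[!is.na(d$value), ]
    res <- tryCatch(mixed_model(d, value = "value"),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::mutate(tidy(res), outcome = outcome,
                  singular = res$singular, .before = 1)
  }) |> dplyr::bind_rows()
  emit(mm, "mixed_model")

  say("stage=report")
  for (mod in unique(whole$modality)) {
    emit(render_summary(scores, profiles, by = "condition", modality = mod),
         paste0("summary_condition_", mod))
    emit(render_summary(scores, profiles, by = "time_block", modality = mod),
         paste0("summary_time_block_", mod))
  }

  paths$log <- file.path(out_dir, "log.txt")
  writeLines(log_lines, paths$log)
  invisible(paths)
}
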