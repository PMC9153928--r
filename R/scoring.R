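#' Tally a block's confusion counts, whole and by half
#'
#' Pure tallies of `is_target` by `responded` for one block of one
#' modality: hits, misses, false alarms and correct rejections, computed
#' for the whole block and for the first and second halves. The half split
#' is by trial index: trials `1..floor(n/2)` form the first half and the
#' remainder (including the odd middle trial, e.g. trials 73-145 of 145)
#' the second half.
#'
#' @param block Tibble with columns `trial`, `is_target`, `responded` for a
#'   single subject x block x modality.
#' @return Tibble with one row per segment (`whole`, `first_half`,
#'   `second_half`) and columns `n_targets`, `n_nontargets`, `hits`,
#'   `misses`, `false_alarms`, `correct_rejections`.
#' @export
tabulate_confusion <- function(block) {
  stopifnot(all(c("trial", "is_target", "responded") %in% names(block)))
  cut <- floor(max(block$trial) / 2)
  segs <- list(
    whole = block,
    first_half = block[block$trial <= cut, ],
    second_half = block[block$trial > cut, ]
  )
  purrr::imap(segs, function(b, nm) {
    tibble::tibble(
      segment = nm,
      n_targets = sum(b$is_target),
      n_nontargets = sum(!b$is_target),
      hits = sum(b$is_target & b$responded),
      misses = sum(b$is_target & !b$responded),
      false_alarms = sum(!b$is_target & b$responded),
      correct_rejections = sum(!b$is_target & !b$responded)
    )
  }) |> dplyr::bind_rows()
}

#' Hit and false-alarm rates from confusion counts
#'
#' `H = hits / n_targets`, `F = false_alarms / n_nontargets`. A zero
#' denominator yields `NA` (rates are flagged as missing, never
#' fabricated).
#'
#' @param counts Tibble with columns `hits`, `false_alarms`, `n_targets`,
#'   `n_nontargets` (e.g. from [tabulate_confusion()]).
#' @return `counts` with columns `H` and `F` appended.
#' @export
rates <- function(counts) {
  dplyr::mutate(
    counts,
    H = ifelse(.data$n_targets > 0, .data$hits / .data$n_targets, NA_real_),
    F = ifelse(.data$n_nontargets > 0,
               .data$false_alarms / .data$n_nontargets, NA_real_)
  )
}

#' Latency summary for a set of responded trials
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of the latencies; the
#' SD is the intrasubject response-time variability outcome. Fewer than
#' one latency gives a missing mean, fewer than two a missing SD.
#'
#' @param rt Numeric latencies (seconds) of the responded trials in a
#'   segment; `NA`s are dropped.
#' @return One-row tibble with `n_responses`, `rt_mean`, `rt_sd`.
#' @examples
#' rt_summary(c(1.2, 1.4, 1.6)) # mean 1.4, sd 0.2
#' @export
rt_summary <- function(rt) {
  rt <- rt[!is.na(rt)]
  tibble::tibble(
    n_responses = length(rt),
    rt_mean = if (length(rt) >= 1) mean(rt) else NA_real_,
    rt_sd = if (length(rt) >= 2) stats::sd(rt) else NA_real_
  )
}

#' Score a trial log into the seven block outcomes
#'
#' Groups the log by whatever design keys are present (`subject_id`,
#' `condition`, `time_block`, `modality`) and computes, per group and per
#' segment (whole block, first half, second half): confusion counts, hit
#' rate `H`, false-alarm rate `F`, sensitivity [a_prime()], response bias
#' [b_double_prime()], working-memory capacity [wm_capacity()], and the
#' latency mean and SD over responded trials.
#'
#' @param trials Trial-log tibble (see [simulate_cohort()] /
#'   [read_trial_log()]).
#' @param rt_pool Which responded trials feed the latency summaries:
#'   `"all"` (hits and false alarms, the default) or `"hits_only"`.
#' @return A tibble of class `dnb_scores`, one row per group x segment.
#' @export
score_blocks <- function(trials, rt_pool = c("all", "hits_only")) {
  rt_pool <- match.arg(rt_pool)
  keys <- intersect(c("subject_id", "condition", "time_block", "modality"),
                    names(trials))
  df <- tibble::as_tibble(trials) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(.second = .data$trial > floor(max(.data$trial) / 2)) |>
    dplyr::ungroup()
  seg <- dplyr::bind_rows(
    dplyr::mutate(df, segment = "whole"),
    dplyr::mutate(dplyr::filter(df, !.data$.second), segment = "first_half"),
    dplyr::mutate(dplyr::filter(df, .data$.second), segment = "second_half")
  )
  in_pool <- if (rt_pool == "all") {
    function(is_target, responded) responded
  } else {
    function(is_target, responded) responded & is_target
  }
  out <- seg |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "segment")))) |>
    dplyr::summarise(
      n_targets = sum(.data$is_target),
      n_nontargets = sum(!.data$is_target),
      hits = sum(.data$is_target & .data$responded),
      misses = sum(.data$is_target & !.data$responded),
      false_alarms = sum(!.data$is_target & .data$responded),
      correct_rejections = sum(!.data$is_target & !.data$responded),
      rt_mean = rt_summary(.data$rt[in_pool(.data$is_target,
                                            .data$responded)])$rt_mean,
      rt_sd = rt_summary(.data$rt[in_pool(.data$is_target,
                                          .data$responded)])$rt_sd,
      .groups = "drop"
    ) |>
    rates() |>
    dplyr::mutate(
      a_prime = ifelse(is.na(.data$H) | is.na(.data$F), NA_real_,
                       a_prime(.data$H, .data$F)),
      b_double_prime = ifelse(is.na(.data$H) | is.na(.data$F), NA_real_,
                              b_double_prime(.data$H, .data$F)),
      wm = ifelse(is.na(.data$H) | is.na(.data$F), NA_real_,
                  wm_capacity(.data$H, .data$F)),
      segment = factor(.data$segment,
                       levels = c("whole", "first_half", "second_half"))
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "segment"))))
  attr(out, "rt_pool") <- rt_pool
  class(out) <- c("dnb_scores", class(out))
  out
}

# outcomes that get half-block deltas (the five delta parameters)
delta_outcomes <- c("H", "F", "a_prime", "wm", "rt_mean")
# all seven block outcomes
score_outcomes <- c("H", "F", "a_prime", "b_double_prime", "wm",
                    "rt_mean", "rt_sd")

#' Half-block delta scores
#'
#' Second-half value minus first-half value for the five delta outcomes
#' (hit rate, false-alarm rate, A', working memory, latency mean). A
#' missing half propagates to a missing delta.
#'
#' @param scores A `dnb_scores` tibble from [score_blocks()].
#' @return Long tibble: design keys, `outcome`, `first_half`,
#'   `second_half`, `delta`.
#' @export
delta_scores <- function(scores) {
  keys <- intersect(c("subject_id", "condition", "time_block", "modality"),
                    names(scores))
  tibble::as_tibble(scores) |>
    dplyr::filter(.data$segment != "whole") |>
    dplyr::select(dplyr::all_of(c(keys, "segment", delta_outcomes))) |>
    tidyr::pivot_longer(dplyr::all_of(delta_outcomes),
                        names_to = "outcome", values_to = "value") |>
    tidyr::pivot_wider(names_from = "segment", values_from = "value") |>
    dplyr::mutate(delta = .data$second_half - .data$first_half)
}

#' Intermodality discrepancy scores
#'
#' Auditory-verbal value minus visuospatial value of the same-name
#' outcome; a positive discrepancy means the verbal parameter is larger.
#' Swapping the modality labels negates the result.
#'
#' @param scores A `dnb_scores` tibble containing both modalities.
#' @param segment Which segment to compare (default whole block).
#' @return Long tibble: design keys (without modality), `outcome`,
#'   `visuospatial`, `auditory_verbal`, `discrepancy`.
#' @export
discrepancy_scores <- function(scores, segment = "whole") {
  stopifnot("modality" %in% names(scores))
  keys <- intersect(c("subject_id", "condition", "time_block"),
                    names(scores))
  seg <- segment
  tibble::as_tibble(scores) |>
    dplyr::filter(.data$segment == seg) |>
    dplyr::select(dplyr::all_of(c(keys, "modality", score_outcomes))) |>
    tidyr::pivot_longer(dplyr::all_of(score_outcomes),
                        names_to = "outcome", values_to = "value") |>
    tidyr::pivot_wider(names_from = "modality", values_from = "value") |>
    dplyr::mutate(
      discrepancy = .data$auditory_verbal - .data$visuospatial
    )
}

#' Midrank values within one subject
#'
#' Average (mid-)ranks with rank 1 for the smallest value, so rank `k` is
#' the largest of `k` conditions; ties share the average of the ranks they
#' span. `NA`s stay `NA` and the remaining values are ranked on a reduced
#' range.
#'
#' @param values Numeric vector (one value per condition).
#' @return Numeric vector of ranks.
#' @examples
#' rank_within_subject(c(1.2, 1.5, 1.3, 1.7, 1.1)) # 2 4 3 5 1
#' @export
rank_within_subject <- function(values) {
  if (all(is.na(values))) {
    return(rep(NA_real_, length(values)))
  }
  rank(values, ties.method = "average", na.last = "keep")
}

#' Rank one outcome across the five conditions, per subject
#'
#' Converts each subject's five condition values of one outcome into ranks
#' 1..5 (midranks on ties), separately per modality. This is the input to
#' the Friedman comparison of the interventions.
#'
#' @param scores A `dnb_scores` tibble.
#' @param outcome One of `H`, `F`, `a_prime`, `b_double_prime`, `wm`,
#'   `rt_mean`, `rt_sd`.
#' @param segment Segment to rank (default whole block).
#' @return Tibble: `subject_id`, `modality`, `condition`, `value`, `rank`.
#' @export
rank_scores <- function(scores, outcome = "wm", segment = "whole") {
  stopifnot(outcome %in% score_outcomes,
            all(c("subject_id", "condition") %in% names(scores)))
  seg <- segment
  keys <- intersect(c("subject_id", "modality"), names(scores))
  tibble::as_tibble(scores) |>
    dplyr::filter(.data$segment == seg) |>
    dplyr::select(dplyr::all_of(c(keys, "condition")),
                  value = dplyr::all_of(outcome)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(rank = rank_within_subject(.data$value)) |>
    dplyr::ungroup()
}

#' Reshape scores to long format
#'
#' One row per (design keys, segment, outcome); the wide form from
#' [score_blocks()] and this long form round-trip losslessly.
#'
#' @param scores A `dnb_scores` tibble.
#' @return Long tibble with columns `outcome` and `value` replacing the
#'   seven outcome columns.
#' @export
scores_long <- function(scores) {
  keys <- intersect(c("subject_id", "condition", "time_block", "modality",
                      "segment"), names(scores))
  tibble::as_tibble(scores) |>
    dplyr::select(dplyr::all_of(c(keys, score_outcomes))) |>
    tidyr::pivot_longer(dplyr::all_of(score_outcomes),
                        names_to = "outcome", values_to = "value")
}
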