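#' Annotate a stimulus stream with target and lure flags
#'
#' Pure re-derivation of the trial classes from the stimulus codes alone:
#' trial `i` is a target when its stimulus equals the stimulus `n_back`
#' trials earlier, and a lure when it is not a target but repeats the
#' stimulus at one of the `lure_lags` (by default the lags adjacent to
#' `n_back`, i.e. 1 and 3 for a 2-back). Targets and lures are therefore
#' mutually exclusive, and no trial with fewer than `n_back` predecessors
#' can be a target.
#'
#' @param stimuli Integer vector of stimulus codes (0-based), one per trial.
#' @param n_back Matching lag.
#' @param lure_lags Lags whose non-target repeats count as lures.
#' @return A tibble with columns `trial` (1-based), `stimulus`,
#'   `is_target`, `is_lure`.
#' @examples
#' annotate_trials(c(3, 5, 3, 5, 3))       # targets at trials 3, 4, 5
#' annotate_trials(c(7, 7, 2))             # lag-1 lure at trial 2
#' @export
annotate_trials <- function(stimuli, n_back = 2,
                            lure_lags = c(n_back - 1, n_back + 1)) {
  stopifnot(length(stimuli) >= 1, n_back >= 1)
  lure_lags <- lure_lags[lure_lags >= 1]
  n <- length(stimuli)
  idx <- seq_len(n)
  is_target <- idx > n_back & stimuli == dplyr::lag(stimuli, n_back)
  is_target[is.na(is_target)] <- FALSE
  is_lure <- rep(FALSE, n)
  for (l in lure_lags) {
    rep_l <- idx > l & stimuli == dplyr::lag(stimuli, l)
    rep_l[is.na(rep_l)] <- FALSE
    is_lure <- is_lure | rep_l
  }
  is_lure <- is_lure & !is_target
  tibble::tibble(
    trial = idx, stimulus = as.integer(stimuli),
    is_target = is_target, is_lure = is_lure
  )
}

#' Generate one modality's pseudorandom n-back stimulus sequence
#'
#' Lays out a block in three trial classes. Exactly `target_count` targets
#' are placed uniformly at random among the eligible positions (trials with
#' at least `n_back` predecessors) and receive a copy of the stimulus
#' `n_back` back. `round(lure_rate * n_trials)` of the remaining trials
#' become lures: the stimulus is copied from lag `n_back - 1` or
#' `n_back + 1` (chosen at random among the lags that do not accidentally
#' create a target). All other trials draw uniformly from the alphabet
#' excluding any value that would create an unintended target or lure.
#'
#' Lure positions are assigned on the fly: at each eligible non-target
#' trial a lure is placed with probability `lures_left / slots_left`,
#' which makes the chosen positions a uniform random subset of the
#' eligible trials while letting the generator skip the rare positions
#' where every available lag would create an accidental target. A block
#' whose final slots cannot absorb an owed lure is discarded and redrawn
#' (bounded rejection sampling over whole blocks, so the emitted sequence
#' is a draw conditioned on satisfying all counts); if no satisfying
#' block is found within `max_attempts`, or a filler trial has no
#' admissible stimulus, a constraint-infeasibility error is raised naming
#' the offending trial.
#'
#' @param spec A [block_spec()].
#' @param target_count Number of target trials (defaults to the spec cap).
#' @param modality Label stored in the output (`"visuospatial"` or
#'   `"auditory_verbal"`).
#' @param seed Optional integer seed; when given, the sequence is a pure
#'   function of `(spec, target_count, seed)` and the caller's RNG state is
#'   left untouched.
#' @param max_attempts Bound on whole-block redraws before giving up.
#' @return A tibble of class `dnb_sequence` with columns `modality`,
#'   `trial`, `stimulus`, `is_target`, `is_lure`; the spec is attached as
#'   attribute `spec`.
#' @examples
#' s <- generate_sequence(block_spec(), seed = 1)
#' sum(s$is_target) # 40
#' sum(s$is_lure)   # 29 = round(0.2 * 145)
#' @export
generate_sequence <- function(spec = block_spec(),
                              target_count = spec$max_targets,
                              modality = "visuospatial", seed = NULL,
                              max_attempts = 100L) {
  stopifnot(inherits(spec, "dnb_block_spec"))
  if (target_count > spec$max_targets) {
    stop("target_count (", target_count, ") exceeds max_targets (",
         spec$max_targets, ")", call. = FALSE)
  }
  out <- NULL
  last_err <- NULL
  for (attempt in seq_len(max_attempts)) {
    attempt_seed <- if (is.null(seed)) NULL else derive_seed(seed, attempt)
    out <- with_seed_if(attempt_seed, tryCatch(
      sequence_core(spec, as.integer(target_count)),
      dnb_retry = function(e) NULL
    ))
    if (!is.null(out)) break
    last_err <- attempt
  }
  if (is.null(out)) {
    stop("infeasible constraint set: no satisfying block in ",
         max_attempts, " attempts", call. = FALSE)
  }
  out <- tibble::add_column(out, modality = modality, .before = 1)
  attr(out, "spec") <- spec
  class(out) <- c("dnb_sequence", class(out))
  out
}

# Single sequential pass over trials; assumes the RNG is already seeded.
sequence_core <- function(spec, target_count) {
  n <- spec$n_trials
  nb <- spec$n_back
  A <- spec$alphabet_size
  alphabet <- seq_len(A) - 1L

  eligible <- seq.int(nb + 1L, n)
  targets <- sort(sample(eligible, target_count))
  is_target <- logical(n)
  is_target[targets] <- TRUE

  n_lures <- round(spec$lure_rate * n)
  n_slots <- sum(!is_target[-1L]) # non-target trials with a predecessor
  if (n_lures > n_slots) {
    stop("infeasible constraint set: ", n_lures, " lures requested but only ",
         n_slots, " non-target trials available", call. = FALSE)
  }

  s <- integer(n)
  is_lure <- logical(n)
  lures_left <- n_lures
  slots_left <- n_slots

  for (i in seq_len(n)) {
    back_val <- if (i > nb) s[i - nb] else NA_integer_
    lags <- c(nb - 1L, nb + 1L)
    lags <- lags[lags >= 1L & i - lags >= 1L]
    lag_vals <- s[i - lags]

    if (is_target[i]) {
      s[i] <- back_val
      next
    }

    if (length(lags) > 0L && lures_left > 0L) {
      take <- stats::runif(1) < lures_left / slots_left
      slots_left <- slots_left - 1L
      if (take) {
        ok <- if (is.na(back_val)) {
          rep(TRUE, length(lag_vals))
        } else {
          lag_vals != back_val
        }
        if (any(ok)) {
          pick <- which(ok)
          pick <- pick[sample.int(length(pick), 1L)]
          s[i] <- lag_vals[pick]
          is_lure[i] <- TRUE
          lures_left <- lures_left - 1L
          next
        }
        # every lag would create an accidental target: skip this position,
        # the owed lure rolls over to the remaining slots
      }
    } else if (length(lags) > 0L) {
      slots_left <- slots_left - 1L
    }

    forbidden <- unique(c(back_val, lag_vals))
    allowed <- setdiff(alphabet, forbidden[!is.na(forbidden)])
    if (length(allowed) == 0L) {
      stop("infeasible constraint set at trial ", i,
           ": no stimulus avoids an unintended target or lure", call. = FALSE)
    }
    s[i] <- allowed[sample.int(length(allowed), 1L)]
  }

  if (lures_left > 0L) {
    # retryable: this draw boxed itself in; the caller redraws the block
    cond <- structure(
      class = c("dnb_retry", "error", "condition"),
      list(message = paste0("lure deficit of ", lures_left), call = NULL)
    )
    stop(cond)
  }

  tibble::tibble(
    trial = seq_len(n), stimulus = s,
    is_target = is_target, is_lure = is_lure
  )
}

#' Generate an aligned dual-modality block
#'
#' The two streams share trial onsets (identical `n_trials`) but are drawn
#' from distinct substreams of the seed, so their target placements are
#' independent: targets of both modalities may fall on the same trial.
#'
#' @param spec_vs,spec_av [block_spec()]s for the visuospatial and
#'   auditory-verbal streams; trial counts must match.
#' @param seed Integer seed for the block.
#' @param target_count_vs,target_count_av Per-modality target counts.
#' @return A tibble of class `dnb_dual_block`: both sequences stacked, with
#'   a `modality` column; the seed is attached as attribute `seed`.
#' @examples
#' b <- generate_dual_block(seed = 7)
#' table(b$modality)
#' @export
generate_dual_block <- function(spec_vs = block_spec(alphabet_size = 9),
                                spec_av = block_spec(alphabet_size = 11),
                                seed = NULL,
                                target_count_vs = spec_vs$max_targets,
                                target_count_av = spec_av$max_targets) {
  if (spec_vs$n_trials != spec_av$n_trials) {
    stop("design error: the two modalities must have identical n_trials (",
         spec_vs$n_trials, " vs ", spec_av$n_trials, ")", call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  vs <- generate_sequence(spec_vs, target_count_vs,
    modality = "visuospatial", seed = derive_seed(seed, 1L)
  )
  av <- generate_sequence(spec_av, target_count_av,
    modality = "auditory_verbal", seed = derive_seed(seed, 2L)
  )
  out <- dplyr::bind_rows(vs, av)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "spec_vs") <- spec_vs
  attr(out, "spec_av") <- spec_av
  class(out) <- c("dnb_dual_block", "tbl_df", "tbl", "data.frame")
  out
}

#' Export a stimulus sequence or dual block as CSV
#'
#' Writes columns `block`, `modality`, `trial` (1-based), `stimulus`,
#' `is_target`, `is_lure`.
#'
#' @param x A tibble from [generate_sequence()] or [generate_dual_block()].
#' @param path Output file path.
#' @param block Block index recorded in the `block` column.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(x, path, block = 1L) {
  out <- dplyr::mutate(tibble::as_tibble(x), block = as.integer(block)) |>
    dplyr::select("block", "modality", "trial", "stimulus",
                  "is_target", "is_lure")
  readr::write_csv(out, path)
  invisible(path)
}
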