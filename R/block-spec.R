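#' Block specification for one modality of a dual n-back task
#'
#' Bundles the structural parameters of a single 8-minute task block:
#' number of trials, n-back lag, trial duration, target cap, lure rate and
#' alphabet size. Defaults reproduce the study task: 145 trials of 3.330 s,
#' n = 2, at most 40 targets per modality and a lure rate of 0.2.
#'
#' @param n_trials Number of trials in the block.
#' @param n_back Matching lag: a trial is a target when its stimulus equals
#'   the stimulus `n_back` trials earlier.
#' @param trial_duration Trial duration in seconds (stimulus onset
#'   asynchrony); responses and simulated latencies live in
#'   `(0, trial_duration]`.
#' @param max_targets Upper bound on the number of target trials per block.
#' @param lure_rate Fraction of `n_trials` to lay out as lures (non-target
#'   repeats at lag `n_back - 1` or `n_back + 1`); the realized count is
#'   `round(lure_rate * n_trials)`.
#' @param alphabet_size Number of distinct stimulus codes (9 grid positions
#'   for the visuospatial stream; 11 spoken digits 0-10 for the
#'   auditory-verbal stream).
#'
#' @return A list of class `dnb_block_spec`.
#' @examples
#' block_spec()                      # visuospatial default
#' block_spec(alphabet_size = 11)    # auditory-verbal default
#' @export
block_spec <- function(n_trials = 145, n_back = 2, trial_duration = 3.330,
                       max_targets = 40, lure_rate = 0.2, alphabet_size = 9) {
  stopifnot(
    length(n_trials) == 1, n_trials >= n_back + 1,
    length(n_back) == 1, n_back >= 1,
    trial_duration > 0,
    max_targets >= 0, max_targets <= n_trials - n_back,
    lure_rate >= 0, lure_rate <= 1,
    alphabet_size >= 3
  )
  structure(
    list(
      n_trials = as.integer(n_trials),
      n_back = as.integer(n_back),
      trial_duration = trial_duration,
      max_targets = as.integer(max_targets),
      lure_rate = lure_rate,
      alphabet_size = as.integer(alphabet_size)
    ),
    class = "dnb_block_spec"
  )
}

#' Default per-modality block specifications
#'
#' @return Named list with elements `visuospatial` (alphabet of 9 grid
#'   positions) and `auditory_verbal` (alphabet of 11 digits).
#' @export
default_specs <- function() {
  list(
    visuospatial = block_spec(alphabet_size = 9),
    auditory_verbal = block_spec(alphabet_size = 11)
  )
}

#' @export
print.dnb_block_spec <- function(x, ...) {
  cat(sprintf(
    "<dnb_block_spec> %d trials, %d-back, %.3f s/trial, <=%d targets, lure rate %.2f, alphabet %d\n",
    x$n_trials, x$n_back, x$trial_duration, x$max_targets, x$lure_rate,
    x$alphabet_size
  ))
  invisible(x)
}
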