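# Independent brute-force oracles, deliberately written with plain loops so
# they share no code path with the package implementations they check.

# trial-class annotator: direct transcription of the definitions
oracle_annotate <- function(stimuli, n_back = 2, lure_lags = c(1, 3)) {
  n <- length(stimuli)
  is_target <- logical(n)
  is_lure <- logical(n)
  for (i in seq_len(n)) {
    if (i > n_back && stimuli[i] == stimuli[i - n_back]) {
      is_target[i] <- TRUE
    } else {
      for (l in lure_lags) {
        if (i > l && stimuli[i] == stimuli[i - l]) is_lure[i] <- TRUE
      }
    }
  }
  list(is_target = is_target, is_lure = is_lure)
}

# confusion recount over raw rows
oracle_confusion <- function(is_target, responded) {
  h <- m <- fa <- cr <- 0
  for (i in seq_along(is_target)) {
    if (is_target[i] && responded[i]) h <- h + 1
    if (is_target[i] && !responded[i]) m <- m + 1
    if (!is_target[i] && responded[i]) fa <- fa + 1
    if (!is_target[i] && !responded[i]) cr <- cr + 1
  }
  c(hits = h, misses = m, false_alarms = fa, correct_rejections = cr)
}

# midranks without rank(): sort-based with explicit tie averaging
oracle_midrank <- function(x) {
  n <- length(x)
  o <- order(x)
  sx <- x[o]
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && sx[j + 1] == sx[i]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# tie-corrected Friedman chi-square from first principles
oracle_friedman <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  r <- t(apply(m, 1, oracle_midrank))
  S <- sum((colSums(r) - n * (k + 1) / 2)^2)
  ties <- 0
  for (i in seq_len(n)) {
    for (t in table(r[i, ])) ties <- ties + t^3 - t
  }
  denom <- n * k * (k + 1) - ties / (k - 1)
  12 * S / denom
}

# a minimal trial tibble: explicit flags, every trial responded as given
make_block <- function(n = 145, target_at = integer(), respond_at = integer(),
                       rt = 1.5) {
  tibble::tibble(
    trial = seq_len(n),
    is_target = seq_len(n) %in% target_at,
    is_lure = FALSE,
    responded = seq_len(n) %in% respond_at,
    rt = ifelse(seq_len(n) %in% respond_at, rt, NA_real_)
  )
}

# a profile with fixed response probabilities and all dynamics switched off
flat_profile <- function(hit = 0.85, fa = 0.10) {
  pop <- default_population(
    hit_vs_mean = stats::qlogis(hit), hit_vs_sd = 0,
    hit_av_mean = stats::qlogis(hit), hit_av_sd = 0,
    fa_vs_mean = stats::qlogis(fa), fa_vs_sd = 0,
    fa_av_mean = stats::qlogis(fa), fa_av_sd = 0,
    lure_fa_logodds = 0, train_hit = 0, train_fa = 0,
    fatigue_hit_vs = 0, fatigue_hit_av = 0,
    fatigue_fa_vs = 0, fatigue_fa_av = 0,
    rt_loc_vs_sd = 0, rt_loc_av_sd = 0, rt_scale_sd = 0,
    rt_train = 0, rt_half = 0, age_rt_coeff = 0, volume_rt_coeff = 0,
    age_sd = 0, p_female = 1
  )
  sample_profiles(1, pop, seed = 1)
}
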