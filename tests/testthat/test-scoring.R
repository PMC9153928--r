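test_that("confusion tallies: perfect and silent responders", {
  blk <- make_block(145, target_at = 1:40 * 3, respond_at = 1:40 * 3)
  tc <- tabulate_confusion(blk)
  whole <- tc[tc$segment == "whole", ]
  expect_equal(whole$hits, 40)
  expect_equal(whole$misses, 0)
  expect_equal(whole$false_alarms, 0)
  expect_equal(whole$correct_rejections, 105)

  silent <- tabulate_confusion(make_block(145, target_at = c(5, 9)))
  expect_true(all(silent$hits == 0))
  expect_true(all(silent$false_alarms == 0))
})

test_that("confusion counts conserve and halves sum to the whole", {
  withr::local_seed(20)
  for (rep in 1:20) {
    blk <- tibble::tibble(
      trial = 1:145,
      is_target = stats::runif(145) < 0.3,
      is_lure = FALSE,
      responded = stats::runif(145) < 0.5,
      rt = stats::runif(145, 0.2, 3.3)
    )
    tc <- tabulate_confusion(blk)
    for (seg in c("whole", "first_half", "second_half")) {
      row <- tc[tc$segment == seg, ]
      expect_equal(row$hits + row$misses, row$n_targets)
      expect_equal(row$false_alarms + row$correct_rejections,
                   row$n_nontargets)
    }
    w <- tc[tc$segment == "whole", -1]
    hs <- tc[tc$segment != "whole", -1]
    expect_equal(as.numeric(w), as.numeric(colSums(hs)))
    # independent recount
    o <- oracle_confusion(blk$is_target, blk$responded)
    expect_equal(unname(o["hits"]), w$hits)
    expect_equal(unname(o["false_alarms"]), w$false_alarms)
    # the half split is trials 1-72 / 73-145
    fh <- tc[tc$segment == "first_half", ]
    expect_equal(fh$n_targets + fh$n_nontargets, 72)
  }
})

test_that("rates follow the integer-division definitions", {
  counts <- tibble::tibble(n_targets = 40, n_nontargets = 105,
                           hits = 34, false_alarms = 7)
  r <- rates(counts)
  expect_equal(r$H, 34 / 40)
  expect_equal(r$F, 7 / 105)
  zero <- rates(tibble::tibble(n_targets = 0, n_nontargets = 10,
                               hits = 0, false_alarms = 2))
  expect_true(is.na(zero$H))
  expect_equal(zero$F, 0.2)
})

test_that("A-prime matches its closed form and limit conventions", {
  expect_equal(a_prime(0.9, 0.1), 0.5 + (0.8 * 1.8) / (4 * 0.9 * 0.9))
  expect_equal(a_prime(0.5, 0.5), 0.5)
  expect_equal(a_prime(0, 0), 0.5)
  expect_equal(a_prime(1, 1), 0.5)
  expect_equal(a_prime(1, 0), 1)
  expect_error(a_prime(1.2, 0), "rates")
})

test_that("A-prime is antisymmetric and monotone in H above chance", {
  g <- seq(0.05, 0.95, by = 0.09)
  for (h in g) {
    for (f in g) {
      expect_equal(a_prime(h, f) + a_prime(f, h), 1)
    }
  }
  for (f in c(0.05, 0.2, 0.4)) {
    hs <- seq(f, 0.99, length.out = 20)
    vals <- a_prime(hs, f)
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("B-double-prime sign, bounds and undefined cells", {
  expect_equal(b_double_prime(0.8, 0.1), (0.16 - 0.09) / (0.16 + 0.09))
  expect_equal(b_double_prime(0.7, 0.3), 0) # F = 1 - H: neutral
  expect_true(is.na(b_double_prime(1, 0)))
  expect_true(is.na(b_double_prime(0, 1)))
  expect_true(is.na(b_double_prime(1, 1)))
  g <- seq(0.02, 0.98, by = 0.06)
  for (h in g) {
    for (f in g) {
      expect_lte(abs(b_double_prime(h, f)), 1)
    }
  }
})

test_that("working memory is 2(H - F), linear for groups; A-prime is not", {
  expect_equal(wm_capacity(0.887, 0.110), 1.554)
  expect_equal(wm_capacity(0.877, 0.118), 1.518)
  expect_equal(wm_capacity(0.3, 0.3), 0)
  h <- c(0.9, 0.6, 0.75, 0.82)
  f <- c(0.1, 0.4, 0.05, 0.3)
  expect_equal(mean(wm_capacity(h, f)), 2 * (mean(h) - mean(f)))
  # the analogous identity must fail for the nonlinear index
  expect_false(isTRUE(all.equal(mean(a_prime(h, f)),
                                a_prime(mean(h), mean(f)))))
})

test_that("latency summaries follow the n-1 conventions", {
  s <- rt_summary(c(1.2, 1.4, 1.6))
  expect_equal(s$rt_mean, 1.4)
  expect_equal(s$rt_sd, 0.2)
  one <- rt_summary(1.5)
  expect_equal(one$rt_mean, 1.5)
  expect_true(is.na(one$rt_sd))
  expect_true(is.na(rt_summary(numeric())$rt_mean))
  expect_equal(rt_summary(rep(1.3, 5))$rt_sd, 0)
})

test_that("score_blocks computes the seven outcomes per segment", {
  blk <- make_block(145, target_at = seq(3, 120, by = 3),
                    respond_at = c(seq(3, 120, by = 3), 7, 11))
  blk$subject_id <- "S01"
  blk$modality <- "visuospatial"
  sc <- score_blocks(blk)
  expect_equal(nrow(sc), 3)
  w <- sc[sc$segment == "whole", ]
  expect_equal(w$H, 1)
  expect_equal(w$F, 2 / (145 - 40))
  expect_equal(w$wm, 2 * (w$H - w$F))
  expect_equal(w$a_prime, a_prime(w$H, w$F))
  expect_equal(w$rt_mean, 1.5)
  expect_equal(w$rt_sd, 0)
})

test_that("rt_pool switch restricts latencies to hits", {
  blk <- make_block(20, target_at = c(5, 9), respond_at = c(5, 9, 12, 13))
  blk$rt[c(12, 13)] <- 3.0 # slow false alarms
  blk$rt[c(5, 9)] <- 1.0
  all_pool <- score_blocks(blk)
  hits_pool <- score_blocks(blk, rt_pool = "hits_only")
  expect_equal(all_pool$rt_mean[all_pool$segment == "whole"], 2.0)
  expect_equal(hits_pool$rt_mean[hits_pool$segment == "whole"], 1.0)
})

test_that("deltas are second minus first half and propagate missingness", {
  blk <- make_block(145, target_at = seq(3, 144, by = 3),
                    respond_at = seq(3, 144, by = 6))
  blk$subject_id <- "S01"
  sc <- score_blocks(blk)
  d <- delta_scores(sc)
  expect_setequal(unique(d$outcome), c("H", "F", "a_prime", "wm", "rt_mean"))
  expect_equal(d$delta, d$second_half - d$first_half)
  # identical halves give zero delta
  sym <- make_block(10, target_at = c(3, 8), respond_at = c(3, 8))
  sym$subject_id <- "S01"
  d0 <- delta_scores(score_blocks(sym))
  expect_true(all(d0$delta[d0$outcome %in% c("H", "F", "wm")] == 0))
})

test_that("discrepancies are verbal minus visuospatial and antisymmetric", {
  blk_vs <- make_block(20, target_at = c(5, 9), respond_at = c(5, 9))
  blk_av <- make_block(20, target_at = c(5, 9), respond_at = 5)
  blk_vs$modality <- "visuospatial"
  blk_av$modality <- "auditory_verbal"
  blk_vs$subject_id <- blk_av$subject_id <- "S01"
  sc <- score_blocks(dplyr::bind_rows(blk_vs, blk_av))
  d <- discrepancy_scores(sc)
  hrow <- d[d$outcome == "H", ]
  expect_equal(hrow$discrepancy, 0.5 - 1.0)
  # swapping the labels negates every defined discrepancy
  swapped <- sc
  swapped$modality <- ifelse(swapped$modality == "visuospatial",
                             "auditory_verbal", "visuospatial")
  d2 <- discrepancy_scores(swapped)
  expect_equal(d2$discrepancy, -d$discrepancy)
})

test_that("within-subject ranks are midranks over the conditions", {
  expect_equal(rank_within_subject(c(1.2, 1.5, 1.3, 1.7, 1.1)),
               c(2, 4, 3, 5, 1))
  expect_equal(rank_within_subject(c(2, 1, 1, 5, 4)),
               c(3, 1.5, 1.5, 5, 4))
  expect_true(all(is.na(rank_within_subject(c(NA, NA)))))
  withr::local_seed(31)
  for (rep in 1:25) {
    x <- round(stats::runif(5), 2)
    expect_equal(rank_within_subject(x), oracle_midrank(x))
  }
})

test_that("scores round-trip through the long format", {
  log <- simulate_cohort(cohort_design(n_subjects = 2), seed = 17)
  sc <- score_blocks(log)
  long <- scores_long(sc)
  expect_equal(nrow(long), nrow(sc) * 7)
  back <- tidyr::pivot_wider(long, names_from = "outcome",
                             values_from = "value")
  keys <- c("subject_id", "condition", "time_block", "modality", "segment")
  merged <- dplyr::left_join(back, tibble::as_tibble(sc),
                             by = keys, suffix = c("", ".orig"))
  for (oc in c("H", "F", "a_prime", "wm", "rt_mean", "rt_sd")) {
    expect_equal(merged[[oc]], merged[[paste0(oc, ".orig")]])
  }
})
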