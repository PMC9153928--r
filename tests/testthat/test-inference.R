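test_that("one-sample t agrees with t.test and round-trips summaries", {
  withr::local_seed(41)
  for (rep in 1:5) {
    x <- stats::rnorm(31, mean = 0.1, sd = 0.5)
    mine <- one_sample_t(x)
    ref <- stats::t.test(x, mu = 0)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p_value, ref$p.value)
    # summary route reproduces the raw route exactly
    summ <- one_sample_t(mean = mean(x), sd = stats::sd(x), n = length(x))
    expect_equal(summ$statistic, mine$statistic)
    expect_equal(summ$p_value, mine$p_value)
  }
})

test_that("one-sample t degenerate-dispersion conventions", {
  expect_equal(one_sample_t(mean = 0, sd = 0, n = 10)$p_value, 1)
  expect_equal(one_sample_t(mean = 0.2, sd = 0, n = 10)$p_value, 0)
  expect_equal(one_sample_t(mean = 5, sd = 2, n = 31, mu0 = 5)$statistic, 0)
  expect_error(one_sample_t(x = 1), "insufficient")
})

test_that("pearson test agrees with cor.test and handles edge cases", {
  withr::local_seed(43)
  x <- stats::rnorm(31)
  y <- 0.5 * x + stats::rnorm(31)
  mine <- pearson_test(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(mine$estimate, unname(ref$estimate))
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
  # collinear pairs: r = 1, p -> 0
  col <- pearson_test(1:10, 2 * (1:10) + 3)
  expect_equal(col$estimate, 1)
  expect_equal(col$p_value, 0)
  expect_error(pearson_test(rep(1, 10), stats::rnorm(10)), "constant")
})

test_that("friedman: maximal separation, ties, and brute-force agreement", {
  m <- matrix(rep(1:5, each = 10) + rep(seq(0, 0.9, 0.1), 5), nrow = 10)
  res <- friedman_ranks(m)
  expect_equal(res$statistic, 40)
  expect_lt(res$p_value, 5e-4)

  const <- matrix(3, nrow = 5, ncol = 5)
  res0 <- friedman_ranks(const)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  withr::local_seed(47)
  for (rep in 1:20) {
    mm <- matrix(sample(1:8, 12, replace = TRUE), nrow = 4, ncol = 3)
    expect_equal(friedman_ranks(mm)$statistic, oracle_friedman(mm))
  }
  # invariance under a strictly monotone per-row transform
  mm <- matrix(stats::rnorm(30), nrow = 6)
  expect_equal(friedman_ranks(exp(mm))$statistic,
               friedman_ranks(mm)$statistic)
})

test_that("friedman excludes incomplete subjects listwise", {
  d <- tidyr::expand_grid(subject_id = sprintf("S%d", 1:6),
                          condition = letters[1:5])
  withr::local_seed(48)
  d$value <- stats::rnorm(30)
  d$value[d$subject_id == "S6" & d$condition == "a"] <- NA
  expect_warning(res <- friedman_ranks(d), "listwise")
  expect_equal(res$n, 5)
})

test_that("bonferroni pairwise: count, cap, and monotonicity", {
  withr::local_seed(49)
  d <- tidyr::expand_grid(subject_id = sprintf("S%d", 1:12),
                          condition = letters[1:5])
  d$value <- stats::rnorm(60)
  out <- bonferroni_pairwise(d)
  expect_equal(nrow(out), 10) # k(k-1)/2 for k = 5
  expect_true(all(out$p_adj >= out$p_value))
  expect_true(all(out$p_adj <= 1))
  expect_equal(out$p_adj, pmin(1, 10 * out$p_value))
  expect_equal(unique(out$df), 11)
})

test_that("GG epsilon stays inside its bounds and is 1 at k = 2", {
  withr::local_seed(50)
  for (k in c(2, 3, 5)) {
    for (rep in 1:10) {
      x <- matrix(stats::rnorm(20 * k), ncol = k)
      e <- gg_epsilon(x)
      expect_gte(e, 1 / (k - 1) - 1e-10)
      expect_lte(e, 1 + 1e-10)
    }
  }
  x2 <- matrix(stats::rnorm(40), ncol = 2)
  expect_equal(gg_epsilon(x2), 1)
})

test_that("rm-ANOVA at two levels reduces to the paired t-test", {
  withr::local_seed(51)
  d <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:20),
                          condition = c("a", "b"))
  d$value <- stats::rnorm(40) + ifelse(d$condition == "b", 0.4, 0)
  res <- tidy(rm_anova(d, within = "condition"))
  wide <- tidyr::pivot_wider(d, names_from = condition,
                             values_from = value)
  tt <- stats::t.test(wide$a, wide$b, paired = TRUE)
  expect_equal(res$statistic[res$term == "condition"],
               unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res$p_value[res$term == "condition"], tt$p.value,
               tolerance = 1e-8)
})

test_that("rm-ANOVA epsilon matches gg_epsilon and is near 1 under
           compound symmetry", {
  withr::local_seed(52)
  n <- 200
  k <- 5
  subj <- stats::rnorm(n, sd = 1)
  y <- outer(subj, rep(1, k)) + matrix(stats::rnorm(n * k), n, k)
  d <- tidyr::expand_grid(subject_id = sprintf("S%03d", 1:n),
                          condition = letters[1:k])
  d$value <- as.vector(t(y))
  res <- tidy(suppressWarnings(rm_anova(d, within = "condition")))
  row <- res[res$term == "condition", ]
  expect_equal(row$gg_epsilon, gg_epsilon(y), tolerance = 1e-6)
  expect_gt(row$gg_epsilon, 0.9)
  expect_equal(row$p_gg, row$p_value, tolerance = 0.02)
})

test_that("rm-ANOVA handles constant responses and covariates", {
  d <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:10),
                          condition = letters[1:5])
  d$value <- 2
  res <- tidy(rm_anova(d, within = "condition"))
  expect_equal(res$p_reported[res$term == "condition"], 1)

  withr::local_seed(53)
  d$value <- stats::rnorm(50)
  covs <- tibble::tibble(subject_id = sprintf("S%02d", 1:10),
                         sex = rep(c("female", "male"), 5),
                         age = stats::runif(10, 20, 40))
  dc <- dplyr::left_join(d, covs, by = "subject_id")
  res2 <- tidy(suppressWarnings(rm_anova(dc, within = "condition",
                                         covariates = c("sex", "age"))))
  expect_true("condition" %in% res2$term)
  expect_true(all(is.finite(res2$p_value)))
})

test_that("mixed model recovers a pure modality offset", {
  withr::local_seed(54)
  n <- 60
  d <- tidyr::expand_grid(
    subject_id = sprintf("S%03d", 1:n),
    condition = c("silence", "pure_tone_240Hz", "BB_10Hz"),
    modality = c("visuospatial", "auditory_verbal")
  )
  subj_fx <- stats::rnorm(n, sd = 0.3)
  d$value <- subj_fx[match(d$subject_id, sprintf("S%03d", 1:n))] +
    0.5 * (d$modality == "auditory_verbal") + stats::rnorm(nrow(d), sd = 0.2)
  fit <- mixed_model(d)
  tab <- tidy(fit)
  expect_lt(tab$p_value[tab$term == "modality"], 1e-6)
  expect_gt(tab$p_value[tab$term == "condition"], 0.05)
  expect_gt(tab$p_value[tab$term == "condition:modality"], 0.05)
  # treatment coding: reference levels are silence / visuospatial
  cf <- tidy(fit, type = "coefficients")
  expect_true(any(grepl("modalityauditory_verbal", cf$term)))
  expect_false(any(grepl("silence|visuospatial", cf$term)))
  expect_lt(abs(unname(cf$estimate[cf$term == "modalityauditory_verbal"]) -
                  0.5), 0.1)
})

test_that("balanced two-condition mixed model equals the paired t-test", {
  withr::local_seed(55)
  n <- 25
  d <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:n),
                          condition = c("silence", "BB_10Hz"))
  d$value <- stats::rnorm(2 * n) + 0.3 * (d$condition == "BB_10Hz")
  fit <- mixed_model(d)
  wide <- tidyr::pivot_wider(d, names_from = condition,
                             values_from = value)
  tt <- stats::t.test(wide$silence, wide$BB_10Hz, paired = TRUE)
  chisq <- tidy(fit)$statistic[tidy(fit)$term == "condition"]
  expect_equal(chisq, unname(tt$statistic)^2, tolerance = 1e-6)
})

test_that("zero random-intercept variance reproduces OLS estimates", {
  withr::local_seed(56)
  d <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:30),
                          condition = c("silence", "BB_10Hz", "BB_16Hz"))
  noise <- stats::rnorm(nrow(d))
  # remove all between-subject variance so the intercept variance is 0
  d$value <- noise - stats::ave(noise, d$subject_id) +
    0.3 * (d$condition == "BB_10Hz")
  fit <- mixed_model(d)
  ols <- stats::lm(value ~ condition,
                   data = dplyr::mutate(d, condition = stats::relevel(
                     factor(condition), ref = "silence")))
  expect_equal(unname(lme4::fixef(fit$fit)), unname(stats::coef(ols)),
               tolerance = 1e-6)
  expect_true(glance(fit)$singular)
})

test_that("delta_t_tests matches per-group one_sample_t", {
  log <- simulate_cohort(cohort_design(n_subjects = 6), seed = 19)
  deltas <- delta_scores(score_blocks(log))
  tests <- delta_t_tests(deltas, by = c("modality", "outcome"))
  one <- deltas[deltas$modality == "visuospatial" & deltas$outcome == "H", ]
  ref <- one_sample_t(one$delta)
  row <- tests[tests$modality == "visuospatial" & tests$outcome == "H", ]
  expect_equal(row$statistic, ref$statistic)
  expect_equal(row$p_value, ref$p_value)
  expect_equal(row$n, 30) # 6 subjects x 5 blocks
})

test_that("p-value display and reporting bands follow the table convention", {
  expect_equal(format_p(c(0.0004, 0.0005, 0.02345, 0.9)),
               c("<0.0005", "0.001", "0.023", "0.900"))
  expect_equal(p_band(c(0.01, 0.07, 0.5, NA)),
               c("significant", "marginally significant", "nonsignificant",
                 NA))
})
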