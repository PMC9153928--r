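new_dnb_test <- function(method, statistic, df, p_value, estimate = NA_real_,
                         n = NA_integer_, effect_label = "",
                         adjustment = "none") {
  structure(
    list(
      method = method, statistic = statistic, df = df, p_value = p_value,
      estimate = estimate, n = n, effect_label = effect_label,
      adjustment = adjustment
    ),
    class = "dnb_test"
  )
}

#' @export
print.dnb_test <- function(x, ...) {
  df_txt <- paste(format(round(x$df, 2)), collapse = ", ")
  cat(sprintf("%s%s: statistic = %.4g, df = %s, p %s\n",
              x$method,
              if (nzchar(x$effect_label)) paste0(" [", x$effect_label, "]") else "",
              x$statistic, df_txt,
              if (x$p_value < 0.0005) "< 0.0005"
              else paste0("= ", sprintf("%.3f", x$p_value))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.dnb_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, effect = x$effect_label, estimate = x$estimate,
    statistic = x$statistic, df = x$df[1],
    df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
    p_value = x$p_value, adjustment = x$adjustment, n = x$n
  )
}

#' One-sample t-test, from raw values or summary statistics
#'
#' Tests `mean == mu0` with `t = (mean - mu0) / (sd / sqrt(n))` on
#' `n - 1` degrees of freedom, two-sided. Accepts either a raw vector `x`
#' or the summary triple `(mean, sd, n)`; both routes give identical
#' results for the summaries of the same data. This is the test applied to
#' the half-block delta outcomes against the constant 0.
#'
#' Degenerate dispersion follows the natural limit: `sd = 0` with
#' `mean != mu0` gives `p = 0`, `sd = 0` with `mean == mu0` gives `p = 1`.
#'
#' @param x Raw values (optional; `NA`s dropped).
#' @param mean,sd,n Summary statistics, used when `x` is `NULL`.
#' @param mu0 Null value (default 0).
#' @param effect_label Free-text label carried into the result.
#' @return A `dnb_test` (see [tidy()]).
#' @examples
#' one_sample_t(mean = -0.080, sd = 0.117, n = 31) # the delta-hit-rate test
#' @export
one_sample_t <- function(x = NULL, mean = NULL, sd = NULL, n = NULL,
                         mu0 = 0, effect_label = "") {
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) stop("insufficient data: need n >= 2 values", call. = FALSE)
    mean <- base::mean(x)
    sd <- stats::sd(x)
  }
  stopifnot(!is.null(mean), !is.null(sd), !is.null(n), n >= 2, sd >= 0)
  if (sd == 0) {
    t <- if (mean == mu0) 0 else Inf * sign(mean - mu0)
    p <- if (mean == mu0) 1 else 0
  } else {
    t <- (mean - mu0) / (sd / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1)
  }
  new_dnb_test("one-sample t", t, n - 1, p, estimate = mean, n = n,
               effect_label = effect_label)
}

#' Pearson correlation test, from paired vectors or from (r, n)
#'
#' Product-moment correlation with the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-sided. The summary form recomputes the p-value printed for a
#' reported coefficient.
#'
#' @param x,y Paired numeric vectors (pairwise-complete).
#' @param r,n Summary form: coefficient and sample size.
#' @param effect_label Free-text label carried into the result.
#' @return A `dnb_test` with `estimate` = r.
#' @examples
#' pearson_test(r = -0.586, n = 31)
#' @export
pearson_test <- function(x = NULL, y = NULL, r = NULL, n = NULL,
                         effect_label = "") {
  if (!is.null(x)) {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]
    y <- y[ok]
    n <- length(x)
    if (n < 3) stop("insufficient data: need n >= 3 pairs", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("undefined correlation: a vector is constant", call. = FALSE)
    }
    r <- stats::cor(x, y)
  }
  stopifnot(!is.null(r), !is.null(n), n >= 3, abs(r) <= 1)
  if (abs(r) == 1) {
    t <- Inf * sign(r)
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  new_dnb_test("Pearson correlation", t, n - 2, p, estimate = r, n = n,
               effect_label = effect_label)
}

# data -> subjects x conditions wide matrix, listwise-complete
rm_wide_matrix <- function(data, value, subject, condition) {
  wide <- tibble::as_tibble(data) |>
    dplyr::select(dplyr::all_of(c(subject, condition, value))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(condition),
                       values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide[[subject]])
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) excluded listwise (incomplete rows)",
            call. = FALSE)
    m <- m[complete, , drop = FALSE]
  }
  m
}

#' Friedman test across the within-subject conditions
#'
#' Rank-based comparison of k related samples: each subject's values are
#' midranked across the conditions and the tie-corrected chi-square
#' statistic is referred to `k - 1` degrees of freedom
#' (via [stats::friedman.test()]). Invariant to any strictly monotone
#' transform of each subject's values. Incomplete subjects are excluded
#' listwise with a warning.
#'
#' @param data Either a subjects x conditions numeric matrix, or a long
#'   tibble with the columns named below.
#' @param value,subject,condition Column names for the long form.
#' @param effect_label Free-text label carried into the result.
#' @return A `dnb_test` with the chi-square statistic.
#' @export
friedman_ranks <- function(data, value = "value", subject = "subject_id",
                           condition = "condition", effect_label = "") {
  m <- if (is.matrix(data)) {
    data[stats::complete.cases(data), , drop = FALSE]
  } else {
    rm_wide_matrix(data, value, subject, condition)
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  }
  if (all(apply(m, 1, function(r) length(unique(r)) == 1))) {
    # every subject fully tied: no information against the null
    return(new_dnb_test("Friedman", 0, ncol(m) - 1, 1, n = nrow(m),
                        effect_label = effect_label))
  }
  ft <- stats::friedman.test(m)
  new_dnb_test("Friedman", unname(ft$statistic), unname(ft$parameter),
               ft$p.value, n = nrow(m), effect_label = effect_label)
}

#' Bonferroni-adjusted pairwise paired comparisons
#'
#' One paired t-test per pair of conditions on the within-subject
#' differences; each raw p-value is multiplied by the number of
#' comparisons `m` (all `k(k-1)/2` pairs by default) and capped at 1. The
#' adjustment never decreases a p-value.
#'
#' @inheritParams friedman_ranks
#' @param m Number of comparisons used in the adjustment; defaults to the
#'   number of pairs emitted.
#' @return Tibble with one row per pair: `condition1`, `condition2`, mean
#'   difference `estimate`, `statistic`, `df`, `p_value` (raw), `p_adj`,
#'   `m`.
#' @export
bonferroni_pairwise <- function(data, value = "value",
                                subject = "subject_id",
                                condition = "condition", m = NULL) {
  mat <- if (is.matrix(data)) {
    data[stats::complete.cases(data), , drop = FALSE]
  } else {
    rm_wide_matrix(data, value, subject, condition)
  }
  k <- ncol(mat)
  pairs <- utils::combn(k, 2)
  if (is.null(m)) m <- ncol(pairs)
  out <- purrr::map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    d <- mat[, i1] - mat[, i2]
    tt <- stats::t.test(d)
    tibble::tibble(
      condition1 = colnames(mat)[i1], condition2 = colnames(mat)[i2],
      estimate = unname(tt$estimate), statistic = unname(tt$statistic),
      df = unname(tt$parameter), p_value = tt$p.value
    )
  }) |> dplyr::bind_rows()
  dplyr::mutate(out, p_adj = pmin(1, m * .data$p_value), m = m,
                adjustment = "bonferroni")
}

#' Greenhouse-Geisser epsilon from a repeated-measures sample
#'
#' Box's sphericity index estimated from the sample covariance matrix of
#' the k repeated measures:
#' `eps = tr(CSC)^2 / ((k - 1) * tr(CSC %*% CSC))` with `C` the centering
#' projection `I - J/k`. Always in `[1/(k-1), 1]`; the repeated-measures F
#' test's degrees of freedom are multiplied by it when sphericity is
#' rejected.
#'
#' @param x Either an n x k data matrix (rows = subjects) or, with
#'   `covariance = TRUE`, a k x k covariance matrix.
#' @param covariance Set `TRUE` when `x` is already a covariance matrix.
#' @return The scalar epsilon estimate.
#' @export
gg_epsilon <- function(x, covariance = FALSE) {
  S <- if (covariance) as.matrix(x) else stats::cov(as.matrix(x))
  k <- ncol(S)
  C <- diag(k) - matrix(1 / k, k, k)
  M <- C %*% S %*% C
  unname(sum(diag(M))^2 / ((k - 1) * sum(M * M)))
}

#' Repeated-measures ANOVA / ANCOVA with sphericity handling
#'
#' Fits the within-subject factorial by the multivariate regression route
#' and reports univariate F tests per within effect, Mauchly's sphericity
#' test, and Greenhouse-Geisser-corrected degrees of freedom and p-values
#' (the correction multiplies both df by the epsilon of [gg_epsilon()]).
#' The reported p (`p_reported`) uses the corrected value whenever
#' Mauchly's test rejects sphericity at 0.05, and the uncorrected one
#' otherwise. Numeric covariates are mean-centered and entered as
#' between-subject regressors (the ANCOVA path); factor covariates (e.g.
#' sex) enter as-is. Subjects with incomplete cells are excluded listwise
#' with a warning; severely unbalanced data should go to [mixed_model()]
#' instead.
#'
#' @param data Long tibble.
#' @param value Response column name.
#' @param subject Subject identifier column.
#' @param within Character vector of one or two within-subject factor
#'   columns (e.g. `"condition"`, or `c("condition", "modality")`).
#' @param covariates Optional character vector of subject-level covariate
#'   columns (constant within subject).
#' @return An object of class `dnb_rm_anova`; see `tidy()` for the
#'   per-effect table and `glance()` for fit-level counts.
#' @export
rm_anova <- function(data, value = "value", subject = "subject_id",
                     within = "condition", covariates = NULL) {
  stopifnot(length(within) %in% 1:2)
  data <- tibble::as_tibble(data)
  cell <- interaction(lapply(within, function(w) data[[w]]),
                      sep = ".", lex.order = TRUE)
  data$.cell <- as.character(cell)
  wide <- data |>
    dplyr::select(dplyr::all_of(c(subject, ".cell", value))) |>
    tidyr::pivot_wider(names_from = ".cell",
                       values_from = dplyr::all_of(value))
  Y <- as.matrix(wide[, -1, drop = FALSE])
  complete <- stats::complete.cases(Y)
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) excluded listwise (incomplete cells)",
            call. = FALSE)
    wide <- wide[complete, , drop = FALSE]
    Y <- Y[complete, , drop = FALSE]
  }
  if (nrow(Y) < 3) stop("too few complete subjects", call. = FALSE)

  idata <- unique(data[, within, drop = FALSE])
  idata <- idata[match(colnames(Y),
                       do.call(paste, c(idata[within], sep = "."))), ,
                 drop = FALSE]
  idata <- as.data.frame(lapply(idata, function(x) factor(x, unique(x))))
  idesign <- stats::reformulate(within)

  rhs <- "1"
  bdat <- data.frame(row.names = seq_len(nrow(Y)))
  if (!is.null(covariates)) {
    cov_tab <- data |>
      dplyr::distinct(dplyr::across(dplyr::all_of(c(subject, covariates))))
    cov_tab <- cov_tab[match(wide[[subject]], cov_tab[[subject]]), ,
                       drop = FALSE]
    for (cv in covariates) {
      v <- cov_tab[[cv]]
      bdat[[cv]] <- if (is.numeric(v)) v - mean(v) else factor(v)
    }
    rhs <- paste(covariates, collapse = " + ")
  }
  bdat$.Y <- Y

  if (all(abs(Y - mean(Y)) < 1e-12)) {
    # constant response: every within contrast is exactly zero
    terms <- attr(stats::terms(idesign), "term.labels")
    tab <- tibble::tibble(
      term = terms, statistic = 0,
      df1 = NA_real_, df2 = NA_real_, p_value = 1,
      mauchly_w = NA_real_, mauchly_p = NA_real_, gg_epsilon = NA_real_,
      df1_gg = NA_real_, df2_gg = NA_real_, p_gg = 1,
      sphericity_violated = FALSE, p_reported = 1
    )
    return(structure(list(table = tab, n_subjects = nrow(Y), fit = NULL),
                     class = "dnb_rm_anova"))
  }

  fit <- stats::lm(stats::reformulate(rhs, response = ".Y"), data = bdat)
  an <- car::Anova(fit, idata = idata, idesign = idesign, type = 3)
  s <- summary(an, multivariate = FALSE)

  uni <- s$univariate.tests
  terms <- setdiff(rownames(uni), "(Intercept)")
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments

  tab <- purrr::map(terms, function(tm) {
    w_p <- if (!is.null(sph) && tm %in% rownames(sph)) {
      c(sph[tm, "Test statistic"], sph[tm, "p-value"])
    } else {
      c(NA_real_, NA_real_)
    }
    eps <- if (!is.null(adj) && tm %in% rownames(adj)) {
      unname(adj[tm, "GG eps"])
    } else {
      NA_real_
    }
    f <- unname(uni[tm, "F value"])
    d1 <- unname(uni[tm, "num Df"])
    d2 <- unname(uni[tm, "den Df"])
    p <- unname(uni[tm, "Pr(>F)"])
    p_gg <- if (!is.na(eps)) {
      stats::pf(f, eps * d1, eps * d2, lower.tail = FALSE)
    } else {
      p
    }
    violated <- !is.na(w_p[2]) && w_p[2] < 0.05
    tibble::tibble(
      term = tm, statistic = f, df1 = d1, df2 = d2, p_value = p,
      mauchly_w = w_p[1], mauchly_p = w_p[2], gg_epsilon = eps,
      df1_gg = if (!is.na(eps)) eps * d1 else d1,
      df2_gg = if (!is.na(eps)) eps * d2 else d2,
      p_gg = p_gg, sphericity_violated = violated,
      p_reported = if (violated) p_gg else p
    )
  }) |> dplyr::bind_rows()

  structure(
    list(table = tab, n_subjects = nrow(Y), anova = an, fit = fit),
    class = "dnb_rm_anova"
  )
}

#' @export
tidy.dnb_rm_anova <- function(x, ...) x$table

#' @export
glance.dnb_rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_terms = nrow(x$table))
}

#' @export
print.dnb_rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$n_subjects, " subjects)\n", sep = "")
  print(as.data.frame(x$table[, c("term", "statistic", "df1", "df2",
                                  "gg_epsilon", "p_value", "p_reported")]),
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Random-intercept mixed model over both modalities
#'
#' Linear mixed model of one outcome with fixed effects condition,
#' modality, their interaction, and any of the covariates `sex`, `age`
#' (mean-centered) and `volume` present in the data, plus a subject-level
#' random intercept. Treatment coding with `silence` and `visuospatial` as
#' reference levels. Per-effect Wald chi-square tests come from
#' [car::Anova()] (type III). A singular random-effect fit is flagged, not
#' dropped.
#'
#' @param data Long tibble with one row per subject x condition x modality
#'   (x block) observation.
#' @param value Response column name.
#' @param subject Subject identifier column.
#' @param fixed Optional character vector of fixed-effect terms overriding
#'   the canonical set.
#' @return Object of class `dnb_mixed`; `tidy()` gives per-term Wald
#'   tests (`type = "terms"`, default) or fixed-effect coefficients
#'   (`type = "coefficients"`); `glance()` gives fit-level summaries
#'   including the singularity flag.
#' @export
mixed_model <- function(data, value = "value", subject = "subject_id",
                        fixed = NULL) {
  data <- tibble::as_tibble(data)
  if ("condition" %in% names(data)) {
    lev <- unique(data$condition)
    ref <- if ("silence" %in% lev) "silence" else lev[1]
    data$condition <- stats::relevel(factor(data$condition), ref = ref)
  }
  if ("modality" %in% names(data)) {
    lev <- unique(data$modality)
    ref <- if ("visuospatial" %in% lev) "visuospatial" else lev[1]
    data$modality <- stats::relevel(factor(data$modality), ref = ref)
  }
  if ("age" %in% names(data)) data$age <- data$age - mean(data$age)
  if (is.null(fixed)) {
    fixed <- c(
      if (all(c("condition", "modality") %in% names(data))) {
        "condition * modality"
      } else {
        intersect(c("condition", "modality"), names(data))
      },
      intersect(c("sex", "age", "volume"), names(data))
    )
  }
  fml <- stats::as.formula(paste(
    value, "~", paste(fixed, collapse = " + "), "+ (1 |", subject, ")"
  ))
  fit <- lme4::lmer(fml, data = data, REML = TRUE)
  singular <- lme4::isSingular(fit)
  wald <- car::Anova(fit, type = 3)
  terms <- setdiff(rownames(wald), "(Intercept)")
  tab <- tibble::tibble(
    term = terms,
    statistic = wald[terms, "Chisq"],
    df = wald[terms, "Df"],
    p_value = wald[terms, "Pr(>Chisq)"]
  )
  structure(
    list(table = tab, fit = fit, singular = singular, formula = fml),
    class = "dnb_mixed"
  )
}

#' @rdname mixed_model
#' @param x A `dnb_mixed` object.
#' @param type `"terms"` for Wald tests, `"coefficients"` for fixed-effect
#'   estimates.
#' @param ... Unused.
#' @export
tidy.dnb_mixed <- function(x, type = c("terms", "coefficients"), ...) {
  type <- match.arg(type)
  if (type == "terms") {
    return(x$table)
  }
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(cf), estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"], statistic = cf[, "t value"]
  )
}

#' @export
glance.dnb_mixed <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(
    nobs = stats::nobs(x$fit),
    n_subjects = lme4::ngrps(x$fit)[[1]],
    sigma = stats::sigma(x$fit),
    sd_intercept = vc$sdcor[vc$grp != "Residual"][1],
    singular = x$singular,
    logLik = as.numeric(stats::logLik(x$fit)),
    AIC = stats::AIC(x$fit)
  )
}

#' @export
print.dnb_mixed <- function(x, ...) {
  cat("Mixed model:", deparse(x$formula), "\n")
  if (x$singular) cat("note: singular random-effect fit\n")
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' One-sample t-tests of the delta outcomes against zero
#'
#' Applies [one_sample_t()] to each group of half-block deltas, one test
#' per combination of the grouping keys and outcome.
#'
#' @param deltas Output of [delta_scores()].
#' @param by Grouping columns (defaults to every design key present plus
#'   `outcome`).
#' @return Tibble: groups, `n`, `mean`, `sd`, `statistic`, `df`,
#'   `p_value`, `p_display`.
#' @export
delta_t_tests <- function(deltas, by = NULL) {
  if (is.null(by)) {
    by <- intersect(c("condition", "time_block", "modality", "outcome"),
                    names(deltas))
  }
  deltas |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = sum(!is.na(.data$delta)),
      mean = mean(.data$delta, na.rm = TRUE),
      sd = stats::sd(.data$delta, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      statistic = ifelse(.data$sd > 0,
                         .data$mean / (.data$sd / sqrt(.data$n)),
                         ifelse(.data$mean == 0, 0, Inf * sign(.data$mean))),
      df = .data$n - 1,
      p_value = ifelse(is.finite(.data$statistic),
                       2 * stats::pt(-abs(.data$statistic), .data$df),
                       0),
      p_display = format_p(.data$p_value)
    )
}

#' Display a p-value the way the summary tables print it
#'
#' Three decimals, with values below 0.0005 shown as `"<0.0005"`.
#' `p_band()` maps a p-value to the reporting band: significant below
#' 0.05, marginally significant in (0.05, 0.10), nonsignificant
#' otherwise (a label, never a decision rule).
#'
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.0005, "<0.0005", sprintf("%.3f", p)))
}

#' @rdname format_p
#' @export
p_band <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.05 ~ "significant",
    p < 0.10 ~ "marginally significant",
    TRUE ~ "nonsignificant"
  )
}
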