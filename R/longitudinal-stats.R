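#' Linear mixed-effects model for a longitudinal network metric
#'
#' Fits, by REML, the model
#' `y = b0 + b1*group + b2*age + b3*group*age + b_subject + e`
#' with a subject random intercept, to one network-by-metric slice of the
#' metric table. Group is coded 0 (control) / 1 (transgenic); age is in
#' months, uncentered by default (centering changes only the intercept and
#' group-term interpretation). Fixed-effect p-values use Satterthwaite
#' degrees of freedom by default (`df = "satterthwaite"`), which is better
#' calibrated at small cohort sizes; `df = "wald"` gives normal-approximation
#' p-values. Correlation responses should be Fisher-z transformed first
#' (`fisher_z = TRUE`).
#'
#' @param data tibble with columns `subject_id`, `group` (0/1), `age_months`
#'   and the response.
#' @param response name of the response column (e.g. `"amplitude"`,
#'   `"shape"`, `"pearson_r"`).
#' @param df p-value method: `"satterthwaite"` or `"wald"`.
#' @param center_age subtract the mean age before fitting.
#' @param fisher_z apply `atanh` to the response (for correlations).
#' @return An `rsn_lme` object; see [tidy.rsn_lme()] / [glance.rsn_lme()].
#' @export
fit_rsn_lme <- function(data, response = "amplitude",
                        df = c("satterthwaite", "wald"),
                        center_age = FALSE, fisher_z = FALSE) {
  df <- match.arg(df)
  stopifnot(all(c("subject_id", "group", "age_months", response) %in%
                  names(data)))
  d <- data.frame(
    y = data[[response]],
    group = as.numeric(data$group),
    age = as.numeric(data$age_months),
    subject = factor(data$subject_id)
  )
  d <- d[is.finite(d$y), , drop = FALSE]
  if (!all(d$group %in% c(0, 1))) stop("group must be coded 0/1")
  if (fisher_z) d$y <- atanh(pmin(pmax(d$y, -1 + 1e-12), 1 - 1e-12))
  if (center_age) d$age <- d$age - mean(d$age)
  tab <- table(d$subject)
  if (sum(tab >= 2) < 2) {
    stop("need at least 2 subjects with >= 2 observations each")
  }

  fit <- tryCatch(
    if (df == "satterthwaite") {
      lmerTest::lmer(y ~ group * age + (1 | subject), data = d, REML = TRUE)
    } else {
      lme4::lmer(y ~ group * age + (1 | subject), data = d, REML = TRUE)
    },
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop("mixed-model fit failed: ", conditionMessage(fit))
  }
  converged <- length(fit@optinfo$conv$lme4$messages) == 0
  singular <- lme4::isSingular(fit)

  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  if (df == "satterthwaite") {
    p <- sm[, "Pr(>|t|)"]
    dfs <- sm[, "df"]
  } else {
    z <- est / se
    p <- 2 * pnorm(-abs(z))
    dfs <- rep(Inf, length(est))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_subject <- sqrt(vc$vcov[vc$grp == "subject"])
  sigma_resid <- sqrt(vc$vcov[vc$grp == "Residual"])

  fixed <- tibble::tibble(
    term = c("(Intercept)", "group", "age", "group:age"),
    estimate = unname(est[c("(Intercept)", "group", "age", "group:age")]),
    std_error = unname(se[c("(Intercept)", "group", "age", "group:age")]),
    df = unname(dfs[c("(Intercept)", "group", "age", "group:age")]),
    p_value = unname(p[c("(Intercept)", "group", "age", "group:age")])
  )
  structure(
    list(response = response, fixed = fixed,
         sigma_subject = sigma_subject, sigma_resid = sigma_resid,
         n_obs = nrow(d), n_subjects = nlevels(droplevels(d$subject)),
         converged = converged, singular = singular,
         df_method = df, fisher_z = fisher_z, model = fit),
    class = "rsn_lme"
  )
}

#' @export
print.rsn_lme <- function(x, ...) {
  cat("<rsn_lme> response:", x$response, " n_obs:", x$n_obs,
      " subjects:", x$n_subjects, "\n")
  print(as.data.frame(x$fixed), row.names = FALSE, digits = 4)
  cat("sigma_subject:", signif(x$sigma_subject, 4),
      " sigma_resid:", signif(x$sigma_resid, 4),
      if (!x$converged) " [NOT CONVERGED]" else "",
      if (x$singular) " [singular RE]" else "", "\n")
  invisible(x)
}

#' Per-group age-only mixed models, gated on the interaction
#'
#' Follow-up analysis: only when the full model's group-by-age interaction is
#' significant (`p < alpha`) are the two groups refit separately with age as
#' the single fixed effect (subject random intercept retained).
#'
#' @inheritParams fit_rsn_lme
#' @param alpha interaction gate (default 0.05).
#' @return List with the full fit (`full`) and, when gated open, `by_group`
#'   (named list of per-group `rsn_lme_age` fits); otherwise `by_group` is
#'   `NULL`.
#' @export
fit_rsn_lme_by_group <- function(data, response = "amplitude",
                                 df = c("satterthwaite", "wald"),
                                 alpha = 0.05, fisher_z = FALSE) {
  df <- match.arg(df)
  full <- fit_rsn_lme(data, response, df = df, fisher_z = fisher_z)
  p_int <- full$fixed$p_value[full$fixed$term == "group:age"]
  by_group <- NULL
  if (is.finite(p_int) && p_int < alpha) {
    by_group <- lapply(split(data, data$group), function(dg) {
      fit_age_lme(dg, response, df = df, fisher_z = fisher_z)
    })
  }
  list(full = full, by_group = by_group, interaction_p = p_int)
}

# Age-only LME for one group's rows.
fit_age_lme <- function(data, response, df = "satterthwaite",
                        fisher_z = FALSE) {
  d <- data.frame(
    y = data[[response]],
    age = as.numeric(data$age_months),
    subject = factor(data$subject_id)
  )
  d <- d[is.finite(d$y), , drop = FALSE]
  if (fisher_z) d$y <- atanh(pmin(pmax(d$y, -1 + 1e-12), 1 - 1e-12))
  fit <- if (df == "satterthwaite") {
    lmerTest::lmer(y ~ age + (1 | subject), data = d, REML = TRUE)
  } else {
    lme4::lmer(y ~ age + (1 | subject), data = d, REML = TRUE)
  }
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  p <- if (df == "satterthwaite") sm[, "Pr(>|t|)"] else
    2 * pnorm(-abs(est / se))
  tibble::tibble(term = rownames(sm), estimate = unname(est),
                 std_error = unname(se), p_value = unname(p))
}

#' Kruskal-Wallis test between two (or more) samples
#'
#' Rank-based H with tie correction and a chi-square p-value
#' (`df = k - 1`), via [stats::kruskal.test()]. All-identical values yield
#' `H = 0`, `p = 1` with a flag.
#'
#' @param values numeric vector of metric values.
#' @param groups grouping vector (each level n >= 2).
#' @return Tibble: `H`, `p_raw`, `degenerate`.
#' @export
kruskal_group_test <- function(values, groups) {
  ok <- is.finite(values)
  values <- values[ok]; groups <- factor(groups[ok])
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  if (length(unique(values)) == 1) {
    return(tibble::tibble(H = 0, p_raw = 1, degenerate = TRUE))
  }
  kt <- kruskal.test(values, groups)
  tibble::tibble(H = unname(kt$statistic), p_raw = unname(kt$p.value),
                 degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone envelope of `p * m / rank`, capped at
#' 1), via [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

# Significance tier from an FDR-adjusted p-value.
significance_tier <- function(p_fdr, alpha = 0.05, tendency = 0.1) {
  dplyr::case_when(
    p_fdr < alpha ~ "significant",
    p_fdr < tendency ~ "tendency",
    TRUE ~ "none"
  )
}

#' Per-timepoint group comparisons with FDR-tiered significance
#'
#' For each network and metric, compares the two genotype groups at each
#' timepoint by a Kruskal-Wallis test, adjusts the per-timepoint p-values by
#' Benjamini-Hochberg within the chosen family, and assigns tiers:
#' `significant` if adjusted p < `alpha` (default 0.05), `tendency` if
#' < `tendency` (default 0.1), else `none`.
#'
#' @param metrics long metric table from [metric_table()].
#' @param metrics_cols metric columns to test.
#' @param family FDR family: `"network_metric"` corrects across timepoints
#'   within each network x metric (default, matching per-network
#'   presentation); `"all"` corrects across everything jointly.
#' @param alpha,tendency tier cut-offs on the adjusted p-value.
#' @return Tibble: `timepoint`, `network`, `metric`, `H`, `p_raw`, `p_fdr`,
#'   `tier`.
#' @export
timepoint_group_tests <- function(metrics,
                                  metrics_cols = c("amplitude", "shape"),
                                  family = c("network_metric", "all"),
                                  alpha = 0.05, tendency = 0.1) {
  family <- match.arg(family)
  long <- tidyr::pivot_longer(metrics, dplyr::all_of(metrics_cols),
                              names_to = "metric", values_to = "value")
  res <- long |>
    dplyr::group_by(.data$network, .data$metric, .data$timepoint) |>
    dplyr::group_modify(function(d, key) {
      kruskal_group_test(d$value, d$group)
    }) |>
    dplyr::ungroup()
  res <- if (family == "network_metric") {
    res |>
      dplyr::group_by(.data$network, .data$metric) |>
      dplyr::mutate(p_fdr = bh_adjust(.data$p_raw)) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(res, p_fdr = bh_adjust(.data$p_raw))
  }
  dplyr::mutate(res, tier = significance_tier(.data$p_fdr, alpha, tendency)) |>
    dplyr::select("timepoint", "network", "metric", "H", "p_raw", "p_fdr",
                  "tier")
}

#' Spearman correlations between network metrics and behaviour
#'
#' Within each group x timepoint x network stratum, rank-correlates the
#' metric (amplitude and/or shape) with each behavioural measure (trial
#' count, correct-response ratio), using average ranks for ties and a
#' two-sided p-value; correlations are flagged at p < 0.05 (uncorrected).
#' Strata with fewer than `min_n` matched subjects are skipped with a
#' warning.
#'
#' @param metrics long metric table from [metric_table()].
#' @param behavior behaviour table (`subject_id`, `timepoint`, `n_trials`,
#'   `correct_ratio`).
#' @param metrics_cols metric columns to correlate.
#' @param min_n minimum stratum size (default 4).
#' @param alpha flag threshold.
#' @return Tibble: `timepoint`, `group`, `network`, `metric`, `measure`,
#'   `n`, `spearman_rho`, `p_value`, `significant`.
#' @export
spearman_behavior <- function(metrics, behavior,
                              metrics_cols = c("amplitude", "shape"),
                              min_n = 4L, alpha = 0.05) {
  joined <- dplyr::inner_join(metrics, behavior,
                              by = c("subject_id", "timepoint"))
  long <- tidyr::pivot_longer(joined, dplyr::all_of(metrics_cols),
                              names_to = "metric", values_to = "value")
  long <- tidyr::pivot_longer(long, c("n_trials", "correct_ratio"),
                              names_to = "measure", values_to = "behavior")
  skipped <- 0L
  res <- long |>
    dplyr::group_by(.data$timepoint, .data$group, .data$network,
                    .data$metric, .data$measure) |>
    dplyr::group_modify(function(d, key) {
      ok <- is.finite(d$value) & is.finite(d$behavior)
      n <- sum(ok)
      if (n < min_n) {
        skipped <<- skipped + 1L
        return(tibble::tibble(n = n, spearman_rho = NA_real_,
                              p_value = NA_real_))
      }
      ct <- suppressWarnings(cor.test(d$value[ok], d$behavior[ok],
                                      method = "spearman"))
      tibble::tibble(n = n, spearman_rho = unname(ct$estimate),
                     p_value = unname(ct$p.value))
    }) |>
    dplyr::ungroup()
  if (skipped > 0) {
    warning(skipped, " stratum/strata below n = ", min_n, " skipped")
  }
  dplyr::mutate(res, significant = !is.na(.data$p_value) &
                  .data$p_value < alpha)
}

#' Fit LME models across networks and metrics
#'
#' Convenience layer over [fit_rsn_lme_by_group()]: one full model per
#' network x metric, with per-group age models where the interaction gate
#' opens, summarised in a single tidy table mirroring the conventional
#' presentation (model term estimates and p-values per network and metric).
#'
#' @param metrics long metric table.
#' @param metrics_cols responses to model.
#' @param df p-value method (see [fit_rsn_lme()]).
#' @param alpha interaction gate for per-group fits.
#' @return Tibble: `network`, `metric`, `model` ("all", "group0", "group1"),
#'   `term`, `estimate`, `std_error`, `p_value`, `n_obs`, `converged`.
#' @export
lme_table <- function(metrics, metrics_cols = c("amplitude", "shape"),
                      df = c("satterthwaite", "wald"), alpha = 0.05) {
  df <- match.arg(df)
  out <- list()
  empty <- tibble::tibble(network = character(0), metric = character(0),
                          model = character(0), term = character(0),
                          estimate = numeric(0), std_error = numeric(0),
                          p_value = numeric(0), n_obs = integer(0),
                          converged = logical(0))
  if (nrow(metrics) == 0) return(empty)
  for (net in unique(metrics$network)) {
    for (mc in metrics_cols) {
      d <- dplyr::filter(metrics, .data$network == net)
      fits <- fit_rsn_lme_by_group(d, mc, df = df, alpha = alpha)
      full <- fits$full
      out[[length(out) + 1L]] <- dplyr::mutate(
        full$fixed, network = net, metric = mc, model = "all",
        n_obs = full$n_obs, converged = full$converged
      )
      if (!is.null(fits$by_group)) {
        for (g in names(fits$by_group)) {
          out[[length(out) + 1L]] <- dplyr::mutate(
            fits$by_group[[g]], network = net, metric = mc,
            model = paste0("group", g), n_obs = NA_integer_,
            converged = NA
          )
        }
      }
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::select("network", "metric", "model", "term", "estimate",
                  "std_error", "p_value", "n_obs", "converged")
}
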