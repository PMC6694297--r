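test_that("the mixed model recovers exactly-generated fixed effects", {
  # noiseless identifiability: y built exactly from the model equation
  sizes <- matrix(3, 2, 4)
  ages <- matrix(rep(c(5, 9, 13, 17), each = 2), 2, 4)
  subj <- expand.grid(s = 1:3, g = 0:1, t = 1:4)
  d <- tibble::tibble(
    subject_id = paste0("S", subj$g, subj$s),
    group = subj$g,
    age_months = c(5, 9, 13, 17)[subj$t] + 0.1 * subj$s,
    amplitude = 1 + 0.5 * subj$g + 0.1 * (c(5, 9, 13, 17)[subj$t] +
                                            0.1 * subj$s) -
      0.2 * subj$g * (c(5, 9, 13, 17)[subj$t] + 0.1 * subj$s)
  )
  # zero-residual data trips lme4 convergence heuristics; estimates are exact
  fit <- suppressWarnings(suppressMessages(fit_rsn_lme(d, "amplitude")))
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  expect_equal(unname(est["(Intercept)"]), 1, tolerance = 1e-6)
  expect_equal(unname(est["group"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(est["age"]), 0.1, tolerance = 1e-6)
  expect_equal(unname(est["group:age"]), -0.2, tolerance = 1e-6)
})

test_that("interaction estimates are unbiased over seeded metric cohorts", {
  est <- vapply(1:40, function(i) {
    mt <- metric_cohort(2000 + i, b0 = 1, b1 = 0.1, b2 = 0.01, b3 = -0.03)
    f <- suppressMessages(fit_rsn_lme(mt, "amplitude"))
    f$fixed$estimate[f$fixed$term == "group:age"]
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - (-0.03)), 2 * mc_se + 1e-4)
})

test_that("per-group fits are gated on a significant interaction", {
  mt <- metric_cohort(77, b0 = 1, b1 = 0, b2 = 0.03, b3 = -0.06)
  res <- suppressMessages(fit_rsn_lme_by_group(mt, "amplitude"))
  expect_lt(res$interaction_p, 0.05)
  expect_named(res$by_group, c("0", "1"))
  slope0 <- res$by_group[["0"]]$estimate[res$by_group[["0"]]$term == "age"]
  slope1 <- res$by_group[["1"]]$estimate[res$by_group[["1"]]$term == "age"]
  expect_gt(slope0, 0)
  expect_lt(slope1, 0)

  # null interaction: gate stays closed
  mt0 <- metric_cohort(78, b0 = 1, b1 = 0, b2 = 0.01, b3 = 0)
  res0 <- suppressMessages(fit_rsn_lme_by_group(mt0, "amplitude"))
  if (res0$interaction_p >= 0.05) expect_null(res0$by_group)
})

test_that("glance and tidy expose the model summaries", {
  mt <- metric_cohort(79)
  f <- suppressMessages(fit_rsn_lme(mt, "amplitude"))
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "group", "age", "group:age"))
  gl <- glance(f)
  expect_equal(gl$n_obs, 84L)
  expect_gte(gl$sigma_subject, 0)
  expect_gte(gl$sigma_resid, 0)
})

test_that("Kruskal-Wallis H matches the hand-computed rank formula", {
  res <- kruskal_group_test(c(1, 2, 3, 4, 5, 6),
                            c("a", "a", "a", "b", "b", "b"))
  # 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7
  expect_equal(res$H, 27 / 7, tolerance = 1e-10)
  expect_equal(res$H, 3.857, tolerance = 1e-3)

  # label permutation invariance
  res2 <- kruskal_group_test(c(1, 2, 3, 4, 5, 6),
                             c("b", "b", "b", "a", "a", "a"))
  expect_equal(res2$H, res$H)

  # identical values: degenerate convention
  deg <- kruskal_group_test(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(deg$p_raw, 1)
  expect_true(deg$degenerate)
})

test_that("Kruskal-Wallis equals the enumeration oracle for all 3+3 splits", {
  # independent oracle: H computed from first principles (no ties, values
  # 1..6), enumerated over all 20 assignments
  vals <- 1:6
  combs <- utils::combn(6, 3)
  for (j in seq_len(ncol(combs))) {
    g <- rep("b", 6)
    g[combs[, j]] <- "a"
    ranks <- rank(vals)
    R_a <- sum(ranks[g == "a"])
    R_b <- sum(ranks[g == "b"])
    H_oracle <- 12 / (6 * 7) * (R_a^2 / 3 + R_b^2 / 3) - 3 * 7
    expect_equal(kruskal_group_test(vals, g)$H, H_oracle, tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the brute-force step-up on small grids", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))

  # brute-force oracle: p_(i) * m / i with monotone envelope from the top
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
    pmin(adj, 1)[order(o)]
  }
  set.seed(51)
  grid <- c(0.001, 0.005, 0.01, 0.04, 0.05, 0.2, 0.5, 0.9)
  for (len in 2:8) {
    for (rep in 1:20) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  }
})

test_that("significance tiers switch exactly at the 0.05 and 0.1 boundaries", {
  mk <- function(p_fdr) rsnlong:::significance_tier(p_fdr)
  expect_equal(mk(c(0.049999, 0.05, 0.099999, 0.1, 0.5)),
               c("significant", "tendency", "tendency", "none", "none"))
})

test_that("timepoint group tests correct within network x metric families", {
  des <- small_design(seed = 55, n_per_group = 5)
  mt <- dplyr::bind_rows(lapply(c("netA", "netB"), function(nw) {
    d <- metric_cohort(55 + match(nw, c("netA", "netB")),
                       b1 = ifelse(nw == "netA", 0.6, 0), b3 = 0)
    dplyr::mutate(d, network = nw, shape = .data$amplitude + 0.5)
  }))
  res <- timepoint_group_tests(mt)
  expect_setequal(unique(res$network), c("netA", "netB"))
  expect_true(all(res$p_fdr >= res$p_raw))
  # within each family the BH adjustment reproduces bh_adjust
  fam <- dplyr::filter(res, .data$network == "netA",
                       .data$metric == "amplitude")
  expect_equal(fam$p_fdr, bh_adjust(fam$p_raw))
  expect_true(all(res$tier %in% c("significant", "tendency", "none")))
})

test_that("spearman_behavior stratifies, flags, and respects antisymmetry", {
  des <- small_design(seed = 57, n_per_group = 6)
  tr <- ground_truth(des, networks = "n1",
                     cognition_coupling = c(n1 = 1),
                     cognition_noise_sd = 1e-6)
  co <- simulate_cohort(des, tr, images = FALSE)
  mt <- dplyr::inner_join(
    dplyr::select(co$cohort, "subject_id", "timepoint",
                  group = "group_code", "age_months"),
    dplyr::mutate(co$truth_amplitudes, network = .data$source),
    by = c("subject_id", "timepoint")
  )
  res <- spearman_behavior(mt, co$behavior, metrics_cols = "amplitude")
  trials <- dplyr::filter(res, .data$measure == "n_trials")
  expect_true(all(trials$spearman_rho > 0.9))
  expect_true(all(trials$significant))

  # reversing behaviour negates rho exactly
  beh_neg <- dplyr::mutate(co$behavior, n_trials = -.data$n_trials)
  res_neg <- spearman_behavior(mt, beh_neg, metrics_cols = "amplitude")
  j <- dplyr::inner_join(
    dplyr::filter(res, .data$measure == "n_trials"),
    dplyr::filter(res_neg, .data$measure == "n_trials"),
    by = c("timepoint", "group", "network", "metric", "measure")
  )
  expect_equal(j$spearman_rho.x, -j$spearman_rho.y, tolerance = 1e-12)

  # undersized strata are skipped with a warning
  mt_small <- dplyr::filter(mt, .data$subject_id %in%
                              unique(mt$subject_id)[1:3])
  expect_warning(
    spearman_behavior(mt_small, co$behavior, metrics_cols = "amplitude"),
    "skipped"
  )
})

test_that("null behaviour correlations flag at close to the nominal rate", {
  flags <- 0L; total <- 0L
  for (r in 1:150) {
    set.seed(6000 + r)
    amp <- rnorm(9)
    beh <- rnorm(9)
    ct <- suppressWarnings(cor.test(amp, beh, method = "spearman"))
    flags <- flags + (ct$p.value < 0.05)
    total <- total + 1L
  }
  expect_gte(flags / total, 0.01)
  expect_lte(flags / total, 0.10)
})

test_that("connectivity responses can be Fisher-z transformed before the fit", {
  mt <- metric_cohort(61, b1 = 0.2)
  mt$pearson_r <- tanh(mt$amplitude - 1)
  f <- suppressMessages(fit_rsn_lme(mt, "pearson_r", fisher_z = TRUE))
  expect_true(f$fisher_z)
  expect_equal(nrow(f$fixed), 4)
  expect_true(all(is.finite(f$fixed$estimate)))
})
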