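test_that("concatenation orders blocks by subject and round-trips bit-exactly", {
  des <- small_design(seed = 21, n_per_group = 1, n_tp = 1)
  tr <- ground_truth(des, networks = c("a", "b"))
  mats <- lapply(1:3, function(i) {
    m <- matrix(rnorm(sum(tr$mask) * 100), ncol = 100)
    volume_series(m, tr$mask, 2, sprintf("S%02d", i), "t1")
  })
  cc <- concatenate_cohort(mats, variance_normalize = FALSE)
  expect_equal(ncol(cc$mat), 300)
  expect_equal(cc$ranges$start, c(1L, 101L, 201L))
  expect_equal(cc$ranges$end, c(100L, 200L, 300L))
  for (i in 1:3) {
    expect_identical(concat_block(cc, i), mats[[i]]$mat)
  }
  one <- concatenate_cohort(mats[1], variance_normalize = FALSE)
  expect_identical(one$mat, mats[[1]]$mat)

  other_mask <- tr$mask
  other_mask[which(other_mask)[1]] <- FALSE
  bad <- volume_series(matrix(rnorm(sum(other_mask) * 100), ncol = 100),
                       other_mask, 2, "S99", "t1")
  expect_error(concatenate_cohort(c(mats, list(bad))), "mask mismatch.*S99")
})

test_that("ICA recovers planted super-Gaussian sources and is seed-deterministic", {
  ps <- planted_sources(V = 500, T = 200, K = 3, noise_sd = 0, seed = 7)
  cs <- reduce_and_ica(ps$X, 3, seed = 1)
  r <- abs(cor(t(cs$maps_z), t(ps$maps)))
  # greedy matching: best |r| per planted source
  expect_true(all(apply(r, 2, max) > 0.95))

  # single source limit
  ps1 <- planted_sources(V = 300, T = 120, K = 1, noise_sd = 0, seed = 3)
  cs1 <- reduce_and_ica(ps1$X + matrix(rnorm(300 * 120, sd = 1e-6), 300),
                        1, seed = 1)
  expect_gt(abs(cor(cs1$maps_z[1, ], ps1$maps[1, ])), 0.99)

  cs_again <- reduce_and_ica(ps$X, 3, seed = 1)
  expect_identical(cs$maps_z, cs_again$maps_z)
  expect_identical(cs$mixing, cs_again$mixing)
})

test_that("component maps are z-scored with non-negative skewness and ordered by energy", {
  ps <- planted_sources(V = 400, T = 150, K = 3, noise_sd = 0.3, seed = 9)
  cs <- reduce_and_ica(ps$X, 3, seed = 2)
  expect_equal(unname(rowMeans(cs$maps_z)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(cs$maps_z, 1, sd)), rep(1, 3), tolerance = 1e-10)
  sk <- apply(cs$maps_z, 1, function(v) mean((v - mean(v))^3) / sd(v)^3)
  expect_true(all(sk >= 0))
  energy <- colSums(cs$mixing^2)
  expect_true(all(diff(energy) <= 1e-8))
})

test_that("PCA subspace accounts for the variance implied by its eigenvalues", {
  ps <- planted_sources(V = 200, T = 80, K = 2, noise_sd = 0.5, seed = 13)
  cs <- reduce_and_ica(ps$X, 2, seed = 1)
  X <- ps$X - rowMeans(ps$X)
  ev_all <- eigen(tcrossprod(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(cs$var_explained, sum(ev_all[1:2]) / sum(ev_all),
               tolerance = 1e-6)
  # discarded variance equals the sum of dropped eigenvalues
  expect_equal((1 - cs$var_explained) * sum(ev_all),
               sum(ev_all[-(1:2)]), tolerance = 1e-6)
})

test_that("ICA is invariant to block order up to sign and permutation", {
  ps <- planted_sources(V = 400, T = 120, K = 3, noise_sd = 0.2, seed = 17)
  X <- ps$X
  perm <- c(61:120, 1:60)     # swap two temporal blocks
  cs1 <- reduce_and_ica(X, 3, seed = 5)
  cs2 <- reduce_and_ica(X[, perm], 3, seed = 5)
  r <- abs(cor(t(cs1$maps_z), t(cs2$maps_z)))
  expect_true(all(apply(r, 1, max) > 0.99))
})

test_that("requesting more components than the rank errors", {
  X <- matrix(rnorm(50 * 4), 50, 4) %*% matrix(rnorm(4 * 100), 4, 100)
  expect_error(reduce_and_ica(X, 10, seed = 1), "rank")
})

test_that("template matching labels by Dice with greedy assignment", {
  V <- 300
  maps <- matrix(0, 2, V)
  maps[1, 1:30] <- 5           # strong focal component
  maps[2, 101:130] <- 5
  maps <- t(apply(maps, 1, function(v) (v - mean(v)) / sd(v)))
  cs <- structure(list(maps_z = maps, mask = NULL,
                       mixing = matrix(0, 10, 2), order = 2),
                  class = "component_set")
  rownames(cs$maps_z) <- c("IC1", "IC2")
  templates <- list(alpha = seq_len(V) %in% 1:30,
                    beta = seq_len(V) %in% 101:130,
                    gamma = seq_len(V) %in% 201:230)
  lab <- match_templates(cs, templates, z_thresh = 2.3)
  expect_equal(lab$label, c("alpha", "beta"))
  expect_equal(lab$dice, c(1, 1))

  # disjoint component stays unlabeled
  cs2 <- cs
  cs2$maps_z[2, ] <- 0
  cs2$maps_z[2, 251:280] <- 5
  cs2$maps_z[2, ] <- (cs2$maps_z[2, ] - mean(cs2$maps_z[2, ])) /
    sd(cs2$maps_z[2, ])
  lab2 <- match_templates(cs2, templates["alpha"], z_thresh = 2.3)
  expect_equal(lab2$label, c("alpha", "unlabeled"))

  # an all-flat component is skipped with a warning
  cs3 <- cs
  cs3$maps_z[2, ] <- 0
  expect_warning(match_templates(cs3, templates, z_thresh = 2.3), "empty")
})

test_that("one label can take two components when allowed a quota", {
  V <- 300
  maps <- matrix(0, 2, V)
  maps[1, 1:30] <- 5
  maps[2, 21:50] <- 5          # overlaps the same template region
  maps <- t(apply(maps, 1, function(v) (v - mean(v)) / sd(v)))
  cs <- structure(list(maps_z = maps, mask = NULL,
                       mixing = matrix(0, 10, 2), order = 2),
                  class = "component_set")
  rownames(cs$maps_z) <- c("IC1", "IC2")
  templates <- list(somatosensorial = seq_len(V) %in% 1:50)
  lab1 <- match_templates(cs, templates, max_per_label = 1L)
  expect_equal(sum(lab1$label == "somatosensorial"), 1)
  lab2 <- match_templates(cs, templates,
                          max_per_label = c(somatosensorial = 2L))
  expect_equal(sum(lab2$label == "somatosensorial"), 2)
})
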